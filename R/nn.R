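## Minimal reverse-mode neural-network engine.
##
## Tensors are R arrays with dim (H, W, C, N); dense activations are N x D
## matrices. Convolutions are stride 1 (zero padding `pad`); spatial reduction
## is 2x2 max-pooling. The engine exists because the saliency machinery
## (Grad-CAM, guided backpropagation) needs access to intermediate activations
## and layer-wise gradients, which a black-box fit could not expose.

#' Rectified linear unit
#'
#' Elementwise `f(z) = z` for `z > 0` and `0` for `z <= 0` — the activation
#' used throughout the convolutional branches.
#'
#' @param z Numeric vector or array of finite values.
#' @return Object of the same shape with negative entries set to zero.
#' @examples
#' relu(c(-3, 0, 2))
#' @export
relu <- function(z) {
  if (!is.numeric(z)) stop("relu: input must be numeric", call. = FALSE)
  if (any(!is.finite(z))) stop("relu: non-finite input", call. = FALSE)
  pmax(z, 0)
}

#' Numerically stable softmax
#'
#' Maps a logit vector \eqn{R = (r_1, \dots, r_x)} to class probabilities
#' \eqn{\sigma(R)_i = e^{r_i} / \sum_j e^{r_j}}, computed after subtracting
#' the maximum logit so that arbitrarily large inputs cannot overflow.
#'
#' @param logits Numeric vector of length >= 2, all finite.
#' @return Numeric probability vector summing to 1.
#' @examples
#' softmax(c(0, log(2)))  # 1/3, 2/3
#' @export
softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) < 2)
    stop("softmax: need a numeric vector of length >= 2", call. = FALSE)
  if (any(!is.finite(logits)))
    stop("softmax: non-finite logits", call. = FALSE)
  e <- exp(logits - max(logits))
  e / sum(e)
}

## row-wise softmax for an N x K logit matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- layer constructors -------------------------------------------------

layer_conv <- function(out_ch, kernel = 3L, pad = 1L,
                       activation = c("relu", "linear", "sigmoid"),
                       name = NULL) {
  list(type = "conv", out_ch = as.integer(out_ch), kernel = as.integer(kernel),
       pad = as.integer(pad), activation = match.arg(activation), name = name)
}

layer_pool <- function(name = NULL) list(type = "pool", name = name)

layer_flatten <- function() list(type = "flatten", name = NULL)

layer_gap <- function(name = NULL) list(type = "gap", name = name)

layer_upsample <- function(name = NULL) list(type = "upsample", name = name)

layer_reshape <- function(shape, name = NULL)
  list(type = "reshape", shape = as.integer(shape), name = name)

layer_dense <- function(out_dim, activation = c("relu", "linear", "sigmoid"),
                        name = NULL) {
  list(type = "dense", out_dim = as.integer(out_dim),
       activation = match.arg(activation), name = name)
}

apply_activation <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

## local gradient of the activation given pre-activation output `a`
activation_grad <- function(d, a, activation, guided = FALSE) {
  switch(activation,
         relu = if (guided) d * (a > 0) * (d > 0) else d * (a > 0),
         sigmoid = d * a * (1 - a),
         linear = d)
}

## ---- network construction ----------------------------------------------

## input_shape: c(H, W, C) for image input, or a single integer for vectors
nn_network <- function(layers, input_shape) {
  net <- list(layers = layers, input_shape = input_shape)
  class(net) <- "edl_net"
  nn_infer_shapes(net)
}

## walks the layer list, records in/out shapes, validates chaining
nn_infer_shapes <- function(net) {
  shape <- net$input_shape
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    ly$in_shape <- shape
    shape <- switch(ly$type,
      conv = {
        if (length(shape) != 3L)
          stop("conv layer ", k, " expects an image input", call. = FALSE)
        ho <- shape[1L] + 2L * ly$pad - ly$kernel + 1L
        wo <- shape[2L] + 2L * ly$pad - ly$kernel + 1L
        if (ho < 1L || wo < 1L)
          stop("conv layer ", k, ": kernel does not fit input ",
               paste(shape, collapse = "x"), call. = FALSE)
        c(ho, wo, ly$out_ch)
      },
      pool = {
        if (shape[1L] %% 2L || shape[2L] %% 2L)
          stop("pool layer ", k, ": odd spatial size ",
               paste(shape[1:2], collapse = "x"), call. = FALSE)
        c(shape[1L] %/% 2L, shape[2L] %/% 2L, shape[3L])
      },
      flatten = prod(shape),
      gap = shape[3L],
      upsample = c(shape[1L] * 2L, shape[2L] * 2L, shape[3L]),
      reshape = {
        if (prod(shape) != prod(ly$shape))
          stop("reshape layer ", k, ": size mismatch", call. = FALSE)
        ly$shape
      },
      dense = {
        if (length(shape) != 1L)
          stop("dense layer ", k, " expects a flat input", call. = FALSE)
        ly$out_dim
      },
      stop("unknown layer type ", ly$type, call. = FALSE))
    ly$out_shape <- shape
    net$layers[[k]] <- ly
  }
  net$out_shape <- shape
  net
}

## He-style initialization, deterministic in `seed`
nn_init <- function(net, seed) {
  old <- mistate_push(seed)
  on.exit(mistate_pop(old))
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    if (ly$type == "conv") {
      fan_in <- ly$kernel^2 * ly$in_shape[3L]
      ly$W <- matrix(stats::rnorm(fan_in * ly$out_ch, sd = sqrt(2 / fan_in)),
                     fan_in, ly$out_ch)
      ly$b <- numeric(ly$out_ch)
      ly$vW <- ly$W * 0; ly$vb <- ly$b
    } else if (ly$type == "dense") {
      fan_in <- ly$in_shape
      ly$W <- matrix(stats::rnorm(fan_in * ly$out_dim, sd = sqrt(2 / fan_in)),
                     fan_in, ly$out_dim)
      ly$b <- numeric(ly$out_dim)
      ly$vW <- ly$W * 0; ly$vb <- ly$b
    }
    net$layers[[k]] <- ly
  }
  net
}

## Save/restore the RNG state so internal seeding does not disturb the caller.
mistate_push <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}

mistate_pop <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## ---- forward ------------------------------------------------------------

## x: (H,W,C,N) array or N x D matrix. Returns list(out, caches) when
## keep_cache, else just the output. caches[[k]] = list(x = input, out = output).
nn_forward <- function(net, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (k in seq_along(net$layers)) {
    ly <- net$layers[[k]]
    xin <- x
    x <- switch(ly$type,
      conv = {
        d <- dim(xin)
        cols <- im2col_cpp(xin, d[1L], d[2L], d[3L], d[4L],
                           ly$kernel, ly$kernel, ly$pad)
        z <- cols %*% ly$W
        z <- z + rep(ly$b, each = nrow(z))
        z <- apply_activation(z, ly$activation)
        os <- ly$out_shape
        dim(z) <- c(os[1L], os[2L], d[4L], os[3L])
        aperm(z, c(1L, 2L, 4L, 3L))
      },
      pool = {
        d <- dim(xin)
        mp <- maxpool_cpp(xin, d[1L], d[2L], d[3L], d[4L])
        out <- mp$out
        dim(out) <- c(d[1L] %/% 2L, d[2L] %/% 2L, d[3L], d[4L])
        attr(out, "argmax") <- mp$argmax
        out
      },
      flatten = {
        d <- dim(xin)
        t(matrix(xin, prod(d[1:3]), d[4L]))
      },
      gap = {
        d <- dim(xin)
        m <- .colMeans(xin, prod(d[1:2]), d[3L] * d[4L])
        t(matrix(m, d[3L], d[4L]))
      },
      upsample = {
        xin[rep(seq_len(dim(xin)[1L]), each = 2L),
            rep(seq_len(dim(xin)[2L]), each = 2L), , , drop = FALSE]
      },
      reshape = {
        n <- nrow(xin)
        z <- t(xin)                      # D x N
        dim(z) <- c(ly$shape, n)
        z
      },
      dense = {
        z <- xin %*% ly$W
        z <- z + rep(ly$b, each = nrow(z))
        apply_activation(z, ly$activation)
      })
    if (keep_cache) caches[[k]] <- list(x = xin, out = x)
  }
  if (keep_cache) list(out = x, caches = caches) else x
}

## ---- backward -----------------------------------------------------------

## dout: gradient w.r.t. the network output. Returns list(grads, dx) where
## grads[[k]] holds dW/db for parametric layers. `guided` switches every ReLU
## to the guided-backpropagation double gate. `stop_layer` (a layer name)
## truncates the pass and returns the gradient w.r.t. that layer's OUTPUT.
nn_backward <- function(net, caches, dout, guided = FALSE, stop_layer = NULL) {
  grads <- vector("list", length(net$layers))
  d <- dout
  for (k in rev(seq_along(net$layers))) {
    ly <- net$layers[[k]]
    if (!is.null(stop_layer) && identical(ly$name, stop_layer))
      return(list(grads = grads, dx = d, stopped = TRUE))
    cache <- caches[[k]]
    d <- switch(ly$type,
      conv = {
        a <- cache$out                   # (Ho,Wo,Cout,N)
        dz <- activation_grad(d, a, ly$activation, guided)
        os <- dim(a)
        dz <- aperm(dz, c(1L, 2L, 4L, 3L))      # (Ho,Wo,N,Cout)
        dim(dz) <- c(prod(os[c(1L, 2L, 4L)]), os[3L])
        din <- dim(cache$x)
        cols <- im2col_cpp(cache$x, din[1L], din[2L], din[3L], din[4L],
                           ly$kernel, ly$kernel, ly$pad)
        grads[[k]] <- list(dW = crossprod(cols, dz), db = colSums(dz))
        dcols <- tcrossprod(dz, ly$W)
        dx <- col2im_cpp(dcols, din[1L], din[2L], din[3L], din[4L],
                         ly$kernel, ly$kernel, ly$pad)
        dim(dx) <- din
        dx
      },
      pool = {
        dx <- maxpool_bwd_cpp(as.numeric(d), attr(cache$out, "argmax"),
                              length(cache$x))
        dim(dx) <- dim(cache$x)
        dx
      },
      flatten = {
        dx <- t(d)
        dim(dx) <- dim(cache$x)
        dx
      },
      gap = {
        din <- dim(cache$x)
        per <- t(d) / prod(din[1:2])     # C x N
        dx <- array(rep(as.numeric(per), each = prod(din[1:2])), dim = din)
        dx
      },
      upsample = {
        i <- seq(1L, dim(d)[1L], by = 2L)
        j <- seq(1L, dim(d)[2L], by = 2L)
        d[i, j, , , drop = FALSE] + d[i + 1L, j, , , drop = FALSE] +
          d[i, j + 1L, , , drop = FALSE] + d[i + 1L, j + 1L, , , drop = FALSE]
      },
      reshape = {
        n <- dim(d)[length(dim(d))]
        dim(d) <- c(length(d) %/% n, n)
        t(d)
      },
      dense = {
        dz <- activation_grad(d, cache$out, ly$activation, guided)
        grads[[k]] <- list(dW = crossprod(cache$x, dz), db = colSums(dz))
        dz %*% t(ly$W)
      })
  }
  list(grads = grads, dx = d, stopped = FALSE)
}

## Rescale a gradient set so its global L2 norm is at most `clip`; guards
## the deep stacks against the occasional exploding minibatch.
clip_grads <- function(grads, clip) {
  if (is.null(clip) || !is.finite(clip)) return(grads)
  sq <- 0
  for (g in grads)
    if (!is.null(g)) sq <- sq + sum(g$dW^2) + sum(g$db^2)
  nrm <- sqrt(sq)
  if (nrm <= clip) return(grads)
  s <- clip / nrm
  lapply(grads, function(g) {
    if (is.null(g)) return(NULL)
    list(dW = g$dW * s, db = g$db * s)
  })
}

## SGD with momentum; grads as returned by nn_backward
nn_sgd_step <- function(net, grads, lr, momentum = 0) {
  for (k in seq_along(net$layers)) {
    g <- grads[[k]]
    if (is.null(g)) next
    ly <- net$layers[[k]]
    ly$vW <- momentum * ly$vW - lr * g$dW
    ly$vb <- momentum * ly$vb - lr * g$db
    ly$W <- ly$W + ly$vW
    ly$b <- ly$b + ly$vb
    net$layers[[k]] <- ly
  }
  net
}

## index of a named layer
nn_layer_index <- function(net, name) {
  for (k in seq_along(net$layers))
    if (identical(net$layers[[k]]$name, name)) return(k)
  stop("unknown layer: ", name, call. = FALSE)
}

## cross-entropy loss + gradient for logit output (linear final dense)
ce_loss_grad <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  p[idx] <- p[idx] - 1
  list(loss = loss, dlogits = p / n)
}
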