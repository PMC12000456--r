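# Engine-level checks: activations, shapes, and exactness of the
# hand-written backward pass against numerical differentiation.

test_that("relu follows its two branches and is idempotent", {
  expect_equal(relu(2), 2)
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  set.seed(1)
  z <- rnorm(100)
  expect_equal(relu(relu(z)), relu(z))
  expect_true(all(relu(z) >= 0))
  expect_error(relu(c(1, NA)), "non-finite")
  expect_error(relu(c(1, Inf)), "non-finite")
})

test_that("softmax normalizes, shifts invariantly, and never overflows", {
  expect_equal(softmax(c(7, 7, 7, 7)), rep(0.25, 4))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3))
  expect_equal(softmax(c(1000, 1001)), softmax(c(0, 1)))
  expect_error(softmax(1), "length")
  expect_error(softmax(c(1, NaN)), "non-finite")
  set.seed(2)
  for (rep in 1:20) {
    v <- rnorm(sample(2:8, 1), sd = 5)
    p <- softmax(v)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0 & p < 1))
    expect_equal(softmax(v + 3.7), p, tolerance = 1e-9)
    i <- sample(length(v), 1)
    v2 <- v; v2[i] <- v2[i] + 0.5
    expect_gt(softmax(v2)[i], p[i])   # monotone in its own logit
  }
})

test_that("backward pass matches numerical gradients to 1e-7", {
  ns <- asNamespace("cystodl")
  layers <- list(ns$layer_conv(2L, 3L, 1L, "relu", "c1"), ns$layer_pool("p1"),
                 ns$layer_conv(3L, 3L, 0L, "relu", "c2"), ns$layer_flatten(),
                 ns$layer_dense(4L, "relu", "f1"),
                 ns$layer_dense(3L, "linear", "out"))
  net <- ns$nn_init(ns$nn_network(layers, c(6L, 6L, 3L)), 7L)
  set.seed(42)
  x <- array(runif(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  y <- c(1L, 3L)
  loss_of <- function(net) ns$ce_loss_grad(ns$nn_forward(net, x), y)$loss
  fw <- ns$nn_forward(net, x, keep_cache = TRUE)
  lg <- ns$ce_loss_grad(fw$out, y)
  bk <- ns$nn_backward(net, fw$caches, lg$dlogits)
  eps <- 1e-6
  for (k in seq_along(net$layers)) {
    if (is.null(bk$grads[[k]])) next
    W <- net$layers[[k]]$W
    for (t in sample(length(W), min(6, length(W)))) {
      np <- net; np$layers[[k]]$W[t] <- W[t] + eps
      nm <- net; nm$layers[[k]]$W[t] <- W[t] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(bk$grads[[k]]$dW[t], num, tolerance = 1e-7)
    }
  }
  # input gradient too
  for (t in sample(length(x), 8)) {
    xp <- x; xp[t] <- x[t] + eps
    xm <- x; xm[t] <- x[t] - eps
    num <- (ns$ce_loss_grad(ns$nn_forward(net, xp), y)$loss -
              ns$ce_loss_grad(ns$nn_forward(net, xm), y)$loss) / (2 * eps)
    expect_equal(bk$dx[t], num, tolerance = 1e-7)
  }
})

test_that("generator-style layers (reshape, upsample, sigmoid) backprop exactly", {
  ns <- asNamespace("cystodl")
  layers <- list(ns$layer_dense(2L * 2L * 3L, "relu", "g1"),
                 ns$layer_reshape(c(2L, 2L, 3L)), ns$layer_upsample(),
                 ns$layer_conv(3L, 3L, 1L, "sigmoid", "go"))
  G <- ns$nn_init(ns$nn_network(layers, 5L), 3L)
  set.seed(8)
  z <- matrix(runif(10), 2)
  fw <- ns$nn_forward(G, z, keep_cache = TRUE)
  target <- array(runif(length(fw$out)), dim(fw$out))
  loss_of <- function(G) sum((ns$nn_forward(G, z) - target)^2) / 2
  bk <- ns$nn_backward(G, fw$caches, fw$out - target)
  eps <- 1e-6
  for (k in seq_along(G$layers)) {
    if (is.null(bk$grads[[k]])) next
    W <- G$layers[[k]]$W
    for (t in sample(length(W), min(5, length(W)))) {
      gp <- G; gp$layers[[k]]$W[t] <- W[t] + eps
      gm <- G; gm$layers[[k]]$W[t] <- W[t] - eps
      expect_equal(bk$grads[[k]]$dW[t], (loss_of(gp) - loss_of(gm)) / (2 * eps),
                   tolerance = 1e-7)
    }
  }
})

test_that("shape inference validates chains and pooling parity", {
  ns <- asNamespace("cystodl")
  expect_error(ns$nn_network(list(ns$layer_conv(4L, 5L, 0L), ns$layer_pool()),
                             c(7L, 7L, 3L)), "odd spatial")
  expect_error(ns$nn_network(list(ns$layer_conv(4L, 9L, 0L)), c(6L, 6L, 3L)),
               "does not fit")
  expect_error(ns$nn_network(list(ns$layer_dense(3L)), c(6L, 6L, 3L)),
               "flat input")
})

test_that("align-corners bilinear resize matches a direct R oracle", {
  oracle_resize <- function(m, ho, wo) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, ho, wo)
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      y <- (i - 1) * (h - 1) / max(ho - 1, 1)
      x <- (j - 1) * (w - 1) / max(wo - 1, 1)
      y0 <- floor(y); x0 <- floor(x)
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      fy <- y - y0; fx <- x - x0
      out[i, j] <- (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
        fy * (1 - fx) * m[y1 + 1, x0 + 1] +
        (1 - fy) * fx * m[y0 + 1, x1 + 1] + fy * fx * m[y1 + 1, x1 + 1]
    }
    out
  }
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(runif(30), 5, 6)
    for (target in list(c(9L, 4L), c(3L, 11L), c(5L, 6L))) {
      got <- resize_image(m, target)
      expect_equal(got, oracle_resize(m, target[1L], target[2L]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(resize_image(matrix(0.3, 4, 4), c(7L, 7L)),
               matrix(0.3, 7, 7), tolerance = 1e-12)
})
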