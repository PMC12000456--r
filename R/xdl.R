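## Explainable ensemble member: a VGG16-shaped backbone with a global
## average pooling head, plus the saliency machinery that makes it
## explainable and drives its training-time augmentation:
##   Grad-CAM      w_k^c = (1/Z) sum_ij d y^c / d A^k_ij   (Z = W*H)
##                 map   = ReLU(sum_k w_k^c A^k)
##   Guided backprop: input gradient with double-gated ReLUs (gradient passes
##                 only where forward activation > 0 AND gradient > 0)
##   Guided Grad-CAM: elementwise product of the bilinearly upsampled
##                 Grad-CAM map and the guided-backprop map.
## y^c is the pre-softmax class score; gradients of the probability would be
## scaled by p_c(1 - p_c) without changing the map's support.

VGG_BLOCKS <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                   c(512L, 512L, 512L), c(512L, 512L, 512L))

#' VGG-shaped architecture specification
#'
#' Thirteen 3x3 same-padding convolutions in five blocks with 2x2 max-pooling
#' (channel widths 64..512 scaled by `width_multiplier`), followed by global
#' average pooling and a linear classification head. At the default
#' multiplier 1 and 224x224 input the spatial chain is
#' 224 -> 112 -> 56 -> 28 -> 14 -> 7.
#'
#' @param input_size `c(H, W)`; both must be at least 32 (five poolings).
#' @param width_multiplier Channel scale in (0, 1].
#' @param n_classes Number of output classes.
#' @return An `edl_arch`.
#' @export
vgg_arch <- function(input_size = c(224L, 224L), width_multiplier = 1,
                     n_classes = 4L) {
  if (min(input_size) < 32L)
    stop("input too small for 5 pooling stages (need >= 32)", call. = FALSE)
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]", call. = FALSE)
  layers <- list()
  for (b in seq_along(VGG_BLOCKS)) {
    ch <- pmax(1L, as.integer(round(VGG_BLOCKS[[b]] * width_multiplier)))
    for (i in seq_along(ch))
      layers <- c(layers, list(layer_conv(ch[i], kernel = 3L, pad = 1L,
                                          activation = "relu",
                                          name = sprintf("conv%d_%d", b, i))))
    layers <- c(layers, list(layer_pool(name = paste0("pool", b))))
  }
  layers <- c(layers, list(layer_gap(name = "gap"),
                           layer_dense(n_classes, activation = "linear",
                                       name = "logits")))
  net <- nn_network(layers, c(as.integer(input_size), 3L))
  structure(list(layers = layers, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), table = arch_table(net)),
            class = "edl_arch")
}

#' Build the untrained explainable backbone
#'
#' @inheritParams vgg_arch
#' @param seed Integer seed for deterministic initialization.
#' @return An `edl_model`.
#' @export
build_backbone <- function(input_size = c(224L, 224L), width_multiplier = 1,
                           n_classes = 4L, seed = 1L) {
  arch <- vgg_arch(input_size, width_multiplier, n_classes)
  net <- nn_init(nn_network(arch$layers, c(arch$input_size, 3L)), seed)
  structure(list(net = net, input_size = arch$input_size,
                 n_classes = arch$n_classes, arch = arch, seed = seed),
            class = "edl_model")
}

#' Global average pooling
#'
#' Reduces each feature map to its spatial mean.
#'
#' @param maps H x W x K array (or H x W matrix for K = 1).
#' @return Length-K numeric vector of spatial means.
#' @export
global_average_pool <- function(maps) {
  if (is.matrix(maps)) return(mean(maps))
  d <- dim(maps)
  as.numeric(.colMeans(maps, prod(d[1:2]), d[3L]))
}

get_net <- function(model) {
  if (inherits(model, c("edl_model", "edl_classifier"))) model$net
  else if (inherits(model, "edl_net")) model
  else stop("expected an edl model, classifier or network", call. = FALSE)
}

last_conv_layer <- function(net) {
  conv <- vapply(net$layers, function(l) identical(l$type, "conv"), TRUE)
  if (!any(conv)) stop("network has no convolutional layer", call. = FALSE)
  net$layers[[max(which(conv))]]$name
}

new_heatmap <- function(kind, values, class_c = NULL, layer = NULL,
                        n_classes = NULL) {
  structure(list(kind = kind, values = values, class_c = class_c,
                 layer = layer, n_classes = n_classes),
            class = "edl_heatmap")
}

#' @export
print.edl_heatmap <- function(x, ...) {
  cat(sprintf("<edl_heatmap %s> %dx%d, range [%.4g, %.4g]",
              x$kind, nrow(x$values), ncol(x$values), min(x$values),
              max(x$values)))
  if (!is.null(x$class_c)) cat("  class", x$class_c)
  cat("\n")
  invisible(x)
}

#' @export
plot.edl_heatmap <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, main = x$kind, ...)
  invisible(x)
}

## onehot rows for a vector of 1-based class indices
onehot_rows <- function(classes, n_classes) {
  m <- matrix(0, length(classes), n_classes)
  m[cbind(seq_along(classes), classes)] <- 1
  m
}

## batched Grad-CAM: caches from nn_forward(keep_cache = TRUE); returns
## (Hf, Wf, N) array of non-negative maps at feature resolution
grad_cam_maps <- function(net, caches, classes, layer_name) {
  k <- nn_layer_index(net, layer_name)
  n_classes <- net$out_shape
  dl <- onehot_rows(classes, n_classes)
  bk <- nn_backward(net, caches, dl, stop_layer = layer_name)
  if (!bk$stopped) stop("layer ", layer_name, " not reached", call. = FALSE)
  dA <- bk$dx                                  # (Hf, Wf, K, N)
  A <- caches[[k]]$out
  d <- dim(A)
  w <- .colMeans(dA, prod(d[1:2]), d[3L] * d[4L])  # spatial mean per (k, n)
  wA <- as.numeric(A) * rep(w, each = prod(d[1:2]))
  dim(wA) <- d
  maps <- colSums(aperm(wA, c(3L, 1L, 2L, 4L)), dims = 1L)  # sum over k
  pmax(maps, 0)
}

## batched guided backprop: returns (H, W, N) non-negative single-channel maps
guided_backprop_maps <- function(net, caches, classes) {
  n_classes <- net$out_shape
  dl <- onehot_rows(classes, n_classes)
  dx <- nn_backward(net, caches, dl, guided = TRUE)$dx  # (H, W, 3, N)
  dx <- pmax(dx, 0)
  d <- dim(dx)
  m <- pmax(pmax(dx[, , 1L, , drop = FALSE], dx[, , 2L, , drop = FALSE]),
            dx[, , 3L, , drop = FALSE])
  dim(m) <- d[c(1L, 2L, 4L)]
  m
}

#' Grad-CAM saliency map
#'
#' Class-specific saliency at the resolution of the chosen convolutional
#' layer: the ReLU-clipped, gradient-weighted sum of its feature maps, with
#' each weight the spatial mean of the class-score gradient over that map.
#'
#' @param model A trained `edl_classifier` (or `edl_model`).
#' @param image H x W x 3 array (resized to the model input if needed).
#' @param class_c 1-based class index to explain.
#' @param layer_name Convolutional layer; default the last one.
#' @return An `edl_heatmap` of kind `"grad_cam"` (non-negative).
#' @export
grad_cam <- function(model, image, class_c, layer_name = NULL) {
  net <- get_net(model)
  if (is.null(layer_name)) layer_name <- last_conv_layer(net)
  x <- as_branch_tensor(image, net$input_shape[1:2])
  fw <- nn_forward(net, x, keep_cache = TRUE)
  maps <- grad_cam_maps(net, fw$caches, class_c, layer_name)
  new_heatmap("grad_cam", maps[, , 1L], class_c = class_c, layer = layer_name)
}

#' Guided backpropagation map
#'
#' Gradient of the pre-softmax class score with respect to the input, where
#' every ReLU passes gradient only at positions whose forward activation was
#' positive AND whose incoming gradient is positive; negative entries of the
#' resulting input gradient are zeroed and the three colour channels are
#' reduced by a per-pixel maximum.
#'
#' @inheritParams grad_cam
#' @return An `edl_heatmap` of kind `"guided_backprop"` at input resolution.
#' @export
guided_backprop <- function(model, image, class_c) {
  net <- get_net(model)
  has_relu <- any(vapply(net$layers, function(l)
    identical(l$activation, "relu"), TRUE))
  if (!has_relu)
    stop("guided backprop needs a ReLU network", call. = FALSE)
  x <- as_branch_tensor(image, net$input_shape[1:2])
  fw <- nn_forward(net, x, keep_cache = TRUE)
  maps <- guided_backprop_maps(net, fw$caches, class_c)
  dim(maps) <- dim(maps)[1:2]
  new_heatmap("guided_backprop", maps, class_c = class_c)
}

#' Guided Grad-CAM
#'
#' Elementwise product of the Grad-CAM map (bilinearly upsampled to input
#' resolution) with the guided-backpropagation map. Both factors are
#' non-negative, so the product is; its support is contained in the support
#' of the upsampled Grad-CAM map.
#'
#' @param cam An `edl_heatmap` of kind `"grad_cam"`.
#' @param gbp An `edl_heatmap` of kind `"guided_backprop"` for the same image
#'   and class.
#' @param input_size `c(H, W)` resolution of `gbp`.
#' @return An `edl_heatmap` of kind `"guided_grad_cam"`.
#' @export
guided_grad_cam <- function(cam, gbp, input_size = dim(gbp$values)) {
  stopifnot(inherits(cam, "edl_heatmap"), inherits(gbp, "edl_heatmap"))
  if (cam$kind != "grad_cam" || gbp$kind != "guided_backprop")
    stop("expected a grad_cam and a guided_backprop heatmap", call. = FALSE)
  if (!is.null(cam$class_c) && !is.null(gbp$class_c) &&
      !identical(cam$class_c, gbp$class_c))
    stop("class mismatch between Grad-CAM and guided-backprop maps",
         call. = FALSE)
  up <- resize_image(cam$values, input_size)
  new_heatmap("guided_grad_cam", up * gbp$values, class_c = cam$class_c,
              layer = cam$layer)
}

#' Average Guided Grad-CAM maps over classes
#'
#' @param per_class_maps List of C >= 2 `edl_heatmap`s of identical shape,
#'   one per class.
#' @return An `edl_heatmap` of kind `"aggregated"` (the arithmetic mean).
#' @export
aggregate_guided_grad_cam <- function(per_class_maps) {
  if (length(per_class_maps) < 2L)
    stop("need at least 2 per-class maps", call. = FALSE)
  vals <- lapply(per_class_maps, function(m)
    if (inherits(m, "edl_heatmap")) m$values else m)
  d0 <- dim(vals[[1L]])
  for (v in vals)
    if (!identical(dim(v), d0)) stop("map shape mismatch", call. = FALSE)
  new_heatmap("aggregated", Reduce(`+`, vals) / length(vals),
              n_classes = length(vals))
}

#' Attention-guided crop
#'
#' Normalizes the heatmap by its maximum, takes the bounding box of pixels at
#' or above `threshold`, expands it by `margin_px`, clips to the image, crops
#' and resizes back to the original size. An all-zero map falls back to the
#' uncropped image.
#'
#' @param image H x W x 3 array.
#' @param heatmap `edl_heatmap` (or matrix) at input resolution.
#' @param threshold Relative threshold in (0, 1].
#' @param margin_px Margin added around the box, in pixels.
#' @return List of one cropped image array; attribute `fallback` is TRUE when
#'   the uncropped image was returned, and attribute `box` records
#'   `c(r1, r2, c1, c2)`.
#' @export
attention_crop <- function(image, heatmap, threshold = 0.5, margin_px = 4L) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  v <- if (inherits(heatmap, "edl_heatmap")) heatmap$values else heatmap
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (!identical(dim(v), c(h, w)))
    stop("heatmap must be at input resolution", call. = FALSE)
  mx <- max(v)
  if (mx <= 0) {
    out <- list(image)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  hot <- which(v / mx >= threshold, arr.ind = TRUE)
  r1 <- max(1L, min(hot[, 1L]) - margin_px)
  r2 <- min(h, max(hot[, 1L]) + margin_px)
  c1 <- max(1L, min(hot[, 2L]) - margin_px)
  c2 <- min(w, max(hot[, 2L]) + margin_px)
  if (r2 < r1 || c2 < c1) {
    out <- list(image)
    attr(out, "fallback") <- TRUE
    attr(out, "box") <- c(r1, r2, c1, c2)
    return(out)
  }
  crop <- image[r1:r2, c1:c2, , drop = FALSE]
  out <- list(resize_image(crop, c(h, w)))
  attr(out, "fallback") <- FALSE
  attr(out, "box") <- c(r1, r2, c1, c2)
  out
}

#' Train the explainable branch
#'
#' Epoch 1 trains the VGG-shaped backbone on the unmodified train split.
#' From epoch 2 on, each epoch regenerates Guided Grad-CAM maps for the
#' current predicted class of every training image and trains on the union
#' of the originals and their attention crops. Early stopping monitors
#' validation accuracy with the configured patience; the best-validation
#' weights are returned.
#'
#' @param manifest Manifest with non-empty train and validation splits.
#' @param config An [edl_config()].
#' @return An `edl_classifier` named `"XDL"`.
#' @export
train_xdl <- function(manifest, config) {
  size <- config$image_size$xdl
  xcf <- config$xdl
  class_names <- config$class_names
  seed <- derive_seed(config$seed, "xdl")
  model <- build_backbone(size, xcf$width_multiplier, config$n_classes, seed)
  net <- model$net
  tr <- load_split_tensor(manifest, "train", size, class_names)
  va <- load_split_tensor(manifest, "validation", size, class_names)
  cam_layer <- if (is.null(xcf$cam_layer)) last_conv_layer(net)
               else xcf$cam_layer

  history <- NULL
  best <- list(acc = -Inf, net = net)
  stall <- 0L
  for (ep in seq_len(config$epochs)) {
    if (ep == 1L) {
      xb <- tr$x; yb <- tr$y
    } else {
      crops <- xdl_crops(net, tr$x, cam_layer, xcf$crop_threshold,
                         xcf$crop_margin)
      n <- dim(tr$x)[4L]
      xb <- array(0, c(size, 3L, 2L * n))
      xb[, , , seq_len(n)] <- tr$x
      xb[, , , n + seq_len(n)] <- crops
      yb <- c(tr$y, tr$y)
    }
    fit <- fit_net(net, xb, yb, epochs = 1L, lr = xcf$learning_rate,
                   batch_size = config$batch_size, momentum = xcf$momentum,
                   seed = seed + ep, xval = va$x, yval = va$y)
    net <- fit$net
    acc <- fit$history$validation_accuracy[1L]
    history <- rbind(history,
                     data.frame(epoch = ep,
                                train_loss = fit$history$train_loss[1L],
                                validation_accuracy = acc))
    edl_log(sprintf("XDL epoch %d: loss %.4f, val acc %.3f", ep,
                    fit$history$train_loss[1L], acc))
    if (acc > best$acc) { best <- list(acc = acc, net = net); stall <- 0L }
    else stall <- stall + 1L
    # the deep stack needs a burn-in before validation accuracy is
    # informative; stopping is only armed after min_epochs
    if (ep >= xcf$min_epochs && stall >= xcf$patience) break
  }
  finish_classifier(best$net, history, model, va, "XDL", class_names)
}

## regenerate Guided Grad-CAM crops for the predicted class of each image
xdl_crops <- function(net, x, cam_layer, threshold, margin, batch_size = 32L) {
  n <- dim(x)[4L]
  size <- dim(x)[1:2]
  out <- array(0, dim(x))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[, , , idx, drop = FALSE]
    fw <- nn_forward(net, xb, keep_cache = TRUE)
    pred <- apply(fw$out, 1L, which.max)
    cams <- grad_cam_maps(net, fw$caches, pred, cam_layer)
    gbps <- guided_backprop_maps(net, fw$caches, pred)
    for (j in seq_along(idx)) {
      gg <- resize_image(cams[, , j], size) * gbps[, , j]
      cr <- attention_crop(xb[, , , j], gg, threshold, margin)
      out[, , , idx[j]] <- cr[[1L]]
    }
  }
  out
}

#' Explain a prediction
#'
#' Computes the Grad-CAM, guided-backprop and Guided Grad-CAM maps of an
#' image for a class (default: the predicted class).
#'
#' @param classifier A trained `edl_classifier`.
#' @param image H x W x 3 array or image file path.
#' @param class_c Optional 1-based class index; default the predicted class.
#' @param layer_name Convolutional layer for Grad-CAM (default last).
#' @return List with `class_c`, `predicted_label`, and the three
#'   `edl_heatmap`s `grad_cam`, `guided_backprop`, `guided_grad_cam`.
#' @export
explain <- function(classifier, image, class_c = NULL, layer_name = NULL) {
  if (is.character(image)) image <- load_image(image)
  pr <- predict(classifier, image)
  if (is.null(class_c)) class_c <- which.max(pr$probs[1L, ])
  cam <- grad_cam(classifier, image, class_c, layer_name)
  gbp <- guided_backprop(classifier, image, class_c)
  ggc <- guided_grad_cam(cam, gbp, dim(gbp$values))
  list(class_c = class_c, predicted_label = pr$labels[1L],
       grad_cam = cam, guided_backprop = gbp, guided_grad_cam = ggc)
}

#' Write a heatmap to disk
#'
#' Raw values as a CSV grid plus a JSON metadata sidecar, and optionally a
#' grayscale PNG rendering normalized to the map maximum.
#'
#' @param heatmap An `edl_heatmap`.
#' @param path_prefix Output prefix (writes `<prefix>.csv`, `<prefix>.json`,
#'   `<prefix>.png`).
#' @param png Also write the PNG rendering.
#' @return `path_prefix`, invisibly.
#' @export
write_heatmap <- function(heatmap, path_prefix, png = TRUE) {
  utils::write.table(heatmap$values, paste0(path_prefix, ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- list(kind = heatmap$kind, class = heatmap$class_c,
               layer = heatmap$layer,
               normalization = "raw values; PNG scaled by map maximum")
  jsonlite::write_json(meta, paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (png) {
    v <- heatmap$values
    if (max(v) > 0) v <- v / max(v)
    write_image(v, paste0(path_prefix, ".png"))
  }
  invisible(path_prefix)
}
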