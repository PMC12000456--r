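## CNN ensemble member and the generic train/evaluate loop shared by all
## branches. The default architecture follows the reference shape chain
## 32x32x3 -> 28x28x8 -> 14x14x8 -> 10x10x16 -> 5x5x16 (5x5 valid
## convolutions, 2x2 max-pooling) with a 400 -> 120 -> 84 -> n_classes head.

#' CNN architecture specification
#'
#' @param input_size `c(H, W)` input size, default 32 x 32.
#' @param n_classes Number of output classes.
#' @param conv_channels Channels of the two convolution blocks.
#' @param dense_widths Hidden widths of the fully connected head.
#' @return An `edl_arch` with the layer list and a shape table.
#' @export
cnn_arch <- function(input_size = c(32L, 32L), n_classes = 4L,
                     conv_channels = c(8L, 16L), dense_widths = c(120L, 84L)) {
  layers <- list(
    layer_conv(conv_channels[1L], kernel = 5L, pad = 0L, activation = "relu",
               name = "conv1"),
    layer_pool(name = "pool1"),
    layer_conv(conv_channels[2L], kernel = 5L, pad = 0L, activation = "relu",
               name = "conv2"),
    layer_pool(name = "pool2"),
    layer_flatten())
  for (i in seq_along(dense_widths))
    layers <- c(layers, list(layer_dense(dense_widths[i], activation = "relu",
                                         name = paste0("fc", i))))
  layers <- c(layers, list(layer_dense(n_classes, activation = "linear",
                                       name = "logits")))
  net <- nn_network(layers, c(as.integer(input_size), 3L))
  structure(list(layers = layers, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 table = arch_table(net)),
            class = "edl_arch")
}

## shape table of a network (for inspection and chain tests)
arch_table <- function(net) {
  fmt <- function(s) paste(s, collapse = "x")
  data.frame(
    kind = vapply(net$layers, `[[`, "", "type"),
    name = vapply(net$layers, function(l) if (is.null(l$name)) "" else l$name,
                  ""),
    input = vapply(net$layers, function(l) fmt(l$in_shape), ""),
    output = vapply(net$layers, function(l) fmt(l$out_shape), ""),
    stringsAsFactors = FALSE)
}

#' Build an untrained CNN
#'
#' @param arch An [cnn_arch()] specification.
#' @param seed Integer seed for the deterministic He initialization.
#' @return An `edl_model` (untrained classifier).
#' @export
build_cnn <- function(arch = cnn_arch(), seed = 1L) {
  stopifnot(inherits(arch, "edl_arch"))
  net <- nn_network(arch$layers, c(arch$input_size, 3L))
  if (net$out_shape != arch$n_classes)
    stop("final layer width must equal n_classes", call. = FALSE)
  net <- nn_init(net, seed)
  structure(list(net = net, input_size = arch$input_size,
                 n_classes = arch$n_classes, arch = arch, seed = seed),
            class = "edl_model")
}

## ---- generic fit/evaluate on tensors ------------------------------------

## One or more epochs of minibatch SGD with cross-entropy. Returns the final
## net, the per-epoch history, and the best-validation-accuracy weights
## (`best_net`): validation accuracy oscillates at this data scale, so the
## branches keep the best epoch rather than the last one.
fit_net <- function(net, x, y, epochs, lr, batch_size, momentum = 0,
                    seed = NULL, xval = NULL, yval = NULL, clip = 5,
                    lr_decay = 1) {
  if (!is.null(seed)) { old <- mistate_push(seed); on.exit(mistate_pop(old)) }
  n <- dim(x)[4L]
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     validation_accuracy = numeric())
  best <- list(acc = -Inf, net = net)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^(ep - 1)
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      fw <- nn_forward(net, xb, keep_cache = TRUE)
      lg <- ce_loss_grad(fw$out, y[idx])
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      bk <- nn_backward(net, fw$caches, lg$dlogits)
      net <- nn_sgd_step(net, clip_grads(bk$grads, clip), lr_ep, momentum)
      losses <- c(losses, lg$loss)
    }
    va <- if (!is.null(xval)) mean(predict_net(net, xval)$labels == yval)
          else NA_real_
    if (!is.na(va) && va > best$acc) best <- list(acc = va, net = net)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   validation_accuracy = va))
  }
  list(net = net, history = hist,
       best_net = if (is.finite(best$acc)) best$net else net)
}

## batched forward; returns probs (N x K) and argmax labels (ties -> first)
predict_net <- function(net, x, batch_size = 64L) {
  n <- dim(x)[4L]
  probs <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    logits <- nn_forward(net, x[, , , idx, drop = FALSE])
    probs <- rbind(probs, softmax_rows(logits))
  }
  list(probs = probs, labels = apply(probs, 1L, which.max))
}

#' Train a classifier branch
#'
#' Minibatch stochastic gradient descent with the cross-entropy objective on
#' softmax outputs. Per-epoch training loss and validation accuracy are
#' recorded, and the weights of the best-validation epoch are kept; the
#' stored validation accuracy and per-class validation recall of those
#' weights are what the ensemble vote later consumes.
#'
#' @param model An untrained `edl_model` (from [build_cnn()] or
#'   [build_backbone()]).
#' @param manifest Manifest with non-empty train and validation splits.
#' @param config An [edl_config()].
#' @param name Branch name stored on the result (`"CNN"`, `"GAN"`, `"XDL"`).
#' @param lr,momentum,lr_decay Optional overrides of the config's SGD
#'   settings.
#' @return An `edl_classifier` with fields `name`, `net`,
#'   `validation_accuracy`, `per_class_recall`, `history`, `seed`.
#' @export
train_classifier <- function(model, manifest, config, name = "CNN",
                             lr = NULL, momentum = NULL, lr_decay = NULL) {
  stopifnot(inherits(model, "edl_model"))
  class_names <- config$class_names
  tr <- load_split_tensor(manifest, "train", model$input_size, class_names)
  va <- load_split_tensor(manifest, "validation", model$input_size,
                          class_names)
  lr <- if (is.null(lr)) config$learning_rate else lr
  momentum <- if (is.null(momentum)) config$momentum else momentum
  lr_decay <- if (is.null(lr_decay)) config$lr_decay else lr_decay
  fit <- fit_net(model$net, tr$x, tr$y, epochs = config$epochs, lr = lr,
                 batch_size = config$batch_size, momentum = momentum,
                 seed = model$seed, xval = va$x, yval = va$y,
                 lr_decay = lr_decay)
  finish_classifier(fit$best_net, fit$history, model, va, name, class_names)
}

## wraps a trained net into the classifier object with validation stats
finish_classifier <- function(net, history, model, va, name, class_names) {
  pv <- predict_net(net, va$x)
  acc <- mean(pv$labels == va$y)
  recall <- vapply(seq_along(class_names), function(k) {
    in_k <- va$y == k
    if (!any(in_k)) return(0)
    mean(pv$labels[in_k] == k)
  }, 0)
  names(recall) <- class_names
  structure(list(name = name, net = net, input_size = model$input_size,
                 class_names = class_names, validation_accuracy = acc,
                 per_class_recall = recall, history = history,
                 seed = model$seed),
            class = "edl_classifier")
}

#' @export
print.edl_classifier <- function(x, ...) {
  cat(sprintf("<edl_classifier %s>  input %s, %d classes\n", x$name,
              paste(x$input_size, collapse = "x"), length(x$class_names)))
  cat(sprintf("  epochs trained: %d   validation accuracy: %.3f\n",
              nrow(x$history), x$validation_accuracy))
  cat("  per-class validation recall:\n")
  print(round(x$per_class_recall, 3))
  invisible(x)
}

#' Predict with a trained branch
#'
#' @param object An `edl_classifier`.
#' @param newdata An H x W x 3 image array, a list of such arrays, or a
#'   manifest (all records used); images are resized to the branch input.
#' @param ... Unused.
#' @return List with `probs` (N x K matrix) and `labels` (predicted class
#'   names; probability ties resolve to the lowest class index).
#' @export
predict.edl_classifier <- function(object, newdata, ...) {
  x <- as_branch_tensor(newdata, object$input_size)
  pv <- predict_net(object$net, x)
  list(probs = pv$probs, labels = object$class_names[pv$labels])
}

## raw [0,1] images in, centred branch-input tensor out
as_branch_tensor <- function(newdata, size) {
  x <- if (inherits(newdata, "edl_manifest")) {
    n <- nrow(newdata)
    x <- array(0, c(size, 3L, n))
    for (i in seq_len(n))
      x[, , , i] <- load_image(newdata$image_path[i], size)
    x
  } else if (is.list(newdata) && !is.array(newdata)) {
    n <- length(newdata)
    x <- array(0, c(size, 3L, n))
    for (i in seq_len(n)) x[, , , i] <- resize_image(newdata[[i]], size)
    x
  } else if (is.array(newdata) && length(dim(newdata)) == 3L) {
    array(resize_image(newdata, size), c(size, 3L, 1L))
  } else if (is.array(newdata) && length(dim(newdata)) == 4L) {
    newdata
  } else stop("unsupported newdata", call. = FALSE)
  x - INPUT_CENTER
}

#' Save / load a trained classifier checkpoint
#'
#' The checkpoint is an opaque weights file plus a JSON sidecar with the
#' branch name, seed, stored validation accuracy and per-class recall.
#'
#' @param classifier An `edl_classifier`.
#' @param dir Directory to write `<name>.rds` and `<name>.json` into.
#' @return The sidecar path, invisibly.
#' @export
save_classifier <- function(classifier, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, tolower(classifier$name))
  saveRDS(classifier, paste0(base, ".rds"))
  sidecar <- list(name = classifier$name,
                  input_size = classifier$input_size,
                  class_names = classifier$class_names,
                  seed = classifier$seed,
                  epochs = nrow(classifier$history),
                  validation_accuracy = classifier$validation_accuracy,
                  per_class_validation_recall =
                    as.list(classifier$per_class_recall))
  jsonlite::write_json(sidecar, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, ".json"))
}

#' @rdname save_classifier
#' @param path Path to a saved `.rds` checkpoint.
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "edl_classifier"))
    stop("not a classifier checkpoint: ", path, call. = FALSE)
  obj
}
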