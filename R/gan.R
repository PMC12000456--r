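## GAN ensemble member: one small unconditional GAN per tissue class
## generates synthetic training images; the branch classifier is then an
## ordinary CNN trained on the augmented train split. The adversarial game is
## the classic two-player minimax value
##   V(D, G) = E_{A ~ Pd}[log D(A)] + E_{s ~ Ps}[log(1 - D(G(s)))],
## with the generator trained on the standard non-saturating surrogate
## (maximize log D(G(s))).

GAN_EPS <- 1e-7

#' Empirical GAN value
#'
#' Computes the two-player minimax value from discriminator outputs on real
#' and generated batches. Outputs are clamped to `[1e-7, 1 - 1e-7]` so the
#' logarithms stay finite. The value is always <= 0 and equals `-2 log 2` at
#' the classic equilibrium where D outputs 1/2 everywhere.
#'
#' @param d_real Discriminator outputs on real images, values in (0, 1).
#' @param d_fake Discriminator outputs on generated images.
#' @return A `gan_value`: `v`, `e_real`, `e_fake`.
#' @export
gan_value <- function(d_real, d_fake) {
  if (!length(d_real) || !length(d_fake))
    stop("empty discriminator output vector", call. = FALSE)
  d_real <- pmin(pmax(d_real, GAN_EPS), 1 - GAN_EPS)
  d_fake <- pmin(pmax(d_fake, GAN_EPS), 1 - GAN_EPS)
  e_real <- mean(log(d_real))
  e_fake <- mean(log(1 - d_fake))
  structure(list(v = e_real + e_fake, e_real = e_real, e_fake = e_fake),
            class = "gan_value")
}

## generator: latent -> (H/4)x(W/4)x16 -> upsample/conv x2 -> sigmoid image
build_generator <- function(latent_dim, out_size, seed) {
  h0 <- out_size[1L] %/% 4L; w0 <- out_size[2L] %/% 4L
  layers <- list(
    layer_dense(h0 * w0 * 16L, activation = "relu", name = "g_fc"),
    layer_reshape(c(h0, w0, 16L)),
    layer_upsample(),
    layer_conv(16L, kernel = 3L, pad = 1L, activation = "relu", name = "g_c1"),
    layer_upsample(),
    layer_conv(8L, kernel = 3L, pad = 1L, activation = "relu", name = "g_c2"),
    layer_conv(3L, kernel = 3L, pad = 1L, activation = "sigmoid",
               name = "g_out"))
  nn_init(nn_network(layers, latent_dim), seed)
}

## discriminator: conv/pool x2 -> dense sigmoid scalar
build_discriminator <- function(in_size, seed) {
  layers <- list(
    layer_conv(8L, kernel = 3L, pad = 1L, activation = "relu", name = "d_c1"),
    layer_pool(),
    layer_conv(16L, kernel = 3L, pad = 1L, activation = "relu", name = "d_c2"),
    layer_pool(),
    layer_flatten(),
    layer_dense(1L, activation = "sigmoid", name = "d_out"))
  nn_init(nn_network(layers, c(in_size, 3L)), seed)
}

## binary cross-entropy gradient for a sigmoid scalar output
bce_grad <- function(p, target) {
  p <- pmin(pmax(p, GAN_EPS), 1 - GAN_EPS)
  # d/dp of -mean(t log p + (1-t) log(1-p))
  (-(target / p) + (1 - target) / (1 - p)) / length(p)
}

#' Train a per-class GAN
#'
#' Alternating updates: one discriminator step ascending the minimax value,
#' one generator step on the non-saturating surrogate. The empirical value
#' `v` of every step is recorded, along with the discriminator's real-vs-fake
#' accuracy after a short warm-up and at the end of training.
#'
#' @param images H x W x 3 x N tensor of one class (N >= 16), values in
#'   `[0, 1]`.
#' @param class_label The tissue class this pair models.
#' @param config An [edl_config()] (uses the `gan` settings).
#' @param seed Integer seed.
#' @return A `gan_pair` with `generator`, `discriminator`, `class_label`,
#'   `value_trace`, `disc_acc_initial`, `disc_acc_final`.
#' @export
train_gan <- function(images, class_label, config, seed = 1L) {
  n <- dim(images)[4L]
  if (n < 16L)
    stop("class ", class_label, " has too few images for GAN training (", n,
         " < 16)", call. = FALSE)
  gcf <- config$gan
  size <- dim(images)[1:2]
  G <- build_generator(gcf$latent_dim, size, seed)
  D <- build_discriminator(size, seed + 1L)
  old <- mistate_push(seed)
  on.exit(mistate_pop(old))

  bs <- min(gcf$batch_size, n)
  trace <- numeric(gcf$steps)
  disc_acc <- function(D, G) {
    idx <- sample.int(n, bs)
    z <- matrix(stats::rnorm(bs * gcf$latent_dim), bs)
    fake <- nn_forward(G, z)
    pr <- as.numeric(nn_forward(D, images[, , , idx, drop = FALSE]))
    pf <- as.numeric(nn_forward(D, fake))
    (mean(pr > 0.5) + mean(pf <= 0.5)) / 2
  }

  # reference point: a discriminator trained alone against the frozen initial
  # generator separates real from generated almost perfectly; adversarial
  # pressure from G training should keep the final discriminator below it
  D0 <- D
  for (step in 1:30) {
    idx <- sample.int(n, bs)
    z <- matrix(stats::rnorm(bs * gcf$latent_dim), bs)
    fake <- nn_forward(G, z)
    fwr <- nn_forward(D0, images[, , , idx, drop = FALSE], keep_cache = TRUE)
    bkr <- nn_backward(D0, fwr$caches, bce_grad(fwr$out, 1))
    fwf <- nn_forward(D0, fake, keep_cache = TRUE)
    bkf <- nn_backward(D0, fwf$caches, bce_grad(fwf$out, 0))
    gsum <- mapply(function(a, b) {
      if (is.null(a)) return(NULL)
      list(dW = a$dW + b$dW, db = a$db + b$db)
    }, bkr$grads, bkf$grads, SIMPLIFY = FALSE)
    D0 <- nn_sgd_step(D0, gsum, gcf$lr, gcf$momentum)
  }
  acc0 <- disc_acc(D0, G)

  for (step in seq_len(gcf$steps)) {
    idx <- sample.int(n, bs)
    real <- images[, , , idx, drop = FALSE]
    z <- matrix(stats::rnorm(bs * gcf$latent_dim), bs)
    fake <- nn_forward(G, z)

    # discriminator step: labels 1 for real, 0 for fake
    fwr <- nn_forward(D, real, keep_cache = TRUE)
    bkr <- nn_backward(D, fwr$caches, bce_grad(fwr$out, 1))
    fwf <- nn_forward(D, fake, keep_cache = TRUE)
    bkf <- nn_backward(D, fwf$caches, bce_grad(fwf$out, 0))
    gsum <- mapply(function(a, b) {
      if (is.null(a)) return(NULL)
      list(dW = a$dW + b$dW, db = a$db + b$db)
    }, bkr$grads, bkf$grads, SIMPLIFY = FALSE)
    D <- nn_sgd_step(D, gsum, gcf$lr, gcf$momentum)

    # generator step: non-saturating, push D(G(s)) toward 1
    fwg <- nn_forward(G, z, keep_cache = TRUE)
    fwd <- nn_forward(D, fwg$out, keep_cache = TRUE)
    dimg <- nn_backward(D, fwd$caches, bce_grad(fwd$out, 1))$dx
    bkg <- nn_backward(G, fwg$caches, dimg)
    G <- nn_sgd_step(G, bkg$grads, gcf$lr, gcf$momentum)

    trace[step] <- gan_value(as.numeric(fwr$out), as.numeric(fwd$out))$v
  }
  acc1 <- disc_acc(D, G)
  structure(list(generator = G, discriminator = D, class_label = class_label,
                 latent_dim = gcf$latent_dim, image_size = size,
                 value_trace = trace, disc_acc_initial = acc0,
                 disc_acc_final = acc1, seed = seed),
            class = "gan_pair")
}

#' Sample images from a trained GAN
#'
#' @param pair A `gan_pair`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return H x W x 3 x n tensor with values in `[0, 1]`.
#' @export
sample_gan <- function(pair, n, seed = 1L) {
  old <- mistate_push(seed)
  on.exit(mistate_pop(old))
  z <- matrix(stats::rnorm(n * pair$latent_dim), n)
  out <- nn_forward(pair$generator, z)
  out
}

#' Augment the train split with GAN-generated images
#'
#' Writes `n_per_class` generated PNGs per class under `out_dir/synthetic/`
#' and appends them to the TRAIN split only, labelled with the generator's
#' class and flagged `synthetic = TRUE`. Validation and test are untouched.
#'
#' @param manifest An [edl_manifest()].
#' @param gan_pairs Named list of `gan_pair`s, one per class in the train
#'   split.
#' @param n_per_class Generated images per class (0 = no-op).
#' @param out_dir Directory for the synthetic subtree.
#' @param seed Integer seed.
#' @return The augmented manifest.
#' @export
augment_dataset <- function(manifest, gan_pairs, n_per_class, out_dir,
                            seed = 1L) {
  if (n_per_class == 0L) return(manifest)
  class_names <- attr(manifest, "class_names")
  train_classes <- unique(manifest$label[manifest$split == "train"])
  miss <- setdiff(train_classes, names(gan_pairs))
  if (length(miss))
    stop("missing GAN pair for class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dir.create(file.path(out_dir, "synthetic"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (cl in train_classes) {
    pair <- gan_pairs[[cl]]
    if (!identical(pair$class_label, cl))
      stop("GAN pair labelled ", pair$class_label, " supplied for class ", cl,
           call. = FALSE)
    dir.create(file.path(out_dir, "synthetic", cl), showWarnings = FALSE)
    x <- sample_gan(pair, n_per_class, seed = seed + match(cl, class_names))
    for (i in seq_len(n_per_class)) {
      p <- file.path(out_dir, "synthetic", cl, sprintf("gan_%s_%03d.png",
                                                       cl, i))
      write_image(x[, , , i], p)
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = p, label = cl, split = "train", is_outlier_truth = NA,
        mask_path = NA_character_, synthetic = TRUE, stringsAsFactors = FALSE)
    }
  }
  df <- rbind(as.data.frame(manifest), do.call(rbind, rows))
  edl_manifest(df, class_names)
}

#' Train the GAN-augmented branch
#'
#' Trains one GAN per class on the train split, augments the train split with
#' generated images, then trains a CNN identical to the plain branch on the
#' augmented set.
#'
#' @param manifest An [edl_manifest()].
#' @param config An [edl_config()].
#' @param out_dir Directory for the synthetic images.
#' @return An `edl_classifier` named `"GAN"` (with the trained `gan_pairs`
#'   attached as attribute `gan_pairs`).
#' @export
train_gan_branch <- function(manifest, config, out_dir = tempfile("gan")) {
  size <- config$image_size$gan
  class_names <- config$class_names
  seed <- derive_seed(config$seed, "gan")
  train <- manifest[manifest$split == "train", , drop = FALSE]
  pairs <- list()
  n_real <- integer()
  for (cl in class_names) {
    rows <- train[train$label == cl, , drop = FALSE]
    x <- array(0, c(size, 3L, nrow(rows)))
    for (i in seq_len(nrow(rows)))
      x[, , , i] <- load_image(rows$image_path[i], size)
    edl_log("GAN[", cl, "]: training on ", nrow(rows), " images")
    pairs[[cl]] <- train_gan(x, cl, config, seed = seed + match(cl, class_names))
    n_real[[cl]] <- nrow(rows)
  }
  n_syn <- config$gan$n_synthetic_per_class
  if (is.na(n_syn)) n_syn <- max(n_real)
  aug <- augment_dataset(manifest, pairs, n_syn, out_dir, seed = seed)
  model <- build_cnn(cnn_arch(input_size = size,
                              n_classes = config$n_classes),
                     seed = seed)
  clf <- train_classifier(model, aug, config, name = "GAN",
                          lr_decay = config$gan$classifier_lr_decay)
  attr(clf, "gan_pairs") <- pairs
  clf
}
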