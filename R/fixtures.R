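## Synthetic endoscopic-like fixtures.
##
## Four texture recipes stand in for the four tissue classes so every
## downstream stage (outlier rejection, the three classifier branches,
## saliency localization) is exercisable without clinical data:
##   NTL - smooth low-frequency background only
##   NST - background + fine high-frequency grating, no lesion
##   LGC - background + one bright soft-edged disc lesion (mask = disc)
##   HGC - background + irregular bright blob (radially perturbed disc) with
##         interior speckle and higher contrast (mask = blob)
## A configurable fraction of images is replaced by over- or under-exposed
## frames (mean brightness >= 0.95 or <= 0.05) flagged is_outlier_truth.

#' Fixture generator configuration
#'
#' @param n_per_class Images per class (>= 1).
#' @param image_size `c(H, W)`, default 64 x 64.
#' @param outlier_fraction Fraction of images replaced by exposure outliers,
#'   in `[0, 1)`.
#' @param lesion_radius_range `c(r_min, r_max)` in pixels for the lesion
#'   classes; `r_max` must be below `min(H, W) / 2`.
#' @param contrast Named additive lesion/texture contrast per class.
#' @param noise_sigma Gaussian pixel noise level.
#' @param seed Integer seed; the whole fixture set is a pure function of it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_per_class = 100L,
                           image_size = c(64L, 64L),
                           outlier_fraction = 0.1,
                           lesion_radius_range = c(6, 14),
                           contrast = c(HGC = 0.35, LGC = 0.25,
                                        NST = 0.15, NTL = 0),
                           noise_sigma = 0.02,
                           seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)", call. = FALSE)
  if (lesion_radius_range[2L] >= min(image_size) / 2)
    stop("r_max must be < min(H, W) / 2", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 outlier_fraction = outlier_fraction,
                 lesion_radius_range = lesion_radius_range,
                 contrast = contrast, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

## smooth tissue-like background with mean brightness in ~[0.38, 0.62]
fixture_background <- function(h, w) {
  b0 <- min(max(stats::rnorm(1, 0.5, 0.04), 0.40), 0.60)
  xg <- matrix(seq_len(w), h, w, byrow = TRUE) / w
  yg <- matrix(seq_len(h), h, w) / h
  field <- matrix(0, h, w)
  for (q in 1:2) {
    th <- stats::runif(1, 0, pi)
    fr <- stats::runif(1, 0.6, 1.8)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.02, 0.04)
    field <- field + amp * sin(2 * pi * fr * (xg * cos(th) + yg * sin(th)) + ph)
  }
  list(base = b0 + field, xg = xg, yg = yg)
}

## one clean image + optional mask for a class; returns list(px, mask)
fixture_image <- function(class, cfg) {
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  bg <- fixture_background(h, w)
  img <- bg$base
  mask <- NULL
  contrast <- cfg$contrast[[class]]
  if (class == "NST") {
    th <- stats::runif(1, 0, pi)
    period <- stats::runif(1, 3, 6)
    ph <- stats::runif(1, 0, 2 * pi)
    xg <- bg$xg * w; yg <- bg$yg * h
    img <- img + 0.5 * contrast *
      sin(2 * pi * (xg * cos(th) + yg * sin(th)) / period + ph)
  } else if (class %in% c("LGC", "HGC")) {
    rmin <- cfg$lesion_radius_range[1L]; rmax <- cfg$lesion_radius_range[2L]
    r0 <- if (class == "LGC") stats::runif(1, rmin, rmax)
          else stats::runif(1, rmin, rmax / 1.35)
    reach <- if (class == "LGC") r0 else 1.35 * r0
    cx <- stats::runif(1, reach + 2, w - reach - 2)
    cy <- stats::runif(1, reach + 2, h - reach - 2)
    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    yg <- matrix(seq_len(h), h, w)
    d <- sqrt((xg - cx)^2 + (yg - cy)^2)
    if (class == "LGC") {
      redge <- r0
    } else {
      k <- sample(3:5, 1L)
      ph <- stats::runif(1, 0, 2 * pi)
      phi <- atan2(yg - cy, xg - cx)
      redge <- r0 * (1 + 0.3 * sin(k * phi + ph))
    }
    soft <- 1 / (1 + exp((d - redge) / 0.8))
    img <- img + contrast * soft
    mask <- (d <= redge) * 1
    if (class == "HGC") {
      speck <- matrix(stats::rnorm(h * w, 0, 0.08), h, w)
      img <- img + speck * mask
    }
  }
  img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sigma), h, w)
  # mild per-channel tint so the images are genuinely RGB
  px <- array(0, c(h, w, 3L))
  px[, , 1L] <- img + 0.04
  px[, , 2L] <- img - 0.01
  px[, , 3L] <- img - 0.03
  list(px = pmin(pmax(px, 0), 1), mask = mask)
}

## exposure outlier: mean brightness >= 0.95 (over) or <= 0.05 (under)
fixture_outlier <- function(cfg, over) {
  h <- cfg$image_size[1L]; w <- cfg$image_size[2L]
  center <- if (over) 0.985 else 0.015
  px <- array(stats::rnorm(h * w * 3L, center, 0.008), c(h, w, 3L))
  if (over) pmin(pmax(px, 0.955), 1) else pmin(pmax(px, 0), 0.045)
}

#' Generate a synthetic fixture dataset
#'
#' Writes `n_per_class` PNG images per class plus lesion masks for the
#' cancer classes, injects exposure outliers, assigns stratified splits, and
#' writes the manifest CSV to `out_dir/manifest.csv`. The whole set is a
#' deterministic function of `config$seed`.
#'
#' @param config A [fixture_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return The [edl_manifest()] of the generated set.
#' @export
generate_fixtures <- function(config, out_dir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  classes <- CLASSES_DEFAULT
  n_total <- config$n_per_class * length(classes)
  n_out <- round(config$outlier_fraction * n_total)

  old <- mistate_push(derive_seed(config$seed, "fixtures"))
  on.exit(mistate_pop(old))

  # spread outliers across classes round-robin, random position within class
  out_per_class <- integer(length(classes))
  if (n_out > 0)
    out_per_class <- tabulate((seq_len(n_out) - 1L) %% length(classes) + 1L,
                              length(classes))

  rows <- vector("list", n_total)
  i <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    dir.create(file.path(out_dir, cl), showWarnings = FALSE)
    which_out <- if (out_per_class[ci] > 0)
      sample.int(config$n_per_class, out_per_class[ci]) else integer()
    for (j in seq_len(config$n_per_class)) {
      i <- i + 1L
      id <- sprintf("%s_%03d", cl, j)
      rel <- file.path(cl, paste0(id, ".png"))
      is_out <- j %in% which_out
      mask_rel <- NA_character_
      if (is_out) {
        px <- fixture_outlier(config, over = stats::runif(1) < 0.5)
      } else {
        im <- fixture_image(cl, config)
        px <- im$px
        if (!is.null(im$mask)) {
          mask_rel <- file.path("masks", paste0(id, "_mask.png"))
          write_image(im$mask, file.path(out_dir, mask_rel))
        }
      }
      write_image(px, file.path(out_dir, rel))
      rows[[i]] <- data.frame(image_path = rel, label = cl, split = "train",
                              is_outlier_truth = is_out, mask_path = mask_rel,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  manifest <- edl_manifest(df)
  manifest <- split_manifest(manifest, fractions = c(0.75, 0.16, 0.09),
                             seed = derive_seed(config$seed, "split"))
  csv <- file.path(out_dir, "manifest.csv")
  utils::write.csv(as.data.frame(manifest), csv, row.names = FALSE, na = "")
  load_manifest(csv)
}

#' Fixture separability probe
#'
#' Trains a deliberately small classifier (one 5x5 convolution, 2x2 pooling,
#' linear head) for 10 epochs on the clean train split and reports clean
#' test-split accuracy. Used as a quality gate: the fixtures must be
#' learnable well above the 1/4 chance level.
#'
#' @param manifest Manifest from [generate_fixtures()] with at least 25 clean
#'   images per class.
#' @param seed Integer seed.
#' @return Scalar accuracy on the clean test split.
#' @export
separability_probe <- function(manifest, seed = 1L) {
  clean <- manifest[!(manifest$is_outlier_truth %in% TRUE), , drop = FALSE]
  class_names <- attr(manifest, "class_names")
  per <- table(factor(clean$label, class_names))
  if (any(per < 25L))
    stop("separability probe needs >= 25 clean images per class (have ",
         min(per), ")", call. = FALSE)
  size <- c(32L, 32L)
  layers <- list(layer_conv(6L, kernel = 5L, pad = 0L, activation = "relu"),
                 layer_pool(),
                 layer_flatten(),
                 layer_dense(length(class_names), activation = "linear"))
  net <- nn_network(layers, c(size, 3L))
  net <- nn_init(net, derive_seed(seed, "probe"))
  tr <- load_split_tensor(clean, "train", size, class_names)
  te <- load_split_tensor(clean, "test", size, class_names)
  net <- fit_net(net, tr$x, tr$y, epochs = 10L, lr = 0.05, batch_size = 16L,
                 momentum = 0.5, seed = derive_seed(seed, "probe"))$net
  mean(predict_net(net, te$x)$labels == te$y)
}
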