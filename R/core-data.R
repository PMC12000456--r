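## Manifest and image plumbing shared by every stage.

CLASSES_DEFAULT <- c("HGC", "LGC", "NST", "NTL")
SPLITS <- c("train", "validation", "test")

#' Construct a dataset manifest
#'
#' The manifest is the record of truth for a dataset: one row per image with
#' its class label, its split assignment, and optional ground-truth columns
#' (outlier flag, lesion-mask path, synthetic flag).
#'
#' @param records Data frame with at least `image_path`, `label`, `split`.
#' @param class_names Allowed class labels (default the four tissue classes
#'   HGC, LGC, NST, NTL).
#' @return An `edl_manifest` (a validated data frame).
#' @export
edl_manifest <- function(records, class_names = CLASSES_DEFAULT) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("image_path", "label", "split")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"is_outlier_truth" %in% names(records))
    records$is_outlier_truth <- NA
  records$is_outlier_truth <- as.logical(records$is_outlier_truth)
  if (!"mask_path" %in% names(records)) records$mask_path <- NA_character_
  if (!"synthetic" %in% names(records)) records$synthetic <- FALSE
  records$synthetic[is.na(records$synthetic)] <- FALSE

  dup <- which(duplicated(records$image_path))
  if (length(dup))
    stop("duplicate image_path at row ", dup[1L], ": ",
         records$image_path[dup[1L]], call. = FALSE)
  bad <- which(!records$label %in% class_names)
  if (length(bad))
    stop("unknown label '", records$label[bad[1L]], "' at row ", bad[1L],
         call. = FALSE)
  bad <- which(!records$split %in% SPLITS)
  if (length(bad))
    stop("unknown split '", records$split[bad[1L]], "' at row ", bad[1L],
         call. = FALSE)
  attr(records, "class_names") <- class_names
  class(records) <- c("edl_manifest", "data.frame")
  records
}

#' Read a dataset manifest from CSV
#'
#' Expects a header `image_path,label,split` with optional
#' `is_outlier_truth`, `mask_path` and `synthetic` columns. Relative image
#' paths are resolved against the CSV's directory.
#'
#' @param path CSV file path.
#' @param class_names Allowed class labels.
#' @return An [edl_manifest()].
#' @export
load_manifest <- function(path, class_names = CLASSES_DEFAULT) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", df$image_path)
  df$image_path[rel] <- file.path(base, df$image_path[rel])
  if ("mask_path" %in% names(df)) {
    has <- !is.na(df$mask_path) & nzchar(df$mask_path)
    rel <- has & !grepl("^(/|[A-Za-z]:)", df$mask_path)
    df$mask_path[rel] <- file.path(base, df$mask_path[rel])
    df$mask_path[!has] <- NA_character_
  }
  edl_manifest(df, class_names)
}

#' Write a manifest to CSV
#'
#' @param manifest An [edl_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load an image as an H x W x 3 array in [0, 1]
#'
#' Reads PNG or JPEG, replicates grayscale to three channels, drops any alpha
#' channel, and (optionally) resizes with deterministic align-corners bilinear
#' interpolation.
#'
#' @param path PNG or JPEG file.
#' @param target_size Optional `c(H, W)` to resize to.
#' @return Numeric H x W x 3 array with values in `[0, 1]`.
#' @export
load_image <- function(path, target_size = NULL) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", path, call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3L] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3L] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (!is.null(target_size)) px <- resize_image(px, target_size)
  px
}

#' Bilinear resize (align-corners)
#'
#' @param px H x W or H x W x C numeric array.
#' @param target_size `c(H, W)`.
#' @return Resized array of the same rank.
#' @export
resize_image <- function(px, target_size) {
  d <- dim(px)
  two_d <- length(d) == 2L
  if (two_d) { dim(px) <- c(d, 1L); d <- dim(px) }
  out <- resize_bilinear_cpp(as.numeric(px), d[1L], d[2L], d[3L], 1L,
                             as.integer(target_size[1L]),
                             as.integer(target_size[2L]))
  dim(out) <- c(target_size[1L], target_size[2L], d[3L])
  if (two_d) dim(out) <- target_size[1:2]
  out
}

#' Write an image array to PNG
#'
#' @param px H x W x 3 (or H x W) array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(px, path) {
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

#' Stratified train/validation/test assignment
#'
#' Reassigns the `split` column by drawing, per class, a seeded permutation
#' and cutting it at the requested fractions (largest-remainder rounding, so
#' per-class counts are within one of the exact fractions).
#'
#' @param manifest An [edl_manifest()].
#' @param fractions Length-3 positive numeric `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer seed; equal seeds give identical assignments.
#' @return The manifest with an updated `split` column.
#' @export
split_manifest <- function(manifest, fractions = c(0.75, 0.16, 0.09),
                           seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 positive numbers summing to 1", call. = FALSE)
  class_names <- attr(manifest, "class_names")
  per_class <- table(factor(manifest$label, class_names))
  if (any(per_class < 3L))
    stop("too few records to populate all splits for class ",
         names(per_class)[which.min(per_class)], call. = FALSE)
  old <- mistate_push(seed)
  on.exit(mistate_pop(old))
  split <- character(nrow(manifest))
  for (cl in class_names) {
    idx <- which(manifest$label == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    raw <- fractions * n
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      order_rem <- order(raw - counts, decreasing = TRUE)
      counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1L
    }
    # every split non-empty when the class has >= 3 records
    for (s in which(counts == 0L)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1L
      counts[s] <- counts[s] + 1L
    }
    split[idx] <- rep(SPLITS, counts)
  }
  manifest$split <- split
  manifest
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with documented defaults. The
#' defaults mirror the reference operating point (32x32 CNN input, 224x224
#' explainable branch, 10 training epochs); [edl_desk_config()] gives the
#' reduced desk-scale profile used in the package's own validation.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param class_names Ordered class labels.
#' @param epochs Training epochs per branch (default 10).
#' @param learning_rate,batch_size,momentum SGD settings for the CNN branches.
#' @param lr_decay Per-epoch learning-rate decay factor (epoch k trains at
#'   `learning_rate * lr_decay^(k-1)`); the augmented branch uses the
#'   faster `gan$classifier_lr_decay` since it sees more updates per epoch.
#' @param image_size Named list of per-branch input sizes `c(H, W)`.
#' @param gan GAN settings: `latent_dim`, `steps`, `batch_size`, `lr`,
#'   `momentum`, `n_synthetic_per_class` (`NA` = match the real class size).
#' @param xdl Explainable-branch settings: `width_multiplier`,
#'   `crop_threshold`, `crop_margin`, `cam_layer`, `patience`,
#'   `learning_rate`, `momentum`.
#' @param voting_mode `"overall"` (one accuracy per member) or `"per_class"`
#'   (member recall on its own predicted class).
#' @param precedence Tie-break order for the accuracy fallback.
#' @param iqr_multiplier IQR fence multiplier (default 1.5).
#' @param outlier_feature `"mean_brightness"` or `"embedding"`.
#' @param split_fractions Train/validation/test fractions.
#' @return A validated `edl_config` list.
#' @export
edl_config <- function(seed = 1L,
                       class_names = CLASSES_DEFAULT,
                       epochs = 10L,
                       learning_rate = 0.05,
                       lr_decay = 0.9,
                       batch_size = 32L,
                       momentum = 0.5,
                       image_size = list(cnn = c(32L, 32L),
                                         gan = c(32L, 32L),
                                         xdl = c(224L, 224L)),
                       gan = list(),
                       xdl = list(),
                       voting_mode = c("overall", "per_class"),
                       precedence = c("XDL", "GAN", "CNN"),
                       iqr_multiplier = 1.5,
                       outlier_feature = c("mean_brightness", "embedding"),
                       split_fractions = c(0.75, 0.16, 0.09)) {
  gan_def <- list(latent_dim = 32L, steps = 2000L, batch_size = 16L,
                  lr = 0.05, momentum = 0.5, n_synthetic_per_class = NA,
                  classifier_lr_decay = 0.8)
  xdl_def <- list(width_multiplier = 1, crop_threshold = 0.5,
                  crop_margin = 4L, cam_layer = "conv5_3", patience = 3L,
                  min_epochs = 6L, learning_rate = 0.015, momentum = 0.9)
  gan <- utils::modifyList(gan_def, gan)
  xdl <- utils::modifyList(xdl_def, xdl)
  cfg <- list(seed = as.integer(seed), class_names = class_names,
              n_classes = length(class_names), epochs = as.integer(epochs),
              learning_rate = learning_rate, lr_decay = lr_decay,
              batch_size = as.integer(batch_size),
              momentum = momentum, image_size = image_size, gan = gan,
              xdl = xdl, voting_mode = match.arg(voting_mode),
              precedence = precedence, iqr_multiplier = iqr_multiplier,
              outlier_feature = match.arg(outlier_feature),
              split_fractions = split_fractions)
  validate_config(cfg)
  class(cfg) <- "edl_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (cfg$n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  if (cfg$n_classes != length(cfg$class_names))
    stop("n_classes must equal length(class_names)", call. = FALSE)
  if (cfg$iqr_multiplier <= 0) stop("iqr_multiplier must be > 0", call. = FALSE)
  th <- cfg$xdl$crop_threshold
  if (th <= 0 || th > 1) stop("crop_threshold must be in (0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Desk-scale configuration profile
#'
#' The reduced operating point the package validates itself at: 64x64
#' fixtures, 32x32 CNN/GAN inputs, a 64x64 explainable branch at width
#' multiplier 1/8, and 500 GAN steps. See the methods vignette for the
#' rationale behind these sizes.
#'
#' @param seed Master seed.
#' @param ... Further overrides passed to [edl_config()].
#' @return An `edl_config`.
#' @export
edl_desk_config <- function(seed = 1L, ...) {
  dots <- list(...)
  dots$gan <- utils::modifyList(list(steps = 300L),
                                if (is.null(dots$gan)) list() else dots$gan)
  dots$xdl <- utils::modifyList(list(width_multiplier = 0.125),
                                if (is.null(dots$xdl)) list() else dots$xdl)
  if (is.null(dots$image_size))
    dots$image_size <- list(cnn = c(32L, 32L), gan = c(32L, 32L),
                            xdl = c(64L, 64L))
  do.call(edl_config, c(list(seed = seed), dots))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors the arguments of [edl_config()]; unknown keys are an
#' error so typos fail fast.
#'
#' @param path YAML file.
#' @return An `edl_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(edl_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(raw$image_size))
    raw$image_size <- lapply(raw$image_size, as.integer)
  do.call(edl_config, raw)
}

## per-stage seeds derived from the master seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  offs <- c(fixtures = 101L, split = 211L, cnn = 307L, gan = 401L,
            xdl = 503L, probe = 601L, filter = 701L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% 2147483629L
}

## timestamped stderr logging
edl_log <- function(..., level = "INFO") {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  message(msg)
  invisible(msg)
}

## Classifier inputs are centred (pixel - 0.5) so activations start balanced;
## the GAN networks keep the raw [0, 1] scale of the images they model.
INPUT_CENTER <- 0.5

## load all images of one split as a centred (H,W,3,N) tensor + labels
load_split_tensor <- function(manifest, split, size, class_names) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("manifest has an empty '", split, "' split", call. = FALSE)
  n <- nrow(rows)
  x <- array(0, c(size[1L], size[2L], 3L, n))
  for (i in seq_len(n)) x[, , , i] <- load_image(rows$image_path[i], size)
  list(x = x - INPUT_CENTER, y = match(rows$label, class_names),
       paths = rows$image_path, labels = rows$label,
       mask_paths = rows$mask_path)
}
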