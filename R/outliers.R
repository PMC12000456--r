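## Interquartile-range outlier rejection: the dataset gate run before any
## training. A scalar feature is extracted per image (mean brightness by
## default, or the L2 norm of a convolutional embedding), quartiles are taken
## over the whole dataset, and images outside
## [Q1 - m*IQR, Q3 + m*IQR] (m = 1.5) are rejected.

#' Extract the outlier-screening feature of an image
#'
#' `mean_brightness` is the mean over all pixels and channels.
#' `embedding` forwards the image through a seeded VGG-shaped backbone (no
#' pretrained weights; the same random backbone for every image) up to global
#' average pooling and reduces the pooled vector to its L2 norm.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param method `"mean_brightness"` or `"embedding"`.
#' @param backbone Optional prebuilt embedding backbone (reused across calls).
#' @return Scalar feature value.
#' @export
extract_feature <- function(image, method = c("mean_brightness", "embedding"),
                            backbone = NULL) {
  method <- match.arg(method)
  if (method == "mean_brightness") return(mean(image))
  if (is.null(backbone)) backbone <- embedding_backbone()
  x <- array(resize_image(image, backbone$input_size),
             c(backbone$input_size, 3L, 1L))
  v <- nn_forward_until(backbone$net, x, backbone$gap_index)
  sqrt(sum(v^2))
}

## small fixed-seed VGG-shaped feature extractor for embedding mode
embedding_backbone <- function(size = c(64L, 64L), seed = 20240101L) {
  model <- build_backbone(input_size = size, width_multiplier = 0.125,
                          n_classes = 2L, seed = seed)
  gap_index <- which(vapply(model$net$layers, `[[`, "", "type") == "gap")
  list(net = model$net, gap_index = gap_index, input_size = size)
}

## forward through layers 1..k only
nn_forward_until <- function(net, x, k) {
  sub <- net
  sub$layers <- net$layers[seq_len(k)]
  nn_forward(sub, x)
}

#' Quartiles and rejection fences of a feature sample
#'
#' Quartiles use sorted linear interpolation at position `p * (n - 1)`
#' (the convention of [stats::quantile()] type 7). The fences are
#' `Q1 - multiplier * IQR` and `Q3 + multiplier * IQR`.
#'
#' @param values At least 4 finite feature values.
#' @param multiplier Fence multiplier, default 1.5.
#' @return An `iqr_bounds` with fields `q1`, `q3`, `iqr`, `multiplier`,
#'   `lower`, `upper`.
#' @export
compute_iqr_bounds <- function(values, multiplier = 1.5) {
  if (length(values) < 4L)
    stop("need at least 4 values for quartiles", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite feature values", call. = FALSE)
  if (multiplier <= 0) stop("multiplier must be > 0", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2L] - q[1L]
  structure(list(q1 = q[1L], q3 = q[2L], iqr = iqr, multiplier = multiplier,
                 lower = q[1L] - multiplier * iqr,
                 upper = q[2L] + multiplier * iqr),
            class = "iqr_bounds")
}

#' @export
print.iqr_bounds <- function(x, ...) {
  cat(sprintf("IQR fences: Q1 = %.4g, Q3 = %.4g, IQR = %.4g (x%.3g)\n",
              x$q1, x$q3, x$iqr, x$multiplier))
  cat(sprintf("  keep interval [%.4g, %.4g]\n", x$lower, x$upper))
  invisible(x)
}

#' Reject outlier images from a manifest
#'
#' Extracts the screening feature for every record, computes the IQR fences
#' over the whole dataset, and partitions the records into kept and rejected.
#' The fence interval is closed: values exactly on a fence are kept.
#'
#' @param manifest Non-empty [edl_manifest()].
#' @param feature `"mean_brightness"` or `"embedding"`.
#' @param multiplier Fence multiplier, default 1.5.
#' @return A `rejection_report`: `kept` (manifest), `rejected` (data frame of
#'   `image_path`, `feature_value`, `reason`), `bounds`, `feature_name`.
#' @export
filter_outliers <- function(manifest, feature = "mean_brightness",
                            multiplier = 1.5) {
  stopifnot(inherits(manifest, "edl_manifest"))
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  backbone <- if (feature == "embedding") embedding_backbone() else NULL
  vals <- vapply(seq_len(nrow(manifest)), function(i) {
    v <- tryCatch(
      extract_feature(load_image(manifest$image_path[i]), feature,
                      backbone = backbone),
      error = function(e) stop("feature extraction failed for ",
                               manifest$image_path[i], ": ",
                               conditionMessage(e), call. = FALSE))
    v
  }, 0)
  bounds <- compute_iqr_bounds(vals, multiplier)
  out <- vals < bounds$lower | vals > bounds$upper
  rejected <- data.frame(
    image_path = manifest$image_path[out],
    feature_value = vals[out],
    reason = ifelse(vals[out] < bounds$lower, "below_lower", "above_upper"),
    stringsAsFactors = FALSE)
  kept <- manifest[!out, , drop = FALSE]
  attr(kept, "class_names") <- attr(manifest, "class_names")
  structure(list(kept = kept, rejected = rejected, bounds = bounds,
                 feature_name = feature, feature_values = vals),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("Outlier rejection on '%s': kept %d, rejected %d\n",
              x$feature_name, nrow(x$kept), nrow(x$rejected)))
  print(x$bounds)
  invisible(x)
}

#' Serialize a rejection report
#'
#' Writes the report as JSON plus the kept manifest as CSV.
#'
#' @param report A `rejection_report`.
#' @param json_path,kept_csv_path Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_rejection_report <- function(report, json_path = NULL,
                                   kept_csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(feature = report$feature_name,
                    bounds = unclass(report$bounds),
                    n_kept = nrow(report$kept),
                    n_rejected = nrow(report$rejected),
                    rejected = report$rejected)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(kept_csv_path)) write_manifest(report$kept, kept_csv_path)
  invisible(report)
}
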