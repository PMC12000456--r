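## Top-level fit: outlier rejection, the three branches, the vote, and the
## metric suite, as one classed model object.

#' Fit the ensemble diagnosis model
#'
#' Runs the full pipeline on a manifest: IQR outlier rejection over the whole
#' dataset, training of the three ensemble members (plain CNN, GAN-augmented
#' CNN, explainable VGG branch with attention-crop augmentation), per-image
#' ensemble voting on the test split, and the confusion-matrix metric suite
#' for each member and for the ensemble.
#'
#' @param manifest An [edl_manifest()]. If any of the three splits is empty
#'   the kept records are re-split with the config's `split_fractions`.
#' @param config An [edl_config()]; see [edl_desk_config()] for the reduced
#'   profile.
#' @param out_dir Optional run directory for artifacts (synthetic images,
#'   checkpoints, reports). A temporary directory is used when `NULL`.
#' @return An `edl` object with elements `members` (3 `edl_classifier`s),
#'   `votes`, `metrics` (per member and `EDL`), `rejection`, `config`,
#'   `manifest` (the kept records), `provenance`.
#' @seealso [predict.edl()], [summary.edl()], [run_all()]
#' @export
edl <- function(manifest, config = edl_desk_config(), out_dir = NULL) {
  stopifnot(inherits(manifest, "edl_manifest"), inherits(config, "edl_config"))
  if (is.null(out_dir)) out_dir <- tempfile("edl_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  edl_log("stage filter: IQR outlier rejection (", config$outlier_feature,
          ", x", config$iqr_multiplier, ")")
  rejection <- filter_outliers(manifest, config$outlier_feature,
                               config$iqr_multiplier)
  kept <- rejection$kept
  edl_log("stage filter: rejected ", nrow(rejection$rejected), " of ",
          nrow(manifest))
  lap(t0, "filter")

  if (any(vapply(SPLITS, function(s) !any(kept$split == s), TRUE)))
    kept <- split_manifest(kept, config$split_fractions,
                           derive_seed(config$seed, "split"))

  t0 <- tic()
  edl_log("stage cnn: training CNN branch")
  cnn <- train_classifier(
    build_cnn(cnn_arch(input_size = config$image_size$cnn,
                       n_classes = config$n_classes),
              seed = derive_seed(config$seed, "cnn")),
    kept, config, name = "CNN")
  lap(t0, "cnn")

  t0 <- tic()
  edl_log("stage gan: training GAN branch")
  gan <- train_gan_branch(kept, config, file.path(out_dir, "gan"))
  lap(t0, "gan")

  t0 <- tic()
  edl_log("stage xdl: training explainable branch")
  xdl <- train_xdl(kept, config)
  lap(t0, "xdl")

  t0 <- tic()
  members <- list(cnn, gan, xdl)
  votes <- ensemble_predict(members, kept, split = "test",
                            mode = config$voting_mode,
                            precedence = config$precedence)
  class_names <- config$class_names
  metrics <- list()
  for (m in members) {
    cmat <- confusion_matrix(votes$predictions$truth,
                             votes$predictions[[paste0("label_",
                                                       tolower(m$name))]],
                             class_names)
    metrics[[m$name]] <- compute_metrics(cmat)
  }
  metrics$EDL <- compute_metrics(
    confusion_matrix(votes$predictions$truth, votes$predictions$final_label,
                     class_names))
  lap(t0, "vote")

  fit <- structure(list(members = members, votes = votes, metrics = metrics,
                        rejection = rejection, config = config,
                        manifest = kept, out_dir = out_dir,
                        provenance = list(seed = config$seed,
                                          config_hash = config_hash(config),
                                          timings = timings)),
                   class = "edl")
  fit
}

## tiny polynomial hash over the serialized config, for provenance only
config_hash <- function(config) {
  bytes <- charToRaw(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
  h <- 5381
  for (b in as.integer(bytes)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.edl <- function(x, ...) {
  cat("Ensemble bladder-tissue classifier (3 members + vote)\n")
  for (m in x$members)
    cat(sprintf("  %-4s validation accuracy %.3f\n", m$name,
                m$validation_accuracy))
  cat(sprintf("  test accuracy: %s; ensemble %.3f\n",
              paste(sprintf("%s %.3f", names(x$metrics)[1:3],
                            vapply(x$metrics[1:3], `[[`, 0, "accuracy")),
                    collapse = ", "),
              x$metrics$EDL$accuracy))
  print(x$votes)
  invisible(x)
}

#' Summarize a fitted ensemble
#'
#' @param object An `edl` fit.
#' @param ... Unused.
#' @return A data frame of the metric suite per member and for the ensemble,
#'   invisibly (also printed).
#' @export
summary.edl <- function(object, ...) {
  rows <- lapply(names(object$metrics), function(nm) {
    m <- object$metrics[[nm]]
    data.frame(model = nm, accuracy = m$accuracy, error = m$error,
               macro_precision = m$macro_precision,
               macro_recall = m$macro_recall,
               micro_precision = m$micro_precision,
               micro_recall = m$micro_recall, f1 = m$f1)
  })
  tab <- do.call(rbind, rows)
  cat(sprintf("Rejected %d image(s) by IQR screening; scored %d test images\n",
              nrow(object$rejection$rejected), object$metrics$EDL$n))
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Predict with a fitted ensemble
#'
#' @param object An `edl` fit.
#' @param newdata An image array, list of arrays, or manifest.
#' @param ... Unused.
#' @return Data frame with the three member labels, the scenario and the
#'   final voted label per image.
#' @export
predict.edl <- function(object, newdata, ...) {
  imgs <- if (is.array(newdata) && length(dim(newdata)) == 3L) list(newdata)
          else if (inherits(newdata, "edl_manifest"))
            lapply(newdata$image_path, load_image)
          else newdata
  out <- lapply(imgs, function(im) {
    reps <- lapply(object$members, member_report_from, image = im)
    v <- ensemble_vote(reps, mode = object$config$voting_mode,
                       precedence = object$config$precedence)
    data.frame(label_cnn = reps[[1L]]$predicted_label,
               label_gan = reps[[2L]]$predicted_label,
               label_xdl = reps[[3L]]$predicted_label,
               scenario = v$scenario, final_label = v$final_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot a fitted ensemble
#'
#' Bar chart of test accuracy per member and for the ensemble.
#'
#' @param x An `edl` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.edl <- function(x, ...) {
  acc <- vapply(x$metrics, `[[`, 0, "accuracy")
  graphics::barplot(acc, ylim = c(0, 1), ylab = "test accuracy", ...)
  graphics::abline(h = 1 / length(x$config$class_names), lty = 2)
  invisible(x)
}

#' Run the whole pipeline from a YAML file
#'
#' The YAML has up to three top-level keys: `config` (arguments of
#' [edl_config()]), `fixtures` (arguments of [fixture_config()]; when present
#' a synthetic dataset is generated), and `data_manifest` (path of an
#' existing manifest CSV; used when `fixtures` is absent). Artifacts —
#' config copy, rejection report, member checkpoints and sidecars,
#' predictions table, metric reports, run summary — are written under
#' `out_dir`.
#'
#' @param config_path YAML file path.
#' @param out_dir Run directory (default: `runs/<time>` under the working
#'   directory).
#' @return The fitted `edl` object, invisibly.
#' @export
run_all <- function(config_path, out_dir = NULL) {
  raw <- yaml::read_yaml(config_path)
  bad <- setdiff(names(raw), c("config", "fixtures", "data_manifest"))
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg_args <- if (is.null(raw$config)) list() else raw$config
  if (!is.null(cfg_args$image_size))
    cfg_args$image_size <- lapply(cfg_args$image_size, as.integer)
  config <- do.call(edl_config, cfg_args)
  if (is.null(out_dir))
    out_dir <- file.path("runs", format(Sys.time(), "%Y%m%d-%H%M%S"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(config_path, file.path(out_dir, "config.yaml"), overwrite = TRUE)

  if (!is.null(raw$fixtures)) {
    fx <- do.call(fixture_config,
                  utils::modifyList(list(seed = config$seed), raw$fixtures))
    edl_log("stage fixtures: generating synthetic dataset")
    manifest <- generate_fixtures(fx, file.path(out_dir, "fixtures"))
  } else if (!is.null(raw$data_manifest)) {
    manifest <- load_manifest(raw$data_manifest, config$class_names)
  } else stop("config must provide either 'fixtures' or 'data_manifest'",
              call. = FALSE)

  fit <- edl(manifest, config, out_dir = out_dir)

  write_rejection_report(fit$rejection,
                         file.path(out_dir, "rejection.json"),
                         file.path(out_dir, "kept_manifest.csv"))
  for (m in fit$members) save_classifier(m, file.path(out_dir, "checkpoints"))
  utils::write.csv(fit$votes$predictions,
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  for (nm in names(fit$metrics))
    write_metrics(fit$metrics[[nm]],
                  file.path(out_dir, paste0("metrics_", tolower(nm), ".json")))
  jsonlite::write_json(
    list(seed = config$seed, config_hash = fit$provenance$config_hash,
         timings = as.list(fit$provenance$timings),
         vote_summary = fit$votes$summary,
         n_rejected = nrow(fit$rejection$rejected)),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  edl_log("run complete; artifacts in ", out_dir)
  invisible(fit)
}
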