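## Two-scenario ensemble vote. With three members there are exactly three
## agreement patterns: all equal (consensus), exactly two equal (relative
## majority), all distinct (the abnormal case) — in the last case the member
## with the highest stored accuracy decides. The Majority Fault Problem
## (a high-accuracy dissenter outvoted by two low-accuracy agreeing members)
## is detected and flagged but not overridden: the remedy is choosing members
## with close accuracies, not a different rule.

#' Build a member report for the vote
#'
#' @param name Member name (`"CNN"`, `"GAN"`, `"XDL"`).
#' @param predicted_label Predicted class label.
#' @param accuracy Stored overall validation accuracy in `[0, 1]`.
#' @param per_class_recall Optional named per-class validation recall (needed
#'   for `mode = "per_class"`).
#' @param probs Optional probability vector.
#' @return A `member_report`.
#' @export
member_report <- function(name, predicted_label, accuracy,
                          per_class_recall = NULL, probs = NULL) {
  if (accuracy < 0 || accuracy > 1)
    stop("accuracy must be in [0, 1]", call. = FALSE)
  structure(list(name = name, predicted_label = predicted_label,
                 accuracy = accuracy, per_class_recall = per_class_recall,
                 probs = probs),
            class = "member_report")
}

#' @rdname member_report
#' @param classifier A trained `edl_classifier`.
#' @param image Image array (resized to the branch input).
#' @export
member_report_from <- function(classifier, image) {
  pr <- predict(classifier, image)
  member_report(classifier$name, pr$labels[1L],
                classifier$validation_accuracy,
                per_class_recall = classifier$per_class_recall,
                probs = pr$probs[1L, ])
}

check_reports <- function(reports) {
  if (length(reports) != 3L)
    stop("the vote needs exactly 3 member reports", call. = FALSE)
  nm <- vapply(reports, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate member names in vote", call. = FALSE)
  nm
}

#' Ensemble vote with accuracy fallback
#'
#' Scenario (i): all three members agree — consensus. Scenario (ii): exactly
#' two agree — that class wins (relative majority). Scenario (iii): all three
#' disagree — the member with the highest stored accuracy (mode `"overall"`)
#' or the highest validation recall on its own predicted class (mode
#' `"per_class"`) decides; accuracy ties break by the precedence order.
#'
#' @param reports List of exactly 3 [member_report()]s with distinct names.
#' @param mode `"overall"` or `"per_class"`.
#' @param precedence Member-name order used to break fallback ties.
#' @return A `vote_outcome`: `final_label`, `scenario`, `decisive_member`
#'   (fallback only), `mfp_flag`.
#' @export
ensemble_vote <- function(reports, mode = c("overall", "per_class"),
                          precedence = c("XDL", "GAN", "CNN")) {
  mode <- match.arg(mode)
  nm <- check_reports(reports)
  labels <- vapply(reports, `[[`, "", "predicted_label")
  tab <- table(labels)
  n_distinct <- length(tab)
  mfp <- detect_mfp(reports)

  if (n_distinct == 1L) {
    out <- list(final_label = labels[1L], scenario = "consensus",
                decisive_member = NULL, mfp_flag = mfp)
  } else if (n_distinct == 2L) {
    win <- names(tab)[tab == 2L]
    out <- list(final_label = win, scenario = "majority",
                decisive_member = NULL, mfp_flag = mfp)
    if (mfp) edl_log("majority fault: high-accuracy dissenter outvoted",
                     level = "WARN")
  } else {
    score <- if (mode == "overall") {
      vapply(reports, `[[`, 0, "accuracy")
    } else {
      vapply(reports, function(r) {
        if (is.null(r$per_class_recall))
          stop("per_class mode needs per_class_recall on every report",
               call. = FALSE)
        unname(r$per_class_recall[r$predicted_label])
      }, 0)
    }
    top <- which(score == max(score))
    if (length(top) > 1L) {
      prec <- match(nm[top], precedence)
      prec[is.na(prec)] <- length(precedence) + match(nm[top], sort(nm))[is.na(prec)]
      top <- top[which.min(prec)]
    }
    out <- list(final_label = labels[top], scenario = "accuracy_fallback",
                decisive_member = nm[top], mfp_flag = mfp)
  }
  structure(out, class = "vote_outcome")
}

#' Detect the Majority Fault Problem
#'
#' TRUE iff exactly two members agree and the dissenting member's accuracy
#' strictly exceeds both agreeing members' accuracies.
#'
#' @param reports List of exactly 3 [member_report()]s.
#' @return Logical flag.
#' @export
detect_mfp <- function(reports) {
  check_reports(reports)
  labels <- vapply(reports, `[[`, "", "predicted_label")
  acc <- vapply(reports, `[[`, 0, "accuracy")
  tab <- table(labels)
  if (length(tab) != 2L) return(FALSE)
  dis <- which(labels == names(tab)[tab == 1L])
  all(acc[dis] > acc[-dis])
}

#' @export
print.vote_outcome <- function(x, ...) {
  cat(sprintf("vote: %s (%s%s)%s\n", x$final_label, x$scenario,
              if (!is.null(x$decisive_member))
                paste0(" via ", x$decisive_member) else "",
              if (isTRUE(x$mfp_flag)) "  [MFP flagged]" else ""))
  invisible(x)
}

#' Run the ensemble over a manifest split
#'
#' Each branch resizes every image to its own input size and predicts; the
#' three member reports are combined per image by [ensemble_vote()].
#'
#' @param members List of 3 trained `edl_classifier`s (CNN, GAN, XDL).
#' @param manifest An [edl_manifest()].
#' @param split Which split to score (default `"test"`).
#' @param mode Voting mode.
#' @param precedence Fallback tie-break order.
#' @return An `edl_votes` list: `predictions` (data frame with one row per
#'   image: member labels and accuracies, scenario, final label), `outcomes`,
#'   and `summary` (scenario and MFP counts).
#' @export
ensemble_predict <- function(members, manifest, split = "test",
                             mode = c("overall", "per_class"),
                             precedence = c("XDL", "GAN", "CNN")) {
  mode <- match.arg(mode)
  if (length(members) != 3L)
    stop("need exactly 3 member classifiers", call. = FALSE)
  cs <- lapply(members, `[[`, "class_names")
  if (!all(vapply(cs, identical, TRUE, cs[[1L]])))
    stop("members were trained on different class sets", call. = FALSE)
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty split: ", split, call. = FALSE)

  branch_labels <- lapply(members, function(m) {
    sub <- rows
    attr(sub, "class_names") <- attr(manifest, "class_names")
    class(sub) <- class(manifest)
    predict(m, sub)$labels
  })
  nm <- vapply(members, `[[`, "", "name")
  outcomes <- vector("list", nrow(rows))
  finals <- character(nrow(rows))
  scenarios <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    reps <- lapply(seq_along(members), function(k)
      member_report(nm[k], branch_labels[[k]][i],
                    members[[k]]$validation_accuracy,
                    per_class_recall = members[[k]]$per_class_recall))
    v <- ensemble_vote(reps, mode = mode, precedence = precedence)
    outcomes[[i]] <- v
    finals[i] <- v$final_label
    scenarios[i] <- v$scenario
  }
  pred <- data.frame(image_path = rows$image_path, truth = rows$label,
                     stringsAsFactors = FALSE)
  for (k in seq_along(members)) {
    pred[[paste0("label_", tolower(nm[k]))]] <- branch_labels[[k]]
    pred[[paste0("accuracy_", tolower(nm[k]))]] <-
      members[[k]]$validation_accuracy
  }
  pred$scenario <- scenarios
  pred$final_label <- finals
  summary <- list(
    n_consensus = sum(scenarios == "consensus"),
    n_majority = sum(scenarios == "majority"),
    n_fallback = sum(scenarios == "accuracy_fallback"),
    n_mfp_flags = sum(vapply(outcomes, function(o) isTRUE(o$mfp_flag), TRUE)))
  structure(list(predictions = pred, outcomes = outcomes, summary = summary),
            class = "edl_votes")
}

#' @export
print.edl_votes <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("ensemble vote over %d images: %d consensus, ",
                     "%d majority, %d fallback (%d MFP flags)\n"),
              nrow(x$predictions), s$n_consensus, s$n_majority, s$n_fallback,
              s$n_mfp_flags))
  invisible(x)
}
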