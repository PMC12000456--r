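mk_reports <- function(labels, accs = c(0.78, 0.82, 0.86),
                       names = c("CNN", "GAN", "XDL"), recalls = NULL) {
  lapply(seq_along(labels), function(i)
    member_report(names[i], labels[i], accs[i],
                  per_class_recall = if (!is.null(recalls)) recalls[[i]]))
}

test_that("the worked voting example reproduces both scenarios", {
  # Case 1: two members agree -> relative majority
  v1 <- ensemble_vote(mk_reports(c("NST", "HGC", "HGC")))
  expect_equal(v1$final_label, "HGC")
  expect_equal(v1$scenario, "majority")
  expect_null(v1$decisive_member)

  # Case 2: full disagreement -> highest-accuracy member decides
  v2 <- ensemble_vote(mk_reports(c("NST", "LGC", "HGC")))
  expect_equal(v2$final_label, "HGC")
  expect_equal(v2$scenario, "accuracy_fallback")
  expect_equal(v2$decisive_member, "XDL")

  v3 <- ensemble_vote(mk_reports(c("LGC", "LGC", "LGC")))
  expect_equal(v3$final_label, "LGC")
  expect_equal(v3$scenario, "consensus")
})

test_that("fallback ties break by the precedence order", {
  v <- ensemble_vote(mk_reports(c("NST", "LGC", "HGC"),
                                accs = c(0.90, 0.90, 0.80)))
  expect_equal(v$decisive_member, "GAN")   # XDL > GAN > CNN, XDL not in tie
  expect_equal(v$final_label, "LGC")
  v2 <- ensemble_vote(mk_reports(c("NST", "LGC", "HGC"),
                                 accs = c(0.90, 0.90, 0.80)),
                      precedence = c("CNN", "GAN", "XDL"))
  expect_equal(v2$decisive_member, "CNN")
  expect_equal(v2$final_label, "NST")
})

test_that("per-class mode follows each member's recall on its own prediction", {
  recalls <- list(
    c(HGC = 0.2, LGC = 0.2, NST = 0.95, NTL = 0.2),
    c(HGC = 0.2, LGC = 0.50, NST = 0.2, NTL = 0.2),
    c(HGC = 0.6, LGC = 0.2, NST = 0.2, NTL = 0.2))
  v <- ensemble_vote(mk_reports(c("NST", "LGC", "HGC"), recalls = recalls),
                     mode = "per_class")
  expect_equal(v$final_label, "NST")       # CNN's own-class recall 0.95 wins
  expect_equal(v$decisive_member, "CNN")
  expect_error(ensemble_vote(mk_reports(c("NST", "LGC", "HGC")),
                             mode = "per_class"), "per_class_recall")
})

test_that("vote validation rejects malformed report sets", {
  expect_error(ensemble_vote(mk_reports(c("NST", "HGC"))), "exactly 3")
  bad <- mk_reports(c("NST", "HGC", "HGC"), names = c("CNN", "CNN", "XDL"))
  expect_error(ensemble_vote(bad), "duplicate")
  expect_error(member_report("CNN", "HGC", 1.2), "accuracy")
})

test_that("scenario classification partitions all 64 label assignments", {
  classes <- c("HGC", "LGC", "NST", "NTL")
  for (a in classes) for (b in classes) for (c in classes) {
    v <- ensemble_vote(mk_reports(c(a, b, c)))
    # independent counting oracle
    n_distinct <- length(unique(c(a, b, c)))
    want <- if (n_distinct == 1L) "consensus"
            else if (n_distinct == 2L) "majority"
            else "accuracy_fallback"
    expect_equal(v$scenario, want)
    if (want == "consensus") expect_equal(v$final_label, a)
    if (want == "majority") {
      agreed <- names(which.max(table(c(a, b, c))))
      expect_equal(v$final_label, agreed)
    }
    if (want == "accuracy_fallback")
      expect_equal(v$final_label, c)       # XDL holds the highest accuracy
  }
})

test_that("with distinct accuracies the fallback follows the argmax member", {
  set.seed(17)
  classes <- c("HGC", "LGC", "NST", "NTL")
  for (rep in 1:40) {
    labels <- sample(classes, 3L)           # all distinct
    accs <- round(runif(3), 3)
    if (anyDuplicated(accs)) next
    v <- ensemble_vote(mk_reports(labels, accs = accs))
    expect_equal(v$final_label, labels[which.max(accs)])
    expect_equal(v$scenario, "accuracy_fallback")
    # determinism
    v2 <- ensemble_vote(mk_reports(labels, accs = accs))
    expect_identical(unclass(v), unclass(v2))
  }
})

test_that("the majority fault is flagged but not overridden", {
  r <- mk_reports(c("LGC", "LGC", "HGC"), accs = c(0.60, 0.62, 0.90))
  expect_true(detect_mfp(r))
  v <- ensemble_vote(r)
  expect_true(v$mfp_flag)
  expect_equal(v$final_label, "LGC")        # majority still wins

  expect_false(detect_mfp(mk_reports(c("LGC", "LGC", "LGC"),
                                     accs = c(0.6, 0.62, 0.9))))
  # dissenter not strictly above both agreeing members
  expect_false(detect_mfp(mk_reports(c("LGC", "LGC", "HGC"),
                                     accs = c(0.60, 0.62, 0.61))))
  expect_false(detect_mfp(mk_reports(c("NST", "LGC", "HGC"),
                                     accs = c(0.6, 0.62, 0.9))))
})
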