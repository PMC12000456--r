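test_that("screening features behave on degenerate images", {
  u <- array(0.5, c(8, 8, 3))
  expect_equal(extract_feature(u, "mean_brightness"), 0.5)
  cb <- array(0, c(8, 8, 3))
  cb[, , ] <- (outer(1:8, 1:8, `+`) %% 2)          # checkerboard of 0 and 1
  expect_equal(extract_feature(cb, "mean_brightness"), 0.5)
  expect_equal(extract_feature(array(0, c(8, 8, 3)), "mean_brightness"), 0)
  expect_error(extract_feature(u, "luminance"))
})

test_that("embedding feature is a deterministic positive scalar", {
  set.seed(3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  bb <- cystodl:::embedding_backbone()
  v1 <- extract_feature(img, "embedding", backbone = bb)
  v2 <- extract_feature(img, "embedding", backbone = bb)
  expect_identical(v1, v2)
  expect_gt(v1, 0)
  expect_length(v1, 1L)
})

test_that("IQR fences match hand-derived quartiles", {
  b <- compute_iqr_bounds(rep(1, 4))
  expect_equal(b$q1, 1); expect_equal(b$q3, 1)
  expect_equal(b$iqr, 0); expect_equal(b$lower, 1); expect_equal(b$upper, 1)

  b <- compute_iqr_bounds(c(2, 4, 6, 8, 10, 12, 14, 16))
  expect_equal(b$q1, 5.5)
  expect_equal(b$q3, 12.5)
  expect_equal(b$iqr, 7)
  expect_equal(b$lower, -5)
  expect_equal(b$upper, 23)
  expect_equal(formals(compute_iqr_bounds)$multiplier, 1.5)

  expect_error(compute_iqr_bounds(c(1, 2, 3)), "at least 4")
  expect_error(compute_iqr_bounds(c(1, 2, 3, NA)), "non-finite")
  expect_error(compute_iqr_bounds(1:8, multiplier = -1), "multiplier")
})

test_that("IQR bounds agree with an independent sort-and-interpolate oracle", {
  # oracle: sorted linear interpolation at position p*(n-1), written from
  # scratch without stats::quantile
  oracle_q <- function(v, p) {
    v <- sort(v)
    pos <- p * (length(v) - 1)
    lo <- floor(pos)
    hi <- ceiling(pos)
    v[lo + 1] + (pos - lo) * (v[hi + 1] - v[lo + 1])
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:50, 1)
    v <- rnorm(n, sd = 10)
    mult <- runif(1, 0.5, 3)
    b <- compute_iqr_bounds(v, mult)
    q1 <- oracle_q(v, 0.25); q3 <- oracle_q(v, 0.75)
    expect_equal(b$q1, q1, tolerance = 1e-12)
    expect_equal(b$q3, q3, tolerance = 1e-12)
    expect_equal(b$iqr, q3 - q1, tolerance = 1e-12)
    expect_equal(b$lower, q1 - mult * (q3 - q1), tolerance = 1e-12)
    expect_equal(b$upper, q3 + mult * (q3 - q1), tolerance = 1e-12)
    expect_lte(b$q1, b$q3)
    expect_lte(b$lower, b$upper)
  }
})

test_that("filtering rejects by fence, keeps boundaries, and partitions", {
  dir <- withr::local_tempdir()
  vals <- c(0.5, 0.5, 0.5, 0.5, 0.9)
  paths <- vapply(seq_along(vals), function(i)
    write_uniform_png(vals[i], file.path(dir, paste0("u", i, ".png"))), "")
  m <- edl_manifest(data.frame(image_path = paths, label = "NTL",
                               split = "train", stringsAsFactors = FALSE))
  rep1 <- filter_outliers(m)
  # hand quartiles of the 5 sorted values collapse the fences to [0.5, 0.5]
  expect_equal(rep1$bounds$q1, 0.5, tolerance = 1 / 255)
  expect_equal(rep1$bounds$q3, 0.5, tolerance = 1 / 255)
  expect_equal(nrow(rep1$rejected), 1L)
  expect_equal(rep1$rejected$reason, "above_upper")
  expect_equal(basename(rep1$rejected$image_path), "u5.png")
  expect_equal(nrow(rep1$kept), 4L)

  # identical features: fences collapse but the closed interval keeps all
  m2 <- m[1:4, ]
  attr(m2, "class_names") <- attr(m, "class_names")
  rep2 <- filter_outliers(m2)
  expect_equal(nrow(rep2$rejected), 0L)
  expect_equal(nrow(rep2$kept), 4L)
})

test_that("raising the multiplier never rejects a previously kept image", {
  fx <- small_fixtures()
  rejected_at <- lapply(c(0.5, 1, 1.5, 3), function(mult)
    filter_outliers(fx$manifest, multiplier = mult)$rejected$image_path)
  for (k in seq_len(length(rejected_at) - 1L))
    expect_true(all(rejected_at[[k + 1L]] %in% rejected_at[[k]]))
  # partition property
  rep1 <- filter_outliers(fx$manifest)
  expect_equal(sort(c(rep1$kept$image_path, rep1$rejected$image_path)),
               sort(fx$manifest$image_path))
  expect_length(intersect(rep1$kept$image_path, rep1$rejected$image_path), 0L)
  expect_true(all(rep1$rejected$feature_value < rep1$bounds$lower |
                    rep1$rejected$feature_value > rep1$bounds$upper))
})

test_that("rejection reports serialize to JSON and CSV", {
  fx <- small_fixtures()
  rep1 <- filter_outliers(fx$manifest)
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "rej.json"); cp <- file.path(dir, "kept.csv")
  write_rejection_report(rep1, jp, cp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$n_rejected, nrow(rep1$rejected))
  expect_equal(nrow(load_manifest(cp)), nrow(rep1$kept))
})
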