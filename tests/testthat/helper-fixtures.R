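# Shared fixtures and the (expensive) end-to-end fit, built once per test run.

.cache <- new.env(parent = emptyenv())

# small fixture set for unit tests: 12/class at 48x48 with 10% outliers
small_fixtures <- function() {
  if (is.null(.cache$small)) {
    dir <- file.path(tempdir(), "cystodl_small_fx")
    cfg <- fixture_config(n_per_class = 12L, image_size = c(48L, 48L),
                          outlier_fraction = 0.1, lesion_radius_range = c(5, 10),
                          seed = 401L)
    .cache$small <- list(manifest = generate_fixtures(cfg, dir),
                         config = cfg, dir = dir)
  }
  .cache$small
}

# the desk-scale study conditions: 100/class at 64x64, 10% exposure outliers
desk_fixtures <- function() {
  if (is.null(.cache$desk)) {
    dir <- file.path(tempdir(), "cystodl_desk_fx")
    cfg <- fixture_config(n_per_class = 100L, seed = 1L)
    .cache$desk <- list(manifest = generate_fixtures(cfg, dir),
                        config = cfg, dir = dir)
  }
  .cache$desk
}

# full desk-scale pipeline fit (trains all three branches); built on demand
desk_fit <- function() {
  if (is.null(.cache$fit)) {
    fx <- desk_fixtures()
    .cache$fit <- edl(fx$manifest, edl_desk_config(seed = 1L),
                      out_dir = file.path(tempdir(), "cystodl_desk_run"))
  }
  .cache$fit
}

# uniform-colour test image written to a PNG, returns the path
write_uniform_png <- function(value, path, size = c(16L, 16L)) {
  write_image(array(value, c(size, 3L)), path)
  path
}

# manifest rows without any on-disk images (for split/vote/metric tests)
dummy_manifest <- function(n_per_class, classes = c("HGC", "LGC", "NST", "NTL")) {
  df <- expand.grid(i = seq_len(n_per_class), label = classes,
                    stringsAsFactors = FALSE)
  edl_manifest(data.frame(image_path = sprintf("%s_%d.png", df$label, df$i),
                          label = df$label, split = "train",
                          stringsAsFactors = FALSE))
}
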