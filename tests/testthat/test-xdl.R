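test_that("the VGG-shaped backbone reproduces the reference shape chain", {
  tab <- vgg_arch(c(224L, 224L), 1, 4L)$table
  expect_equal(tab$output[tab$name == "conv1_1"], "224x224x64")
  expect_equal(tab$output[tab$name == "pool1"], "112x112x64")
  expect_equal(tab$output[tab$name == "pool2"], "56x56x128")
  expect_equal(tab$output[tab$name == "pool3"], "28x28x256")
  expect_equal(tab$output[tab$name == "pool4"], "14x14x512")
  expect_equal(tab$output[tab$name == "pool5"], "7x7x512")
  expect_equal(sum(tab$kind == "conv"), 13L)

  expect_error(vgg_arch(c(24L, 24L)), "too small")
  expect_error(vgg_arch(width_multiplier = 0), "width_multiplier")

  m1 <- build_backbone(c(64L, 64L), 0.125, 4L, seed = 2L)
  m2 <- build_backbone(c(64L, 64L), 0.125, 4L, seed = 2L)
  expect_identical(m1$net$layers[[1L]]$W, m2$net$layers[[1L]]$W)
  set.seed(1)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  clf <- structure(list(name = "XDL", net = m1$net, input_size = c(64L, 64L),
                        class_names = c("HGC", "LGC", "NST", "NTL")),
                   class = "edl_classifier")
  pr <- predict(clf, img)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-9)
})

test_that("global average pooling is the spatial mean and is linear", {
  expect_equal(global_average_pool(matrix(3.2, 5, 7)), 3.2)
  expect_equal(global_average_pool(matrix(c(1, 5, 3, 7), 2, 2)), 4)
  a <- array(stats::rnorm(4 * 4 * 3), c(4, 4, 3))
  b <- array(stats::rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(global_average_pool(2 * a + 3 * b),
               2 * global_average_pool(a) + 3 * global_average_pool(b))
  expect_length(global_average_pool(a), 3L)
})

# hand-built model: 1x1 linear conv "A" (identity on one channel), then a
# linear head whose class weights set d y^c / d A exactly
toy_cam_net <- function(head_w) {
  ns <- asNamespace("cystodl")
  layers <- list(ns$layer_conv(1L, 1L, 0L, "linear", "A"),
                 ns$layer_flatten(),
                 ns$layer_dense(ncol(head_w), "linear", "logits"))
  net <- ns$nn_init(ns$nn_network(layers, c(2L, 2L, 1L)), 1L)
  net$layers[[1L]]$W[] <- 1
  net$layers[[1L]]$b[] <- 0
  net$layers[[3L]]$W <- head_w
  net$layers[[3L]]$b[] <- 0
  net
}

test_that("Grad-CAM weights and maps match hand application of the formulas", {
  ns <- asNamespace("cystodl")
  A1 <- matrix(c(1, 0, 0, 0), 2, 2)
  x <- array(A1, c(2, 2, 1, 1))
  # class 1: dy/dA = +1 everywhere; class 2: -1; class 3: 0
  head_w <- cbind(rep(1, 4), rep(-1, 4), rep(0, 4))
  net <- toy_cam_net(head_w)
  fw <- ns$nn_forward(net, x, keep_cache = TRUE)

  m1 <- ns$grad_cam_maps(net, fw$caches, 1L, "A")
  expect_equal(m1[, , 1L], A1)                    # w = +1 -> ReLU(A)
  m2 <- ns$grad_cam_maps(net, fw$caches, 2L, "A")
  expect_equal(m2[, , 1L], matrix(0, 2, 2))       # w = -1 -> ReLU(-A) = 0
  m3 <- ns$grad_cam_maps(net, fw$caches, 3L, "A")
  expect_equal(m3[, , 1L], matrix(0, 2, 2))       # zero gradient -> zero map
})

test_that("Grad-CAM weights equal brute-force gradient means on random models", {
  ns <- asNamespace("cystodl")
  set.seed(21)
  for (rep in 1:3) {
    layers <- list(ns$layer_conv(2L, 3L, 1L, "relu", "feat"),
                   ns$layer_conv(3L, 3L, 1L, "relu", "top"),
                   ns$layer_gap("gap"),
                   ns$layer_dense(3L, "linear", "logits"))
    net <- ns$nn_init(ns$nn_network(layers, c(6L, 6L, 3L)), 30L + rep)
    x <- array(runif(6 * 6 * 3), c(6, 6, 3, 1))
    fw <- ns$nn_forward(net, x, keep_cache = TRUE)
    cls <- sample(3L, 1L)

    # analytic dA at layer "feat"
    bk <- ns$nn_backward(net, fw$caches, ns$onehot_rows(cls, 3L),
                         stop_layer = "feat")
    dA <- bk$dx
    # brute-force oracle: finite differences of the head applied to A
    A <- fw$caches[[1L]]$out
    head <- net; head$layers <- net$layers[2:4]
    y_of <- function(A) ns$nn_forward(head, A)[1L, cls]
    eps <- 1e-5
    for (t in sample(length(A), 12)) {
      Ap <- A; Ap[t] <- A[t] + eps
      Am <- A; Am[t] <- A[t] - eps
      expect_equal(dA[t], (y_of(Ap) - y_of(Am)) / (2 * eps), tolerance = 1e-6)
    }
    # per-map weights are the spatial means of dA
    w_impl <- as.numeric(.colMeans(dA, 36L, 2L))
    w_brute <- c(mean(dA[, , 1L, 1L]), mean(dA[, , 2L, 1L]))
    expect_equal(w_impl, w_brute, tolerance = 1e-12)

    cam <- ns$grad_cam_maps(net, fw$caches, cls, "feat")
    expect_true(all(cam >= 0))
    manual <- pmax(w_brute[1L] * A[, , 1L, 1L] + w_brute[2L] * A[, , 2L, 1L], 0)
    expect_equal(cam[, , 1L], manual, tolerance = 1e-12)
  }
})

test_that("guided backprop applies the double gate and clamps the input map", {
  ns <- asNamespace("cystodl")
  # y = ReLU(x1 - x2) realised as a 1x1 conv over a 1x1x3 image
  layers <- list(ns$layer_conv(1L, 1L, 0L, "relu", "c"),
                 ns$layer_flatten(),
                 ns$layer_dense(2L, "linear", "logits"))
  net <- ns$nn_init(ns$nn_network(layers, c(1L, 1L, 3L)), 1L)
  net$layers[[1L]]$W <- matrix(c(1, -1, 0), 3, 1)
  net$layers[[1L]]$b[] <- 0
  net$layers[[3L]]$W <- matrix(c(1, 0), 1, 2)
  net$layers[[3L]]$b[] <- 0

  x_active <- array(c(2, 1, 0), c(1, 1, 3, 1))     # pre-activation 1 > 0
  fw <- ns$nn_forward(net, x_active, keep_cache = TRUE)
  g <- ns$guided_backprop_maps(net, fw$caches, 1L)
  # plain input gradient is (1, -1, 0); the rule keeps only the +1 channel
  expect_equal(as.numeric(g), 1)

  x_blocked <- array(c(1, 2, 0), c(1, 1, 3, 1))    # pre-activation -1 <= 0
  fw2 <- ns$nn_forward(net, x_blocked, keep_cache = TRUE)
  g2 <- ns$guided_backprop_maps(net, fw2$caches, 1L)
  expect_equal(as.numeric(g2), 0)

  # non-negativity on a random ReLU model
  set.seed(3)
  m <- build_backbone(c(32L, 32L), 0.125, 4L, seed = 7L)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  hb <- guided_backprop(m, img, 2L)
  expect_true(all(hb$values >= 0))
  expect_equal(dim(hb$values), c(32L, 32L))

  no_relu <- structure(list(net = ns$nn_network(
    list(ns$layer_dense(2L, "linear", "out")), 4L)), class = "edl_model")
  expect_error(guided_backprop(no_relu, img, 1L), "ReLU")
})

test_that("Guided Grad-CAM is the upsampled product with contained support", {
  gbp <- cystodl:::new_heatmap("guided_backprop", matrix(2, 4, 4), class_c = 1L)
  cam0 <- cystodl:::new_heatmap("grad_cam", matrix(0, 2, 2), class_c = 1L)
  gg0 <- guided_grad_cam(cam0, gbp, c(4L, 4L))
  expect_equal(gg0$values, matrix(0, 4, 4))

  cam <- cystodl:::new_heatmap("grad_cam", matrix(c(1, 0, 0, 0), 2, 2),
                               class_c = 1L)
  gg <- guided_grad_cam(cam, gbp, c(4L, 4L))
  # align-corners upsample of a corner delta: value (1-h)(1-w), h,w in {0,1/3,2/3,1}
  expect_equal(max(gg$values), 2)
  expect_equal(which(gg$values == 2, arr.ind = TRUE)[1, ], c(row = 1, col = 1))
  expect_true(all(gg$values[4L, ] == 0))           # h = 1 row outside support
  expect_true(all(gg$values[, 4L] == 0))
  expect_equal(gg$values[2L, 2L], 2 * (2 / 3)^2)

  camX <- cystodl:::new_heatmap("grad_cam", matrix(1, 2, 2), class_c = 2L)
  expect_error(guided_grad_cam(camX, gbp), "class mismatch")
  expect_error(guided_grad_cam(gbp, gbp), "expected")

  # support containment on a random trained-shape model
  m <- build_backbone(c(32L, 32L), 0.125, 4L, seed = 4L)
  set.seed(9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  cam2 <- grad_cam(m, img, 1L)
  expect_true(all(cam2$values >= 0))
  gbp2 <- guided_backprop(m, img, 1L)
  gg2 <- guided_grad_cam(cam2, gbp2, c(32L, 32L))
  up <- resize_image(cam2$values, c(32L, 32L))
  expect_true(all(gg2$values[up == 0] == 0))
  expect_true(all(gg2$values >= 0))
})

test_that("class-aggregated maps are the arithmetic mean", {
  m1 <- matrix(0, 3, 3); m2 <- matrix(1, 3, 3)
  agg <- aggregate_guided_grad_cam(list(m1, m2))
  expect_equal(agg$values, matrix(0.5, 3, 3))
  expect_equal(agg$n_classes, 2L)
  same <- matrix(runif(9), 3, 3)
  expect_equal(aggregate_guided_grad_cam(list(same, same, same))$values, same)
  expect_equal(aggregate_guided_grad_cam(list(3 * m2, 3 * m1))$values,
               3 * aggregate_guided_grad_cam(list(m2, m1))$values)
  expect_error(aggregate_guided_grad_cam(list(m1)), "at least 2")
  expect_error(aggregate_guided_grad_cam(list(m1, matrix(0, 2, 2))),
               "shape mismatch")
})

test_that("attention crops frame the hot region and fall back on flat maps", {
  set.seed(12)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  v <- matrix(0, 32, 32)
  xg <- matrix(1:32, 32, 32, byrow = TRUE); yg <- matrix(1:32, 32, 32)
  v[(xg - 20)^2 + (yg - 10)^2 <= 9] <- 1           # disc at (row 10, col 20)
  cr <- attention_crop(img, v, threshold = 0.5, margin_px = 2L)
  expect_false(attr(cr, "fallback"))
  box <- attr(cr, "box")
  expect_true(box[1L] <= 10 && 10 <= box[2L])
  expect_true(box[3L] <= 20 && 20 <= box[4L])
  expect_equal(dim(cr[[1L]]), dim(img))

  flat <- attention_crop(img, matrix(0, 32, 32))
  expect_true(attr(flat, "fallback"))
  expect_identical(flat[[1L]], img)

  # threshold 1: the box is the argmax pixel set before the margin
  v2 <- matrix(0, 32, 32); v2[10, 12] <- 5; v2[11, 12] <- 2
  cr2 <- attention_crop(img, v2, threshold = 1, margin_px = 0L)
  expect_equal(unname(attr(cr2, "box")), c(10, 10, 12, 12))
  expect_error(attention_crop(img, v2, threshold = 0), "threshold")
})

test_that("the explainable branch trains with crops and keeps its best epoch", {
  fx <- small_fixtures()
  cfg <- edl_desk_config(seed = 4L, epochs = 3L,
                         image_size = list(cnn = c(32L, 32L),
                                           gan = c(32L, 32L),
                                           xdl = c(32L, 32L)))
  clf <- train_xdl(fx$manifest, cfg)
  expect_equal(clf$name, "XDL")
  expect_lte(nrow(clf$history), 3L)
  expect_true(all(is.finite(clf$history$train_loss)))
  # stored accuracy is recomputable from the returned weights
  ns <- asNamespace("cystodl")
  va <- ns$load_split_tensor(fx$manifest, "validation", clf$input_size,
                             clf$class_names)
  expect_equal(mean(ns$predict_net(clf$net, va$x)$labels == va$y),
               clf$validation_accuracy, tolerance = 1e-9)

  ex <- explain(clf, load_image(fx$manifest$image_path[1L]))
  expect_s3_class(ex$grad_cam, "edl_heatmap")
  expect_equal(dim(ex$guided_grad_cam$values), c(32L, 32L))
  expect_true(all(ex$guided_grad_cam$values >= 0))

  dir <- withr::local_tempdir()
  write_heatmap(ex$grad_cam, file.path(dir, "cam"))
  expect_true(file.exists(file.path(dir, "cam.csv")))
  expect_true(file.exists(file.path(dir, "cam.json")))
  expect_true(file.exists(file.path(dir, "cam.png")))
})
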