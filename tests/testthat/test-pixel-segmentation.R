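test_that("derivative features vanish on a constant image", {
  st <- compute_pixel_features(matrix(42, 48, 48))
  expect_equal(ncol(st$features), 25)
  deriv <- grep("gradmag|laplacian|hess|st_", st$names)
  expect_lt(max(abs(st$features[, deriv])), 1e-9)
  expect_true(all(st$features[, "intensity"] == 42))
  expect_error(compute_pixel_features(matrix(c(1, NA, 3, 4), 2)), "finite")
})

test_that("Hessian ridge response peaks on an ideal ridge centerline", {
  img <- matrix(0, 64, 64)
  img[31:33, ] <- 300  # horizontal ridge, 3 px wide
  st <- compute_pixel_features(img)
  f <- matrix(st$features[, "hess_min_s2"], 64, 64)
  # oracle: direct finite differences of the sigma=2 smoothed ridge
  g <- neuritequant:::gauss_smooth(img, 2)
  d2 <- g[30:34, 32] # profile across the ridge
  expect_lt(f[32, 32], f[20, 32])  # strongly negative on the centerline
  expect_equal(f[32, 32],
               (g[31, 32] - 2 * g[32, 32] + g[33, 32]), tolerance = 1e-6)
  # centerline is the most negative response across the ridge (interior col)
  expect_equal(which.min(f[25:39, 32]), 8L)
})

test_that("features are translation-equivariant in the interior", {
  set.seed(31)
  img <- neuritequant:::gauss_smooth(matrix(rnorm(64 * 64, 100, 30), 64), 1.5)
  st_a <- compute_pixel_features(img)
  sh <- matrix(0, 64, 64); sh[11:64, 1:64] <- img[1:54, 1:64]
  st_b <- compute_pixel_features(sh)
  fa <- matrix(st_a$features[, "hess_max_s2"], 64, 64)
  fb <- matrix(st_b$features[, "hess_max_s2"], 64, 64)
  expect_equal(fb[30:40, 20:40], fa[20:30, 20:40], tolerance = 1e-6)
})

test_that("classifier memorizes a noiseless scene almost perfectly", {
  cfg <- scene_config(width = 192, height = 192, n_cells = 3,
                      poisson_scale = Inf, gaussian_sd = 0, seed = 13)
  out <- generate_scene(cfg, paper_effects("Q")$Q, "neurofilament")
  st <- compute_pixel_features(out$scene$green)
  lab <- truth_label_map(out$truth)
  clf <- train_pixel_classifier(st, lab, seed = 2)
  sm <- segment(out$scene, clf, prefilter = FALSE)
  expect_gte(mean(sm$labels == lab), 0.99)
})

test_that("training requires at least two classes", {
  st <- compute_pixel_features(matrix(rnorm(32 * 32, 100, 5), 32))
  expect_error(train_pixel_classifier(st, matrix(0L, 32, 32)),
               "single class")
})

test_that("held-out neurite IoU reaches 0.7 at default noise", {
  clf <- cached_segmenter()
  cfg <- small_config()
  ious <- vapply(1:4, function(i) {
    out <- generate_scene(cfg, paper_effects(c("control", "Q"))[[(i %% 2) + 1]],
                          "neurofilament", seed = 400 + i)
    sm <- segment(out$scene, clf)
    pred <- sm$labels == 2
    truth <- out$truth$neurite_mask
    sum(pred & truth) / sum(pred | truth)
  }, 0)
  expect_gte(mean(ious), 0.7)
})

test_that("a blank scene segments to pure background; no DAPI means no count", {
  clf <- cached_segmenter()
  cfg <- scene_config(width = 128, height = 128, n_cells = 0, seed = 3)
  out <- generate_scene(cfg, condition_effects("control"))
  sm <- segment(out$scene, clf)
  expect_true(all(sm$labels == 0))
  # matrix input: no DAPI channel -> nucleus count unavailable
  sm2 <- segment(out$scene$green, clf)
  expect_true(is.na(sm2$nucleus_count))
  expect_error(neurite_length_per_cell(sm2), "unavailable")
})

test_that("segmentation is deterministic for a fixed classifier and image", {
  clf <- cached_segmenter()
  out <- generate_scene(small_config(), paper_effects("Q")$Q, seed = 77)
  a <- segment(out$scene, clf)
  b <- segment(out$scene, clf)
  expect_identical(a$labels, b$labels)
  expect_identical(a$skeleton, b$skeleton)
})

test_that("skeleton length matches analytic bar lengths", {
  px <- 0.65
  m <- matrix(FALSE, 60, 200); m[30:32, 50:150] <- TRUE  # 101 px, 3 px wide
  seg <- list(skeleton = skeletonize(m), nucleus_count = 1, pixel_size = px)
  expect_equal(neurite_length_per_cell(seg), 65, tolerance = 2 * px / 65)
  # 45-degree bar of 100 steps
  m2 <- matrix(FALSE, 200, 200)
  for (i in 0:100) m2[50 + i, 50 + i] <- TRUE
  m2 <- as.matrix(EBImage::dilate(EBImage::Image(m2 * 1),
                                  EBImage::makeBrush(3, "box"))) > 0
  seg2 <- list(skeleton = skeletonize(m2), nucleus_count = 1, pixel_size = px)
  expect_equal(neurite_length_per_cell(seg2), 100 * sqrt(2) * px,
               tolerance = 2 * px / (100 * sqrt(2) * px))
  # empty mask with 3 nuclei measures zero
  seg0 <- list(skeleton = matrix(FALSE, 20, 20), nucleus_count = 3,
               pixel_size = px)
  expect_equal(neurite_length_per_cell(seg0), 0)
})

test_that("length measurement is rotation-robust within 5 percent", {
  measure <- function(ang, L = 120) {
    m <- matrix(FALSE, 250, 250)
    t <- seq(0, L, by = 0.25)
    m[cbind(round(60 + t * sin(ang)), round(60 + t * cos(ang)))] <- TRUE
    m <- as.matrix(EBImage::dilate(EBImage::Image(m * 1),
                                   EBImage::makeBrush(3, "box"))) > 0
    neuritequant:::skeleton_length_px(skeletonize(m)) / L
  }
  vals <- vapply(c(0, pi / 6, pi / 4), measure, 0)
  expect_lt(max(vals) / min(vals) - 1, 0.05)
})

test_that("measured length per cell increases with the length multiplier", {
  clf <- cached_segmenter()
  cfg <- small_config()
  means <- vapply(c(1, 1.5, 3), function(m) {
    eff <- condition_effects("x", neurite_length_multiplier = m)
    mean(measure_condition_lengths(cfg, eff, clf, n_scenes = 3, seed = 60),
         na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) > 0))
})
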