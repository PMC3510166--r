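test_that("noise-only images yield no detections in almost all trials", {
  hits <- 0
  set.seed(101)
  for (i in 1:100) {
    img <- matrix(rnorm(64 * 64, 100, 10), 64, 64) +
      matrix(rpois(64 * 64, 100) - 100, 64, 64)
    sp <- detect_spots(img, k_sigma = 3)
    if (nrow(sp) > 0) hits <- hits + 1
  }
  expect_lte(hits, 5)  # >= 95% of trials spot-free
})

test_that("a single rendered spot is found once, within a pixel", {
  img <- gaussian_spot_image(64, r0 = 30.3, c0 = 37.6, amp = 1500,
                             sigma = 1.5, bg = 100)
  set.seed(5)
  noisy <- img + matrix(rnorm(length(img), 0, 10), 64, 64)
  sp <- detect_spots(noisy)
  expect_equal(nrow(sp), 1)
  # oracle: argmax of the noiseless ideal map
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_lt(sqrt((sp$row - 30.3)^2 + (sp$col - 37.6)^2), 1)
  expect_lt(sqrt((sp$row - peak[1])^2 + (sp$col - peak[2])^2), 1.5)
})

test_that("detections are invariant to an additive constant offset", {
  img <- gaussian_spot_image(64, 20.2, 44.8, amp = 1200, sigma = 1.4, bg = 50)
  set.seed(6)
  img <- img + matrix(rnorm(length(img), 0, 8), 64, 64)
  a <- detect_spots(img)
  b <- detect_spots(img + 500)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$row, b$row, tolerance = 1e-9)
  expect_equal(a$col, b$col, tolerance = 1e-9)
})

test_that("whole-pixel translation translates the detections", {
  base <- gaussian_spot_image(96, 40.0, 50.0, amp = 1500, sigma = 1.5, bg = 100) +
    gaussian_spot_image(96, 66.0, 30.0, amp = 1200, sigma = 1.3, bg = 0)
  set.seed(7)
  noise <- matrix(rnorm(96 * 96, 0, 8), 96, 96)
  a <- detect_spots(base + noise)
  shifted <- matrix(100, 96, 96)
  shifted[6:96, 4:96] <- (base + noise)[1:91, 1:93]
  b <- detect_spots(shifted)
  expect_equal(nrow(a), nrow(b))
  a <- a[order(a$row), ]; b <- b[order(b$row), ]
  expect_equal(b$row, a$row + 5, tolerance = 0.2)
  expect_equal(b$col, a$col + 3, tolerance = 0.2)
})

test_that("structures outside the radii range are not detected", {
  # a disk of radius 20 px has no scale-2/3 signature at its interior
  img <- matrix(100, 128, 128)
  idx <- which(outer((1:128 - 64)^2, (1:128 - 64)^2, `+`) <= 20^2)
  img[idx] <- 600
  img <- neuritequant:::gauss_smooth(img, 1.2)
  set.seed(8)
  img <- img + matrix(rnorm(length(img), 0, 8), 128, 128)
  sp <- detect_spots(img, scale_range = c(1, 2), min_area = 2, max_area = 40)
  # nothing the size of a punctum inside the disk body
  if (nrow(sp)) {
    d <- sqrt((sp$row - 64)^2 + (sp$col - 64)^2)
    expect_true(all(d > 15))
  } else succeed()
})

test_that("parameter validation rejects empty ranges and bad thresholds", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  expect_error(detect_spots(img, scale_range = c(3, 2)), "j_min")
  expect_error(detect_spots(img, k_sigma = 0), "k_sigma")
})

test_that("nuclei are counted and localized from the DAPI channel", {
  cfg <- scene_config(width = 512, height = 512, n_cells = 12, seed = 21)
  out <- generate_scene(cfg, condition_effects("control"), "neurofilament")
  det <- detect_nuclei_spots(out$scene$dapi)
  expect_equal(det$count, 12)
  # greedy matching: every true nucleus has a detection within 5 px
  gt <- out$truth$nucleus_centroids
  d <- sqrt(outer(gt[, 1], det$centroids[, 1], `-`)^2 +
              outer(gt[, 2], det$centroids[, 2], `-`)^2)
  expect_true(all(apply(d, 1, min) <= 5))
})

test_that("well-separated nucleus pairs give two sub-pixel detections", {
  img <- matrix(30, 160, 160)
  for (ctr in list(c(50, 50), c(110, 120))) {
    idx <- which(outer((1:160 - ctr[1])^2, (1:160 - ctr[2])^2, `+`) <= 8^2)
    img[idx] <- 630
  }
  img <- neuritequant:::gauss_smooth(img, 1.2)
  set.seed(9)
  img <- img + matrix(rnorm(length(img), 0, 8), 160, 160)
  det <- detect_nuclei_spots(img)
  expect_equal(det$count, 2)
  cen <- det$centroids[order(det$centroids[, 1]), , drop = FALSE]
  expect_lt(sqrt(sum((cen[1, ] - c(50, 50))^2)), 1)
  expect_lt(sqrt(sum((cen[2, ] - c(110, 120))^2)), 1)
})

test_that("a blank DAPI channel propagates a missing-denominator error", {
  cfg <- scene_config(width = 96, height = 96, n_cells = 0, seed = 2)
  out <- generate_scene(cfg, condition_effects("control"))
  det <- detect_nuclei_spots(out$scene$dapi)
  expect_equal(det$count, 0)
  fake_seg <- list(skeleton = matrix(FALSE, 96, 96), nucleus_count = 0,
                   pixel_size = 0.65)
  expect_error(neurite_length_per_cell(fake_seg), "zero")
})
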