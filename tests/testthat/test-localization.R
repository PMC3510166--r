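make_disk <- function(n, ctr, r) {
  outer(seq_len(n), seq_len(n), function(a, b)
    (a - ctr[1])^2 + (b - ctr[2])^2 <= r^2)
}

test_that("cytoplasm is the green mask minus the nuclear objects", {
  n <- 128
  dapi <- matrix(10, n, n)
  d1 <- make_disk(n, c(40, 40), 9); d2 <- make_disk(n, c(90, 80), 9)
  dapi[d1 | d2] <- 600
  green <- matrix(400, n, n)  # uniform green everywhere
  m <- compartment_masks(dapi, green, threshold_method = "fixed",
                         fixed_threshold = c(300, 200))
  expect_false(any(m$nuclear_mask & m$cytoplasmic_mask))
  expect_true(all(m$cytoplasmic_mask == (!m$nuclear_mask)))
  expect_equal(max(m$nucleus_labels), 2)
})

test_that("masks are disjoint on generated scenes", {
  cfg <- small_config()
  for (s in 1:5) {
    sc <- generate_scene(cfg, paper_effects("control")$control, "rhoa",
                         seed = 600 + s)
    m <- compartment_masks(sc$scene$dapi, sc$scene$green)
    expect_false(any(m$nuclear_mask & m$cytoplasmic_mask))
  }
})

test_that("degenerate channels raise contract errors", {
  n <- 96
  dapi <- matrix(10, n, n); dapi[make_disk(n, c(48, 48), 10)] <- 600
  blank_green <- matrix(5, n, n)
  expect_error(compartment_masks(dapi, blank_green, "fixed",
                                 fixed_threshold = c(300, 200)),
               "no cytoplasmic signal")
  expect_error(compartment_masks(matrix(5, n, n), matrix(400, n, n), "fixed",
                                 fixed_threshold = c(300, 200)),
               "no cells")
})

test_that("identical compartment intensities give a unit ratio", {
  n <- 128
  dapi <- matrix(10, n, n); dapi[make_disk(n, c(64, 64), 10)] <- 600
  green <- matrix(0, n, n)
  green[make_disk(n, c(64, 64), 30)] <- 350  # same level inside and out
  m <- compartment_masks(dapi, green, "fixed", fixed_threshold = c(300, 200))
  loc <- rhoa_localization(green, m)
  expect_equal(loc$nc_ratio, 1, tolerance = 1e-9)
  expect_equal(loc$nuclear_sd_norm, 0, tolerance = 1e-9)
})

test_that("the configured nuclear/cytoplasmic ratio is recovered noiselessly", {
  cfg <- scene_config(width = 256, height = 256, n_cells = 5, seed = 3,
                      poisson_scale = Inf, gaussian_sd = 0, psf_sigma = 0.1)
  sc <- generate_scene(cfg, condition_effects("control"), "rhoa")
  m <- compartment_masks(sc$scene$dapi, sc$scene$green)
  loc <- rhoa_localization(sc$scene$green, m)
  expect_equal(loc$nc_ratio, 2, tolerance = 0.05 / 2)
})

test_that("ratio metrics are scale-invariant; offsets pull the ratio to 1", {
  cfg <- small_config()
  sc <- generate_scene(cfg, condition_effects("control"), "rhoa", seed = 61)
  m <- compartment_masks(sc$scene$dapi, sc$scene$green)
  base <- rhoa_localization(sc$scene$green, m)
  scaled <- rhoa_localization(sc$scene$green * 3.7, m)
  expect_equal(scaled$nc_ratio, base$nc_ratio, tolerance = 1e-9)
  expect_equal(scaled$nuclear_sd_norm, base$nuclear_sd_norm, tolerance = 1e-9)
  # additive offsets move nc_ratio monotonically toward 1
  offs <- c(0, 200, 800, 3000)
  ratios <- vapply(offs, function(o)
    rhoa_localization(sc$scene$green + o, m)$nc_ratio, 0)
  expect_true(all(diff(abs(ratios - 1)) < 0))
})

test_that("measured ratio increases with the configured ratio", {
  # fixed thresholds: the compartment definition must not move with the
  # configured ratio (Otsu would fail once nuclei dominate the histogram)
  ratios <- vapply(c(0.5, 1, 2, 4), function(r) {
    cfg <- scene_config(width = 192, height = 192, n_cells = 3, seed = 3,
                        nuc_cyto_ratio = r)
    sc <- generate_scene(cfg, condition_effects("control"), "rhoa", seed = 62)
    m <- compartment_masks(sc$scene$dapi, sc$scene$green,
                           threshold_method = "fixed",
                           fixed_threshold = c(300, 200))
    rhoa_localization(sc$scene$green, m)$nc_ratio
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("cells with an empty cytoplasm partition are skipped", {
  n <- 128
  dapi <- matrix(10, n, n)
  dapi[make_disk(n, c(40, 40), 9)] <- 600
  dapi[make_disk(n, c(100, 100), 9)] <- 600
  green <- matrix(0, n, n)
  green[make_disk(n, c(40, 40), 25)] <- 300
  green[make_disk(n, c(40, 40), 9)] <- 500
  green[make_disk(n, c(100, 100), 9)] <- 500  # nucleus-only cell: no cytoplasm
  m <- compartment_masks(dapi, green, "fixed", fixed_threshold = c(300, 100))
  loc <- rhoa_localization(green, m)
  expect_equal(loc$n_cells, 1)
})
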