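test_that("the descriptor always has exactly 50 features", {
  img <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  v <- extract_spot_features(img, c(32, 32))
  expect_length(v, 50)
  expect_identical(names(v),
                   c(sprintf("ang_%02d", 0:39), "n_max",
                     sprintf("win_%02d", seq(3, 19, 2))))
})

test_that("a uniform neighbourhood gives a flat profile and equal windows", {
  img <- matrix(55, 64, 64)
  v <- extract_spot_features(img, c(32, 32))
  expect_equal(unname(diff(range(v[1:40]))), 0, tolerance = 1e-12)
  expect_equal(unname(v["n_max"]), 0)
  expect_equal(unname(v[42:50]), rep(55, 9), tolerance = 1e-12)
})

test_that("a straight neurite crossing the circle produces two profile maxima", {
  img <- matrix(0, 64, 64)
  img[31:33, ] <- 400            # ridge through the spot position
  img <- neuritequant:::gauss_smooth(img, 1)
  v <- extract_spot_features(img, c(32, 32))
  expect_equal(unname(v["n_max"]), 2)
})

test_that("window means decrease with size for an isolated round spot", {
  img <- gaussian_spot_image(64, 32, 32, amp = 900, sigma = 1.5, bg = 0)
  v <- extract_spot_features(img, c(32, 32))
  expect_true(all(diff(v[42:50]) < 0))
})

test_that("rotating the scene by 90 degrees cyclically permutes the profile", {
  set.seed(12)
  img <- neuritequant:::gauss_smooth(matrix(rnorm(81 * 81, 100, 40), 81), 1.5)
  ctr <- c(41, 41)
  v <- extract_spot_features(img, ctr)
  rot <- t(img)[, ncol(img):1]  # 90-degree rotation
  vr <- extract_spot_features(rot, ctr)
  # angular samples shift cyclically by a quarter turn (10 positions; this
  # rotation direction shifts by 30 = -10 mod 40)
  expect_equal(unname(vr[1:40]),
               unname(v[((0:39 + 30) %% 40) + 1]), tolerance = 1e-6)
  expect_equal(unname(vr["n_max"]), unname(v["n_max"]))
  expect_equal(unname(vr[42:50]), unname(v[42:50]), tolerance = 1e-6)
})

test_that("border spots are flagged as mirror-padded", {
  img <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  expect_true(attr(extract_spot_features(img, c(4, 30)), "padded"))
  expect_false(attr(extract_spot_features(img, c(30, 30)), "padded"))
})

test_that("spot classification beats 0.85 balanced accuracy on held-out scenes", {
  clf <- cached_spot_classifier()
  te <- collect_spot_training(11:16)
  pred <- classify_spots(clf, te$features)
  tab <- table(factor(te$labels, levels = clf$classes),
               factor(pred, levels = clf$classes))
  per_class <- diag(tab) / pmax(rowSums(tab), 1)
  bal_acc <- mean(per_class[rowSums(tab) > 0])
  expect_gte(bal_acc, 0.85)
  # on/off-neurite discrimination beats a profile-free baseline (windows only)
  tr <- collect_spot_training(1:6)
  keep_tr <- tr$labels != "false_detection"
  keep_te <- te$labels != "false_detection"
  full <- train_spot_classifier(tr$features[keep_tr, ], tr$labels[keep_tr],
                                seed = 3)
  acc_full <- mean(classify_spots(full, te$features[keep_te, ]) ==
                     te$labels[keep_te])
  base_cols <- 42:50
  base_tr <- cbind(tr$features[keep_tr, base_cols],
                   matrix(0, sum(keep_tr), 41))
  colnames(base_tr) <- c(colnames(tr$features)[base_cols], paste0("z", 1:41))
  base_te <- cbind(te$features[keep_te, base_cols],
                   matrix(0, sum(keep_te), 41))
  colnames(base_te) <- colnames(base_tr)
  base <- train_spot_classifier(base_tr, tr$labels[keep_tr], seed = 3)
  acc_base <- mean(classify_spots(base, base_te) == te$labels[keep_te])
  expect_gte(acc_full, acc_base)
})

test_that("duplicating every training vector leaves predictions unchanged", {
  tr <- collect_spot_training(1:2)
  te <- collect_spot_training(3)
  a <- train_spot_classifier(tr$features, tr$labels, seed = 5)
  b <- train_spot_classifier(rbind(tr$features, tr$features),
                             c(tr$labels, tr$labels), seed = 5)
  expect_equal(classify_spots(a, te$features), classify_spots(b, te$features))
})

test_that("on-neurite counts track the configured density multiplier", {
  clf <- cached_spot_classifier()
  cfg <- small_config()
  count_for <- function(mult, seeds) {
    vapply(seeds, function(s) {
      eff <- condition_effects("x", spot_on_neurite_multiplier = mult)
      sc <- generate_scene(cfg, eff, "synaptotagmin", seed = s)
      count_spots_on_neurites(sc$scene, clf)$on_neurite
    }, 0)
  }
  c1 <- count_for(1, 31:36)
  c2 <- count_for(2, 31:36)
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.25)
  # zero density: counts at the classifier's false-positive floor
  cfg0 <- small_config(spot_density_on_neurite = 0)
  res0 <- lapply(31:33, function(s) {
    sc <- generate_scene(cfg0, condition_effects("control"), "synaptotagmin",
                         seed = s)
    count_spots_on_neurites(sc$scene, clf)
  })
  on0 <- sum(vapply(res0, `[[`, 0, "on_neurite"))
  tot0 <- sum(vapply(res0, `[[`, 0, "total"))
  expect_lte(on0, max(0.05 * tot0, 1))
})

test_that("an empty image yields zero spots", {
  clf <- cached_spot_classifier()
  blank <- structure(list(green = matrix(100, 96, 96),
                          dapi = matrix(30, 96, 96), pixel_size = 0.65),
                     class = "nq_scene")
  res <- count_spots_on_neurites(blank, clf)
  expect_equal(res$total, 0)
  expect_equal(res$on_neurite, 0)
})
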