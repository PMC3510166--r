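# Shared fixtures. Heavy objects (classifiers) are trained once per test run
# and cached in this environment.
nq_cache <- new.env(parent = emptyenv())

small_config <- function(...) {
  scene_config(width = 256, height = 256, n_cells = 5, seed = 3, ...)
}

cached_segmenter <- function() {
  if (is.null(nq_cache$segmenter))
    nq_cache$segmenter <- train_segmenter_on_synthetic(
      small_config(), n_scenes = 3, seed = 100)
  nq_cache$segmenter
}

# Spot training set collected over a few synaptotagmin scenes of mixed
# conditions, labelled from ground truth.
collect_spot_training <- function(seeds, conds = c("control", "Q")) {
  cfg <- small_config()
  feats <- NULL; labs <- character(0)
  for (s in seeds) for (cond in conds) {
    sc <- generate_scene(cfg, paper_effects(cond)[[1]], "synaptotagmin",
                         seed = s)
    sp <- detect_spots(sc$scene$green)
    lab <- label_spots_from_truth(sp, sc$truth)
    fm <- spot_feature_matrix(sc$scene$green, sp)
    feats <- rbind(feats, fm$features); labs <- c(labs, lab)
  }
  list(features = feats, labels = labs)
}

cached_spot_classifier <- function() {
  if (is.null(nq_cache$spot_clf)) {
    tr <- collect_spot_training(1:6)
    nq_cache$spot_clf <- train_spot_classifier(tr$features, tr$labels, seed = 1)
  }
  nq_cache$spot_clf
}

# Render an ideal Gaussian bump image (for detector/feature oracles).
gaussian_spot_image <- function(n = 64, r0 = 32.0, c0 = 32.0, amp = 1000,
                                sigma = 1.5, bg = 0) {
  outer(seq_len(n), seq_len(n), function(r, c)
    bg + amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sigma^2)))
}
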