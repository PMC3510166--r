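#' Ground-truth label map for classifier training
#'
#' @param truth an `nq_truth`.
#' @return integer matrix: 0 background, 1 cell (soma + nucleus), 2 neurite.
#' @export
truth_label_map <- function(truth) {
  lab <- matrix(0L, nrow(truth$cell_mask), ncol(truth$cell_mask))
  lab[truth$cell_mask] <- 1L
  lab[truth$neurite_mask] <- 2L
  lab
}

#' Train a pixel segmenter on freshly generated synthetic scenes
#'
#' Convenience wrapper: generates `n_scenes` training scenes (cycling over
#' the supplied conditions so short and long neurites are both represented),
#' computes feature stacks and fits [train_pixel_classifier()].
#'
#' @param config a [scene_config()].
#' @param effects_list list of [condition_effects()] to cycle over.
#' @param n_scenes number of training scenes.
#' @param marker marker for [generate_scene()].
#' @param seed base seed; scene i uses `seed + i`.
#' @param ... passed to [train_pixel_classifier()].
#' @return an `nq_pixel_classifier`.
#' @export
train_segmenter_on_synthetic <- function(config,
                                         effects_list = paper_effects(c("control", "Q")),
                                         n_scenes = 4,
                                         marker = "neurofilament",
                                         seed = 100, ...) {
  stacks <- list(); labs <- list()
  for (i in seq_len(n_scenes)) {
    eff <- effects_list[[(i - 1) %% length(effects_list) + 1]]
    sc <- generate_scene(config, eff, marker = marker, seed = seed + i)
    stacks[[i]] <- compute_pixel_features(sc$scene$green)
    labs[[i]] <- truth_label_map(sc$truth)
  }
  train_pixel_classifier(stacks, labs, seed = seed, ...)
}

#' Measure neurite length/cell over a set of generated scenes
#'
#' @param config a [scene_config()].
#' @param effects a [condition_effects()].
#' @param classifier an `nq_pixel_classifier`.
#' @param n_scenes number of scenes.
#' @param seed base seed; scene i uses `seed * 1000 + i`.
#' @return numeric vector of per-scene neurite length/cell (um).
#' @export
measure_condition_lengths <- function(config, effects, classifier,
                                      n_scenes = 10, seed = 1) {
  vapply(seq_len(n_scenes), function(i) {
    sc <- generate_scene(config, effects, marker = "neurofilament",
                         seed = seed * 1000L + i)
    sm <- segment(sc$scene, classifier)
    if (is.na(sm$nucleus_count) || sm$nucleus_count == 0) return(NA_real_)
    neurite_length_per_cell(sm)
  }, 0)
}
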