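#' Condition effect sizes
#'
#' Constructs the effect record for one experimental condition. Multipliers
#' act on the corresponding control quantity: neurite length per cell,
#' on-neurite puncta density, G-LISA RhoA activity OD, BrdU proliferation OD,
#' and the nuclear/cytoplasmic marker ratio. Expression shifts are log2 fold
#' changes applied to qPCR Ct values (housekeeping gapdh is never shifted).
#'
#' @param condition character label, e.g. `"control"`, `"Q"`, `"Q+Y27632"`.
#' @param neurite_length_multiplier,spot_on_neurite_multiplier,rhoa_activity_multiplier,proliferation_multiplier,nuc_cyto_multiplier
#'   positive scalars; all 1 for control.
#' @param rhoq_log2_expression_shift,rhoa_log2_expression_shift log2-unit
#'   expression shifts applied to rhoQ and rhoA Ct values; 0 for control.
#' @return list of class `nq_effects`.
#' @export
condition_effects <- function(condition,
                              neurite_length_multiplier = 1,
                              spot_on_neurite_multiplier = 1,
                              rhoa_activity_multiplier = 1,
                              proliferation_multiplier = 1,
                              nuc_cyto_multiplier = 1,
                              rhoq_log2_expression_shift = 0,
                              rhoa_log2_expression_shift = 0) {
  mults <- c(neurite_length_multiplier, spot_on_neurite_multiplier,
             rhoa_activity_multiplier, proliferation_multiplier,
             nuc_cyto_multiplier)
  if (any(!is.finite(mults)) || any(mults <= 0))
    stop_field("all condition multipliers must be positive and finite")
  structure(list(
    condition = as.character(condition),
    neurite_length_multiplier = neurite_length_multiplier,
    spot_on_neurite_multiplier = spot_on_neurite_multiplier,
    rhoa_activity_multiplier = rhoa_activity_multiplier,
    proliferation_multiplier = proliferation_multiplier,
    nuc_cyto_multiplier = nuc_cyto_multiplier,
    rhoq_log2_expression_shift = rhoq_log2_expression_shift,
    rhoa_log2_expression_shift = rhoa_log2_expression_shift
  ), class = "nq_effects")
}

#' Shipped effect-size calibration for the isoquercitrin study conditions
#'
#' Returns the calibration table used throughout the package: one
#' [condition_effects()] record per condition, encoding the study's headline
#' effect sizes. Q is 40 uM isoquercitrin; Y27632 the ROCK inhibitor; C3 the
#' Rho inhibitor exoenzyme C3 transferase; calpeptin the RhoA activator (the
#' calpeptin rows describe the 6-h rescue design, isoquercitrin added 30 min
#' after calpeptin).
#'
#' Calibrated entries (treated/control unless stated):
#' * `Q`: neurite length 1.5x at 48 h; G-LISA RhoA activity 0.53x (a 47%
#'   reduction, reached at >= 40 uM); BrdU proliferation 0.75x (25% lower);
#'   nuclear/cytoplasmic RhoA ratio scaled by 1/1.7 (nuclear variation is
#'   1.7-fold higher in control than treated cells); rhoQ (TC10) expression
#'   up 3.2-fold and rhoA down to 0.8-fold.
#' * `Y27632`: neurite length 2x; no RhoA-activity or proliferation change
#'   (ROCK sits downstream of RhoA).
#' * `Q+Y27632`: neurite length 3x over control (1.5x over Y27632 alone,
#'   the synergy condition); activity/proliferation as Q.
#' * `C3` / `Q+C3`: strong outgrowth, with the combination slightly below C3
#'   alone (4x vs 4.5x over control); C3 gives the lowest proliferation.
#' * `calpeptin`: neurite length 0.5x (RhoA activation retracts neurites),
#'   RhoA activity raised 1.5x.
#' * `calpeptin+Q`: rescue arm - neurite length 3x the calpeptin arm
#'   (0.5 -> 1.5) and RhoA activity 40% below the 6-h calpeptin arm
#'   (1.5 -> 0.9).
#'
#' @param conditions optional character vector to subset (and order) the
#'   returned list.
#' @return named list of `nq_effects` records.
#' @export
paper_effects <- function(conditions = NULL) {
  eff <- list(
    condition_effects("control"),
    condition_effects("Q",
      neurite_length_multiplier = 1.5,
      spot_on_neurite_multiplier = 2,
      rhoa_activity_multiplier = 0.53,
      proliferation_multiplier = 0.75,
      nuc_cyto_multiplier = 1 / 1.7,
      rhoq_log2_expression_shift = log2(3.2),
      rhoa_log2_expression_shift = log2(0.8)),
    condition_effects("Y27632",
      neurite_length_multiplier = 2,
      spot_on_neurite_multiplier = 1.5),
    condition_effects("Q+Y27632",
      neurite_length_multiplier = 3,
      spot_on_neurite_multiplier = 2,
      rhoa_activity_multiplier = 0.53,
      proliferation_multiplier = 0.75,
      nuc_cyto_multiplier = 1 / 1.7),
    condition_effects("C3",
      neurite_length_multiplier = 4.5,
      spot_on_neurite_multiplier = 1.5,
      rhoa_activity_multiplier = 0.5,
      proliferation_multiplier = 0.6),
    condition_effects("Q+C3",
      neurite_length_multiplier = 4,
      spot_on_neurite_multiplier = 2,
      rhoa_activity_multiplier = 0.5,
      proliferation_multiplier = 0.75),
    condition_effects("calpeptin",
      neurite_length_multiplier = 0.5,
      rhoa_activity_multiplier = 1.5),
    condition_effects("calpeptin+Q",
      neurite_length_multiplier = 1.5,
      rhoa_activity_multiplier = 0.9,
      proliferation_multiplier = 0.75)
  )
  names(eff) <- vapply(eff, `[[`, "", "condition")
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, names(eff))
    if (length(missing))
      stop_field(paste0("unknown condition(s): ", paste(missing, collapse = ", ")))
    eff <- eff[conditions]
  }
  eff
}

#' Shipped calibration as a data frame
#'
#' @return data.frame with one row per condition and one column per effect.
#' @export
paper_effects_table <- function() {
  eff <- paper_effects()
  do.call(rbind, lapply(eff, function(e) as.data.frame(unclass(e))))
}
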