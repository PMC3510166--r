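#' Generate a synthetic plate-reader absorbance table
#'
#' Simulates a G-LISA RhoA-activity plate (OD 490 nm) or a BrdU
#' proliferation plate (OD 450-540 nm). Replicate ODs are drawn as
#' `control_mean * multiplier + N(0, noise_sd)`, where the multiplier is the
#' condition's `rhoa_activity_multiplier` (glisa) or
#' `proliferation_multiplier` (brdu), so replicate means equal the scaled
#' control mean in expectation (exactly, when `noise_sd = 0`).
#'
#' @param effects list of [condition_effects()] records (one per condition).
#' @param assay `"glisa"` or `"brdu"`.
#' @param n_replicates replicates per condition (>= 2).
#' @param noise_sd OD noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param control_mean control-condition mean OD (default 0.8 for glisa,
#'   1.2 for brdu).
#' @return data.frame of class `nq_assay_table` with columns `condition`,
#'   `replicate`, `OD`; attributes `assay` and `wavelength`.
#' @export
generate_plate_assay <- function(effects, assay = c("glisa", "brdu"),
                                 n_replicates = 3, noise_sd = 0.02, seed = 1,
                                 control_mean = NULL) {
  assay <- match.arg(assay)
  if (inherits(effects, "nq_effects")) effects <- list(effects)
  stopifnot(all(vapply(effects, inherits, TRUE, "nq_effects")))
  if (n_replicates < 2) stop_field("`n_replicates` must be >= 2")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_field("`noise_sd` must be >= 0")
  control_mean <- control_mean %||% if (assay == "glisa") 0.8 else 1.2
  tab <- with_seed(as.integer(seed), {
    do.call(rbind, lapply(effects, function(e) {
      mult <- if (assay == "glisa") e$rhoa_activity_multiplier else
        e$proliferation_multiplier
      data.frame(condition = e$condition,
                 replicate = seq_len(n_replicates),
                 OD = control_mean * mult +
                   stats::rnorm(n_replicates, 0, noise_sd))
    }))
  })
  tab$OD <- pmax(tab$OD, 0)
  structure(tab, assay = assay,
            wavelength = if (assay == "glisa") "490 nm" else "450-540 nm",
            class = c("nq_assay_table", "data.frame"))
}

#' Generate a synthetic qPCR Ct table
#'
#' Simulates triplicate Ct values for the housekeeping gene gapdh and the
#' targets rhoA and rhoQ (TC10), for the control condition and the treated
#' condition of `effects`. Treated Ct for gene g is
#' `control Ct(g) - log2_expression_shift(g) + N(0, ct_sd)`; gapdh is never
#' shifted, so the delta-delta-Ct fold change recovered downstream equals
#' `2^shift` exactly in the noiseless limit.
#'
#' @param effects a [condition_effects()] record (the treated condition).
#' @param n_triplicates technical replicates per gene/condition (default 3).
#' @param ct_sd Ct noise SD (>= 0).
#' @param seed integer seed.
#' @param base_ct named baseline Ct values for the control condition.
#' @return data.frame of class `nq_ct_table` with columns `condition`,
#'   `gene`, `replicate`, `Ct`.
#' @export
generate_qpcr <- function(effects, n_triplicates = 3, ct_sd = 0.15, seed = 1,
                          base_ct = c(gapdh = 18, rhoA = 24, rhoQ = 26)) {
  stopifnot(inherits(effects, "nq_effects"))
  if (!is.finite(ct_sd) || ct_sd < 0) stop_field("`ct_sd` must be >= 0")
  genes <- c("gapdh", "rhoA", "rhoQ")
  if (!all(genes %in% names(base_ct)))
    stop_field("`base_ct` must name gapdh, rhoA and rhoQ")
  shifts <- c(gapdh = 0,
              rhoA = effects$rhoa_log2_expression_shift,
              rhoQ = effects$rhoq_log2_expression_shift)
  with_seed(as.integer(seed), {
    rows <- list()
    for (cond in c("control", effects$condition)) {
      for (g in genes) {
        ct <- base_ct[[g]] - if (cond == "control") 0 else shifts[[g]]
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, gene = g, replicate = seq_len(n_triplicates),
          Ct = ct + stats::rnorm(n_triplicates, 0, ct_sd))
      }
    }
    structure(do.call(rbind, rows), class = c("nq_ct_table", "data.frame"))
  })
}

#' qPCR primer sequences used for the gapdh/rhoA/rhoQ assays
#'
#' Reads the shipped primer table (forward/reverse sequences for the
#' housekeeping gene gapdh and the targets rhoA and rhoQ/TC10).
#'
#' @return data.frame with columns `gene`, `direction`, `sequence`.
#' @export
qpcr_primers <- function() {
  utils::read.csv(system.file("extdata", "qpcr_primers.csv",
                              package = "neuritequant"),
                  stringsAsFactors = FALSE)
}
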