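#' Neurite length/cell time course from time-lapse series
#'
#' Segments every frame of one or more imaging positions and measures the
#' mean neurite length per cell, returning per-position curves plus the
#' mean and standard error across positions at each time point. Frames
#' whose nucleus detection returns zero are recorded as missing (`NA`),
#' never as zero length.
#'
#' @param series a single `nq_timelapse` or a list of them (positions).
#' @param classifier an `nq_pixel_classifier` for [segment()].
#' @param ... passed to [segment()].
#' @return object of class `nq_timecourse`: `curves` data.frame
#'   (`position`, `minute`, `value`), `summary` data.frame (`minute`,
#'   `mean`, `sem`, `n`), `condition`.
#' @export
timecourse_from_scenes <- function(series, classifier, ...) {
  if (inherits(series, "nq_timelapse")) series <- list(series)
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "nq_timelapse")))
  curves <- do.call(rbind, lapply(seq_along(series), function(p) {
    tl <- series[[p]]
    vals <- vapply(tl$frames, function(fr) {
      sm <- segment(fr$scene, classifier, ...)
      if (is.na(sm$nucleus_count) || sm$nucleus_count == 0) return(NA_real_)
      neurite_length_per_cell(sm)
    }, 0)
    data.frame(position = p, minute = tl$times, value = vals)
  }))
  summ <- do.call(rbind, lapply(split(curves, curves$minute), function(d) {
    v <- d$value[!is.na(d$value)]
    data.frame(minute = d$minute[1], mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  rownames(summ) <- NULL
  structure(list(curves = curves, summary = summ,
                 condition = series[[1]]$condition),
            class = "nq_timecourse")
}

#' Fold change between treated and reference measurements
#'
#' `fold = mean(treated) / mean(reference)`; for reductions (`fold < 1`) the
#' percent change is reported as `(1 - fold) * 100`, for increases as the
#' (negative) same expression, so the sign convention is "positive =
#' reduction".
#'
#' @param treated,reference numeric vectors of per-image (or per-replicate)
#'   values.
#' @return object of class `nq_condition_report`: `fold_change`,
#'   `percent_change`, and per-arm `mean`, `sem`, `n`.
#' @export
fold_change <- function(treated, reference) {
  treated <- treated[!is.na(treated)]; reference <- reference[!is.na(reference)]
  if (!length(treated) || !length(reference))
    stop_field("both `treated` and `reference` must be non-empty")
  if (mean(reference) <= 0)
    stop_field("reference mean must be positive")
  fold <- mean(treated) / mean(reference)
  structure(list(
    fold_change = fold,
    percent_change = (1 - fold) * 100,
    treated = list(mean = mean(treated),
                   sem = stats::sd(treated) / sqrt(length(treated)),
                   n = length(treated)),
    reference = list(mean = mean(reference),
                     sem = stats::sd(reference) / sqrt(length(reference)),
                     n = length(reference))
  ), class = "nq_condition_report")
}

#' Joint neurite-length / RhoA-activity rescue report
#'
#' Summarises the calpeptin rescue design in one record: the neurite-length
#' fold change of the rescue arm (calpeptin followed by isoquercitrin) over
#' calpeptin alone, and the percent difference in G-LISA RhoA activity
#' between the same arms, mirroring a double-y-axis bar presentation.
#'
#' @param calpeptin_values,calpeptin_plus_q_values per-image neurite
#'   length/cell values for the two arms.
#' @param glisa_table an `nq_assay_table` containing both arms.
#' @param calpeptin_condition,rescue_condition condition labels in
#'   `glisa_table`.
#' @return list of class `nq_rescue_report`: `length_fold` (rescue /
#'   calpeptin), `activity_percent_reduction` (rescue vs calpeptin arm), and
#'   the underlying reports.
#' @export
rescue_analysis <- function(calpeptin_values, calpeptin_plus_q_values,
                            glisa_table,
                            calpeptin_condition = "calpeptin",
                            rescue_condition = "calpeptin+Q") {
  if (missing(calpeptin_values) || missing(calpeptin_plus_q_values) ||
      !length(calpeptin_values) || !length(calpeptin_plus_q_values))
    stop_field("both rescue arms are required")
  len <- fold_change(calpeptin_plus_q_values, calpeptin_values)
  act <- activity_reduction(glisa_table, treated = rescue_condition,
                            reference = calpeptin_condition)
  structure(list(length_fold = len$fold_change,
                 activity_percent_reduction = act$percent_reduction,
                 length_report = len, activity_report = act),
            class = "nq_rescue_report")
}
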