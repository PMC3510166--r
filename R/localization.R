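#' Nuclear and cytoplasmic compartment masks from a two-channel image
#'
#' Thresholds both channels (default: Otsu on the 1 px-smoothed channel) and
#' builds disjoint compartments: the nuclear mask is the DAPI objects of at
#' least `min_nucleus_area` pixels; the cytoplasmic mask is the thresholded
#' green signal minus the nuclear mask.
#'
#' @param dapi,green numeric matrices (registered channels).
#' @param threshold_method `"otsu"`, `"fixed"` or `"percentile"`.
#' @param fixed_threshold intensity cutoffs `c(dapi, green)` for
#'   `"fixed"`.
#' @param percentile upper-tail probability for `"percentile"` (the cutoff is
#'   the `1 - percentile` quantile of each channel).
#' @param min_nucleus_area smallest DAPI object kept, pixels.
#' @return list with logical `nuclear_mask`, `cytoplasmic_mask` (disjoint),
#'   `nucleus_labels` (integer matrix of nucleus objects) and
#'   `nucleus_centroids`.
#' @export
compartment_masks <- function(dapi, green,
                              threshold_method = c("otsu", "fixed", "percentile"),
                              fixed_threshold = c(200, 200),
                              percentile = 0.2,
                              min_nucleus_area = 30) {
  threshold_method <- match.arg(threshold_method)
  thr <- function(img, which) {
    sm <- gauss_smooth(img, 1)
    cut <- switch(threshold_method,
      otsu = {
        rng <- range(sm)
        if (diff(rng) <= 0) return(matrix(FALSE, nrow(img), ncol(img)))
        EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)), range = c(0, 1)) *
          diff(rng) + rng[1]
      },
      fixed = fixed_threshold[which],
      percentile = stats::quantile(sm, 1 - percentile))
    sm > cut
  }
  nuc_raw <- thr(dapi, 1)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(nuc_raw * 1)))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_nucleus_area)
    if (length(small)) lab[matrix(lab %in% small, nrow(lab))] <- 0L
    # relabel contiguously
    lab <- matrix(match(lab, sort(unique(lab[lab > 0]))), nrow(lab))
    lab[is.na(lab)] <- 0L
  }
  nuclear_mask <- lab > 0
  if (!any(nuclear_mask)) stop_field("no cells: nuclear mask is empty")
  green_mask <- thr(green, 2)
  cyto <- green_mask & !nuclear_mask
  if (!any(cyto)) stop_field("no cytoplasmic signal")
  cents <- do.call(rbind, lapply(seq_len(max(lab)), function(i) {
    idx <- which(lab == i)
    c(row = mean((idx - 1) %% nrow(lab) + 1),
      col = mean((idx - 1) %/% nrow(lab) + 1))
  }))
  list(nuclear_mask = nuclear_mask, cytoplasmic_mask = cyto,
       nucleus_labels = lab, nucleus_centroids = cents)
}

#' Per-cell nuclear vs cytoplasmic marker quantification
#'
#' Computes, for each cell, the nuclear/cytoplasmic mean-intensity ratio and
#' the nuclear variation metric: the standard deviation of the green
#' intensities inside the nucleus normalized by the cell's cytoplasmic mean
#' (`nuclear_sd_norm`). Cytoplasm pixels are assigned to the nearest nucleus
#' centroid (Euclidean); a 2 px guard band dilated around each nucleus is
#' excluded from the cytoplasm so PSF-blurred nuclear boundary pixels do not
#' contaminate the cytoplasmic statistics. Statistics use raw intensities; both metrics are ratios
#' and hence invariant to rescaling the green channel. Cells with an empty
#' cytoplasm partition are skipped.
#'
#' @param green numeric matrix (marker channel).
#' @param masks output of [compartment_masks()].
#' @param guard_px guard-band width eroded around nuclei, pixels.
#' @return list of class `nq_localization`: `per_cell` data.frame (`cell`,
#'   `nuclear_mean`, `cytoplasmic_mean`, `nc_ratio`, `nuclear_sd_norm`),
#'   image-level `nc_ratio` and `nuclear_sd_norm` (means over cells), and
#'   `n_cells`.
#' @export
rhoa_localization <- function(green, masks, guard_px = 2) {
  lab <- masks$nucleus_labels
  if (is.null(lab) || max(lab) == 0) stop_field("masks contain no nuclei")
  n_nuc <- max(lab)
  brush <- EBImage::makeBrush(2 * guard_px + 1, shape = "disc")
  banded <- as.matrix(EBImage::dilate(EBImage::Image((lab > 0) * 1), brush)) > 0
  cyto <- masks$cytoplasmic_mask & !banded

  cyto_idx <- which(cyto)
  cr <- (cyto_idx - 1) %% nrow(lab) + 1
  cc <- (cyto_idx - 1) %/% nrow(lab) + 1
  cents <- masks$nucleus_centroids
  if (length(cyto_idx)) {
    d2 <- outer(cr, cents[, "row"], `-`)^2 + outer(cc, cents[, "col"], `-`)^2
    assign_cell <- max.col(-d2, ties.method = "first")
  } else assign_cell <- integer(0)

  rows <- lapply(seq_len(n_nuc), function(i) {
    nuc_px <- green[lab == i]
    cy_px <- green[cyto_idx[assign_cell == i]]
    if (!length(cy_px)) return(NULL)  # skipped: empty cytoplasm partition
    cm <- mean(cy_px)
    data.frame(cell = i, nuclear_mean = mean(nuc_px), cytoplasmic_mean = cm,
               nc_ratio = mean(nuc_px) / cm,
               nuclear_sd_norm = stats::sd(nuc_px) / cm)
  })
  per_cell <- do.call(rbind, rows)
  if (is.null(per_cell) || !nrow(per_cell))
    stop_field("no cell has a non-empty cytoplasm partition")
  structure(list(per_cell = per_cell,
                 nc_ratio = mean(per_cell$nc_ratio),
                 nuclear_sd_norm = mean(per_cell$nuclear_sd_norm),
                 n_cells = nrow(per_cell)),
            class = "nq_localization")
}
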