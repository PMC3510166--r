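#' Train the background/cell/neurite pixel classifier
#'
#' Fits a seeded ensemble-of-trees classifier (ranger probability forest) on
#' per-pixel features with ground-truth class labels. Pixels are subsampled
#' per class per scene to keep training balanced and fast. The classifier
#' contract is per-pixel posterior probabilities over the three classes.
#'
#' @param stacks list of [compute_pixel_features()] stacks.
#' @param label_maps list of integer matrices with values 0 (background),
#'   1 (cell), 2 (neurite), aligned with the stacks.
#' @param n_per_class pixels sampled per class per scene.
#' @param num_trees trees in the ensemble.
#' @param max_depth tree depth cap.
#' @param seed RNG seed (sampling and forest).
#' @return object of class `nq_pixel_classifier`.
#' @export
train_pixel_classifier <- function(stacks, label_maps, n_per_class = 3000,
                                   num_trees = 100, max_depth = 14, seed = 1) {
  if (inherits(stacks, "nq_pixel_features")) stacks <- list(stacks)
  if (is.matrix(label_maps)) label_maps <- list(label_maps)
  stopifnot(length(stacks) == length(label_maps))
  dat <- with_seed(as.integer(seed), {
    parts <- lapply(seq_along(stacks), function(i) {
      lab <- as.vector(label_maps[[i]])
      f <- stacks[[i]]$features
      stopifnot(length(lab) == nrow(f))
      idx <- unlist(lapply(split(seq_along(lab), lab), function(ix)
        if (length(ix) > n_per_class) sample(ix, n_per_class) else ix))
      cbind(label = lab[idx], f[idx, , drop = FALSE])
    })
    do.call(rbind, parts)
  })
  classes <- sort(unique(dat[, 1]))
  if (length(classes) < 2)
    stop_field("training data contains a single class; need >= 2 of background/cell/neurite")
  df <- as.data.frame(dat[, -1, drop = FALSE])
  df$.class <- factor(dat[, 1], levels = c(0, 1, 2),
                      labels = c("background", "cell", "neurite"))
  df$.class <- droplevels(df$.class)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df, probability = TRUE,
    num.trees = num_trees, max.depth = max_depth, seed = as.integer(seed),
    num.threads = 1, verbose = FALSE)
  structure(list(forest = fit, feature_names = stacks[[1]]$names,
                 classes = levels(df$.class), seed = as.integer(seed),
                 format_version = 1L),
            class = "nq_pixel_classifier")
}

#' Segment a scene into background, cell and neurite pixels
#'
#' Applies the pixel classifier (argmax of posterior probabilities), then
#' morphological cleanup: neurite components smaller than `min_neurite_px`
#' are dropped and holes smaller than `fill_holes_px` inside cell bodies are
#' filled. The nucleus count is taken from [detect_nuclei_spots()] on the
#' DAPI channel when one is available.
#'
#' A conservative intensity prefilter (pixels of the 2 px-smoothed image
#' below median + 3 MAD are labelled background directly) limits classifier
#' evaluation to candidate foreground; set `prefilter = FALSE` to classify
#' every pixel.
#'
#' @param scene an `nq_scene`, or a plain matrix (green channel only).
#' @param classifier an `nq_pixel_classifier`.
#' @param min_neurite_px,fill_holes_px cleanup thresholds, pixels.
#' @param prefilter logical; use the background gate.
#' @return object of class `nq_segmentation`: `labels` (matrix, 0 background
#'   / 1 cell / 2 neurite), `skeleton` (logical matrix), `nucleus_count`
#'   (integer or NA when no DAPI channel), `nucleus_centroids`, `pixel_size`.
#' @export
segment <- function(scene, classifier, min_neurite_px = 5, fill_holes_px = 25,
                    prefilter = TRUE) {
  stopifnot(inherits(classifier, "nq_pixel_classifier"))
  if (is.matrix(scene))
    scene <- structure(list(green = scene, dapi = NULL, pixel_size = 1),
                       class = "nq_scene")
  img <- scene$green
  stack <- compute_pixel_features(img)
  if (!identical(stack$names, classifier$feature_names))
    stop_field("feature definition of the stack does not match the classifier")

  n <- length(img)
  lab <- integer(n)
  cand <- rep(TRUE, n)
  if (prefilter) {
    sm <- as.vector(gauss_smooth(img, 2))
    cand <- sm > stats::median(sm) + 3 * mad_sigma(sm)
  }
  if (any(cand)) {
    pr <- stats::predict(classifier$forest,
                         data = as.data.frame(stack$features[cand, , drop = FALSE]),
                         num.threads = 1)$predictions
    cls <- max.col(pr, ties.method = "first")
    lab[cand] <- match(classifier$classes[cls],
                       c("background", "cell", "neurite")) - 1L
  }
  labels <- matrix(lab, nrow(img), ncol(img))

  # cleanup: drop tiny neurite fragments
  neur <- labels == 2
  if (any(neur)) {
    cc <- as.matrix(EBImage::bwlabel(EBImage::Image(neur * 1)))
    sizes <- tabulate(cc[cc > 0])
    drop <- which(sizes < min_neurite_px)
    if (length(drop)) {
      labels[neur & matrix(cc %in% drop, nrow(cc))] <- 0L
      neur <- labels == 2
    }
  }
  # cleanup: fill small holes inside cell bodies
  cellm <- labels == 1
  if (any(cellm)) {
    filled <- as.matrix(EBImage::fillHull(EBImage::Image(cellm * 1))) > 0
    holes <- filled & !cellm & labels != 2
    if (any(holes)) {
      hc <- as.matrix(EBImage::bwlabel(EBImage::Image(holes * 1)))
      hs <- tabulate(hc[hc > 0])
      keep <- which(hs < fill_holes_px)
      if (length(keep)) labels[holes & matrix(hc %in% keep, nrow(hc))] <- 1L
    }
  }

  nucleus_count <- NA_integer_
  nucleus_centroids <- NULL
  if (!is.null(scene$dapi)) {
    det <- detect_nuclei_spots(scene$dapi)
    nucleus_count <- det$count
    nucleus_centroids <- det$centroids
  }
  skel <- skeletonize(labels == 2)
  structure(list(labels = labels, skeleton = skel,
                 nucleus_count = nucleus_count,
                 nucleus_centroids = nucleus_centroids,
                 pixel_size = scene$pixel_size %||% 1),
            class = "nq_segmentation")
}

#' Mean neurite length per cell from a segmentation
#'
#' Measures the total skeleton (centerline) length of the neurite class and
#' divides by the nucleus count. Length is estimated from the skeleton's
#' adjacency graph: orthogonal neighbour steps count 1 pixel, diagonal steps
#' sqrt(2) pixels (diagonal links that are short-circuited by a shared
#' orthogonal neighbour are skipped), minus a 0.1 px corner correction per
#' orthogonal/diagonal direction change on path pixels, which removes the
#' staircase over-estimate for oblique segments.
#'
#' @param segmap an `nq_segmentation` (or any list with `skeleton`,
#'   `nucleus_count`, `pixel_size`).
#' @param nucleus_count optional override of the segmentation's count.
#' @return length in um per cell (scalar).
#' @export
neurite_length_per_cell <- function(segmap, nucleus_count = NULL) {
  n <- nucleus_count %||% segmap$nucleus_count
  if (is.null(n) || is.na(n))
    stop_field("nucleus count unavailable; segment a scene with a DAPI channel or pass `nucleus_count`")
  if (n < 1) stop_field("nucleus count is zero: per-cell normalization undefined")
  skeleton_length_px(segmap$skeleton) * segmap$pixel_size / n
}

# Total skeleton length in pixel units (see neurite_length_per_cell).
skeleton_length_px <- function(skel) {
  if (!any(skel)) return(0)
  s <- skel
  e <- shift_pad(s, 0, -1)  # right neighbour
  so <- shift_pad(s, -1, 0) # below
  n_orth <- sum(s & e) + sum(s & so)
  d1 <- shift_pad(s, -1, -1) # down-right
  d2 <- shift_pad(s, -1, 1)  # down-left
  # skip diagonals short-circuited by a shared orthogonal neighbour
  dr_ok <- s & d1 & !(shift_pad(s, 0, -1) | shift_pad(s, -1, 0))
  dl_ok <- s & d2 & !(shift_pad(s, 0, 1) | shift_pad(s, -1, 0))
  n_diag <- sum(dr_ok) + sum(dl_ok)
  n_corner <- skeleton_corner_count(s)
  # thinning retracts each free end by about half the stroke width;
  # compensate 1 px per endpoint (degree-1 pixels)
  n_end <- skeleton_endpoint_count(s)
  max(n_orth + sqrt(2) * n_diag - 0.1 * n_corner + n_end, 0)
}

skeleton_endpoint_count <- function(s) {
  deg <- shift_pad(s, 1, 0) + shift_pad(s, -1, 0) +
    shift_pad(s, 0, 1) + shift_pad(s, 0, -1) +
    shift_pad(s, 1, 1) + shift_pad(s, 1, -1) +
    shift_pad(s, -1, 1) + shift_pad(s, -1, -1)
  sum(s & deg == 1)
}

# Corners: degree-2 path pixels whose two links mix orthogonal and diagonal.
skeleton_corner_count <- function(s) {
  orth <- shift_pad(s, 1, 0) + shift_pad(s, -1, 0) +
    shift_pad(s, 0, 1) + shift_pad(s, 0, -1)
  diag <- shift_pad(s, 1, 1) + shift_pad(s, 1, -1) +
    shift_pad(s, -1, 1) + shift_pad(s, -1, -1)
  deg <- orth + diag
  sum(s & deg == 2 & orth == 1 & diag == 1)
}

#' Morphological thinning of a binary mask to 1-pixel centerlines
#'
#' Zhang-Suen two-subiteration thinning, vectorized over the whole mask and
#' iterated to convergence, followed by a staircase-removal pass: corner
#' pixels with exactly two mutually perpendicular orthogonal neighbours are
#' deleted (their neighbours stay diagonally connected), which replaces
#' zigzag orthogonal step pairs by diagonal steps and removes the thinning
#' algorithm's oblique-line length bias.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same size (the skeleton).
#' @export
skeletonize <- function(mask) {
  s <- zhang_suen(mask)
  diagonalize_skeleton(s)
}

zhang_suen <- function(mask) {
  s <- mask
  if (!any(s)) return(s)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_pad(s, -1, 0); p3 <- shift_pad(s, -1, 1)
      p4 <- shift_pad(s, 0, 1);  p5 <- shift_pad(s, 1, 1)
      p6 <- shift_pad(s, 1, 0);  p7 <- shift_pad(s, 1, -1)
      p8 <- shift_pad(s, 0, -1); p9 <- shift_pad(s, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- s & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- s & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { s[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  s
}

# Remove staircase corner pixels. A pixel with exactly one vertical and one
# horizontal orthogonal neighbour (say N and E) may be deleted when the
# opposite sides and the opposite outer corner (S, W, SW) are empty: N and E
# stay connected through their mutual diagonal adjacency and any remaining
# diagonal neighbours (NW, NE, SE) stay attached to N or E. Adjacent
# candidates are removed one pass at a time (independent subsets) so
# square-wave staircases are not broken.
diagonalize_skeleton <- function(s) {
  repeat {
    n_ <- shift_pad(s, 1, 0); s_ <- shift_pad(s, -1, 0)
    e_ <- shift_pad(s, 0, -1); w_ <- shift_pad(s, 0, 1)
    ne <- shift_pad(s, 1, -1); nw <- shift_pad(s, 1, 1)
    se <- shift_pad(s, -1, -1); sw <- shift_pad(s, -1, 1)
    corner <- s & (
      (n_ & e_ & !s_ & !w_ & !sw) |
      (n_ & w_ & !s_ & !e_ & !se) |
      (s_ & e_ & !n_ & !w_ & !nw) |
      (s_ & w_ & !n_ & !e_ & !ne))
    if (!any(corner)) break
    # independent subset: drop candidates adjacent to an earlier candidate
    idx <- which(corner)
    rr <- (idx - 1) %% nrow(s) + 1
    cc <- (idx - 1) %/% nrow(s) + 1
    keep <- logical(length(idx))
    taken <- matrix(FALSE, nrow(s), ncol(s))
    for (i in seq_along(idx)) {
      r0 <- max(1, rr[i] - 1):min(nrow(s), rr[i] + 1)
      c0 <- max(1, cc[i] - 1):min(ncol(s), cc[i] + 1)
      if (!any(taken[r0, c0])) { keep[i] <- TRUE; taken[rr[i], cc[i]] <- TRUE }
    }
    s[idx[keep]] <- FALSE
  }
  s
}
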