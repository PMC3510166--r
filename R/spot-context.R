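spot_feature_names <- function() {
  c(sprintf("ang_%02d", 0:39), "n_max",
    sprintf("win_%02d", seq(3, 19, by = 2)))
}

#' 50-feature local description of a detected spot
#'
#' Computes the frozen 50-feature vector describing a spot's neighbourhood:
#' 40 intensity samples on the circle of radius 9 px around the centroid
#' (bilinear interpolation, angles increasing counter-clockwise from the
#' +column axis), the number of local maxima of that circular profile
#' (counted on a 3-sample circular moving average, strict inequality, flat
#' plateaus collapsed to a single maximum), and the mean intensity of
#' centered square windows of sides 3, 5, ..., 19 px. A spot crossing a
#' straight neurite shows exactly two profile maxima (the two crossing
#' points), which separates genuine on-neurite puncta from isolated or
#' spurious detections. Positions outside the image are mirror-padded and
#' the vector is flagged.
#'
#' @param image numeric matrix.
#' @param spot one-row data.frame with `row` and `col` (or a numeric pair).
#' @param radius profile radius, pixels.
#' @param n_angles number of profile samples.
#' @return numeric vector of length 50 with names `ang_00..ang_39`, `n_max`,
#'   `win_03..win_19`; attribute `padded` marks border spots.
#' @export
extract_spot_features <- function(image, spot, radius = 9, n_angles = 40) {
  if (is.data.frame(spot)) spot <- c(spot$row[1], spot$col[1])
  r0 <- spot[1]; c0 <- spot[2]
  padded <- r0 < radius + 1 || c0 < radius + 1 ||
    r0 > nrow(image) - radius || c0 > ncol(image) - radius
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  prof <- bilinear(image, r0 + radius * sin(ang), c0 + radius * cos(ang))
  nmax <- circular_local_maxima(circular_ma3(prof))
  sides <- seq(3, 19, by = 2)
  ri <- round(r0); ci <- round(c0)
  wmeans <- vapply(sides, function(s) {
    h <- (s - 1) / 2
    rr <- mirror_index((ri - h):(ri + h), nrow(image))
    cc <- mirror_index((ci - h):(ci + h), ncol(image))
    mean(image[rr, cc])
  }, 0)
  out <- c(prof, nmax, wmeans)
  names(out) <- spot_feature_names()
  stopifnot(length(out) == 50L)
  attr(out, "padded") <- padded
  out
}

# Circular 3-sample moving average.
circular_ma3 <- function(x) {
  n <- length(x)
  (x + x[c(n, 1:(n - 1))] + x[c(2:n, 1)]) / 3
}

# Count local maxima of a circular sequence; strict inequality, with flat
# plateaus collapsed so a plateau flanked by lower values counts once.
# Values are quantized to 1e-8 of the profile range first so that numerical
# ripple in flat regions does not create spurious maxima.
circular_local_maxima <- function(x) {
  n <- length(x)
  rng <- diff(range(x))
  if (n < 3 || rng < .Machine$double.eps * 10) return(0L)
  tol <- rng * 1e-8
  x <- round(x / tol) * tol
  r <- rle(x)
  v <- r$values
  m <- length(v)
  if (m == 1) return(0L)
  # merge circular wrap of equal first/last runs
  if (v[1] == v[m] && m > 1) { v <- v[-m]; m <- m - 1 }
  if (m < 2) return(0L)
  prev <- v[c(m, 1:(m - 1))]
  nxt <- v[c(2:m, 1)]
  sum(v > prev & v > nxt)
}

#' Build 50-feature matrices for a set of detected spots
#'
#' @param image numeric matrix.
#' @param spots an `nq_spots` data.frame.
#' @return list with `features` (n x 50 matrix) and `padded` (logical).
#' @export
spot_feature_matrix <- function(image, spots) {
  if (!nrow(spots))
    return(list(features = matrix(numeric(0), 0, 50,
                                  dimnames = list(NULL, spot_feature_names())),
                padded = logical(0)))
  rows <- lapply(seq_len(nrow(spots)), function(i)
    extract_spot_features(image, spots[i, ]))
  list(features = do.call(rbind, rows),
       padded = vapply(rows, function(x) isTRUE(attr(x, "padded")), TRUE))
}

#' Label detections against generator ground truth
#'
#' Greedy nearest matching of detected spots to ground-truth puncta within
#' `max_dist` pixels; matched spots inherit the on/off-neurite flag,
#' unmatched detections are labelled `false_detection`.
#'
#' @param spots an `nq_spots` data.frame.
#' @param truth an `nq_truth` with `spot_positions`.
#' @param max_dist match radius, pixels.
#' @return character vector of labels, one per spot.
#' @export
label_spots_from_truth <- function(spots, truth, max_dist = 3) {
  gt <- truth$spot_positions
  lab <- rep("false_detection", nrow(spots))
  if (!nrow(spots) || !nrow(gt)) return(lab)
  d <- outer(spots$row, gt$row, `-`)^2 + outer(spots$col, gt$col, `-`)^2
  used <- logical(nrow(gt))
  ord <- order(apply(d, 1, min))
  for (i in ord) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (length(j) && is.finite(d[i, j]) && d[i, j] <= max_dist^2) {
      lab[i] <- if (gt$on_neurite[j]) "on_neurite" else "off_neurite"
      used[j] <- TRUE
    }
  }
  lab
}

#' Train the on-neurite / off-neurite / false-detection spot classifier
#'
#' Seeded ranger probability forest over the 50-feature spot descriptors.
#'
#' @param feature_matrix n x 50 matrix from [spot_feature_matrix()].
#' @param labels character vector in
#'   `{on_neurite, off_neurite, false_detection}`.
#' @param num_trees,seed forest parameters.
#' @return object of class `nq_spot_classifier`.
#' @export
train_spot_classifier <- function(feature_matrix, labels, num_trees = 200,
                                  seed = 1) {
  labels <- factor(labels,
                   levels = c("on_neurite", "off_neurite", "false_detection"))
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop_field("spot training data contains a single class; need >= 2")
  df <- as.data.frame(feature_matrix)
  df$.class <- labels
  # no bootstrap resampling: every tree sees the full sample (diversity from
  # feature subsampling only), so the decision function depends on the
  # empirical distribution alone and duplicating the training set is a no-op
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        probability = TRUE, num.trees = num_trees,
                        replace = FALSE, sample.fraction = 1,
                        seed = as.integer(seed), num.threads = 1,
                        verbose = FALSE)
  structure(list(forest = fit, classes = levels(labels),
                 feature_names = spot_feature_names(),
                 seed = as.integer(seed), format_version = 1L),
            class = "nq_spot_classifier")
}

#' Classify detected spots
#'
#' @param classifier an `nq_spot_classifier`.
#' @param feature_matrix n x 50 feature matrix.
#' @return character vector of predicted labels.
#' @export
classify_spots <- function(classifier, feature_matrix) {
  stopifnot(inherits(classifier, "nq_spot_classifier"))
  if (!nrow(feature_matrix)) return(character(0))
  pr <- stats::predict(classifier$forest, data = as.data.frame(feature_matrix),
                       num.threads = 1)$predictions
  classifier$classes[max.col(pr, ties.method = "first")]
}

#' Count puncta lying on neurites in one image
#'
#' Full spot pipeline: wavelet detection on the green channel, 50-feature
#' extraction, classification, and counting of `on_neurite` predictions.
#'
#' @param scene an `nq_scene` (green + DAPI channels).
#' @param spot_classifier an `nq_spot_classifier`.
#' @param scale_range,k_sigma,min_area,max_area detector parameters, see
#'   [detect_spots()].
#' @return list with `on_neurite`, `off_neurite`, `false_detection`,
#'   `total` counts and the annotated `spots` table.
#' @export
count_spots_on_neurites <- function(scene, spot_classifier,
                                    scale_range = c(1, 3), k_sigma = 3,
                                    min_area = 2, max_area = 200) {
  spots <- detect_spots(scene$green, scale_range = scale_range,
                        k_sigma = k_sigma, min_area = min_area,
                        max_area = max_area)
  fm <- spot_feature_matrix(scene$green, spots)
  lab <- classify_spots(spot_classifier, fm$features)
  spots$label <- if (length(lab)) lab else character(0)
  list(on_neurite = sum(lab == "on_neurite"),
       off_neurite = sum(lab == "off_neurite"),
       false_detection = sum(lab == "false_detection"),
       total = nrow(spots), spots = spots)
}
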