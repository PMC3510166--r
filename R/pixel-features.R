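# Feature-bank definition: raw intensity plus, at each smoothing scale
# sigma in {1, 2, 4, 8} px, the Gaussian smoothing, gradient magnitude,
# Laplacian, largest and smallest Hessian eigenvalues and the largest
# structure-tensor eigenvalue. 1 + 4 * 6 = 25 features per pixel.
# The order is frozen; classifiers store it and refuse mismatched stacks.
pixel_feature_names <- function(scales = c(1, 2, 4, 8)) {
  fams <- c("gauss", "gradmag", "laplacian", "hess_max", "hess_min", "st_max")
  c("intensity",
    as.vector(t(outer(scales, fams, function(s, f) sprintf("%s_s%g", f, s)))))
}

#' Per-pixel filter-bank features for pixel classification
#'
#' Computes the fixed 25-feature stack used by the background/cell/neurite
#' pixel classifier: raw intensity and, at scales sigma = 1, 2, 4, 8 px,
#' Gaussian smoothing, gradient magnitude, Laplacian, the two Hessian
#' eigenvalues (ridge detectors: a bright thin neurite gives a strongly
#' negative smallest eigenvalue across it), and the largest structure-tensor
#' eigenvalue. Derivatives are central finite differences on the smoothed
#' image with replicated borders.
#'
#' @param image numeric matrix (single channel).
#' @return object of class `nq_pixel_features`: list with `features`
#'   (n_pixels x 25 matrix, pixels in column-major order), `names`, `dim`.
#' @export
compute_pixel_features <- function(image) {
  if (!is.matrix(image)) stop_field("`image` must be a matrix")
  if (any(!is.finite(image))) stop_field("`image` contains non-finite pixels")
  scales <- c(1, 2, 4, 8)
  feat <- matrix(NA_real_, length(image), 1 + 6 * length(scales))
  feat[, 1] <- as.vector(image)
  k <- 2
  for (s in scales) {
    g <- gauss_smooth(image, s)
    gx <- (shift_clamp(g, 0, 1) - shift_clamp(g, 0, -1)) / 2
    gy <- (shift_clamp(g, 1, 0) - shift_clamp(g, -1, 0)) / 2
    gxx <- shift_clamp(g, 0, 1) - 2 * g + shift_clamp(g, 0, -1)
    gyy <- shift_clamp(g, 1, 0) - 2 * g + shift_clamp(g, -1, 0)
    gxy <- (shift_clamp(g, 1, 1) - shift_clamp(g, 1, -1) -
              shift_clamp(g, -1, 1) + shift_clamp(g, -1, -1)) / 4
    tr <- gxx + gyy
    disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    # structure tensor: smoothed outer products of the gradient
    jxx <- gauss_smooth(gx * gx, s); jyy <- gauss_smooth(gy * gy, s)
    jxy <- gauss_smooth(gx * gy, s)
    st_disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
    feat[, k]     <- as.vector(g)
    feat[, k + 1] <- as.vector(sqrt(gx^2 + gy^2))
    feat[, k + 2] <- as.vector(tr)
    feat[, k + 3] <- as.vector((tr + disc) / 2)
    feat[, k + 4] <- as.vector((tr - disc) / 2)
    feat[, k + 5] <- as.vector((jxx + jyy + st_disc) / 2)
    k <- k + 6
  }
  colnames(feat) <- pixel_feature_names(scales)
  structure(list(features = feat, names = colnames(feat), dim = dim(image)),
            class = "nq_pixel_features")
}
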