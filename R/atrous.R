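#' Undecimated a trous B3-spline wavelet decomposition
#'
#' Decomposes an image into `n_scales` wavelet planes plus a smooth residual
#' using the shift-invariant ("a trous", with holes) scheme. At scale j the
#' B3-spline kernel (1/16, 1/4, 3/8, 1/4, 1/16) is dilated by inserting
#' `2^(j-1) - 1` zeros between taps and applied separably to rows and columns;
#' the wavelet plane is the difference of consecutive smoothings,
#' `w_j = A_(j-1) - A_j`. Borders are mirror-reflected, which preserves the
#' exact reconstruction identity `image = residual + sum_j w_j`.
#'
#' @param image numeric matrix (single channel).
#' @param n_scales integer J >= 1, number of wavelet planes.
#' @return An object of class `nq_atrous`: list with `planes` (list of J
#'   matrices `w_1..w_J`, fine to coarse), `residual` (the smooth map `A_J`)
#'   and `scales` (J).
#' @examples
#' img <- matrix(rnorm(64 * 64), 64)
#' dec <- atrous_decompose(img, 3)
#' max(abs(img - (dec$residual + Reduce(`+`, dec$planes))))  # ~ 1e-15
#' @export
atrous_decompose <- function(image, n_scales) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_field("`image` must be a numeric matrix")
  if (any(!is.finite(image))) stop_field("`image` contains non-finite pixels")
  n_scales <- as.integer(n_scales)
  if (is.na(n_scales) || n_scales < 1L) stop_field("`n_scales` must be >= 1")
  jmax <- atrous_max_scales(dim(image))
  if (n_scales > jmax)
    stop_field(sprintf(
      "image of %d x %d supports at most J = %d a trous scales (kernel half-width 2^(J-1)*2 must fit)",
      nrow(image), ncol(image), jmax))

  a <- image
  planes <- vector("list", n_scales)
  for (j in seq_len(n_scales)) {
    s <- atrous_smooth(a, step = 2L^(j - 1L))
    planes[[j]] <- a - s
    a <- s
  }
  structure(list(planes = planes, residual = a, scales = n_scales),
            class = "nq_atrous")
}

# Largest feasible J: requires the dilated kernel half-width 2 * 2^(J-1)
# to stay below the image size so mirror indexing is well defined.
atrous_max_scales <- function(dm) {
  n <- min(dm)
  j <- 0L
  while (2L * 2L^j < n) j <- j + 1L
  max(j, 0L)
}

# One separable B3-spline smoothing pass with hole step `step`.
atrous_smooth <- function(m, step) {
  k <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * step
  # rows
  out <- matrix(0, nrow(m), ncol(m))
  for (i in 1:5) out <- out + k[i] * shift_mirror(m, off[i], 0L)
  # columns
  res <- matrix(0, nrow(m), ncol(m))
  for (i in 1:5) res <- res + k[i] * shift_mirror(out, 0L, off[i])
  res
}

#' Reconstruct an image from its a trous decomposition
#'
#' @param dec an `nq_atrous` object.
#' @return numeric matrix, `residual + sum(planes)`.
#' @export
atrous_reconstruct <- function(dec) {
  stopifnot(inherits(dec, "nq_atrous"))
  Reduce(`+`, dec$planes, dec$residual)
}
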