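# Internal helpers shared across modules.

# Mirror-reflected index into 1..n (reflection about the edges, no repeated
# border sample: ... 3 2 | 1 2 3 ... n-1 n | n-1 ...).
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j < n, j + 1L, p - j + 1L)
}

# Shift a matrix by (dr, dc) with mirror-reflected borders.
shift_mirror <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[mirror_index(seq_len(nr) + dr, nr), mirror_index(seq_len(nc) + dc, nc), drop = FALSE]
}

# Shift with replicated (clamped) borders; used by finite differences.
shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Shift a logical matrix, padding with FALSE (used by thinning / counting).
shift_pad <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Robust Gaussian noise scale: MAD about the median, scaled to sigma.
mad_sigma <- function(x) stats::median(abs(x - stats::median(x))) / 0.67449

# Gaussian smoothing of a plain matrix via EBImage, returning a matrix.
# Images smaller than the filter support are mirror-padded first.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  need <- 2L * as.integer(ceiling(3 * sigma)) + 3L
  if (min(dim(m)) <= need) {
    p <- need
    nr <- nrow(m); nc <- ncol(m)
    big <- m[mirror_index((1 - p):(nr + p), nr),
             mirror_index((1 - p):(nc + p), nc)]
    sm <- strip_img(EBImage::gblur(EBImage::Image(big), sigma = sigma))
    return(sm[(p + 1):(p + nr), (p + 1):(p + nc)])
  }
  strip_img(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

# Drop EBImage attributes, keeping a plain numeric matrix.
strip_img <- function(img) {
  m <- as.matrix(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Out-of-range positions are mirror-reflected.
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  i0 <- mirror_index(as.integer(r0), nr); i1 <- mirror_index(as.integer(r0) + 1L, nr)
  j0 <- mirror_index(as.integer(c0), nc); j1 <- mirror_index(as.integer(c0) + 1L, nc)
  m[cbind(i0, j0)] * (1 - fr) * (1 - fc) +
    m[cbind(i1, j0)] * fr * (1 - fc) +
    m[cbind(i0, j1)] * (1 - fr) * fc +
    m[cbind(i1, j1)] * fr * fc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg) stop(msg, call. = FALSE)
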