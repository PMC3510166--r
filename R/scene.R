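#' Synthetic scene configuration
#'
#' Parameters of one synthetic two-channel fluorescence scene (channel 1 =
#' DAPI nuclear stain, channel 2 = green marker). Geometry is expressed in
#' micrometres and converted internally using `pixel_size`; intensities are
#' arbitrary camera units on a 16-bit range.
#'
#' Defaults emulate a 20x-class acquisition (0.65 um/pixel) of NG108-15-like
#' cells: ~12 cells per 512 x 512 field, nuclei of ~5 um radius inside ~9 um
#' somata, 1-4 curvilinear neurites per cell of ~60 um design length
#' (pre-multiplier), punctate marker density 0.12 spots/um along neurites.
#' Noise is Poisson shot noise (`poisson_scale` photons per intensity unit;
#' `Inf` disables it) plus additive zero-mean Gaussian read noise.
#'
#' @param width,height image size in pixels.
#' @param pixel_size um per pixel.
#' @param n_cells number of cells (0 allowed: blank scene).
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius, um.
#' @param soma_radius_mean soma radius, um.
#' @param neurites_per_cell_mean mean neurite count per cell (count is
#'   `1 + Poisson(mean - 1)`).
#' @param neurite_length_mean design neurite length, um, before the condition
#'   multiplier.
#' @param neurite_length_jitter half-width of the uniform per-neurite length
#'   factor (0 = all neurites share the design length).
#' @param neurite_width rendered neurite width, um.
#' @param spot_density_on_neurite puncta per um of neurite (pre-multiplier).
#' @param spot_density_off_neurite spurious puncta per um^2 of field.
#' @param spot_amplitude peak intensity of a rendered punctum.
#' @param psf_sigma Gaussian PSF sigma, um.
#' @param background_level green-channel background intensity.
#' @param poisson_scale photons per intensity unit (Inf = no shot noise).
#' @param gaussian_sd additive Gaussian read-noise sigma, intensity units.
#' @param nuc_cyto_ratio design nuclear/cytoplasmic mean green ratio for the
#'   RhoA-style marker (pre-multiplier).
#' @param soma_amplitude,neurite_amplitude,dapi_amplitude,cyto_level rendered
#'   intensities of soma, neurite, nucleus (DAPI) and cytoplasm (RhoA marker).
#' @param seed integer RNG seed; identical (config, seed) pairs reproduce
#'   identical scenes.
#' @return list of class `nq_scene_config`.
#' @export
scene_config <- function(width = 512, height = 512, pixel_size = 0.65,
                         n_cells = 12,
                         nucleus_radius_mean = 5, nucleus_radius_sd = 0.5,
                         soma_radius_mean = 9,
                         neurites_per_cell_mean = 2,
                         neurite_length_mean = 60,
                         neurite_length_jitter = 0.25,
                         neurite_width = 1.3,
                         spot_density_on_neurite = 0.04,
                         spot_density_off_neurite = 3e-4,
                         spot_amplitude = 800,
                         psf_sigma = 0.8,
                         background_level = 100,
                         poisson_scale = 1,
                         gaussian_sd = 10,
                         nuc_cyto_ratio = 2,
                         soma_amplitude = 400,
                         neurite_amplitude = 350,
                         dapi_amplitude = 600,
                         cyto_level = 300,
                         seed = 1) {
  cfg <- as.list(environment())
  pos_fields <- c("width", "height", "pixel_size", "nucleus_radius_mean",
                  "soma_radius_mean", "neurites_per_cell_mean",
                  "neurite_length_mean", "neurite_width", "spot_amplitude",
                  "nuc_cyto_ratio", "poisson_scale")
  for (f in pos_fields)
    if (!is.finite(cfg[[f]]) && !(f == "poisson_scale" && is.infinite(cfg[[f]])) ||
        cfg[[f]] <= 0)
      stop_field(sprintf("scene_config field `%s` must be positive", f))
  nonneg <- c("n_cells", "nucleus_radius_sd", "neurite_length_jitter",
              "spot_density_on_neurite",
              "spot_density_off_neurite", "psf_sigma", "background_level",
              "gaussian_sd")
  for (f in nonneg)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop_field(sprintf("scene_config field `%s` must be >= 0", f))
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "nq_scene_config")
}

# Evaluate code with a private, restored-afterwards RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- geometry -------------------------------------------------------------

# Cell layout: positions, radii, neurite counts/angles/length factors.
# All draws here are independent of condition multipliers, so a fixed seed
# yields the same layout for every condition.
gen_layout <- function(cfg) {
  n <- cfg$n_cells
  if (n == 0) return(list(cells = list()))
  soma_r <- cfg$soma_radius_mean / cfg$pixel_size
  nuc_r_mean <- cfg$nucleus_radius_mean / cfg$pixel_size
  min_dist <- max(2.3 * soma_r, 4.5 * nuc_r_mean)
  margin <- soma_r + 5
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n) {
    p <- c(stats::runif(1, margin, cfg$height - margin),
           stats::runif(1, margin, cfg$width - margin))
    ok <- !nrow(centers) ||
      all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >= min_dist^2)
    if (ok) centers <- rbind(centers, p)
    tries <- tries + 1
    if (tries > 5000)
      stop_field("could not place all cells with the required separation; reduce n_cells or cell size")
  }
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    nuc_r <- max(2, stats::rnorm(1, cfg$nucleus_radius_mean, cfg$nucleus_radius_sd) /
                   cfg$pixel_size)
    n_neur <- 1L + stats::rpois(1, max(cfg$neurites_per_cell_mean - 1, 0))
    cells[[i]] <- list(
      center = centers[i, ],
      nucleus_r = nuc_r,
      soma_r = soma_r,
      n_neurites = n_neur,
      angles = stats::runif(n_neur, 0, 2 * pi),
      length_factors = stats::runif(n_neur, 1 - cfg$neurite_length_jitter,
                                    1 + cfg$neurite_length_jitter)
    )
  }
  list(cells = cells)
}

# Random-walk neurite polyline with bounded curvature and billiard
# reflection at a border margin. Unit-pixel steps plus one fractional final
# step make the polyline length exactly `len_px`.
walk_neurite <- function(start, heading, len_px, width, height,
                         curvature_sd = 0.10, margin = 6) {
  n_full <- floor(len_px)
  rem <- len_px - n_full
  steps <- if (rem > 1e-9) c(rep(1, n_full), rem) else rep(1, n_full)
  if (!length(steps)) return(matrix(start, 1, 2))
  turns <- stats::rnorm(length(steps), 0, curvature_sd)
  verts <- matrix(NA_real_, length(steps) + 1, 2)
  verts[1, ] <- start
  pos <- start; h <- heading
  for (i in seq_along(steps)) {
    h <- h + turns[i]
    d <- c(sin(h), cos(h)) * steps[i]
    p <- pos + d
    # reflect off the margin box (row axis then col axis)
    if (p[1] < margin || p[1] > height - margin) {
      d[1] <- -d[1]; p <- pos + d
    }
    if (p[2] < margin || p[2] > width - margin) {
      d[2] <- -d[2]; p <- pos + d
    }
    h <- atan2(d[1] / steps[i], d[2] / steps[i])
    pos <- p
    verts[i + 1, ] <- pos
  }
  verts
}

polyline_length <- function(verts) {
  if (nrow(verts) < 2) return(0)
  sum(sqrt(rowSums((verts[-1, , drop = FALSE] - verts[-nrow(verts), , drop = FALSE])^2)))
}

# Point at arc length s along a polyline (s in [0, total length]).
polyline_point <- function(verts, s) {
  seg <- sqrt(rowSums((verts[-1, , drop = FALSE] - verts[-nrow(verts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  f <- (s - cs[idx]) / pmax(seg[idx], 1e-12)
  verts[idx, , drop = FALSE] * (1 - f) + verts[idx + 1, , drop = FALSE] * f
}

# Rasterize polylines into a logical mask, stroke width `width_px`.
rasterize_polylines <- function(polys, nrow_, ncol_, width_px) {
  mask <- matrix(FALSE, nrow_, ncol_)
  pts <- do.call(rbind, lapply(polys, function(v) {
    if (nrow(v) < 2) return(v)
    seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    total <- sum(seg)
    n <- max(2L, ceiling(total / 0.35))
    polyline_point(v, seq(0, total, length.out = n))
  }))
  if (is.null(pts) || !nrow(pts)) return(mask)
  r <- pmin(pmax(round(pts[, 1]), 1), nrow_)
  c <- pmin(pmax(round(pts[, 2]), 1), ncol_)
  mask[cbind(r, c)] <- TRUE
  if (width_px > 1.5) {
    brush <- EBImage::makeBrush(2 * floor(width_px / 2) + 1, shape = "box")
    mask <- as.matrix(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  }
  mask
}

# Greedy hard-core thinning: drop any point closer than d_min to a kept one.
hardcore_thin <- function(spots, d_min) {
  if (nrow(spots) < 2) return(spots)
  keep <- logical(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    ki <- which(keep)
    keep[i] <- !length(ki) ||
      all((spots$row[ki] - spots$row[i])^2 +
            (spots$col[ki] - spots$col[i])^2 >= d_min^2)
  }
  spots[keep, , drop = FALSE]
}

disk_mask <- function(nrow_, ncol_, center, radius, base = NULL) {
  m <- base %||% matrix(FALSE, nrow_, ncol_)
  r0 <- max(1, floor(center[1] - radius)); r1 <- min(nrow_, ceiling(center[1] + radius))
  c0 <- max(1, floor(center[2] - radius)); c1 <- min(ncol_, ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(m)
  rr <- r0:r1; cc <- c0:c1
  sub <- outer((rr - center[1])^2, (cc - center[2])^2, `+`) <= radius^2
  m[rr, cc] <- m[rr, cc] | sub
  m
}

# Add a Gaussian bump at fractional position (r, c).
add_gaussian_spot <- function(map, r, c, amp, sigma) {
  w <- ceiling(4 * sigma)
  r0 <- max(1, floor(r) - w); r1 <- min(nrow(map), ceiling(r) + w)
  c0 <- max(1, floor(c) - w); c1 <- min(ncol(map), ceiling(c) + w)
  if (r0 > r1 || c0 > c1) return(map)
  rr <- r0:r1; cc <- c0:c1
  g <- amp * exp(-outer((rr - r)^2, (cc - c)^2, `+`) / (2 * sigma^2))
  map[rr, cc] <- map[rr, cc] + g
  map
}

# ---- rendering ------------------------------------------------------------

apply_noise <- function(ideal, cfg) {
  img <- ideal
  if (is.finite(cfg$poisson_scale)) {
    lam <- pmax(img, 0) * cfg$poisson_scale
    img <- matrix(stats::rpois(length(lam), lam) / cfg$poisson_scale,
                  nrow(img), ncol(img))
  }
  if (cfg$gaussian_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, cfg$gaussian_sd),
                        nrow(img), ncol(img))
  img
}

#' Generate one synthetic two-channel fluorescence scene with ground truth
#'
#' Renders somata, nuclei and curvilinear neurites, draws marker-specific
#' green-channel content, blurs with a Gaussian PSF, and applies Poisson shot
#' noise plus additive Gaussian read noise. Ground truth (masks, spot
#' positions, exact per-cell neurite length) is taken from the pre-noise
#' geometry.
#'
#' Markers:
#' * `"neurofilament"`: green signal fills somata and neurites.
#' * `"synaptotagmin"`: faint cell outline plus bright puncta, placed along
#'   neurite centerlines (density scaled by the condition's on-neurite
#'   multiplier) and sparsely elsewhere.
#' * `"rhoa"`: cytoplasmic level in the soma and neurites; nuclear signal at
#'   `nuc_cyto_ratio * nuc_cyto_multiplier` times the cytoplasmic level,
#'   partly concentrated in subnuclear puncta so that both the
#'   nuclear/cytoplasmic mean ratio and the nuclear intensity SD scale with
#'   the condition multiplier.
#'
#' @param config a [scene_config()].
#' @param effects a [condition_effects()] record.
#' @param marker one of `"neurofilament"`, `"synaptotagmin"`, `"rhoa"`.
#' @param seed optional seed overriding `config$seed`.
#' @return list with elements `scene` (class `nq_scene`: matrices `green`,
#'   `dapi`, plus `pixel_size`, `marker`, `condition`, `saturation`) and
#'   `truth` (class `nq_truth`: `cell_mask`, `neurite_mask`, `nucleus_mask`,
#'   `nucleus_centroids`, `spot_positions`, `true_neurite_length_per_cell`
#'   (um), `true_nuc_cyto_ratio`, `neurite_polylines`).
#' @export
generate_scene <- function(config, effects = condition_effects("control"),
                           marker = c("neurofilament", "synaptotagmin", "rhoa"),
                           seed = NULL) {
  stopifnot(inherits(config, "nq_scene_config"), inherits(effects, "nq_effects"))
  marker <- match.arg(marker)
  seed <- as.integer(seed %||% config$seed)
  with_seed(seed, generate_scene_impl(config, effects, marker))
}

generate_scene_impl <- function(cfg, eff, marker) {
  h <- cfg$height; w <- cfg$width; px <- cfg$pixel_size
  layout <- gen_layout(cfg)
  cells <- layout$cells
  n_cells <- length(cells)

  soma_mask <- matrix(FALSE, h, w)
  nucleus_mask <- matrix(FALSE, h, w)
  nucleus_list <- vector("list", n_cells)
  for (ci in seq_along(cells)) {
    cl <- cells[[ci]]
    soma_mask <- disk_mask(h, w, cl$center, cl$soma_r, soma_mask)
    nucleus_list[[ci]] <- disk_mask(h, w, cl$center, cl$nucleus_r)
    nucleus_mask <- nucleus_mask | nucleus_list[[ci]]
  }

  # neurites: design length = mean * condition multiplier * per-neurite factor
  polys <- list()
  total_len_px <- 0
  for (cl in cells) {
    for (k in seq_len(cl$n_neurites)) {
      len_um <- cfg$neurite_length_mean * eff$neurite_length_multiplier *
        cl$length_factors[k]
      start <- cl$center + cl$soma_r * c(sin(cl$angles[k]), cos(cl$angles[k]))
      v <- walk_neurite(start, cl$angles[k], len_um / px, w, h)
      polys[[length(polys) + 1]] <- v
      total_len_px <- total_len_px + polyline_length(v)
    }
  }
  width_px <- max(1, cfg$neurite_width / px)
  neurite_raw <- rasterize_polylines(polys, h, w, width_px)
  neurite_mask <- neurite_raw & !soma_mask
  cell_mask <- soma_mask

  # puncta ground truth (synaptotagmin marker only); a hard-core thinning
  # (5 px minimum spacing) keeps puncta optically resolvable
  spots <- data.frame(row = numeric(0), col = numeric(0), on_neurite = logical(0))
  if (marker == "synaptotagmin") {
    for (v in polys) {
      len_um <- polyline_length(v) * px
      n_on <- stats::rpois(1, cfg$spot_density_on_neurite *
                              eff$spot_on_neurite_multiplier * len_um)
      if (n_on > 0) {
        p <- polyline_point(v, stats::runif(n_on, 0, polyline_length(v)))
        keep <- neurite_mask[cbind(pmin(pmax(round(p[, 1]), 1), h),
                                   pmin(pmax(round(p[, 2]), 1), w))]
        if (any(keep))
          spots <- rbind(spots, data.frame(row = p[keep, 1], col = p[keep, 2],
                                           on_neurite = TRUE))
      }
    }
    area_um2 <- h * w * px^2
    n_off <- stats::rpois(1, cfg$spot_density_off_neurite * area_um2)
    if (n_off > 0) {
      p <- cbind(stats::runif(n_off, 12, h - 12), stats::runif(n_off, 12, w - 12))
      # keep a 3 px buffer to the neurite stroke so the off-neurite class is
      # geometrically unambiguous
      near_neurite <- if (any(neurite_raw))
        as.matrix(EBImage::dilate(EBImage::Image(neurite_raw * 1),
                                  EBImage::makeBrush(7, "disc"))) > 0
      else neurite_raw
      keep <- !near_neurite[cbind(round(p[, 1]), round(p[, 2]))]
      if (any(keep))
        spots <- rbind(spots, data.frame(row = p[keep, 1], col = p[keep, 2],
                                         on_neurite = FALSE))
    }
    spots <- hardcore_thin(spots, d_min = 5)
  }

  # green-channel ideal map
  green <- matrix(cfg$background_level, h, w)
  r_eff <- cfg$nuc_cyto_ratio * eff$nuc_cyto_multiplier
  if (marker == "neurofilament") {
    green <- green + pmax(cfg$soma_amplitude * soma_mask,
                          cfg$neurite_amplitude * neurite_raw)
  } else if (marker == "synaptotagmin") {
    # punctate marker: the diffuse (non-vesicular) component is faint
    green <- green + pmax(0.05 * cfg$soma_amplitude * soma_mask,
                          0.05 * cfg$neurite_amplitude * neurite_raw)
    if (nrow(spots))
      for (i in seq_len(nrow(spots)))
        green <- add_gaussian_spot(green, spots$row[i], spots$col[i],
                                   cfg$spot_amplitude, sigma = 1.2)
  } else { # rhoa
    cyto_mask <- (soma_mask & !nucleus_mask) | neurite_mask
    green <- green + cfg$cyto_level * cyto_mask
    for (ci in seq_along(cells)) {
      nm <- nucleus_list[[ci]]
      npx <- which(nm)
      if (!length(npx)) next
      cl <- cells[[ci]]
      pat <- matrix(0, h, w)
      for (k in 1:5) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * 0.7 * cl$nucleus_r
        pat <- add_gaussian_spot(pat, cl$center[1] + rad * sin(ang),
                                 cl$center[2] + rad * cos(ang), 1, sigma = 1.6)
      }
      pat_mean <- mean(pat[npx])
      if (pat_mean <= 0) pat_mean <- 1
      # raw nuclear mean = r_eff * raw cytoplasmic level, partly in puncta;
      # both the mean ratio and the nuclear SD scale with the multiplier
      nuc_level <- (cfg$background_level + cfg$cyto_level) * r_eff *
        (0.6 + 0.4 * pat[npx] / pat_mean)
      green[npx] <- nuc_level
    }
  }

  # DAPI ideal map
  dapi <- matrix(30, h, w) + cfg$dapi_amplitude * nucleus_mask

  psf_px <- cfg$psf_sigma / px
  if (psf_px > 0) {
    green <- gauss_smooth(green, psf_px)
    dapi <- gauss_smooth(dapi, psf_px)
  }
  green_n <- apply_noise(green, cfg)
  dapi_n <- apply_noise(dapi, cfg)
  sat <- (sum(green_n > 65535) + sum(dapi_n > 65535)) / (2 * h * w)
  green_n <- pmin(pmax(green_n, 0), 65535)
  dapi_n <- pmin(pmax(dapi_n, 0), 65535)

  centroids <- if (n_cells) do.call(rbind, lapply(cells, `[[`, "center")) else
    matrix(numeric(0), 0, 2)
  colnames(centroids) <- c("row", "col")

  scene <- structure(list(
    green = green_n, dapi = dapi_n, ideal_green = green, ideal_dapi = dapi,
    pixel_size = px, marker = marker, condition = eff$condition,
    saturation = sat
  ), class = "nq_scene")
  truth <- structure(list(
    cell_mask = cell_mask, neurite_mask = neurite_mask,
    nucleus_mask = nucleus_mask, nucleus_centroids = centroids,
    spot_positions = spots,
    true_neurite_length_per_cell = if (n_cells) total_len_px * px / n_cells else NA_real_,
    true_nuc_cyto_ratio = r_eff,
    neurite_polylines = polys
  ), class = "nq_truth")
  list(scene = scene, truth = truth)
}
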