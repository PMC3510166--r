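#' Time-lapse acquisition configuration
#'
#' Describes a simulated live-cell imaging run. In `"elongation"` mode
#' neurites grow linearly at `growth_rate` um/h; in `"retraction"` mode
#' (RhoA-activator style) length decays as a single exponential toward a
#' residual: `L(t) = L0 * (1 - total * (1 - exp(-t / tau)))`. With the
#' default time constant `tau = 27` min more than half of the total
#' retraction happens within the first 40 minutes; `retraction_at_60` fixes
#' the fractional length decrease reached at t = 60 min (default 0.77, the
#' calpeptin calibration), from which the asymptotic total is derived.
#'
#' @param frame_interval minutes between frames (> 0).
#' @param duration total imaged time, minutes (>= frame_interval).
#' @param mode `"elongation"` or `"retraction"`.
#' @param growth_rate um/h (elongation mode).
#' @param retraction_tau exponential time constant, minutes.
#' @param retraction_at_60 fractional decrease of neurite length at 60 min.
#' @param onset_delay minutes before the dynamic starts.
#' @return list of class `nq_timelapse_config`.
#' @export
timelapse_config <- function(frame_interval = 56, duration = 48 * 60,
                             mode = c("elongation", "retraction"),
                             growth_rate = 2,
                             retraction_tau = 27,
                             retraction_at_60 = 0.77,
                             onset_delay = 0) {
  mode <- match.arg(mode)
  if (frame_interval <= 0) stop_field("`frame_interval` must be > 0")
  if (duration < frame_interval)
    stop_field("`duration` must be >= `frame_interval`")
  if (retraction_tau <= 0) stop_field("`retraction_tau` must be > 0")
  if (retraction_at_60 < 0 || retraction_at_60 >= 1)
    stop_field("`retraction_at_60` must be in [0, 1)")
  structure(list(frame_interval = frame_interval, duration = duration,
                 mode = mode, growth_rate = growth_rate,
                 retraction_tau = retraction_tau,
                 retraction_at_60 = retraction_at_60,
                 onset_delay = onset_delay),
            class = "nq_timelapse_config")
}

# Neurite length (um) at time t (minutes) given the t = 0 length.
# Elongation is additive (um/h per neurite tip); retraction is a single
# exponential toward the residual length.
timelapse_length_at <- function(tcfg, len0_um, t) {
  te <- pmax(t - tcfg$onset_delay, 0)
  if (tcfg$mode == "elongation") {
    len0_um + tcfg$growth_rate * te / 60
  } else {
    total <- tcfg$retraction_at_60 / (1 - exp(-60 / tcfg$retraction_tau))
    len0_um * (1 - total * (1 - exp(-te / tcfg$retraction_tau)))
  }
}

#' Generate a synthetic time-lapse series
#'
#' Produces `floor(duration / frame_interval) + 1` frames of the same field
#' of cells (layout and neurite paths are fixed across frames); only the
#' neurite lengths evolve, by truncating or extending each master polyline to
#' the mode-dependent length at the frame time. Per-frame ground truth length
#' is therefore monotone nondecreasing in elongation mode and nonincreasing
#' in retraction mode. Noise is drawn independently per frame.
#'
#' @param config a [scene_config()] (the `neurite_length_mean` is the t = 0
#'   length, pre-multiplier).
#' @param tconfig a [timelapse_config()].
#' @param effects a [condition_effects()] record.
#' @param seed optional override of `config$seed`.
#' @return list of class `nq_timelapse`: `times` (minutes) and `frames`, a
#'   list of `(scene, truth)` pairs as returned by [generate_scene()].
#' @export
generate_timelapse <- function(config, tconfig,
                               effects = condition_effects("control"),
                               seed = NULL) {
  stopifnot(inherits(config, "nq_scene_config"),
            inherits(tconfig, "nq_timelapse_config"),
            inherits(effects, "nq_effects"))
  seed <- as.integer(seed %||% config$seed)
  times <- seq(0, by = tconfig$frame_interval,
               length.out = floor(tconfig$duration / tconfig$frame_interval) + 1)
  t_max_len <- if (tconfig$mode == "elongation") max(times) else 0

  # master geometry at each neurite's maximal length, drawn once; layout
  # draws are length-independent so the field is stable across frames
  master <- with_seed(seed, {
    layout <- gen_layout(config)
    polys <- list(); len0 <- numeric(0)
    for (cl in layout$cells) {
      for (k in seq_len(cl$n_neurites)) {
        l0 <- config$neurite_length_mean * effects$neurite_length_multiplier *
          cl$length_factors[k]
        lmax <- timelapse_length_at(tconfig, l0, t_max_len)
        start <- cl$center + cl$soma_r * c(sin(cl$angles[k]), cos(cl$angles[k]))
        polys[[length(polys) + 1]] <-
          walk_neurite(start, cl$angles[k], lmax / config$pixel_size,
                       config$width, config$height)
        len0 <- c(len0, l0)
      }
    }
    list(layout = layout, polys = polys, len0 = len0)
  })

  frames <- vector("list", length(times))
  for (fi in seq_along(times)) {
    target_um <- pmax(timelapse_length_at(tconfig, master$len0, times[fi]), 0)
    frames[[fi]] <- with_seed(seed + 7919L * fi,
      render_timelapse_frame(config, effects, master,
                             target_um / config$pixel_size))
  }
  structure(list(times = times, frames = frames,
                 condition = effects$condition, mode = tconfig$mode),
            class = "nq_timelapse")
}

# Render one frame: truncate master polylines to the per-neurite target
# lengths (px), rasterize and apply the neurofilament-style rendering + noise.
render_timelapse_frame <- function(cfg, eff, master, target_px) {
  h <- cfg$height; w <- cfg$width; px <- cfg$pixel_size
  cells <- master$layout$cells
  n_cells <- length(cells)
  soma_mask <- matrix(FALSE, h, w)
  nucleus_mask <- matrix(FALSE, h, w)
  for (cl in cells) {
    soma_mask <- disk_mask(h, w, cl$center, cl$soma_r, soma_mask)
    nucleus_mask <- disk_mask(h, w, cl$center, cl$nucleus_r, nucleus_mask)
  }
  polys <- lapply(seq_along(master$polys), function(i) {
    v <- master$polys[[i]]
    s_target <- target_px[i]
    if (s_target <= 0) return(v[1, , drop = FALSE])
    truncate_polyline(v, s_target)
  })
  total_len_px <- sum(vapply(polys, polyline_length, 0))
  width_px <- max(1, cfg$neurite_width / px)
  neurite_raw <- rasterize_polylines(polys, h, w, width_px)
  neurite_mask <- neurite_raw & !soma_mask

  green <- matrix(cfg$background_level, h, w) +
    pmax(cfg$soma_amplitude * soma_mask, cfg$neurite_amplitude * neurite_raw)
  dapi <- matrix(30, h, w) + cfg$dapi_amplitude * nucleus_mask
  psf_px <- cfg$psf_sigma / px
  if (psf_px > 0) {
    green <- gauss_smooth(green, psf_px)
    dapi <- gauss_smooth(dapi, psf_px)
  }
  green_n <- pmin(pmax(apply_noise(green, cfg), 0), 65535)
  dapi_n <- pmin(pmax(apply_noise(dapi, cfg), 0), 65535)

  centroids <- if (n_cells) do.call(rbind, lapply(cells, `[[`, "center")) else
    matrix(numeric(0), 0, 2)
  colnames(centroids) <- c("row", "col")
  list(
    scene = structure(list(green = green_n, dapi = dapi_n,
                           ideal_green = green, ideal_dapi = dapi,
                           pixel_size = px, marker = "neurofilament",
                           condition = eff$condition, saturation = 0),
                      class = "nq_scene"),
    truth = structure(list(cell_mask = soma_mask, neurite_mask = neurite_mask,
                           nucleus_mask = nucleus_mask,
                           nucleus_centroids = centroids,
                           spot_positions = data.frame(),
                           true_neurite_length_per_cell =
                             if (n_cells) total_len_px * px / n_cells else NA_real_,
                           true_nuc_cyto_ratio = cfg$nuc_cyto_ratio,
                           neurite_polylines = polys),
                      class = "nq_truth")
  )
}

# Cut a polyline at arc length s (exact: interpolated final vertex).
truncate_polyline <- function(v, s) {
  if (nrow(v) < 2) return(v)
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cs <- cumsum(seg)
  if (s >= cs[length(cs)] - 1e-12) return(v)
  i <- which(cs >= s)[1]
  prev <- if (i == 1) 0 else cs[i - 1]
  f <- (s - prev) / seg[i]
  end <- v[i, ] * (1 - f) + v[i + 1, ] * f
  rbind(v[seq_len(i), , drop = FALSE], end)
}
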