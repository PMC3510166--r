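#' Write a scene as a multi-page 16-bit TIFF
#'
#' Page 1 is the DAPI channel, page 2 the green marker channel. Intensities
#' are clipped to [0, 65535] and quantized to 16-bit; the pixel size (um) is
#' stored in the TIFF X/Y resolution tags as pixels per centimetre.
#'
#' @param scene an `nq_scene`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(scene, path) {
  pages <- lapply(list(scene$dapi, scene$green), function(m)
    round(pmin(pmax(m, 0), 65535)) / 65535)
  res <- 1e4 / scene$pixel_size  # pixels per cm
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Read a scene from a multi-page TIFF written by [write_scene_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size um per pixel of the acquisition.
#' @return an `nq_scene` with intensities on the 16-bit scale.
#' @export
read_scene_tiff <- function(path, pixel_size = 0.65) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop_field("expected a 2-page (DAPI, green) TIFF")
  structure(list(dapi = pages[[1]] * 65535, green = pages[[2]] * 65535,
                 pixel_size = pixel_size, marker = NA_character_,
                 condition = NA_character_, saturation = NA_real_),
            class = "nq_scene")
}

# Run-length encode a logical mask (column-major) for JSON sidecars.
rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), values = as.integer(r$values), lengths = r$lengths)
}

rle_decode_mask <- function(enc) {
  matrix(rep(as.logical(enc$values), enc$lengths),
         enc$dim[1], enc$dim[2])
}

#' Write a ground-truth sidecar as JSON
#'
#' Masks are stored run-length encoded; coordinates are 0-based (row, col).
#'
#' @param truth an `nq_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    cell_mask = rle_encode_mask(truth$cell_mask),
    neurite_mask = rle_encode_mask(truth$neurite_mask),
    nucleus_mask = rle_encode_mask(truth$nucleus_mask),
    nucleus_centroids = unname(truth$nucleus_centroids) - 1,
    spot_positions = if (nrow(truth$spot_positions))
      data.frame(row = truth$spot_positions$row - 1,
                 col = truth$spot_positions$col - 1,
                 on_neurite = truth$spot_positions$on_neurite)
      else list(),
    true_neurite_length_per_cell = truth$true_neurite_length_per_cell,
    true_nuc_cyto_ratio = truth$true_nuc_cyto_ratio)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a segmentation as a single-channel label TIFF plus JSON summary
#'
#' Label values: 0 = background, 1 = cell, 2 = neurite.
#'
#' @param segmap an `nq_segmentation`.
#' @param path_tiff,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_segmentation <- function(segmap, path_tiff = NULL, path_json = NULL) {
  if (!is.null(path_tiff))
    tiff::writeTIFF(segmap$labels / 255, path_tiff, bits.per.sample = 8L)
  if (!is.null(path_json))
    jsonlite::write_json(list(
      nucleus_count = segmap$nucleus_count,
      pixel_size = segmap$pixel_size,
      n_background = sum(segmap$labels == 0),
      n_cell = sum(segmap$labels == 1),
      n_neurite = sum(segmap$labels == 2),
      skeleton_px = sum(segmap$skeleton)),
      path_json, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = path_tiff, json = path_json))
}
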