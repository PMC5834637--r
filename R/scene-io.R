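# TIFF I/O for multispectral scenes and guano masks, using the same
# world-file + JSON-sidecar convention as orthomosaics.

#' Write / read a multispectral scene as multi-page TIFF
#'
#' Bands are stored as one TIFF page each (32-bit, values rescaled to the
#' unit interval); band names, sensor id, cell size and the value range
#' travel in a JSON sidecar.
#'
#' @param scene an [ms_scene()].
#' @param path output path ending in `.tif`.
#' @return `path` invisibly / an [ms_scene()].
#' @export
write_ms_scene <- function(scene, path) {
  bands <- names(scene$bands)
  lo <- min(vapply(scene$bands, min, 0))
  hi <- max(vapply(scene$bands, max, 0))
  pages <- lapply(scene$bands, function(b)
    if (hi > lo) (b - lo) / (hi - lo) else b * 0)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(bands = bands, sensor_id = scene$sensor_id,
         cell_size = scene$cell_size, value_min = lo, value_max = hi),
    sub("\\.tiff?$", ".meta.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ms_scene
#' @export
read_ms_scene <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".meta.json", path),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  bl <- lapply(pages, function(p)
    p * (meta$value_max - meta$value_min) + meta$value_min)
  names(bl) <- meta$bands
  ms_scene(bl, sensor_id = meta$sensor_id,
           cell_size = as.numeric(meta$cell_size))
}

#' Write / read a guano mask as TIFF
#'
#' @param mask a [guano_mask()].
#' @param path output path ending in `.tif`.
#' @return `path` invisibly / a [guano_mask()].
#' @export
write_guano_mask <- function(mask, path) {
  tiff::writeTIFF(mask$cells + 0, path, bits.per.sample = 8L, reduce = FALSE)
  jsonlite::write_json(
    list(cell_size = mask$cell_size, epoch = mask$epoch),
    sub("\\.tiff?$", ".meta.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_guano_mask
#' @export
read_guano_mask <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".meta.json", path),
                              simplifyVector = TRUE)
  cells <- tiff::readTIFF(path) > 0.5
  guano_mask(cells, cell_size = as.numeric(meta$cell_size),
             epoch = meta$epoch %||% NA_character_)
}
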