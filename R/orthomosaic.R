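#' Georeferenced orthomosaic raster
#'
#' A minimal in-memory container for a top-down, georeferenced composite
#' image in which every pixel corresponds to a fixed ground dimension
#' (the ground sample distance, gsd). World coordinates are metres with y
#' increasing northwards; pixel indices are row-major with the pixel-centre
#' convention, so the centre of the top-left pixel sits half a gsd inside
#' `origin` (the outer corner of that pixel).
#'
#' @param pixels numeric matrix (rows x cols) or 3-d array (rows x cols x
#'   bands) of pixel values.
#' @param gsd ground sample distance, metres per pixel (> 0).
#' @param origin length-2 numeric, world coordinate (x, y) of the outer
#'   top-left corner of pixel (1, 1).
#' @param island_id character identifier of the imaged island.
#' @return An object of class `orthomosaic`.
#' @seealso [tile_raster()], [detect_candidates()], [write_orthomosaic()]
#' @export
orthomosaic <- function(pixels, gsd, origin, island_id = "island") {
  if (!is.numeric(gsd) || length(gsd) != 1 || !is.finite(gsd) || gsd <= 0)
    stop("gsd must be a single positive number (metres/pixel)")
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop("origin must be a finite (x, y) world coordinate")
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    stop("pixels must be a matrix or a rows x cols x bands array")
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  structure(
    list(pixels = pixels, gsd = gsd, origin = as.numeric(origin),
         island_id = as.character(island_id)),
    class = "orthomosaic")
}

ortho_dim <- function(ortho) dim(ortho$pixels)[1:2]

# single grey band used for detection (mean over bands if multiband)
ortho_band <- function(ortho) {
  px <- ortho$pixels
  if (is.matrix(px)) px else apply(px, c(1, 2), mean)
}

#' Convert between world coordinates and pixel indices
#'
#' The affine mapping is invertible: `pixel_to_world` returns the world
#' position of a pixel centre, `world_to_pixel` the (row, col) indices
#' (1-based) of the pixel containing a world point.
#'
#' @param ortho an [orthomosaic()].
#' @param row,col 1-based pixel indices.
#' @param x,y world coordinates in metres.
#' @return A two-column matrix: `(x, y)` for `pixel_to_world`,
#'   `(row, col)` for `world_to_pixel`.
#' @export
pixel_to_world <- function(ortho, row, col) {
  cbind(x = ortho$origin[1] + (col - 0.5) * ortho$gsd,
        y = ortho$origin[2] - (row - 0.5) * ortho$gsd)
}

#' @rdname pixel_to_world
#' @export
world_to_pixel <- function(ortho, x, y) {
  cbind(row = floor((ortho$origin[2] - y) / ortho$gsd) + 1,
        col = floor((x - ortho$origin[1]) / ortho$gsd) + 1)
}

# world rectangle covered by the raster: (xmin, xmax, ymin, ymax)
ortho_extent <- function(ortho) {
  d <- ortho_dim(ortho)
  c(ortho$origin[1], ortho$origin[1] + d[2] * ortho$gsd,
    ortho$origin[2] - d[1] * ortho$gsd, ortho$origin[2])
}

#' @export
print.orthomosaic <- function(x, ...) {
  d <- ortho_dim(x)
  nb <- if (is.matrix(x$pixels)) 1L else dim(x$pixels)[3]
  cat(sprintf("orthomosaic '%s': %d x %d px, %d band(s), gsd %.3f m/px\n",
              x$island_id, d[1], d[2], nb, x$gsd))
  ext <- ortho_extent(x)
  cat(sprintf("  extent: x [%.1f, %.1f] m, y [%.1f, %.1f] m\n",
              ext[1], ext[2], ext[3], ext[4]))
  invisible(x)
}

#' @export
plot.orthomosaic <- function(x, ...) {
  m <- ortho_band(x)
  image(t(m)[, nrow(m):1], col = gray.colors(128), asp = nrow(m) / ncol(m),
        axes = FALSE, main = x$island_id, ...)
  invisible(x)
}

#' Write / read an orthomosaic as TIFF with a world-file sidecar
#'
#' The raster is stored as a 32-bit TIFF with pixel values rescaled to the
#' unit interval; the affine georeferencing (gsd and origin) travels in an
#' ESRI world file (`.tfw`) next to it — the long-standing sidecar
#' convention for georeferenced imagery — and the value range plus island id
#' in a small JSON sidecar, so reading restores the raster on its original
#' scale.
#'
#' @param ortho an [orthomosaic()].
#' @param path output path ending in `.tif`.
#' @return `write_orthomosaic` returns `path` invisibly; `read_orthomosaic`
#'   returns an [orthomosaic()].
#' @export
write_orthomosaic <- function(ortho, path) {
  px <- ortho$pixels
  lo <- min(px)
  hi <- max(px)
  scaled <- if (hi > lo) (px - lo) / (hi - lo) else px * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  # world file: x-scale, rot, rot, y-scale (negative), centre of pixel (1,1)
  ctr <- pixel_to_world(ortho, 1, 1)
  writeLines(format(c(ortho$gsd, 0, 0, -ortho$gsd, ctr[1], ctr[2]),
                    digits = 15), tfw)
  jsonlite::write_json(
    list(island_id = ortho$island_id, value_min = lo, value_max = hi),
    sub("\\.tiff?$", ".meta.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orthomosaic
#' @param island_id identifier to attach on read (overrides the sidecar).
#' @export
read_orthomosaic <- function(path, island_id = NULL) {
  px <- tiff::readTIFF(path)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  if (!file.exists(tfw)) stop("world file not found: ", tfw)
  w <- as.numeric(readLines(tfw))
  gsd <- w[1]
  origin <- c(w[5] - gsd / 2, w[6] + gsd / 2)
  meta_path <- sub("\\.tiff?$", ".meta.json", path)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(island_id = "island", value_min = 0, value_max = 1)
  px <- px * (meta$value_max - meta$value_min) + meta$value_min
  orthomosaic(px, gsd = gsd, origin = origin,
              island_id = island_id %||% meta$island_id)
}
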