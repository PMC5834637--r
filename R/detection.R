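#' Set of candidate nest detections
#'
#' The currency passed between the detector, the spatial filter and the
#' calibration stage: georeferenced points in world metres with a detector
#' score in \[0, 1\].
#'
#' @param x,y numeric world coordinates (metres).
#' @param score numeric detector scores in \[0, 1\].
#' @param raster_id identifier of the source raster.
#' @param settings list recording the detector settings that produced the set.
#' @return A `detection_set`: a data.frame with columns `x`, `y`, `score`
#'   and attributes `raster_id` and `settings`.
#' @export
detection_set <- function(x = numeric(0), y = numeric(0),
                          score = numeric(0), raster_id = "raster",
                          settings = list()) {
  if (length(score) == 0 && length(x) > 0) score <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(score) == length(x))
  if (length(score) && (any(score < 0) || any(score > 1 + 1e-9)))
    stop("scores must lie in [0, 1]")
  structure(
    data.frame(x = as.numeric(x), y = as.numeric(y),
               score = pmin(as.numeric(score), 1)),
    raster_id = as.character(raster_id), settings = settings,
    class = c("detection_set", "data.frame"))
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("detection_set: %d points from raster '%s'\n",
              nrow(x), attr(x, "raster_id")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Split a raster into tiles
#'
#' Full-island detection is run tile-by-tile (default 512 x 512 pixels, the
#' standard sub-image size for patch-based detectors). Tiles partition the
#' raster exactly: edge tiles keep their native, smaller size so that pixel
#' content is conserved.
#'
#' @param ortho an [orthomosaic()].
#' @param tile_size tile edge in pixels (>= 32).
#' @return List of `tile` objects, each with `pixels`, `offset` (0-based
#'   row/col of the tile within the parent), `parent_id`, `gsd` and the
#'   parent `origin`.
#' @export
#' @examples
#' o <- orthomosaic(matrix(0, 1024, 1024), gsd = 0.05, origin = c(0, 51.2))
#' length(tile_raster(o, 512))  # 4
tile_raster <- function(ortho, tile_size = 512) {
  stopifnot(inherits(ortho, "orthomosaic"))
  if (tile_size < 32) stop("tile_size must be >= 32")
  d <- ortho_dim(ortho)
  if (any(d == 0)) stop("cannot tile an empty raster")
  band <- ortho_band(ortho)
  r0 <- seq(0, d[1] - 1, by = tile_size)
  c0 <- seq(0, d[2] - 1, by = tile_size)
  tiles <- list()
  for (r in r0) for (cc in c0) {
    rows <- (r + 1):min(r + tile_size, d[1])
    cols <- (cc + 1):min(cc + tile_size, d[2])
    tiles[[length(tiles) + 1]] <- structure(
      list(pixels = band[rows, cols, drop = FALSE],
           offset = c(row = r, col = cc),
           parent_id = ortho$island_id, gsd = ortho$gsd,
           origin = ortho$origin),
      class = "tile")
  }
  tiles
}

# difference-of-Gaussians response and local maxima on a plain matrix;
# origin/gsd give the world frame of this matrix's top-left corner.
dog_detect <- function(m, gsd, origin, threshold, blob_scale,
                       raster_id, settings) {
  s1 <- blob_scale / gsd
  if (s1 < 1)
    stop("blob_scale is below one pixel at this gsd")
  g1 <- as.matrix(EBImage::gblur(m, sigma = s1, boundary = "replicate"))
  g2 <- as.matrix(EBImage::gblur(m, sigma = 1.6 * s1, boundary = "replicate"))
  resp <- g1 - g2

  nr <- nrow(resp); nc <- ncol(resp)
  # 8-neighbour local maxima; out-of-raster neighbours count as -Inf
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- resp
  is_max <- resp >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    # ties broken towards the earlier pixel in raster order
    if (dr > 0 || (dr == 0 && dc > 0)) is_max <- is_max & (resp >= nb)
    else is_max <- is_max & (resp > nb)
  }
  idx <- which(is_max)
  if (length(idx) == 0)
    return(detection_set(raster_id = raster_id, settings = settings))
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  sc <- resp[idx] / max(resp)
  detection_set(x = origin[1] + (cols - 0.5) * gsd,
                y = origin[2] - (rows - 0.5) * gsd,
                score = sc, raster_id = raster_id, settings = settings)
}

#' Detect candidate nests with a difference-of-Gaussians blob detector
#'
#' The detection stage contract is: points in world metres with a score,
#' tuned for high recall, tolerating spatially unstructured false positives
#' that the downstream nearest-neighbour filter removes. The operator is a
#' classical scale-matched difference-of-Gaussians response with 8-neighbour
#' local maxima above an absolute response threshold; scores are the
#' response normalised by the strongest response in the analysed raster.
#'
#' @param x an [orthomosaic()] or a `tile` from [tile_raster()].
#' @param threshold absolute response cutoff; raising it never increases the
#'   number of detections.
#' @param blob_scale expected blob (nest) Gaussian scale in metres; must be
#'   at least one pixel at the raster's gsd.
#' @return A [detection_set()] in world coordinates.
#' @export
detect_candidates <- function(x, threshold = 0.08, blob_scale = 0.12) {
  settings <- list(threshold = threshold, blob_scale = blob_scale,
                   detector = "difference-of-gaussians")
  if (inherits(x, "orthomosaic")) {
    dog_detect(ortho_band(x), x$gsd, x$origin, threshold, blob_scale,
               x$island_id, settings)
  } else if (inherits(x, "tile")) {
    tile_origin <- c(x$origin[1] + x$offset["col"] * x$gsd,
                     x$origin[2] - x$offset["row"] * x$gsd)
    dog_detect(x$pixels, x$gsd, tile_origin, threshold, blob_scale,
               x$parent_id, settings)
  } else stop("x must be an orthomosaic or a tile")
}

#' Merge per-tile detections, collapsing tile-seam duplicates
#'
#' Points closer than `merge_radius` (across tile seams or otherwise) are
#' merged to their score-weighted centroid; the merged score is the maximum
#' of the member scores. Merging is iterated to a fixed point, so the result
#' has no pair of points closer than `merge_radius` and a second application
#' changes nothing.
#'
#' @param sets a list of [detection_set()] objects sharing a parent raster,
#'   or a single `detection_set`.
#' @param merge_radius metres; default 0.35, the expected nest radius.
#' @return A single merged [detection_set()].
#' @export
merge_tile_detections <- function(sets, merge_radius = 0.35) {
  if (inherits(sets, "detection_set")) sets <- list(sets)
  ids <- unique(vapply(sets, attr, "", "raster_id"))
  if (length(ids) > 1)
    stop("cannot merge detections from different rasters: ",
         paste(ids, collapse = ", "))
  df <- do.call(rbind, lapply(sets, as.data.frame))
  settings <- attr(sets[[1]], "settings")
  if (is.null(df) || nrow(df) <= 1)
    return(detection_set(df$x, df$y, df$score, raster_id = ids %||% "raster",
                         settings = settings))
  repeat {
    if (nrow(df) <= 1) break
    d <- dist(df[, c("x", "y")])
    if (min(d) >= merge_radius) break
    # cut exactly at merge_radius: any pair that blocked the break above is
    # then guaranteed to merge, so the point count strictly decreases and
    # the loop terminates
    cl <- cutree(hclust(d, method = "single"), h = merge_radius)
    w <- df$score
    df <- data.frame(
      x = as.numeric(tapply(df$x * w, cl, sum) / tapply(w, cl, sum)),
      y = as.numeric(tapply(df$y * w, cl, sum) / tapply(w, cl, sum)),
      score = as.numeric(tapply(df$score, cl, max)))
  }
  detection_set(df$x, df$y, df$score, raster_id = ids, settings = settings)
}

#' Tile, detect and merge over a whole orthomosaic
#'
#' Convenience wrapper for full-island detection: tiles the raster, runs
#' [detect_candidates()] on each tile extended by a `halo` of context pixels
#' from its neighbours (so blobs straddling a seam are seen whole), keeps
#' each maximum only in the tile that owns its pixel, and merges the
#' per-tile sets. With the default halo this reproduces full-raster
#' detection exactly.
#'
#' @param ortho an [orthomosaic()].
#' @param tile_size tile edge in pixels.
#' @param halo context pixels borrowed from neighbouring tiles.
#' @inheritParams detect_candidates
#' @param merge_radius seam-duplicate merge radius in metres.
#' @return A [detection_set()].
#' @export
detect_island <- function(ortho, tile_size = 512, halo = 16,
                          threshold = 0.08, blob_scale = 0.12,
                          merge_radius = 0.35) {
  stopifnot(inherits(ortho, "orthomosaic"))
  d <- ortho_dim(ortho)
  band <- ortho_band(ortho)
  r0 <- seq(0, d[1] - 1, by = tile_size)
  c0 <- seq(0, d[2] - 1, by = tile_size)
  settings <- list(threshold = threshold, blob_scale = blob_scale,
                   tile_size = tile_size, halo = halo,
                   detector = "difference-of-gaussians")
  sets <- list()
  for (r in r0) for (cc in c0) {
    core_rows <- c(r + 1, min(r + tile_size, d[1]))
    core_cols <- c(cc + 1, min(cc + tile_size, d[2]))
    rows <- max(1, core_rows[1] - halo):min(d[1], core_rows[2] + halo)
    cols <- max(1, core_cols[1] - halo):min(d[2], core_cols[2] + halo)
    win_origin <- c(ortho$origin[1] + (cols[1] - 1) * ortho$gsd,
                    ortho$origin[2] - (rows[1] - 1) * ortho$gsd)
    det <- dog_detect(band[rows, cols, drop = FALSE], ortho$gsd, win_origin,
                      threshold, blob_scale, ortho$island_id, settings)
    if (nrow(det) > 0) {
      pix <- world_to_pixel(ortho, det$x, det$y)
      keep <- pix[, "row"] >= core_rows[1] & pix[, "row"] <= core_rows[2] &
        pix[, "col"] >= core_cols[1] & pix[, "col"] <= core_cols[2]
      det <- detection_set(det$x[keep], det$y[keep], det$score[keep],
                           raster_id = ortho$island_id, settings = settings)
    }
    sets[[length(sets) + 1]] <- det
  }
  merge_tile_detections(sets, merge_radius = merge_radius)
}
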