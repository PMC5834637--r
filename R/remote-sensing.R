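# Cross-sensor calibration and guano-area change comparison.
#
# Colony (guano) area is mapped from multispectral satellite scenes taken by
# different sensors across decades. Scenes are made comparable by removing
# per-band mean differences relative to a reference sensor, classified into
# guano / non-guano, reduced to a common 30 m grid, and compared across
# epochs.

#' Multispectral scene
#'
#' @param bands named list of equally sized numeric matrices (reflectance).
#' @param sensor_id sensor identifier (e.g. `"Landsat-7"`).
#' @param cell_size ground cell size in metres (default 30).
#' @return An `ms_scene` object.
#' @export
ms_scene <- function(bands, sensor_id = "sensor", cell_size = 30) {
  if (is.null(names(bands)) || any(names(bands) == ""))
    stop("bands must be a named list")
  dims <- lapply(bands, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all bands must share the same shape")
  if (!all(vapply(bands, function(b) all(is.finite(b)), TRUE)))
    stop("reflectance values must be finite")
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(bands = bands, sensor_id = as.character(sensor_id),
                 cell_size = cell_size),
            class = "ms_scene")
}

#' @export
print.ms_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("ms_scene '%s': %d x %d cells (%g m), bands: %s\n",
              x$sensor_id, d[1], d[2], x$cell_size,
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Boolean guano raster
#'
#' @param cells logical matrix; `TRUE` cells are guano.
#' @param cell_size cell size in metres (> 0).
#' @param epoch epoch label (e.g. `"1957"`).
#' @return A `guano_mask` object.
#' @export
guano_mask <- function(cells, cell_size = 30, epoch = NA_character_) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "logical"
  dimnames(cells) <- NULL
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(cells = cells, cell_size = cell_size,
                 epoch = as.character(epoch)),
            class = "guano_mask")
}

#' Guano area of a mask, in square metres
#' @param mask a [guano_mask()].
#' @return Numeric area (m^2).
#' @export
guano_area <- function(mask) sum(mask$cells) * mask$cell_size^2

#' Estimate per-band cross-sensor offsets
#'
#' For every shared band, the offset is the mean difference
#' `scene - reference` over the comparable pixels — the statistic used to
#' cross-calibrate scenes from different sensors before classification.
#'
#' @param scene,reference [ms_scene()] objects on identical band names.
#' @param mask optional logical matrix of comparable pixels (default: all).
#' @return A `sensor_offsets` object: named per-band offsets plus the
#'   reference sensor id.
#' @export
estimate_offsets <- function(scene, reference, mask = NULL) {
  bands <- names(scene$bands)
  if (!identical(sort(bands), sort(names(reference$bands))))
    stop("band names of scene and reference do not match")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(scene$bands[[1]]),
                                    ncol(scene$bands[[1]]))
  if (!any(mask)) stop("empty comparable-pixel mask")
  off <- vapply(bands, function(b)
    mean(scene$bands[[b]][mask] - reference$bands[[b]][mask]), 0)
  structure(list(reference = reference$sensor_id,
                 offsets = setNames(off, bands)),
            class = "sensor_offsets")
}

#' @export
print.sensor_offsets <- function(x, ...) {
  cat(sprintf("sensor_offsets relative to '%s':\n", x$reference))
  print(round(x$offsets, 5))
  invisible(x)
}

#' Apply cross-calibration offsets to a scene
#'
#' Each band is shifted by minus its estimated offset, so re-estimating the
#' offsets against the same reference afterwards gives values at (noiseless
#' case: exactly) zero.
#'
#' @param scene an [ms_scene()].
#' @param offsets a [estimate_offsets()] result.
#' @return The adjusted [ms_scene()].
#' @export
apply_offsets <- function(scene, offsets) {
  bands <- names(scene$bands)
  if (!identical(sort(bands), sort(names(offsets$offsets))))
    stop("offset band names do not match the scene")
  adj <- lapply(bands, function(b) scene$bands[[b]] - offsets$offsets[[b]])
  names(adj) <- bands
  ms_scene(adj, sensor_id = scene$sensor_id, cell_size = scene$cell_size)
}

#' Classify guano pixels in a multispectral scene
#'
#' The guano retrieval algorithm is a pluggable slot. The default is a
#' two-class minimum-distance discriminant on the reflectance vectors:
#' a pixel is guano iff its band vector is closer (Euclidean) to the guano
#' class mean than to the non-guano mean — linear discriminant analysis with
#' equal priors and isotropic covariance. Supply `classifier` to plug in a
#' different algorithm.
#'
#' @param scene an [ms_scene()].
#' @param classifier optional `function(scene, params)` returning a logical
#'   matrix; overrides the default.
#' @param params for the default classifier, a list with `spectra` (as in
#'   [generate_scene_pair()]) and optional `epoch`.
#' @return A [guano_mask()] at the scene's cell size.
#' @export
classify_guano <- function(scene, classifier = NULL, params = list()) {
  if (!is.null(classifier)) {
    cells <- classifier(scene, params)
  } else {
    spectra <- params$spectra
    if (is.null(spectra))
      stop("untrained classifier: supply params$spectra (guano / nonguano ",
           "band means) or a classifier function")
    bands <- names(scene$bands)
    if (!all(bands %in% names(spectra$guano)))
      stop("classifier spectra not configured for this scene's band set")
    d_g <- d_n <- 0
    for (b in bands) {
      d_g <- d_g + (scene$bands[[b]] - spectra$guano[[b]])^2
      d_n <- d_n + (scene$bands[[b]] - spectra$nonguano[[b]])^2
    }
    cells <- d_g < d_n
  }
  guano_mask(cells, cell_size = scene$cell_size,
             epoch = params$epoch %||% NA_character_)
}

#' Reduce fine-scale classifications to a coarse grid
#'
#' Historical manual classifications (polygons) and fine-resolution masks
#' are reduced to the Landsat grid (30 m cells by default) so areas can be
#' compared across sources: a coarse cell is guano iff the covered fraction
#' meets `threshold` (default 0.5, majority coverage, which nearly conserves
#' area). For a mask input the coarse cell size must be an integer multiple
#' of the fine cell size; applying the reduction to a mask already on the
#' target grid is the identity.
#'
#' @param x a [guano_mask()] at finer resolution, or a polygon: a two-column
#'   matrix / data.frame of (x, y) vertices in metres.
#' @param cell_size target cell size in metres (default 30).
#' @param threshold minimum covered fraction for a cell to be guano.
#' @param epoch epoch label for the result.
#' @param subsamples per-side supersampling density for polygon coverage
#'   (each cell is probed at `subsamples^2` points).
#' @return A [guano_mask()] at `cell_size`.
#' @export
reduce_to_grid <- function(x, cell_size = 30, threshold = 0.5,
                           epoch = NA_character_, subsamples = 8) {
  if (inherits(x, "guano_mask")) {
    f <- cell_size / x$cell_size
    if (abs(f - round(f)) > 1e-9 || f < 1)
      stop("target cell_size must be an integer multiple of the mask's")
    f <- as.integer(round(f))
    m <- x$cells
    nr <- ceiling(nrow(m) / f) * f
    nc <- ceiling(ncol(m) / f) * f
    pad <- matrix(FALSE, nr, nc)
    pad[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    # block means via row/col group sums
    rg <- rep(seq_len(nr / f), each = f)
    cg <- rep(seq_len(nc / f), each = f)
    frac <- rowsum(t(rowsum(pad + 0, rg)), cg) / f^2
    cells <- t(frac) >= threshold
    return(guano_mask(cells, cell_size = cell_size, epoch = epoch))
  }
  poly <- as.matrix(as.data.frame(x))
  if (ncol(poly) < 2 || !all(is.finite(poly)))
    stop("polygon must be a finite two-column matrix of vertices")
  poly <- poly[, 1:2, drop = FALSE]
  # grid snapped outward to cell_size multiples around the polygon
  x0 <- floor(min(poly[, 1]) / cell_size) * cell_size
  y0 <- floor(min(poly[, 2]) / cell_size) * cell_size
  nx <- ceiling((max(poly[, 1]) - x0) / cell_size)
  ny <- ceiling((max(poly[, 2]) - y0) / cell_size)
  sub <- (seq_len(subsamples) - 0.5) / subsamples
  cells <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    px <- x0 + (j - 1 + rep(sub, each = subsamples)) * cell_size
    py <- y0 + (ny - i + rep(sub, times = subsamples)) * cell_size
    inside <- mgcv::in.out(poly, cbind(px, py))
    cells[i, j] <- mean(inside) >= threshold
  }
  guano_mask(cells, cell_size = cell_size, epoch = epoch)
}

#' Compare guano area across epochs
#'
#' @param masks list of [guano_mask()] objects on a common grid (same shape
#'   and cell size), ordered by epoch.
#' @return An `epoch_comparison`: list with `areas` (per-epoch data.frame:
#'   `epoch`, `cells`, `area_m2`) and `changes` (consecutive-pair
#'   data.frame: `from`, `to`, `ratio`, `gained`, `lost`, `stable` in
#'   cells).
#' @export
compare_epochs <- function(masks) {
  if (length(masks) < 1) stop("at least one mask is required")
  dims <- vapply(masks, function(m) paste(dim(m$cells), collapse = "x"), "")
  cs <- vapply(masks, function(m) m$cell_size, 0)
  if (length(unique(dims)) != 1 || length(unique(cs)) != 1)
    stop("masks are not on a common grid")
  eps <- vapply(seq_along(masks), function(i) {
    e <- masks[[i]]$epoch
    if (is.na(e)) paste0("epoch", i) else e
  }, "")
  areas <- data.frame(
    epoch = eps,
    cells = vapply(masks, function(m) sum(m$cells), 0L),
    area_m2 = vapply(masks, guano_area, 0))
  changes <- NULL
  if (length(masks) > 1) {
    changes <- do.call(rbind, lapply(seq_len(length(masks) - 1), function(i) {
      a <- masks[[i]]$cells; b <- masks[[i + 1]]$cells
      data.frame(from = eps[i], to = eps[i + 1],
                 ratio = if (sum(a) > 0) sum(b) / sum(a) else NA_real_,
                 gained = sum(b & !a), lost = sum(a & !b),
                 stable = sum(a & b))
    }))
  }
  structure(list(areas = areas, changes = changes),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat("guano area by epoch:\n")
  print(x$areas)
  if (!is.null(x$changes)) {
    cat("changes between consecutive epochs:\n")
    print(x$changes)
  }
  invisible(x)
}
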