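# CSV / GeoJSON / JSON serialisation of the pipeline's intermediate
# artifacts, so every stage can be audited and re-run from files.

#' Write / read detections as CSV
#'
#' Columns `x_m`, `y_m`, `score`.
#'
#' @param detections a [detection_set()].
#' @param path CSV path.
#' @return `path` invisibly / a [detection_set()].
#' @export
write_detections_csv <- function(detections, path) {
  df <- as.data.frame(detections)
  write.csv(data.frame(x_m = df$x, y_m = df$y, score = df$score),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @param raster_id raster identifier to attach on read.
#' @export
read_detections_csv <- function(path, raster_id = "raster") {
  df <- read.csv(path)
  detection_set(df$x_m, df$y_m, df$score, raster_id = raster_id)
}

#' Write detections as GeoJSON points
#'
#' @inheritParams write_detections_csv
#' @export
write_detections_geojson <- function(detections, path) {
  df <- as.data.frame(detections)
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = list(score = df$score[i]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a colony layout (with optional artifact truth) as CSV
#'
#' Columns `island_id`, `subcolony_id`, `x_m`, `y_m`, `class`
#' (`nest` / `artifact`).
#'
#' @param layout a [generate_colony_layout()] result.
#' @param path CSV path.
#' @param artifacts optional data.frame of artifact truth points (`x`, `y`).
#' @export
write_layout_csv <- function(layout, path, artifacts = NULL) {
  df <- data.frame(island_id = layout$island_id,
                   subcolony_id = layout$nests$subcolony,
                   x_m = layout$nests$x, y_m = layout$nests$y,
                   class = "nest")
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    df <- rbind(df, data.frame(island_id = layout$island_id,
                               subcolony_id = NA_integer_,
                               x_m = artifacts$x, y_m = artifacts$y,
                               class = "artifact"))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a filter rule as JSON
#'
#' @param rule a [filter_rule()].
#' @param path JSON path.
#' @export
write_filter_rule <- function(rule, path) {
  jsonlite::write_json(unclass(rule), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_rule
#' @export
read_filter_rule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_rule(x$r, x$m, x$method)
}
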