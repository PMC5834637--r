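# Pipeline orchestration: one declarative config, one master seed fanned out
# to per-stage substreams, every intermediate artifact written to disk.

#' Default pipeline configuration
#'
#' Returns the full parameter set for a simulated-archipelago run. The
#' simulation defaults describe a realistic Adelie colony: nests at least
#' 0.7 m apart, clustered in sub-colonies of ~150 nests with a 3 m
#' dispersion scale; orthomosaics at 5 cm/px; artifacts (rock/shadow false
#' positives) as a uniform Poisson field rendered identically to nests;
#' single-count observer error of 3% relative sd.
#'
#' @return Nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    species = "adeliae",
    output_dir = "pengcensus-run",
    fixture_counts = NULL,
    islands = list(n = 3, extent = c(0, 200, 0, 200), n_subcolonies = 4,
                   nests_per_subcolony = 150, cluster_radius = 3,
                   hardcore = 0.7),
    render = list(gsd = 0.05, artifact_intensity = 0.003, blob_sigma = 0.12,
                  blob_amplitude = 1, noise_sd = 0.02),
    detection = list(tile_size = 512, halo = 16, threshold = 0.08,
                     blob_scale = 0.12, merge_radius = 0.35),
    filter = list(method = "mixture", k = 2, m = 2),
    calibration = list(n_plots = 16, plot_size = 20, observer_cv = 0.01,
                       observer_bias = 1),
    census = list(interpretation = "normal95", n_reps = 1e5),
    landsat = list(
      enabled = FALSE, scene_size = 64, cell_size = 30, noise_sd = 0.01,
      spectra = list(guano = c(green = 0.28, red = 0.32, nir = 0.35),
                     nonguano = c(green = 0.12, red = 0.14, nir = 0.18)),
      offsets = c(green = 0.02, red = -0.015, nir = 0.03)))
}

read_config <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    # yaml delivers vectors as lists; flatten the numeric blocks we own
    cfg$islands$extent <- as.numeric(unlist(cfg$islands$extent))
    if (!is.null(cfg$landsat$spectra)) {
      cfg$landsat$spectra <- lapply(cfg$landsat$spectra,
                                    function(s) unlist(s))
      cfg$landsat$offsets <- unlist(cfg$landsat$offsets)
    }
    cfg
  } else config
}

chk <- function(report, field, ok, problem) {
  if (!isTRUE(ok)) rbind(report, data.frame(field = field, problem = problem))
  else report
}

#' Validate a pipeline configuration
#'
#' Checks the stage parameter blocks against each module's contract (unknown
#' keys, out-of-range values, missing blocks) without running anything.
#'
#' @param config a config list as from [default_config()], or the path of a
#'   YAML config file.
#' @return A `config_report` data.frame (`field`, `problem`), zero rows if
#'   valid; attribute `valid` carries the verdict.
#' @export
#' @examples
#' validate_config(default_config())  # valid, empty report
validate_config <- function(config) {
  config <- read_config(config)
  rep <- data.frame(field = character(0), problem = character(0))
  known <- c("seed", "species", "output_dir", "fixture_counts", "islands",
             "render", "detection", "filter", "calibration", "census",
             "landsat")
  for (k in setdiff(names(config), known))
    rep <- chk(rep, k, FALSE, "unknown config key")
  for (k in c("islands", "render", "detection", "filter", "calibration",
              "census"))
    rep <- chk(rep, k, !is.null(config[[k]]), "missing stage block")
  if (!is.null(config$islands)) {
    i <- config$islands
    rep <- chk(rep, "islands$n", (i$n %||% 0) >= 0, "must be >= 0")
    rep <- chk(rep, "islands$extent",
               length(i$extent %||% numeric(0)) == 4 &&
                 i$extent[2] > i$extent[1] && i$extent[4] > i$extent[3],
               "must be (xmin, xmax, ymin, ymax) with positive spans")
    rep <- chk(rep, "islands$hardcore", (i$hardcore %||% 1) > 0,
               "must be > 0")
    rep <- chk(rep, "islands$hardcore",
               (i$hardcore %||% 0) < (i$cluster_radius %||% Inf),
               "must be smaller than cluster_radius")
  }
  if (!is.null(config$render)) {
    r <- config$render
    rep <- chk(rep, "render$gsd", (r$gsd %||% 1) > 0, "must be > 0")
    rep <- chk(rep, "render$artifact_intensity",
               (r$artifact_intensity %||% 0) >= 0, "must be >= 0")
    rep <- chk(rep, "render$noise_sd", (r$noise_sd %||% 0) >= 0,
               "must be >= 0")
  }
  if (!is.null(config$detection)) {
    d <- config$detection
    rep <- chk(rep, "detection$tile_size", (d$tile_size %||% 512) >= 32,
               "below minimum 32")
    rep <- chk(rep, "detection$threshold", (d$threshold %||% 0.08) > 0,
               "must be > 0")
    rep <- chk(rep, "detection$merge_radius", (d$merge_radius %||% 0.35) > 0,
               "must be > 0")
  }
  if (!is.null(config$filter)) {
    f <- config$filter
    rep <- chk(rep, "filter$method",
               (f$method %||% "quantile") %in%
                 c("quantile", "mixture", "fixed", "none"),
               "unknown method")
    rep <- chk(rep, "filter$m", (f$m %||% 2) >= 1, "must be >= 1")
  }
  if (!is.null(config$calibration)) {
    cb <- config$calibration
    rep <- chk(rep, "calibration$n_plots", (cb$n_plots %||% 12) >= 2,
               "must be >= 2")
    rep <- chk(rep, "calibration$observer_cv", (cb$observer_cv %||% 0) >= 0,
               "negative cv")
  }
  if (!is.null(config$census)) {
    cs <- config$census
    rep <- chk(rep, "census$interpretation",
               (cs$interpretation %||% "normal95") %in%
                 c("normal95", "uniform"), "unknown interpretation")
    rep <- chk(rep, "census$n_reps", (cs$n_reps %||% 1e5) >= 1000,
               "must be >= 1000")
  }
  if (isTRUE(config$landsat$enabled)) {
    ls <- config$landsat
    rep <- chk(rep, "landsat$noise_sd", (ls$noise_sd %||% 0) >= 0,
               "must be >= 0")
    rep <- chk(rep, "landsat$offsets",
               identical(sort(names(ls$offsets)),
                         sort(names(ls$spectra$guano))),
               "offset band names do not match the spectra")
  }
  structure(rep, valid = nrow(rep) == 0, class = c("config_report",
                                                   "data.frame"))
}

#' @export
print.config_report <- function(x, ...) {
  if (nrow(x) == 0) cat("config valid\n")
  else {
    cat("config problems:\n")
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Survey one island end to end: detect, filter, calibrate, estimate
#'
#' Runs the automated-count chain on a rendered island: tiled
#' difference-of-Gaussians detection, nearest-neighbour false-positive
#' filtering, and per-site linear calibration against manually counted
#' validation plots. Validation plots are square cells of the island grid
#' chosen to span the range of local detection density; their "manual"
#' counts come from the observer model applied to the true nests in each
#' plot.
#'
#' @param layout the island's [generate_colony_layout()].
#' @param rendered the island's [render_orthomosaic()] output.
#' @param config a [default_config()]-style list (detection, filter and
#'   calibration blocks are used).
#' @param seed integer seed for the observer draws.
#' @return List: `estimate`, `rel_uncertainty`, `true_n`, `n_detected`,
#'   `n_retained`, `calibration` (a [fit_calibration()]), `rule`,
#'   `detections`, `retained`, `rejected`, `plots` (data.frame).
#' @export
survey_island <- function(layout, rendered, config = default_config(),
                          seed = NULL) {
  dcfg <- config$detection
  det <- detect_island(rendered$ortho,
                       tile_size = dcfg$tile_size %||% 512,
                       halo = dcfg$halo %||% 16,
                       threshold = dcfg$threshold %||% 0.08,
                       blob_scale = dcfg$blob_scale %||% 0.12,
                       merge_radius = dcfg$merge_radius %||% 0.35)
  fcfg <- config$filter
  method <- fcfg$method %||% "quantile"
  if (method == "none") {
    rule <- NULL
    retained <- det
    rejected <- detection_set(raster_id = attr(det, "raster_id"))
  } else {
    rule <- fit_filter_rule(det, method = method,
                            params = fcfg[setdiff(names(fcfg), "method")])
    flt <- apply_filter(det, rule)
    retained <- flt$retained
    rejected <- flt$rejected
  }

  # validation plots: grid cells spanning the local density range
  ccfg <- config$calibration
  plot_size <- ccfg$plot_size %||% 10
  n_plots <- ccfg$n_plots %||% 12
  ext <- layout$extent
  gx <- seq(ext[1], ext[2], by = plot_size)
  gy <- seq(ext[3], ext[4], by = plot_size)
  cell_of <- function(x, y) {
    ix <- pmin(findInterval(x, gx, rightmost.closed = TRUE),
               length(gx) - 1)
    iy <- pmin(findInterval(y, gy, rightmost.closed = TRUE),
               length(gy) - 1)
    ix + (iy - 1) * (length(gx) - 1)
  }
  det_cells <- cell_of(retained$x, retained$y)
  true_cells <- cell_of(layout$nests$x, layout$nests$y)
  occupied <- sort(unique(det_cells))
  det_per_cell <- vapply(occupied, function(cl) sum(det_cells == cl), 0L)
  n_plots <- min(n_plots, length(occupied))
  if (n_plots < 2)
    stop("not enough occupied validation plots to fit a calibration")
  pick <- occupied[order(det_per_cell)][
    unique(round(seq(1, length(occupied), length.out = n_plots)))]
  plots <- data.frame(
    cell = pick,
    detected = vapply(pick, function(cl) sum(det_cells == cl), 0L),
    true = vapply(pick, function(cl) sum(true_cells == cl), 0L))
  obs <- observer_model(cv = ccfg$observer_cv %||% 0.03,
                        bias = ccfg$observer_bias %||% 1)
  plots$manual <- simulate_observer_count(plots$true, obs, seed = seed)

  cal <- fit_calibration(plots$detected, plots$manual,
                         site = layout$island_id)
  # the regression is fit at plot scale, so the island estimate aggregates
  # per-cell predictions over every occupied cell (sum of a + b*d_j, floored
  # at 0 per cell); predicting once at the island total would wrongly apply
  # the per-plot intercept a single time
  pred_cells <- pmax(0, cal$intercept + cal$slope * det_per_cell)
  estimate <- as.integer(round(sum(pred_cells)))
  rel <- NA_real_
  if (cal$n > 2 && estimate > 0) {
    # residual prediction noise summed over the occupied cells
    rel <- 1.96 * cal$sigma * sqrt(length(det_per_cell)) / estimate
  }
  list(estimate = estimate, rel_uncertainty = rel,
       true_n = nrow(layout$nests), n_detected = nrow(det),
       n_retained = nrow(retained), calibration = cal, rule = rule,
       detections = det, retained = retained, rejected = rejected,
       plots = plots)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full census pipeline from a configuration
#'
#' Two modes, combinable:
#' \itemize{
#'   \item simulation mode (`islands$n > 0`): simulate, render, detect,
#'     filter and calibrate each island, then aggregate the per-island
#'     automated counts (classified N2) into a census with a Monte Carlo
#'     95% confidence interval and the regional share;
#'   \item fixture mode (`fixture_counts` set to a site-count CSV path or
#'     `"packaged"` for the shipped archipelago table): aggregate an
#'     existing per-island table directly.
#' }
#' If `landsat$enabled`, the remote-sensing track also runs: a synthetic
#' scene pair is generated, cross-calibrated by per-band mean differences,
#' classified, and compared across epochs.
#'
#' All stage outputs are written under `output_dir`; the returned manifest
#' records the config hash, file paths and per-stage wall-clock. Re-running
#' with an identical config and seed reproduces the census summary
#' byte-for-byte.
#'
#' @param config config list or YAML path (see [default_config()],
#'   [validate_config()]).
#' @param output_dir overrides `config$output_dir`.
#' @return A `run_manifest` list: `config_hash`, `files`, `timings_s`,
#'   `census` (the summary list), `islands` (per-island data.frame, if
#'   simulated), `versions`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  config <- read_config(config)
  report <- validate_config(config)
  if (!attr(report, "valid")) {
    print(report)
    stop("invalid configuration")
  }
  out <- output_dir %||% config$output_dir %||% "pengcensus-run"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1)
  species <- config$species %||% "adeliae"
  files <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }

  sites <- NULL
  island_rows <- NULL
  if (!is.null(config$fixture_counts)) {
    path <- config$fixture_counts
    if (identical(path, "packaged"))
      path <- system.file("extdata", "danger_islands_census.csv",
                          package = "pengcensus", mustWork = TRUE)
    sites <- stage("fixture", read_site_counts(path))
  }

  n_islands <- config$islands$n %||% 0
  if (n_islands > 0) {
    icfg <- config$islands
    rcfg <- config$render
    rows <- list()
    for (i in seq_len(n_islands)) {
      id <- sprintf("sim%02d", i)
      lay <- stage(paste0(id, "/layout"), generate_colony_layout(
        icfg$extent, icfg$n_subcolonies, icfg$nests_per_subcolony,
        icfg$cluster_radius, icfg$hardcore,
        seed = substream_seed(seed, paste0(id, "/layout")), island_id = id))
      rnd <- stage(paste0(id, "/render"), render_orthomosaic(
        lay, gsd = rcfg$gsd, artifact_intensity = rcfg$artifact_intensity,
        blob_params = list(sigma = rcfg$blob_sigma,
                           amplitude = rcfg$blob_amplitude),
        noise_sd = rcfg$noise_sd,
        seed = substream_seed(seed, paste0(id, "/render"))))
      svy <- stage(paste0(id, "/survey"), survey_island(
        lay, rnd, config, seed = substream_seed(seed, paste0(id, "/survey"))))

      files[[paste0(id, "_layout")]] <- write_layout_csv(
        lay, file.path(out, paste0(id, "_truth.csv")), rnd$artifacts)
      files[[paste0(id, "_detections")]] <- write_detections_csv(
        svy$detections, file.path(out, paste0(id, "_detections.csv")))
      files[[paste0(id, "_retained")]] <- write_detections_csv(
        svy$retained, file.path(out, paste0(id, "_retained.csv")))
      if (!is.null(svy$rule))
        files[[paste0(id, "_rule")]] <- write_filter_rule(
          svy$rule, file.path(out, paste0(id, "_filter_rule.json")))

      rows[[i]] <- data.frame(
        island = id, species = species, count = svy$estimate,
        precision = "N2", method = "uav", true_n = svy$true_n,
        n_detected = svy$n_detected, n_retained = svy$n_retained,
        rel_uncertainty = svy$rel_uncertainty)
    }
    island_rows <- do.call(rbind, rows)
    sim_sites <- island_rows[, c("island", "species", "count", "precision",
                                 "method")]
    sites <- if (is.null(sites)) sim_sites else rbind(sites, sim_sites)
  }
  if (is.null(sites))
    stop("nothing to do: set islands$n > 0 or fixture_counts")

  census <- stage("census", {
    sel <- sites[sites$species == species, , drop = FALSE]
    total <- sum_census(sites, species)
    est <- propagate_error(sel,
                           interpretation = config$census$interpretation,
                           n_reps = config$census$n_reps,
                           seed = substream_seed(seed, "census"))
    share <- regional_share(total)
    list(species = species, total = total,
         ci_low = est$ci_low, ci_high = est$ci_high, level = est$level,
         interpretation = est$interpretation, n_reps = est$n_reps,
         regional_share_percent = share$percent,
         regional_share_rounded = share$percent_rounded,
         seed = seed)
  })
  files$site_counts <- file.path(out, "site_counts.csv")
  write.csv(sites, files$site_counts, row.names = FALSE)
  files$census_summary <- file.path(out, "census_summary.json")
  jsonlite::write_json(census, files$census_summary, auto_unbox = TRUE,
                       digits = NA)

  landsat <- NULL
  if (isTRUE(config$landsat$enabled)) {
    landsat <- stage("landsat", {
      ls <- config$landsat
      n <- ls$scene_size %||% 64
      ctr <- (n + 1) / 2
      truth <- outer(seq_len(n), seq_len(n), function(i, j)
        (i - ctr)^2 + (j - ctr)^2 <= (n / 4)^2)
      pair <- generate_scene_pair(truth, ls$spectra, ls$offsets,
                                  noise_sd = ls$noise_sd,
                                  cell_size = ls$cell_size %||% 30,
                                  seed = substream_seed(seed, "landsat"))
      off <- estimate_offsets(pair$offset, pair$reference)
      adj <- apply_offsets(pair$offset, off)
      m_ref <- classify_guano(pair$reference,
                              params = list(spectra = ls$spectra,
                                            epoch = "reference"))
      m_adj <- classify_guano(adj,
                              params = list(spectra = ls$spectra,
                                            epoch = "calibrated"))
      cmp <- compare_epochs(list(m_ref, m_adj))
      list(offsets = off, comparison = cmp, truth_cells = sum(truth))
    })
    files$landsat_offsets <- file.path(out, "landsat_offsets.json")
    jsonlite::write_json(as.list(landsat$offsets$offsets),
                         files$landsat_offsets, auto_unbox = TRUE,
                         digits = NA)
    files$landsat_changes <- file.path(out, "landsat_changes.csv")
    write.csv(landsat$comparison$changes, files$landsat_changes,
              row.names = FALSE)
  }

  manifest <- structure(
    list(config_hash = config_hash(config), files = files,
         timings_s = timings, census = census, islands = island_rows,
         landsat = landsat,
         versions = list(pengcensus = as.character(
           utils::packageVersion("pengcensus")),
           r = R.version.string)),
    class = "run_manifest")
  files$manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(
    list(config_hash = manifest$config_hash,
         files = lapply(files, as.character),
         timings_s = timings, versions = manifest$versions),
    files$manifest, auto_unbox = TRUE, digits = NA)
  manifest$files <- files
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run %s\n", x$config_hash))
  cat(sprintf("  census: %s %s nests, %.0f%% CI [%s, %s], share %d%%\n",
              x$census$species, format(x$census$total, big.mark = ","),
              100 * x$census$level,
              format(x$census$ci_low, big.mark = ","),
              format(x$census$ci_high, big.mark = ","),
              x$census$regional_share_rounded))
  if (!is.null(x$islands)) {
    cat("  islands:\n")
    print(x$islands[, c("island", "true_n", "n_detected", "n_retained",
                        "count")])
  }
  invisible(x)
}
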