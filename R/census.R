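# Archipelago-wide aggregation: per-island counts with N-level precision
# classes are summed per species, and the class half-widths are propagated
# to a 95% confidence interval on the total by Monte Carlo.

#' Read a per-island census table
#'
#' Expects the schema of the packaged census fixture: columns `island`,
#' `species`, `count`, `precision` (N1/N2/N4), `method` (ground/photo/uav).
#'
#' @param path CSV path.
#' @return A validated data.frame of site counts.
#' @export
read_site_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("island", "species", "count", "precision", "method")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site-count table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$count < 0)) stop("counts must be >= 0")
  bad <- setdiff(unique(df$precision), names(precision_half_widths))
  if (length(bad))
    stop("unknown precision class(es): ", paste(bad, collapse = ", "))
  df
}

#' The packaged Danger Islands census table
#'
#' Per-island, per-species nest counts with their precision classes and
#' survey methods for the nine-island Danger Islands archipelago census
#' (Adelie, gentoo and chinstrap penguins and imperial shag).
#'
#' @return Data.frame as from [read_site_counts()].
#' @export
#' @examples
#' sum_census(danger_islands_counts(), "adeliae")  # 751527
danger_islands_counts <- function() {
  read_site_counts(system.file("extdata", "danger_islands_census.csv",
                               package = "pengcensus", mustWork = TRUE))
}

#' Sum per-island counts for one species
#'
#' @param sites data.frame from [read_site_counts()].
#' @param species species tag (e.g. `"adeliae"`).
#' @return Integer total of nests.
#' @export
sum_census <- function(sites, species) {
  sel <- sites[sites$species == species, , drop = FALSE]
  if (anyDuplicated(sel$island))
    stop("duplicate island x species records: ",
         paste(sel$island[duplicated(sel$island)], collapse = ", "))
  as.integer(sum(sel$count))
}

#' Propagate per-island precision classes to a census confidence interval
#'
#' Each island's count carries an N-level precision class (N1 <= 5%,
#' N2 +/-10%, N4 +/-50%). How a "+/-X%" label maps to a distribution is not
#' standardised, so two interpretations are offered: `normal95` reads the
#' half-width as the 95% half-width of a normal error (sd = half-width /
#' 1.96, the default) and `uniform` reads it as the half-width of a uniform
#' error. Per replicate, every island's count is drawn independently under
#' its class, truncated at zero, and the replicate totals' empirical 2.5 and
#' 97.5 percentiles give the interval. The point estimate is the
#' deterministic sum, not a Monte Carlo average.
#'
#' @param sites data.frame of one species' site counts (see
#'   [read_site_counts()]).
#' @param interpretation `"normal95"` or `"uniform"`.
#' @param n_reps Monte Carlo replicates (>= 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param half_width_scale multiplier on every class half-width; 1 for the
#'   stated classes, 0 for a degenerate sensitivity mode in which the CI
#'   collapses onto the point sum.
#' @return A `census_estimate`: list with `total`, `ci_low`, `ci_high`,
#'   `level`, `n_reps`, `seed`, `interpretation`.
#' @export
propagate_error <- function(sites, interpretation = c("normal95", "uniform"),
                            n_reps = 1e5, seed = NULL, level = 0.95,
                            half_width_scale = 1) {
  interpretation <- match.arg(interpretation)
  if (n_reps < 1000) stop("n_reps must be >= 1000")
  counts <- sites$count
  hw <- unname(precision_half_widths[sites$precision]) * counts *
    half_width_scale
  total <- as.integer(sum(counts))
  totals <- with_seed(seed, {
    draws <- matrix(0, n_reps, length(counts))
    for (j in seq_along(counts)) {
      draws[, j] <- if (hw[j] == 0) {
        counts[j]
      } else if (interpretation == "normal95") {
        rnorm_trunc0(n_reps, counts[j], hw[j] / 1.96)
      } else {
        pmax(0, runif(n_reps, counts[j] - hw[j], counts[j] + hw[j]))
      }
    }
    rowSums(draws)
  })
  alpha <- (1 - level) / 2
  ci <- as.integer(round(quantile(totals, c(alpha, 1 - alpha),
                                  names = FALSE)))
  structure(list(total = total, ci_low = ci[1], ci_high = ci[2],
                 level = level, n_reps = as.integer(n_reps), seed = seed,
                 interpretation = interpretation),
            class = "census_estimate")
}

#' @export
print.census_estimate <- function(x, ...) {
  cat(sprintf(
    "census_estimate: %s nests (%.0f%% CI [%s, %s]; %s, %d reps)\n",
    format(x$total, big.mark = ","), 100 * x$level,
    format(x$ci_low, big.mark = ","), format(x$ci_high, big.mark = ","),
    x$interpretation, x$n_reps))
  invisible(x)
}

#' Regional abundance baseline: CCAMLR subarea 48.1 excluding the archipelago
#'
#' The published abundance of Adelie penguins in CCAMLR subarea 48.1
#' *excluding* the Danger Islands: 606,526 pairs, 95% CI [322,477; 990,402].
#'
#' @return A `regional_baseline` list with `label`, `pairs` and `ci`.
#' @export
regional_baseline_481 <- function() {
  structure(list(label = "CCAMLR 48.1 excluding Danger Islands",
                 pairs = 606526L, ci = c(322477L, 990402L)),
            class = "regional_baseline")
}

#' Share of the regional population held by the archipelago
#'
#' `100 * total / (total + baseline)` — the percentage of the combined
#' regional abundance contributed by the censused archipelago.
#'
#' @param total archipelago total (nesting pairs, >= 0).
#' @param baseline a [regional_baseline_481()]-style object.
#' @return List with `percent` (exact) and `percent_rounded` (integer
#'   presentation value).
#' @export
#' @examples
#' regional_share(751527)$percent_rounded  # 55
regional_share <- function(total, baseline = regional_baseline_481()) {
  if (total < 0) stop("total must be >= 0")
  p <- if (total == 0) 0 else 100 * total / (total + baseline$pairs)
  list(percent = p, percent_rounded = as.integer(round(p)))
}
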