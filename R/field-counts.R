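# Ground-count protocol: each counting unit is counted three times and the
# three counts must agree within 5% of their mean (the 'N1' precision level
# of standard seabird census practice); units failing the check are
# subdivided and recounted until agreement.

#' Precision classes for seabird census counts
#'
#' The standard accuracy labels: N1 counts are accurate to within 5%, N2 to
#' within 10%, N4 to within 50% of the true value.
#'
#' @format Named numeric vector mapping label to relative half-width.
#' @export
precision_half_widths <- c(N1 = 0.05, N2 = 0.10, N4 = 0.50)

#' Classify a relative error into an N-level precision class
#'
#' Returns the smallest class whose half-width bounds the given relative
#' half-width: <= 0.05 is N1, <= 0.10 is N2, <= 0.50 is N4. Boundaries are
#' inclusive (a count known to +/-10% is an N2 count).
#'
#' @param relative_half_width non-negative relative error (e.g. 0.04).
#' @return Character label `"N1"`, `"N2"` or `"N4"`.
#' @export
#' @examples
#' classify_precision(0.04)  # "N1"
#' classify_precision(0.10)  # "N2"
classify_precision <- function(relative_half_width) {
  if (length(relative_half_width) != 1 || !is.finite(relative_half_width) ||
      relative_half_width < 0)
    stop("relative_half_width must be a single non-negative number")
  if (relative_half_width <= 0.05) return("N1")
  if (relative_half_width <= 0.10) return("N2")
  if (relative_half_width <= 0.50) return("N4")
  stop(sprintf("relative error %.3f is worse than N4 (+/-50%%); not classifiable",
               relative_half_width))
}

#' Do three replicate counts agree within 5% of their mean?
#'
#' The acceptance rule of the ground protocol: every one of the three counts
#' must deviate from their mean by at most 5% of that mean (boundary
#' inclusive). An all-zero triple is accepted. The check is invariant to the
#' order of the counts.
#'
#' @param counts integer vector of exactly three non-negative counts.
#' @return `TRUE` if the triple is accepted.
#' @export
#' @examples
#' assess_agreement(c(95, 100, 105))   # TRUE (deviation exactly 5%)
#' assess_agreement(c(90, 100, 110))   # FALSE
assess_agreement <- function(counts) {
  if (length(counts) != 3) stop("exactly three counts are required")
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- mean(counts)
  if (m == 0) return(TRUE)
  all(abs(counts - m) <= 0.05 * m)
}

#' Simulate the triple-count ground protocol over colony sections
#'
#' For each section, three observer counts are drawn; if they fail the 5%
#' agreement rule the section is split into two halves (binomial allocation
#' of its true nests) and each half is counted recursively, mirroring the
#' field practice of subdividing a sub-colony with natural markers or rope
#' until three counts agree. An accepted section contributes the rounded
#' mean of its three agreeing counts. Sections still in disagreement at
#' `max_depth` are flagged unresolved: their last mean is used but the total
#' loses N1 eligibility.
#'
#' @param true_units integer vector of true nests per top-level section.
#' @param observer an [observer_model()].
#' @param max_depth maximum subdivision depth (default 8).
#' @param seed integer seed.
#' @return List with `total` (integer), `sessions` (data.frame: `unit`,
#'   `depth`, `true`, `c1`, `c2`, `c3`, `accepted`, `estimate`) and
#'   `all_resolved` (logical, `FALSE` if any section hit `max_depth`).
#' @export
#' @examples
#' protocol_count(c(400, 250), observer_model(cv = 0))$total  # 650
protocol_count <- function(true_units, observer = observer_model(),
                           max_depth = 8, seed = NULL) {
  if (any(true_units < 0)) stop("section sizes must be >= 0")
  with_seed(seed, {
    rows <- list()
    count_section <- function(n_true, id, depth) {
      cts <- simulate_observer_count(rep(n_true, 3), observer)
      ok <- assess_agreement(cts)
      if (ok || depth >= max_depth) {
        est <- as.integer(floor(mean(cts) + 0.5))  # round half-up
        rows[[length(rows) + 1]] <<- data.frame(
          unit = id, depth = depth, true = n_true,
          c1 = cts[1], c2 = cts[2], c3 = cts[3],
          accepted = ok, estimate = est)
        return(est)
      }
      left <- rbinom(1, n_true, 0.5)
      count_section(left, paste0(id, ".L"), depth + 1) +
        count_section(n_true - left, paste0(id, ".R"), depth + 1)
    }
    total <- 0L
    for (i in seq_along(true_units))
      total <- total + count_section(true_units[i], as.character(i), 0L)
    sessions <- do.call(rbind, rows)
    list(total = total, sessions = sessions,
         all_resolved = all(sessions$accepted))
  })
}
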