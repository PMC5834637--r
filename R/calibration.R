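#' Calibrate automated counts against manual validation counts
#'
#' Automated detection misses some nests and keeps some false positives, and
#' the net effect differs between sites (lighting, substrate, nest density).
#' A per-site simple linear regression of the manual validation count on the
#' automated count corrects these site-specific differences: the calibrated
#' island count is the regression prediction at the island's automated
#' total.
#'
#' @param detected numeric vector of automated (detected, filtered) counts in
#'   the validation plots.
#' @param manual numeric vector of manual counts of the same plots.
#' @param site site (island) identifier.
#' @return A `nest_calibration` object wrapping the `lm` fit, with `slope`,
#'   `intercept`, `sigma` (residual scale; 0 when n = 2) and `n`.
#' @seealso [apply_calibration()], [predict.nest_calibration()]
#' @export
#' @examples
#' cal <- fit_calibration(c(10, 20), c(21, 41))
#' coef(cal)  # intercept 1, slope 2
fit_calibration <- function(detected, manual, site = "site") {
  if (length(detected) != length(manual))
    stop("detected and manual must have the same length")
  if (length(detected) < 2) stop("at least 2 validation plots are required")
  if (var(detected) == 0)
    stop("degenerate design: detected counts are all equal")
  fit <- lm(manual ~ detected, data = data.frame(detected = detected,
                                                 manual = manual))
  n <- length(detected)
  # suppressWarnings: summary.lm warns on exact (zero-residual) fits
  sigma <- if (n == 2) 0 else suppressWarnings(summary(fit)$sigma)
  structure(list(site = as.character(site), fit = fit,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 sigma = sigma, n = n),
            class = "nest_calibration")
}

#' @export
print.nest_calibration <- function(x, ...) {
  cat(sprintf(
    "nest_calibration '%s': nests = %.4f + %.4f x detected (sigma %.2f, n = %d)\n",
    x$site, x$intercept, x$slope, x$sigma, x$n))
  invisible(x)
}

#' @export
coef.nest_calibration <- function(object, ...) coef(object$fit)

#' @export
summary.nest_calibration <- function(object, ...) summary(object$fit)

#' Predict calibrated nest counts
#'
#' @param object a [fit_calibration()] model.
#' @param detected automated counts to calibrate.
#' @param interval passed to [stats::predict.lm()] (`"none"` or
#'   `"prediction"`).
#' @param ... unused.
#' @return As `predict.lm`.
#' @export
predict.nest_calibration <- function(object, detected, interval = "none", ...) {
  predict(object$fit, newdata = data.frame(detected = detected),
          interval = interval)
}

#' Apply a calibration model to an island's automated total
#'
#' The point estimate is `slope * detected + intercept`, floored at zero and
#' rounded to a whole nest count. The relative uncertainty is the half-width
#' of the 95% prediction interval divided by the estimate — the quantity
#' classified into an N-level by [classify_precision()] (automated counts
#' calibrated this way are treated as +/-10%, i.e. N2).
#'
#' @param model a [fit_calibration()] model.
#' @param detected_total automated count for the whole island (>= 0).
#' @return List with `estimate` (integer nests) and `rel_uncertainty`
#'   (`NA` when the fit has no residual degrees of freedom or the estimate
#'   is 0).
#' @export
apply_calibration <- function(model, detected_total) {
  stopifnot(inherits(model, "nest_calibration"))
  if (detected_total < 0) stop("detected_total must be >= 0")
  raw <- model$slope * detected_total + model$intercept
  if (raw < 0 && detected_total > 0)
    warning("calibrated estimate is negative; forcing to 0")
  est <- as.integer(max(0, round(raw)))
  rel <- NA_real_
  if (model$n > 2 && est > 0) {
    pi95 <- predict(model$fit,
                    newdata = data.frame(detected = detected_total),
                    interval = "prediction", level = 0.95)
    rel <- unname((pi95[1, "upr"] - pi95[1, "lwr"]) / 2 / est)
  }
  list(estimate = est, rel_uncertainty = rel)
}
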