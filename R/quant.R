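# dsRNA quantification by linear standard curve from a marker dilution
# series (capillary-electrophoresis fluorescence signal vs concentration).

#' Default dsRNA marker dilution series (ng/uL)
#' @export
default_standard_series <- function() c(1, 2.5, 5, 10, 25, 50)

#' Fit a dsRNA standard curve
#'
#' Ordinary least squares of `signal = slope * concentration + intercept`
#' (classical calibration: the curve is inverted for unknowns by
#' [estimate_concentration()]).
#'
#' @param concentrations Numeric vector, ng/uL.
#' @param signals Numeric vector of fluorescence signals, same length.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n_points`, `range` (calibrated concentration range),
#'   `se_slope`, `se_intercept`.
#' @export
fit_standard_curve <- function(concentrations, signals) {
  stopifnot(length(concentrations) == length(signals),
            length(concentrations) >= 2)
  if (length(unique(concentrations)) < 2) {
    stop("need at least 2 distinct concentrations")
  }
  fit <- stats::lm(signals ~ concentrations)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  # exact calibration lines are legitimate here; silence the perfect-fit note
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) c(NA, NA))
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, n_points = length(concentrations),
                 range = range(concentrations),
                 se_intercept = unname(se[1]), se_slope = unname(se[2])),
            class = "standard_curve")
}

#' Estimate dsRNA concentrations from a standard curve
#'
#' Inverts the calibration line: `(signal - intercept) / slope`. Negative
#' estimates are clamped to 0 and flagged `below_range`; estimates outside
#' the calibrated concentration range are flagged `extrapolated`.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param signals Numeric vector of sample signals.
#' @return data.frame: `signal`, `concentration` (ng/uL), `flag`
#'   (`ok` / `below_range` / `extrapolated`).
#' @export
estimate_concentration <- function(curve, signals) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) ||
      abs(curve$slope) <= sqrt(.Machine$double.eps) *
        max(1, abs(curve$intercept))) {
    stop("degenerate standard curve: slope is zero")
  }
  est <- (signals - curve$intercept) / curve$slope
  flag <- rep("ok", length(est))
  tol <- 1e-8 * max(1, abs(curve$range))   # floating-point slack at bounds
  flag[est < curve$range[1] - tol | est > curve$range[2] + tol] <-
    "extrapolated"
  flag[est < 0] <- "below_range"
  est[est < 0] <- 0
  data.frame(signal = signals, concentration = est, flag = flag,
             stringsAsFactors = FALSE)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "dsRNA standard curve: signal = %.4g * conc + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
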