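#' Trapezoidal peak integration
#'
#' @param time numeric vector of retention times (min), sorted.
#' @param intensity matching intensity values (counts).
#' @param bounds length-2 integration window in minutes; only points
#'   inside it contribute.
#' @return integrated area in intensity-minutes.
#' @export
integrate_peak <- function(time, intensity, bounds = range(time)) {
  stopifnot(length(time) == length(intensity), length(bounds) == 2L)
  keep <- time >= bounds[1] & time <= bounds[2]
  t <- time[keep]; y <- intensity[keep]
  if (length(t) < 2L) stop("need at least 2 points inside the bounds")
  o <- order(t)
  trapz_area(t[o], y[o])
}

#' Peak-area ratio against the internal standard
#'
#' @param analyte_area analyte (or isomer-assigned) peak area.
#' @param is_area internal-standard peak area; must be positive.
#' @return the PAR, `analyte_area / is_area`.
#' @export
compute_par <- function(analyte_area, is_area) {
  if (!is.finite(is_area) || is_area <= 0)
    stop("internal-standard area must be positive")
  analyte_area / is_area
}

#' Fit an internal-standard calibration curve
#'
#' Ordinary unweighted least squares of the peak-area ratio on the
#' nominal concentration. Detection and quantitation limits follow the
#' standard-error-of-response-and-slope approach with the response SE
#' taken as the standard error of the y-intercept:
#' `LOD = 3.3 * Y-SE / slope`, `LOQ = 10 * Y-SE / slope`.
#'
#' @param levels nominal concentrations (ng/mL), at least 3 distinct.
#' @param pars matching peak-area ratios.
#' @param analyte optional analyte label.
#' @param quant_ion optional m/z of the quantitation ion.
#' @return an object of class `calibration_curve`: `slope`,
#'   `y_intercept`, `r_squared`, `y_se`, `lod`, `loq` (the latter two
#'   `NA` when the slope is not positive) and the `levels`/`pars` data.
#' @export
fit_calibration <- function(levels, pars, analyte = NA_character_,
                            quant_ion = NA_real_) {
  stopifnot(length(levels) == length(pars))
  if (length(unique(levels)) < 3L)
    stop("calibration needs at least 3 distinct levels")
  if (stats::var(levels) == 0) stop("calibration levels have zero variance")
  fit <- stats::lm(pars ~ levels)
  # exact synthetic lines fit perfectly; silence the perfect-fit note
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  slope <- co["levels", "Estimate"]
  y_se <- co["(Intercept)", "Std. Error"]
  if (!is.finite(y_se)) y_se <- 0   # exact fit: zero residual variance
  r2 <- if (is.null(s$r.squared)) NA_real_ else s$r.squared
  lod <- loq <- NA_real_
  if (slope > 0) {
    lod <- 3.3 * y_se / slope
    loq <- 10 * y_se / slope
  }
  structure(
    list(analyte = analyte, quant_ion = quant_ion,
         levels = as.numeric(levels), pars = as.numeric(pars),
         slope = slope, y_intercept = co["(Intercept)", "Estimate"],
         r_squared = r2, y_se = y_se, lod = lod, loq = loq),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration%s: PAR = %.4g * conc %+.4g; R2 %.4f; LOD %.3g, LOQ %.3g ng/mL\n",
    if (is.na(x$analyte)) "" else paste0(" (", x$analyte, ")"),
    x$slope, x$y_intercept, x$r_squared, x$lod, x$loq))
  invisible(x)
}

#' Concentration from a peak-area ratio
#'
#' Inverts the calibration line: `(par - y_intercept) / slope`. Negative
#' back-calculated concentrations are clipped to zero and flagged.
#'
#' @param par measured peak-area ratio.
#' @param curve a [fit_calibration()] result.
#' @return concentration in ng/mL with attribute `clipped` (logical).
#' @export
quantify <- function(par, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (par - curve$y_intercept) / curve$slope
  clipped <- conc < 0
  conc[clipped] <- 0
  structure(conc, clipped = clipped)
}

#' Validation plot of deconvolution accuracy and precision
#'
#' Regresses the deconvolution-estimated compositions on the expected
#' (prepared) compositions, both on the fraction scale. A slope near 1
#' with intercept near 0 certifies accuracy across all tested levels at
#' once; the residual standard error of the fit (`se_lin`,
#' `sqrt(SSR / (n - 2))`) summarises precision — read `+/- 2 * se_lin`
#' as a 95% band on the recovered purity ratio.
#'
#' @param expected prepared isomer fractions (0-1 scale).
#' @param estimated matching deconvolved fractions.
#' @return an object of class `validation_plot`: `points`, `slope`,
#'   `y_intercept`, `r_squared`, `se_lin`.
#' @export
build_validation_plot <- function(expected, estimated) {
  stopifnot(length(expected) == length(estimated))
  if (length(expected) < 3L) stop("validation plot needs at least 3 points")
  fit <- stats::lm(estimated ~ expected)
  s <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  structure(
    list(points = data.frame(expected = as.numeric(expected),
                             estimated = as.numeric(estimated)),
         slope = unname(stats::coef(fit)[2L]),
         y_intercept = unname(stats::coef(fit)[1L]),
         r_squared = s$r.squared,
         se_lin = s$sigma),
    class = "validation_plot")
}

#' @export
print.validation_plot <- function(x, ...) {
  cat(sprintf(
    "validation plot (n=%d): slope %.3f, intercept %+.3f, R2 %.4f, SE-Lin %.4f\n",
    nrow(x$points), x$slope, x$y_intercept, x$r_squared, x$se_lin))
  invisible(x)
}
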