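#' Survival yield at one ramp step
#'
#' The survival yield (SY) is the precursor-ion abundance as a percentage
#' of the total detected ion signal,
#' `SY = 100 * prec / (prec + sum(products))`. It describes the energetics
#' of degradation of the precursor ion as the excitation amplitude grows.
#'
#' @param precursor_abundance precursor-ion abundance (counts).
#' @param product_abundances numeric vector of product-ion abundances.
#' @return SY in percent, or `NA` when the total signal is zero (an
#'   undefined point, dropped from curves).
#' @export
compute_sy <- function(precursor_abundance, product_abundances) {
  stopifnot(precursor_abundance >= 0, all(product_abundances >= 0))
  tot <- precursor_abundance + sum(product_abundances)
  if (tot <= 0) return(NA_real_)
  # ratio first so the result can never round above 100
  100 * (precursor_abundance / tot)
}

#' Product-ion formation at one ramp step
#'
#' The product-ion formation (PiF) value is the summed product-ion
#' abundance as a percentage of the total detected signal; the exact
#' complement of [compute_sy()].
#'
#' @inheritParams compute_sy
#' @return PiF in percent, or `NA` for a zero-signal point.
#' @export
compute_pif <- function(precursor_abundance, product_abundances) {
  stopifnot(precursor_abundance >= 0, all(product_abundances >= 0))
  tot <- precursor_abundance + sum(product_abundances)
  if (tot <= 0) return(NA_real_)
  100 * (sum(product_abundances) / tot)
}

#' Pre-fragmentation precursor signal
#'
#' Averages the precursor abundance over the low-amplitude steps acquired
#' before the fragmentation channels activate (operationalised as
#' PiF <= `activation_threshold_pct`, so a threshold of zero still admits
#' exactly-zero-PiF steps). This "precursor ion max" is the
#' quantity of precursor signal available to the CID process and the
#' denominator of the product-ion yield.
#'
#' @param dataset an [erms_dataset()].
#' @param activation_threshold_pct PiF cutoff (%) below which a step
#'   counts as pre-activation.
#' @return mean precursor abundance (counts) over the qualifying steps;
#'   if no step qualifies, the lowest-amplitude step is used with a
#'   warning.
#' @export
estimate_precursor_max <- function(dataset, activation_threshold_pct = 1.0) {
  stopifnot(inherits(dataset, "erms_dataset"))
  pif <- vapply(seq_along(dataset$exa), function(i)
    compute_pif(dataset$precursor[i], dataset$products[i, ]), numeric(1))
  ok <- !is.na(pif) & pif <= activation_threshold_pct
  if (!any(ok)) {
    warning("all steps show fragmentation above the activation threshold; ",
            "falling back to the lowest-amplitude step")
    return(dataset$precursor[1L])
  }
  mean(dataset$precursor[ok])
}

# Linear interpolation of the ExA where a curve crosses `level`,
# scanning bracketing grid pairs; NA when no crossing exists.
interp_crossing <- function(exa, y, level) {
  ok <- !is.na(y)
  exa <- exa[ok]; y <- y[ok]
  if (length(y) < 2L) return(NA_real_)
  d <- y - level
  hit <- which(d == 0)
  if (length(hit)) return(exa[hit[1L]])
  sgn <- which(d[-1] * d[-length(d)] < 0)
  if (!length(sgn)) return(NA_real_)
  i <- sgn[1L]
  exa[i] + (level - y[i]) * (exa[i + 1L] - exa[i]) / (y[i + 1L] - y[i])
}

#' Energy profile of an ERMS ramp
#'
#' Computes, per excitation-amplitude step, the survival yield (SY),
#' product-ion formation (PiF) and product-ion yield
#' (`PiY = 100 * sum(products) / precursor_ion_max`) curves, and the
#' summary energetics: the amplitude at which half the precursor
#' population has fragmented (`sy_exa50`, SY = PiF = 50%, located by
#' linear interpolation between bracketing grid points), and the maximum
#' CID efficiency (`piy_max_pct`) with the grid amplitude achieving it
#' (`exa_max`; ties resolve to the lowest amplitude).
#'
#' Unlike PiF, PiY is referenced to the pre-fragmentation precursor
#' signal, so it is depressed by precursor ejection losses and by product
#' ions falling below the trap's low-mass cut-off — it measures the true
#' efficiency of the CID process.
#'
#' @param dataset an [erms_dataset()].
#' @param activation_threshold_pct passed to [estimate_precursor_max()].
#' @return an object of class `energy_profile`: list with `points`
#'   (data frame `exa`, `sy_pct`, `pif_pct`, `piy_pct`; zero-signal steps
#'   dropped), `precursor_ion_max`, `sy_exa50` (`NA` when SY never
#'   crosses 50), `piy_max_pct`, `exa_max` and `ext_ms`.
#' @export
build_energy_profile <- function(dataset, activation_threshold_pct = 1.0) {
  stopifnot(inherits(dataset, "erms_dataset"))
  n <- length(dataset$exa)
  sy <- pif <- numeric(n)
  tots <- rowSums(dataset$products)
  for (i in seq_len(n)) {
    sy[i] <- compute_sy(dataset$precursor[i], dataset$products[i, ])
    pif[i] <- compute_pif(dataset$precursor[i], dataset$products[i, ])
  }
  pmax_ <- estimate_precursor_max(dataset, activation_threshold_pct)
  piy <- 100 * tots / pmax_
  keep <- !is.na(sy)
  points <- data.frame(exa = dataset$exa[keep], sy_pct = sy[keep],
                       pif_pct = pif[keep], piy_pct = piy[keep])
  i_max <- which.max(points$piy_pct)[1L]   # which.max already takes lowest tie
  structure(
    list(ext_ms = dataset$ext_ms,
         points = points,
         precursor_ion_max = pmax_,
         sy_exa50 = interp_crossing(points$exa, points$sy_pct, 50),
         piy_max_pct = points$piy_pct[i_max],
         exa_max = points$exa[i_max]),
    class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf(
    "energy profile (ExT %g ms): %d points, precursor max %.4g, SY_ExA50 %s a.u., PiY_max %.3g%% at ExA %g a.u.\n",
    x$ext_ms, nrow(x$points), x$precursor_ion_max,
    if (is.na(x$sy_exa50)) "absent" else sprintf("%.3g", x$sy_exa50),
    x$piy_max_pct, x$exa_max))
  invisible(x)
}

#' Per-ion breakdown curves
#'
#' For every ion (the precursor included) the yield curve versus
#' excitation amplitude, where yield is the ion's abundance relative to
#' the pre-fragmentation precursor signal
#' (`100 * abundance / precursor_ion_max`).
#'
#' @inheritParams build_energy_profile
#' @return an object of class `breakdown_curves`: list with `exa`,
#'   `yield_pct` (matrix, one column per ion; precursor column named by
#'   its m/z) and `precursor_ion_max`.
#' @export
build_breakdown_curves <- function(dataset, activation_threshold_pct = 1.0) {
  stopifnot(inherits(dataset, "erms_dataset"))
  pmax_ <- estimate_precursor_max(dataset, activation_threshold_pct)
  ions <- cbind(dataset$precursor, dataset$products)
  colnames(ions)[1] <- format(dataset$precursor_mz, digits = 12)
  structure(
    list(exa = dataset$exa, yield_pct = 100 * ions / pmax_,
         precursor_ion_max = pmax_, precursor_mz = dataset$precursor_mz),
    class = "breakdown_curves")
}

#' Half-fragmentation amplitude across excitation times
#'
#' Collects `sy_exa50` from profiles acquired at different excitation
#' times. Longer excitation transfers energy more effectively, so the
#' half-fragmentation amplitude falls with growing ExT, approaching a
#' plateau; the successive differences quantify that saturation.
#'
#' @param profiles list of [build_energy_profile()] results at distinct
#'   excitation times.
#' @return data frame `ext_ms`, `sy_exa50`, `diff_from_prev`, sorted by
#'   `ext_ms`.
#' @export
compare_sy_exa50_vs_ext <- function(profiles) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "energy_profile")))
  ext <- vapply(profiles, `[[`, numeric(1), "ext_ms")
  if (anyDuplicated(ext)) stop("profiles must be at distinct excitation times")
  o <- order(ext)
  v <- vapply(profiles, `[[`, numeric(1), "sy_exa50")[o]
  data.frame(ext_ms = ext[o], sy_exa50 = v,
             diff_from_prev = c(NA, diff(v)))
}

#' Write energy-profile curves to CSV
#' @param profile an `energy_profile`.
#' @param path output CSV path (columns `exa`, `sy_pct`, `pif_pct`,
#'   `piy_pct`).
#' @return `path`, invisibly.
#' @export
write_energy_profile_csv <- function(profile, path) {
  utils::write.csv(profile$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write energy-profile summary to JSON
#' @param profile an `energy_profile`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_energy_profile_json <- function(profile, path) {
  jsonlite::write_json(
    list(ext_ms = profile$ext_ms,
         precursor_ion_max = profile$precursor_ion_max,
         sy_exa50 = profile$sy_exa50,
         piy_max_pct = profile$piy_max_pct,
         exa_max = profile$exa_max),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
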