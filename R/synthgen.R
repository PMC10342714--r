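# Multiplicative lognormal noise factors with unit mean and the given CV.
lnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Default product-ion branching fractions: the relative channel yields of
# the ELF94 reference spectrum, normalised to sum to one.
default_branching <- function() {
  b <- c("392" = 0.01, "384" = 0.09, "366" = 0.19,
         "279" = 0.10, "253" = 0.01, "221" = 0.38)
  b / sum(b)
}

#' Generate a synthetic ERMS ramp
#'
#' Emulates an excitation-amplitude ramp at fixed excitation time.
#' The precursor survival follows a logistic decay: below the
#' fragmentation onset (`sy_midpoint - 2 * sy_width`) the precursor sits
#' at its plateau with no product formation (the pre-activation region
#' used to estimate the precursor-ion maximum); above it the surviving
#' fraction is `plogis((sy_midpoint - exa) / sy_width)` and the
#' fragmented precursor is shared among the product channels by the
#' branching fractions, after removing the `ejection_loss_fraction`
#' lost to precursor ejection or to ions below the low-mass cut-off.
#' An optional high-amplitude roll-off attenuates product signals above
#' `exa_rolloff`, reproducing the post-maximum decline of product-ion
#' yield curves.
#'
#' @param sy_midpoint amplitude (a.u.) at which half the precursor has
#'   fragmented; this is the true `sy_exa50`.
#' @param sy_width logistic scale (a.u.).
#' @param ejection_loss_fraction fraction of fragmented precursor signal
#'   that never reaches a detected product ion, in `[0, 1)`.
#' @param branching named numeric vector (names are product m/z) of
#'   channel fractions, summing to at most 1.
#' @param plateau_abundance precursor plateau signal (counts).
#' @param exa excitation-amplitude grid (a.u., within `[0, 50]`).
#' @param noise_cv multiplicative lognormal noise CV on every abundance.
#' @param exa_rolloff amplitude above which product signals decay
#'   (`NA` for none).
#' @param rolloff_rate exponential decay rate (per a.u.) of the roll-off.
#' @param precursor_mz,ext_ms metadata for the resulting dataset.
#' @param seed RNG seed; the generator is a pure function of
#'   (parameters, seed).
#' @return an [erms_dataset()] with attribute `truth` holding the
#'   generating parameters and noise-free abundances.
#' @export
gen_erms <- function(sy_midpoint = 30, sy_width = 3,
                     ejection_loss_fraction = 0,
                     branching = default_branching(),
                     plateau_abundance = 1e5,
                     exa = seq(0, 50, by = 1),
                     noise_cv = 0,
                     exa_rolloff = NA_real_, rolloff_rate = 0.05,
                     precursor_mz = 604, ext_ms = 50, seed = NULL) {
  if (any(exa < 0) || any(exa > 50))
    stop("excitation amplitudes must lie in [0, 50]")
  if (any(branching < 0)) stop("branching fractions must be non-negative")
  if (sum(branching) > 1 + 1e-12) stop("branching fractions must sum to at most 1")
  if (ejection_loss_fraction < 0 || ejection_loss_fraction >= 1)
    stop("ejection_loss_fraction must be in [0, 1)")
  onset <- sy_midpoint - 2 * sy_width
  s <- stats::plogis((sy_midpoint - exa) / sy_width)
  active <- exa > onset
  prec <- ifelse(active, plateau_abundance * s, plateau_abundance)
  frag <- ifelse(active, plateau_abundance * (1 - s), 0)
  detected <- frag * (1 - ejection_loss_fraction)
  if (!is.na(exa_rolloff))
    detected <- detected * exp(-pmax(0, exa - exa_rolloff) * rolloff_rate)
  prods <- outer(detected, branching)
  colnames(prods) <- names(branching)
  truth <- list(sy_midpoint = sy_midpoint, sy_width = sy_width,
                onset = onset, ejection_loss_fraction = ejection_loss_fraction,
                branching = branching, plateau_abundance = plateau_abundance,
                precursor_clean = prec, products_clean = prods)
  make <- function() {
    p <- prec * lnoise(length(prec), noise_cv)
    q <- prods * matrix(lnoise(length(prods), noise_cv), nrow(prods))
    ds <- erms_dataset(exa, p, q, precursor_mz = precursor_mz, ext_ms = ext_ms)
    attr(ds, "truth") <- truth
    ds
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Generate noisy measured ratio vectors for a known mixture
#'
#' Each replicate is the composition-weighted combination of the pure
#' isomers' characteristic ratios plus independent Gaussian noise per
#' ion (the replicate SDs of the ratio table motivate the default SD of
#' 0.01), truncated at zero.
#'
#' @param table a [ratio_table()].
#' @param fractions non-negative isomer fractions (table column order).
#' @param noise_sd Gaussian SD added to every ratio.
#' @param n_replicates number of vectors to generate.
#' @param seed RNG seed.
#' @return list of `ratio_vector` objects with attribute `truth` (the
#'   noise-free vector and the fractions).
#' @export
gen_mixture_ratios <- function(table, fractions, noise_sd = 0.01,
                               n_replicates = 1, seed = NULL) {
  stopifnot(inherits(table, "ratio_table"))
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (length(fractions) != length(table$isomers))
    stop("need one fraction per isomer")
  clean <- as.numeric(table$mean_ratio %*% fractions)
  make <- function() {
    out <- lapply(seq_len(n_replicates), function(i) {
      r <- pmax(0, clean + stats::rnorm(length(clean), 0, noise_sd))
      structure(list(pi_mz = table$pi_mz, ratios = r,
                     ri_abundance = NA_real_, defined = TRUE),
                class = "ratio_vector")
    })
    attr(out, "truth") <- list(fractions = fractions, clean = clean)
    out
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Generate a synthetic two-segment event chromatogram
#'
#' Builds the acquisition the deconvolution modules consume: Gaussian
#' elution envelopes sampled by alternating MS/MS events. Segment 1
#' holds the internal-standard event; segment 2 alternates a
#' reference-ion event (low collision energy, abundance = the summed
#' isomer envelopes at the reference m/z) and a product-ion scan event
#' whose per-ion abundances are the envelope values weighted by each
#' isomer's characteristic ratios. By default both isomers share one
#' retention time (full co-elution); supply per-isomer `rt_isomers` to
#' simulate partial resolution. When all fractions are zero, segment 2
#' is left empty (an internal-standard-only run).
#'
#' @param table a [ratio_table()] supplying isomer names, product m/z
#'   and characteristic ratios.
#' @param fractions isomer fractions scaling the shared reference-ion
#'   envelope.
#' @param rt_is,rt_isomers retention times (min); `rt_is` must fall in
#'   segment 1, `rt_isomers` (scalar or per isomer) in segment 2.
#' @param peak_sigma Gaussian peak sigma (min).
#' @param ri_height reference-ion envelope height at unit fraction
#'   (counts).
#' @param is_height internal-standard envelope height (counts).
#' @param scan_period_s period of one Ri+Pis event pair (seconds); the
#'   internal-standard event repeats at the same period.
#' @param noise_cv multiplicative lognormal noise CV on abundances.
#' @param config a [run_config()] giving segment bounds and ion m/z.
#' @param seed RNG seed.
#' @return an [event_chromatogram()] with attribute `truth` (fractions,
#'   envelope parameters and the per-isomer analytic envelope areas
#'   `height * sigma * sqrt(2*pi)`).
#' @export
gen_chromatogram <- function(table, fractions, rt_is = 1.5, rt_isomers = 5.0,
                             peak_sigma = 0.2, ri_height = 1e6,
                             is_height = 5e5, scan_period_s = 0.6,
                             noise_cv = 0, config = run_config(),
                             seed = NULL) {
  stopifnot(inherits(table, "ratio_table"))
  n_iso <- length(table$isomers)
  if (length(fractions) != n_iso) stop("need one fraction per isomer")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  rt_x <- rep_len(rt_isomers, n_iso)
  b1 <- config$segment_bounds[[1]]; b2 <- config$segment_bounds[[2]]
  if (rt_is < b1[1] || rt_is >= b1[2])
    stop("rt_is must lie inside segment 1")
  if (any(rt_x < b2[1] | rt_x >= b2[2]))
    stop("isomer retention times must lie inside segment 2")
  period <- scan_period_s / 60
  env <- function(t, rt, h) h * exp(-(t - rt)^2 / (2 * peak_sigma^2))
  ion_names <- c(fmt_mz(config$is_mz), fmt_mz(table$ri_mz),
                 fmt_mz(table$pi_mz))
  t1 <- seq(b1[1] + period, b1[2] - 1e-9, by = period)
  t_ri <- seq(b2[1] + period, b2[2] - 1e-9, by = period)
  t_pi <- t_ri + period / 2
  t_pi <- t_pi[t_pi < b2[2]]
  t_ri <- t_ri[seq_along(t_pi) + 0]        # keep pairs aligned
  analyte <- sum(fractions) > 0
  make <- function() {
    rows <- list()
    is_ab <- env(t1, rt_is, is_height) * lnoise(length(t1), noise_cv)
    seg1 <- data.frame(time_min = t1, segment = 1L, event = "IS")
    seg1[, ion_names] <- 0
    seg1[[fmt_mz(config$is_mz)]] <- is_ab
    rows[[1]] <- seg1
    if (analyte) {
      env_x_ri <- sapply(seq_len(n_iso), function(x)
        env(t_ri, rt_x[x], ri_height * fractions[x]))
      env_x_ri <- matrix(env_x_ri, length(t_ri))
      ri_ab <- rowSums(env_x_ri) * lnoise(length(t_ri), noise_cv)
      seg_ri <- data.frame(time_min = t_ri, segment = 2L, event = "Ri")
      seg_ri[, ion_names] <- 0
      seg_ri[[fmt_mz(table$ri_mz)]] <- ri_ab
      env_x_pi <- sapply(seq_len(n_iso), function(x)
        env(t_pi, rt_x[x], ri_height * fractions[x]))
      env_x_pi <- matrix(env_x_pi, length(t_pi))
      pi_ab <- env_x_pi %*% t(table$mean_ratio)
      pi_ab <- pi_ab * matrix(lnoise(length(pi_ab), noise_cv), nrow(pi_ab))
      seg_pi <- data.frame(time_min = t_pi, segment = 2L, event = "Pis")
      seg_pi[, ion_names] <- 0
      seg_pi[, fmt_mz(table$pi_mz)] <- pi_ab
      rows[[2]] <- seg_ri
      rows[[3]] <- seg_pi
    }
    chrom <- event_chromatogram(do.call(rbind, rows),
                                segment_bounds = config$segment_bounds)
    attr(chrom, "truth") <- list(
      fractions = fractions, rt_is = rt_is, rt_isomers = rt_x,
      peak_sigma = peak_sigma, ri_height = ri_height, is_height = is_height,
      ri_area = stats::setNames(
        ri_height * fractions * peak_sigma * sqrt(2 * pi), table$isomers),
      is_area = is_height * peak_sigma * sqrt(2 * pi))
    chrom
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Generate a synthetic calibration set
#'
#' Peak-area ratios on a proportional response,
#' `PAR = slope_true * level * (1 + eps)` with Gaussian relative noise.
#'
#' @param slope_true true response slope (PAR per ng/mL), positive.
#' @param levels nominal concentrations (ng/mL); the default is the
#'   five-level design 5, 10, 25, 50 and 100 ng/mL.
#' @param noise_cv relative noise SD.
#' @param seed RNG seed.
#' @return data frame `level`, `par`.
#' @export
gen_calibration_set <- function(slope_true, levels = c(5, 10, 25, 50, 100),
                                noise_cv = 0, seed = NULL) {
  if (slope_true <= 0) stop("slope_true must be positive")
  if (!length(levels)) stop("levels must be non-empty")
  make <- function() {
    eps <- if (noise_cv > 0) stats::rnorm(length(levels), 0, noise_cv) else 0
    data.frame(level = levels, par = slope_true * levels * (1 + eps))
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Generate a plasma-stability degradation panel
#'
#' First-order decay sampled on the study schedule: triplicates at
#' 0, 30, 60 and 120 min of incubation, nominal 1 uM starting
#' concentration, multiplicative lognormal measurement noise.
#'
#' @param k_true named numeric vector of true rate constants
#'   (ln(uM)/min), one per compound.
#' @param c0 starting concentration (uM).
#' @param times incubation schedule (min).
#' @param replicates replicates per time point.
#' @param cv lognormal noise CV.
#' @param seed RNG seed.
#' @return named list of [degradation_series()].
#' @export
gen_degradation_panel <- function(k_true, c0 = 1, times = c(0, 30, 60, 120),
                                  replicates = 3, cv = 0.05, seed = NULL) {
  if (c0 <= 0) stop("c0 must be positive")
  if (is.null(names(k_true)))
    names(k_true) <- paste0("compound", seq_along(k_true))
  make <- function() {
    lapply(stats::setNames(names(k_true), names(k_true)), function(nm) {
      tt <- rep(times, each = replicates)
      rep_id <- rep(seq_len(replicates), times = length(times))
      conc <- c0 * exp(k_true[[nm]] * tt) * lnoise(length(tt), cv)
      degradation_series(nm, tt, rep_id, conc, c0_nominal = c0)
    })
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}
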