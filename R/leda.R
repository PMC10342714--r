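#' Characteristic product-ion ratio table
#'
#' The deconvolution matrix: for each isomer, the mean abundance ratio of
#' every selected product ion (Pi) to the shared reference ion (Ri),
#' measured on pure standards, plus the replicate standard deviations.
#' With more product ions than isomers the system is overdetermined,
#' which is the default and recommended configuration.
#'
#' @param isomers character vector of isomer names (column order).
#' @param pi_mz numeric vector of product-ion m/z (row order).
#' @param mean_ratio numeric matrix (`length(pi_mz)` x `length(isomers)`)
#'   of characteristic Pi/Ri ratios.
#' @param sd_ratio matrix of replicate SDs, same shape (0 when built from
#'   a single replicate).
#' @param ri_mz reference-ion m/z.
#' @return an object of class `ratio_table`.
#' @export
ratio_table <- function(isomers, pi_mz, mean_ratio, sd_ratio = NULL, ri_mz) {
  mean_ratio <- as.matrix(mean_ratio)
  if (is.null(sd_ratio)) sd_ratio <- matrix(0, nrow(mean_ratio), ncol(mean_ratio))
  sd_ratio <- as.matrix(sd_ratio)
  stopifnot(length(pi_mz) == nrow(mean_ratio),
            length(isomers) == ncol(mean_ratio),
            all(dim(sd_ratio) == dim(mean_ratio)),
            all(mean_ratio >= 0), all(sd_ratio >= 0))
  if (nrow(mean_ratio) < ncol(mean_ratio))
    stop("need at least as many product ions as isomers")
  dimnames(mean_ratio) <- dimnames(sd_ratio) <- list(fmt_mz(pi_mz), isomers)
  structure(
    list(isomers = isomers, pi_mz = as.numeric(pi_mz), ri_mz = ri_mz,
         mean_ratio = mean_ratio, sd_ratio = sd_ratio),
    class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("characteristic ratio table: %d Pi/Ri equations x %d isomers (Ri m/z %g)\n",
              length(x$pi_mz), length(x$isomers), x$ri_mz))
  lab <- sprintf("%g/%g", x$pi_mz, x$ri_mz)
  m <- x$mean_ratio
  rownames(m) <- lab
  print(round(m, 4))
  invisible(x)
}

#' Build a ratio table from pure-isomer runs
#'
#' Takes replicate MS/MS acquisitions of each pure isomer (typically the
#' highest calibration level) and assembles the characteristic ratio
#' matrix. A product ion enters the table if its relative abundance — its
#' signal as a percentage of the most abundant product ion in the
#' spectrum — reaches `inclusion_threshold_pct` in at least one isomer's
#' mean spectrum. Rows are ordered by descending mean ratio of the first
#' isomer (ties by descending m/z).
#'
#' @param pure_runs named list (one entry per isomer) of replicate lists;
#'   each replicate is a list with `ri_abundance` (counts, > 0) and
#'   `pi_abundances` (named numeric vector, names are m/z).
#' @param inclusion_threshold_pct relative-abundance cutoff in percent.
#' @param ri_mz reference-ion m/z recorded in the table.
#' @return a [ratio_table()].
#' @export
build_ratio_table <- function(pure_runs, inclusion_threshold_pct = 5,
                              ri_mz = NA_real_) {
  stopifnot(is.list(pure_runs), length(pure_runs) >= 1L,
            !is.null(names(pure_runs)))
  isomers <- names(pure_runs)
  all_mz <- sort(unique(unlist(lapply(pure_runs, function(reps)
    lapply(reps, function(r) as.numeric(names(r$pi_abundances)))))))
  # per-isomer mean spectrum and per-ion ratio replicates
  mean_spec <- matrix(0, length(all_mz), length(isomers))
  ratios <- vector("list", length(isomers))
  for (j in seq_along(isomers)) {
    reps <- pure_runs[[j]]
    rmat <- matrix(NA_real_, length(reps), length(all_mz))
    smat <- matrix(0, length(reps), length(all_mz))
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      if (is.null(r$ri_abundance) || r$ri_abundance <= 0)
        stop("each pure-isomer replicate needs a positive Ri abundance")
      mzk <- as.numeric(names(r$pi_abundances))
      idx <- vapply(mzk, function(m) match_mz(all_mz, m), integer(1))
      smat[k, idx] <- r$pi_abundances
      rmat[k, idx] <- r$pi_abundances / r$ri_abundance
      rmat[k, is.na(rmat[k, ])] <- 0
    }
    mean_spec[, j] <- colMeans(smat)
    ratios[[j]] <- rmat
  }
  # relative abundance within each isomer's mean product-ion spectrum
  rel <- sweep(mean_spec, 2, apply(mean_spec, 2, max), "/") * 100
  keep <- which(apply(rel, 1, max) >= inclusion_threshold_pct)
  if (!length(keep))
    stop("no product ion reaches the inclusion threshold of ",
         inclusion_threshold_pct, "%")
  mean_ratio <- sapply(ratios, function(r) colMeans(r)[keep])
  sd_ratio <- sapply(ratios, function(r)
    if (nrow(r) > 1L) apply(r[, keep, drop = FALSE], 2, stats::sd) else
      rep(0, length(keep)))
  mean_ratio <- matrix(mean_ratio, length(keep))
  sd_ratio <- matrix(sd_ratio, length(keep))
  o <- order(-mean_ratio[, 1L], -all_mz[keep])
  ratio_table(isomers, all_mz[keep][o], mean_ratio[o, , drop = FALSE],
              sd_ratio[o, , drop = FALSE], ri_mz = ri_mz)
}

#' Read a ratio table from CSV
#'
#' Long format with columns `isomer`, `pi_mz`, `ri_mz`, `mean_ratio`,
#' `sd`; row order of the first isomer fixes the equation order.
#'
#' @param path CSV file path.
#' @return a [ratio_table()].
#' @export
read_ratio_table_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("isomer", "pi_mz", "ri_mz", "mean_ratio", "sd")
  if (!all(req %in% names(df)))
    stop("ratio table CSV needs columns ", paste(req, collapse = ", "))
  isomers <- unique(df$isomer)
  pi_mz <- unique(df$pi_mz)
  m <- s <- matrix(NA_real_, length(pi_mz), length(isomers))
  for (j in seq_along(isomers)) {
    dj <- df[df$isomer == isomers[j], ]
    i <- match(pi_mz, dj$pi_mz)
    if (anyNA(i)) stop("isomer ", isomers[j], " is missing some product ions")
    m[, j] <- dj$mean_ratio[i]
    s[, j] <- dj$sd[i]
  }
  ratio_table(isomers, pi_mz, m, s, ri_mz = df$ri_mz[1L])
}

#' Write a ratio table to CSV
#' @param table a [ratio_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table_csv <- function(table, path) {
  df <- do.call(rbind, lapply(seq_along(table$isomers), function(j)
    data.frame(isomer = table$isomers[j], pi_mz = table$pi_mz,
               ri_mz = table$ri_mz, mean_ratio = table$mean_ratio[, j],
               sd = table$sd_ratio[, j])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Built-in characteristic ratio table for the ELF94/ELF96 isomer pair
#'
#' The six-equation Pi/Ri table (product ions at m/z 392, 384, 366, 279,
#' 253 and 221 against the precursor reference ion at m/z 604) measured
#' on pure standards of the positional isomers ELF94 and ELF96, shipped
#' with the package as a worked example and test input.
#'
#' @return a [ratio_table()] with 6 equations and 2 isomers.
#' @export
elf_ratio_table <- function() {
  read_ratio_table_csv(system.file("extdata", "elf_characteristic_ratios.csv",
                                   package = "ledams", mustWork = TRUE))
}

#' Measured Pi/Ri ratio vector
#'
#' Forms the measured ratios of a sample: each selected product-ion
#' abundance divided by the reference-ion abundance.
#'
#' @param ri_abundance reference-ion abundance (counts).
#' @param pi_abundances named numeric vector of product-ion abundances
#'   (names are m/z).
#' @return an object of class `ratio_vector` with fields `pi_mz`,
#'   `ratios`, `ri_abundance` and `defined`; when `ri_abundance <= 0` the
#'   vector is flagged undefined (and skipped in scan-by-scan mode)
#'   rather than raising an error.
#' @export
measure_ratios <- function(ri_abundance, pi_abundances) {
  pi_mz <- as.numeric(names(pi_abundances))
  if (is.null(names(pi_abundances)) || anyNA(pi_mz))
    stop("pi_abundances must be named by numeric m/z")
  defined <- is.finite(ri_abundance) && ri_abundance > 0
  structure(
    list(pi_mz = pi_mz,
         ratios = if (defined) as.numeric(pi_abundances) / ri_abundance
                  else rep(NA_real_, length(pi_mz)),
         ri_abundance = ri_abundance, defined = defined),
    class = "ratio_vector")
}

# Reindex a measured vector onto the table's canonical ion order,
# matching by m/z tolerance.
align_measured <- function(table, measured, tol = MZ_TOL) {
  if (inherits(measured, "ratio_vector")) {
    idx <- vapply(table$pi_mz, function(m) match_mz(measured$pi_mz, m, tol),
                  integer(1))
    if (anyNA(idx))
      stop("measured vector is missing product ions: ",
           paste(table$pi_mz[is.na(idx)], collapse = ", "))
    measured$ratios[idx]
  } else {
    r <- as.numeric(measured)
    if (length(r) != length(table$pi_mz))
      stop("measured ratios must match the table's ", length(table$pi_mz),
           " product ions")
    r
  }
}

new_deconvolution_result <- function(table, fractions, solver) {
  fitted <- as.numeric(table$mean_ratio %*% fractions$f)
  structure(
    list(isomers = table$isomers,
         fractions = stats::setNames(fractions$f, table$isomers),
         percent = stats::setNames(100 * fractions$f, table$isomers),
         residual_ss = fractions$rss,
         fitted_ratios = stats::setNames(fitted, fmt_mz(table$pi_mz)),
         measured_ratios = stats::setNames(fractions$r, fmt_mz(table$pi_mz)),
         solver = solver),
    class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution (%s solver): %s; residual SS %.4g\n",
              x$solver,
              paste(sprintf("%s %.2f%%", x$isomers, x$percent), collapse = ", "),
              x$residual_ss))
  invisible(x)
}

#' Deconvolve a measured ratio vector into isomer fractions
#'
#' Solves the linear system `M f = r` in the least-squares sense, where
#' `M` is the characteristic ratio matrix (one row per product ion, one
#' column per isomer), `r` the measured Pi/Ri vector and `f` the isomer
#' fractions ("ratio purity"). The fractions are deliberately not
#' constrained to sum to one: forcing `B = 1 - A` would silently absorb
#' any unknown co-eluting contributor, whereas a free fit exposes it in
#' the residual.
#'
#' The default solver is nonnegative least squares; an unconstrained
#' ordinary least-squares mode is available for exact linear-regression
#' semantics (it may return negative fractions). The two agree whenever
#' the unconstrained optimum already lies in the nonnegative orthant.
#'
#' @param table a [ratio_table()].
#' @param measured a [measure_ratios()] vector (reindexed onto the
#'   table's ion order by m/z match) or a bare numeric vector already in
#'   table order.
#' @param solver `"nonnegative"` (default) or `"unconstrained"`.
#' @return a `deconvolution_result`: per-isomer `fractions` (and
#'   `percent`), `residual_ss`, `fitted_ratios` vs `measured_ratios`, and
#'   the `solver` used.
#' @export
solve_mixture <- function(table, measured,
                          solver = c("nonnegative", "unconstrained")) {
  stopifnot(inherits(table, "ratio_table"))
  solver <- match.arg(solver)
  r <- align_measured(table, measured)
  if (anyNA(r)) stop("measured ratio vector is undefined (Ri signal <= 0)")
  M <- table$mean_ratio
  if (qr(M)$rank < ncol(M)) {
    cc <- stats::cor(M)
    pair <- which(abs(cc - 1) < 1e-12 & upper.tri(cc), arr.ind = TRUE)
    who <- if (nrow(pair)) paste(table$isomers[pair[1, 1]],
                                 table$isomers[pair[1, 2]], sep = " vs ")
           else paste(table$isomers, collapse = ", ")
    stop("degenerate system: indistinguishable isomer columns (", who, ")")
  }
  f <- if (solver == "nonnegative") pracma::lsqnonneg(M, r)$x
       else as.numeric(qr.solve(qr(M), r))
  rss <- sum((r - as.numeric(M %*% f))^2)
  new_deconvolution_result(table, list(f = f, rss = rss, r = r), solver)
}

#' Brute-force mixture search (independent oracle)
#'
#' Exhaustive grid search over fraction tuples minimising the residual
#' sum of squares. Slow by design; it exists as an independent check on
#' [solve_mixture()] and supports at most three isomers.
#'
#' @inheritParams solve_mixture
#' @param grid_step fraction grid resolution.
#' @param max_fraction upper bound of the searched fraction range
#'   (above 1 so over-unity totals from co-elution remain findable).
#' @return a `deconvolution_result` with solver flag `"grid"`.
#' @export
brute_force_mixture <- function(table, measured, grid_step = 0.005,
                                max_fraction = 1.2) {
  stopifnot(inherits(table, "ratio_table"))
  n <- length(table$isomers)
  if (n > 3L) stop("grid search supports at most 3 isomers")
  r <- align_measured(table, measured)
  g <- seq(0, max_fraction, by = grid_step)
  F_ <- as.matrix(do.call(expand.grid, rep(list(g), n)))
  resid <- F_ %*% t(table$mean_ratio)
  resid <- sweep(resid, 2, r)
  rss <- rowSums(resid^2)
  best <- which.min(rss)
  new_deconvolution_result(
    table, list(f = as.numeric(F_[best, ]), rss = rss[best], r = r), "grid")
}

# Trapezoidal integral of y(t); assumes t sorted.
trapz_area <- function(t, y) {
  if (length(t) < 2L) stop("need at least 2 points to integrate")
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

# Pull the column index of an ion m/z in a chromatogram's scan table.
chrom_ion_col <- function(chrom, mz, tol = MZ_TOL) {
  ions <- chromatogram_ion_mz(chrom)
  i <- match_mz(as.numeric(ions), mz, tol)
  if (is.na(i)) return(NA_integer_)
  match(names(ions)[i], names(chrom$scans))
}

#' Peak-area deconvolution of a co-eluting isomer peak
#'
#' Integrates the reference-ion trace and every product-ion trace over
#' the peak (trapezoid rule on the event scans inside `peak_bounds`),
#' forms one measured ratio vector from the areas, deconvolves it, and
#' distributes the integrated Ri area over the isomers in proportion to
#' the (renormalised) fractions, so the assigned areas conserve the Ri
#' signal.
#'
#' @param chrom an [event_chromatogram()].
#' @param table a [ratio_table()].
#' @param peak_bounds length-2 numeric, integration window in minutes
#'   (must lie in segment 2).
#' @param solver passed to [solve_mixture()].
#' @return list with `result` (the `deconvolution_result`), `ri_area`,
#'   and `assigned_area` (named per isomer).
#' @export
deconvolve_peak <- function(chrom, table, peak_bounds,
                            solver = c("nonnegative", "unconstrained")) {
  stopifnot(inherits(chrom, "event_chromatogram"),
            inherits(table, "ratio_table"), length(peak_bounds) == 2L)
  solver <- match.arg(solver)
  sc <- chrom$scans
  inb <- sc$time_min >= peak_bounds[1] & sc$time_min <= peak_bounds[2]
  ri_sc <- sc[inb & sc$event == "Ri", , drop = FALSE]
  pi_sc <- sc[inb & sc$event == "Pis", , drop = FALSE]
  if (nrow(ri_sc) < 2L || nrow(pi_sc) < 2L)
    stop("no analyte scans: peak bounds must contain at least 2 Ri and 2 Pis event scans")
  ri_col <- chrom_ion_col(chrom, table$ri_mz)
  if (is.na(ri_col)) stop("chromatogram has no column for Ri m/z ", table$ri_mz)
  ri_area <- trapz_area(ri_sc$time_min, ri_sc[[ri_col]])
  pi_areas <- vapply(table$pi_mz, function(m) {
    j <- chrom_ion_col(chrom, m)
    if (is.na(j)) stop("chromatogram has no column for Pi m/z ", m)
    trapz_area(pi_sc$time_min, pi_sc[[j]])
  }, numeric(1))
  measured <- measure_ratios(ri_area,
                             stats::setNames(pi_areas, fmt_mz(table$pi_mz)))
  res <- solve_mixture(table, measured, solver)
  fsum <- sum(res$fractions)
  assigned <- if (fsum > 0) ri_area * res$fractions / fsum else {
    warning("all fractions zero; no Ri area assigned")
    stats::setNames(rep(0, length(table$isomers)), table$isomers)
  }
  list(result = res, ri_area = ri_area, assigned_area = assigned)
}

#' Scan-by-scan deconvolution into per-isomer profiles
#'
#' Deconvolves every product-ion scan of segment 2 individually and
#' reconstructs one chromatographic profile per isomer: the measured
#' ratio vector of each Pis scan is formed against the reference-ion
#' abundance linearly interpolated in time from the neighbouring Ri-event
#' scans, solved, and the interpolated Ri abundance is split by the
#' renormalised fractions. Summed over isomers the reconstructed profiles
#' reproduce the interpolated Ri trace at every assigned scan.
#'
#' @inheritParams deconvolve_peak
#' @return data frame with `time_min`, `ri_interpolated` and one column
#'   per isomer; scans whose interpolated Ri is non-positive are kept as
#'   `NA` gaps.
#' @export
deconvolve_scanwise <- function(chrom, table,
                                solver = c("nonnegative", "unconstrained")) {
  stopifnot(inherits(chrom, "event_chromatogram"),
            inherits(table, "ratio_table"))
  solver <- match.arg(solver)
  sc <- chrom$scans
  ri_sc <- sc[sc$event == "Ri", , drop = FALSE]
  pi_sc <- sc[sc$event == "Pis", , drop = FALSE]
  if (nrow(ri_sc) == 0L) stop("no Ri scans in segment 2")
  if (nrow(pi_sc) == 0L) stop("no analyte scans in segment 2")
  ri_col <- chrom_ion_col(chrom, table$ri_mz)
  if (is.na(ri_col)) stop("chromatogram has no column for Ri m/z ", table$ri_mz)
  pi_cols <- vapply(table$pi_mz, function(m) chrom_ion_col(chrom, m), integer(1))
  if (anyNA(pi_cols))
    stop("chromatogram is missing product ions: ",
         paste(table$pi_mz[is.na(pi_cols)], collapse = ", "))
  ri_interp <- stats::approx(ri_sc$time_min, ri_sc[[ri_col]],
                             xout = pi_sc$time_min, rule = 2)$y
  prof <- matrix(NA_real_, nrow(pi_sc), length(table$isomers),
                 dimnames = list(NULL, table$isomers))
  for (i in seq_len(nrow(pi_sc))) {
    measured <- measure_ratios(
      ri_interp[i],
      stats::setNames(as.numeric(pi_sc[i, pi_cols]), fmt_mz(table$pi_mz)))
    if (!measured$defined) next
    res <- solve_mixture(table, measured, solver)
    fsum <- sum(res$fractions)
    if (fsum > 0) prof[i, ] <- ri_interp[i] * res$fractions / fsum
    else prof[i, ] <- 0
  }
  out <- data.frame(time_min = pi_sc$time_min, ri_interpolated = ri_interp)
  cbind(out, as.data.frame(prof))
}
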