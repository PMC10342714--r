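#' ledams: isomer recognition in ion-trap MS/MS by linear-equation deconvolution
#'
#' Core workflow: acquire an energy-resolved MS/MS ramp ([gen_erms()] or
#' [read_erms_csv()]), characterise the collision-induced dissociation
#' energetics ([build_energy_profile()]), assemble a characteristic
#' product-ion/reference-ion ratio table from pure-isomer runs
#' ([build_ratio_table()]), deconvolve mixed MS/MS signals
#' ([solve_mixture()], [deconvolve_peak()], [deconvolve_scanwise()]),
#' quantify against internal-standard calibration ([fit_calibration()],
#' [quantify()]) and fit first-order plasma degradation kinetics
#' ([fit_first_order()]).
#'
#' @keywords internal
"_PACKAGE"

# m/z tolerance used when matching data columns to configured ions;
# unit-resolution ion traps justify a generous default.
MZ_TOL <- 0.5

# Per-element m/z -> column-label formatting (no vector-wide padding).
fmt_mz <- function(x) sprintf("%g", x)

#' Match m/z values against a set of column labels
#'
#' Column headers of abundance tables carry m/z values as text; this maps a
#' target m/z onto the (at most one) column within `tol` Thomson.
#'
#' @param candidates numeric vector of available m/z values.
#' @param target single m/z to locate.
#' @param tol match tolerance in Th.
#' @return integer index into `candidates`, or `NA_integer_` if no match.
#' @keywords internal
match_mz <- function(candidates, target, tol = MZ_TOL) {
  d <- abs(candidates - target)
  i <- which.min(d)
  if (length(i) == 0L || d[i] > tol) return(NA_integer_)
  i
}

#' Construct an ERMS dataset
#'
#' One excitation-amplitude (ExA) ramp acquired at a fixed excitation time
#' (ExT): per-step abundances of the precursor ion and of every product ion.
#'
#' @param exa numeric vector of excitation amplitudes (a.u.), strictly
#'   increasing, within `[0, 50]`.
#' @param precursor numeric vector of precursor-ion abundances (counts),
#'   one per step.
#' @param products numeric matrix of product-ion abundances, one row per
#'   step; column names are product m/z values.
#' @param precursor_mz precursor m/z (Th).
#' @param ext_ms excitation time in milliseconds.
#' @return an object of class `erms_dataset`.
#' @export
erms_dataset <- function(exa, precursor, products, precursor_mz, ext_ms) {
  exa <- as.numeric(exa)
  precursor <- as.numeric(precursor)
  products <- as.matrix(products)
  if (length(exa) < 3L)
    stop("an ERMS ramp needs at least 3 excitation-amplitude steps")
  if (any(diff(exa) <= 0))
    stop("excitation amplitudes must be strictly increasing")
  if (length(precursor) != length(exa) || nrow(products) != length(exa))
    stop("precursor and product abundances must have one value per step")
  if (any(precursor < 0) || any(products < 0))
    stop("abundances must be non-negative")
  if (is.null(colnames(products)))
    stop("product matrix must carry m/z column names")
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be a positive m/z value")
  if (!is.numeric(ext_ms) || ext_ms <= 0)
    stop("ext_ms must be a positive excitation time in ms")
  structure(
    list(exa = exa, precursor = precursor, products = products,
         precursor_mz = as.numeric(precursor_mz), ext_ms = as.numeric(ext_ms)),
    class = "erms_dataset")
}

#' @export
print.erms_dataset <- function(x, ...) {
  cat(sprintf(
    "ERMS ramp: %d steps, ExA %.3g-%.3g a.u., ExT %g ms, precursor m/z %g, %d product ions\n",
    length(x$exa), min(x$exa), max(x$exa), x$ext_ms, x$precursor_mz,
    ncol(x$products)))
  invisible(x)
}

product_mz <- function(dataset) as.numeric(colnames(dataset$products))

#' Read an ERMS ramp from CSV
#'
#' Expects a header row `exa` followed by one column per ion m/z; the
#' precursor column is located by m/z tolerance match against
#' `precursor_mz`.
#'
#' @param path CSV file path.
#' @param precursor_mz precursor m/z used to flag the precursor column.
#' @param ext_ms excitation time (ms) of the ramp.
#' @inheritParams match_mz
#' @return an [erms_dataset()].
#' @export
read_erms_csv <- function(path, precursor_mz, ext_ms, tol = MZ_TOL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "exa")
    stop("malformed ERMS CSV: first column must be 'exa'")
  ion_mz <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(ion_mz))
    stop("malformed ERMS CSV: ion columns must be named by numeric m/z")
  pc <- match_mz(ion_mz, precursor_mz, tol)
  if (is.na(pc))
    stop(sprintf("no column within %.2g Th of precursor m/z %g", tol, precursor_mz))
  if (anyDuplicated(df$exa))
    stop("duplicate exa rows are not allowed")
  prod_cols <- setdiff(seq_along(ion_mz), pc)
  products <- as.matrix(df[, 1L + prod_cols, drop = FALSE])
  colnames(products) <- names(df)[1L + prod_cols]
  erms_dataset(df$exa, df[[1L + pc]], products,
               precursor_mz = ion_mz[pc], ext_ms = ext_ms)
}

#' Write an ERMS ramp to CSV
#'
#' Inverse of [read_erms_csv()]; round trips preserve all values.
#'
#' @param dataset an [erms_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_erms_csv <- function(dataset, path) {
  df <- data.frame(exa = dataset$exa, precursor = dataset$precursor,
                   dataset$products, check.names = FALSE)
  names(df)[2] <- format(dataset$precursor_mz, digits = 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Acquisition run configuration
#'
#' Describes the MS/MS event schedule of a two-segment run: an
#' internal-standard (IS) event in segment 1, then alternating
#' reference-ion (Ri, low collision energy, unfragmented precursor) and
#' product-ion scan (Pis, high collision energy) events in segment 2.
#'
#' @param precursor_mz analyte precursor m/z (Th).
#' @param is_mz internal-standard precursor m/z (Th).
#' @param ri_window length-2 m/z range scanned by the Ri event.
#' @param pis_window length-2 m/z range scanned by the Pis event.
#' @param exa_ri excitation amplitude of the Ri event (a.u.).
#' @param exa_pis excitation amplitude of the Pis event (a.u.).
#' @param segment_bounds list of two half-open time intervals
#'   `[start, end)` in minutes.
#' @param inclusion_threshold_pct relative-abundance cutoff (%) for a
#'   product ion to enter the deconvolution matrix.
#' @return an object of class `run_config`.
#' @export
run_config <- function(precursor_mz = 604, is_mz = 455,
                       ri_window = c(580, 620), pis_window = c(165, 450),
                       exa_ri = 20, exa_pis = 35,
                       segment_bounds = list(c(0, 3.28), c(3.28, 10)),
                       inclusion_threshold_pct = 5) {
  stopifnot(length(ri_window) == 2L, diff(ri_window) > 0,
            length(pis_window) == 2L, diff(pis_window) > 0,
            exa_ri >= 0, exa_ri <= 50, exa_pis >= 0, exa_pis <= 50,
            length(segment_bounds) == 2L)
  structure(
    list(precursor_mz = precursor_mz, is_mz = is_mz,
         ri_window = as.numeric(ri_window), pis_window = as.numeric(pis_window),
         exa_ri = exa_ri, exa_pis = exa_pis,
         segment_bounds = unname(lapply(segment_bounds, as.numeric)),
         inclusion_threshold_pct = inclusion_threshold_pct),
    class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # the two equal-length intervals come back as a 2x2 matrix; re-split
  if (is.matrix(x$segment_bounds))
    x$segment_bounds <- split(x$segment_bounds, row(x$segment_bounds))
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' Write a run configuration to JSON
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

segment_of_time <- function(time_min, segment_bounds) {
  s <- rep(NA_integer_, length(time_min))
  for (i in seq_along(segment_bounds)) {
    b <- segment_bounds[[i]]
    s[time_min >= b[1] & time_min < b[2]] <- i
  }
  s
}

#' Construct an event chromatogram
#'
#' A time-ordered list of MS/MS event scans. Each scan belongs to one of
#' two time segments and one of three events: `IS` (internal standard,
#' segment 1 only), `Ri` or `Pis` (segment 2 only, strictly alternating).
#'
#' @param scans data frame with columns `time_min`, `segment`, `event`,
#'   then one abundance column per ion m/z.
#' @param segment_bounds list of two half-open `[start, end)` intervals in
#'   minutes.
#' @return an object of class `event_chromatogram`.
#' @export
event_chromatogram <- function(scans,
                               segment_bounds = list(c(0, 3.28), c(3.28, 10))) {
  req <- c("time_min", "segment", "event")
  if (!all(req %in% names(scans)))
    stop("scans need columns time_min, segment, event")
  scans <- scans[order(scans$time_min), , drop = FALSE]
  rownames(scans) <- NULL
  if (!all(scans$event %in% c("IS", "Ri", "Pis")))
    stop("events must be one of IS, Ri, Pis")
  seg <- segment_of_time(scans$time_min, segment_bounds)
  if (anyNA(seg))
    stop("scan time outside both segment intervals")
  if (any(seg != scans$segment))
    stop("scan time outside its labelled segment interval")
  if (any(scans$event == "IS" & scans$segment != 1L))
    stop("IS events are only valid in segment 1")
  if (any(scans$event %in% c("Ri", "Pis") & scans$segment != 2L))
    stop("Ri/Pis events are only valid in segment 2")
  ev2 <- scans$event[scans$segment == 2L]
  if (length(ev2) > 1L && any(ev2[-1] == ev2[-length(ev2)]))
    stop("segment-2 events must strictly alternate Ri and Pis")
  structure(list(scans = scans, segment_bounds = segment_bounds),
            class = "event_chromatogram")
}

#' @export
print.event_chromatogram <- function(x, ...) {
  tab <- table(x$scans$event)
  cat(sprintf("event chromatogram: %d scans (%s), %.2f-%.2f min\n",
              nrow(x$scans),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
              min(x$scans$time_min), max(x$scans$time_min)))
  invisible(x)
}

chromatogram_ion_mz <- function(chrom) {
  nm <- setdiff(names(chrom$scans), c("time_min", "segment", "event"))
  stats::setNames(suppressWarnings(as.numeric(nm)), nm)
}

#' Read an event chromatogram from CSV
#'
#' @param path CSV with columns `time_min`, `segment`, `event` and one
#'   column per ion m/z.
#' @param config a [run_config()] supplying the segment bounds the scan
#'   labels are validated against.
#' @return an [event_chromatogram()].
#' @export
read_chromatogram_csv <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  event_chromatogram(df, segment_bounds = config$segment_bounds)
}

#' Write an event chromatogram to CSV
#' @param chrom an [event_chromatogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(chrom$scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
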