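test_that("ratio table built from pure runs reproduces the ELF pair", {
  tab <- build_ratio_table(make_pure_runs(n_reps = 3), ri_mz = 604)
  expect_setequal(tab$pi_mz, c(392, 384, 366, 279, 253, 221))
  expect_equal(tab$isomers, c("ELF94", "ELF96"))
  i <- match(elf_tab$pi_mz, tab$pi_mz)
  expect_equal(tab$mean_ratio[i, ], elf_tab$mean_ratio, ignore_attr = TRUE)
  expect_true(all(tab$sd_ratio == 0))   # identical replicates
})

test_that("inclusion threshold and canonical ordering are applied", {
  runs <- make_pure_runs(n_reps = 1)
  # a trace ion below 5% relative abundance in both spectra is dropped
  for (iso in names(runs))
    runs[[iso]][[1]]$pi_abundances <- c(runs[[iso]][[1]]$pi_abundances,
                                        "150" = 1)
  tab <- build_ratio_table(runs, inclusion_threshold_pct = 5, ri_mz = 604)
  expect_false(150 %in% tab$pi_mz)
  expect_length(tab$pi_mz, 6)
  # rows sorted by descending ratio of the first isomer, ties by m/z
  r1 <- tab$mean_ratio[, 1]
  expect_true(all(diff(r1) <= 0))
  # single replicate -> zero SDs
  expect_true(all(tab$sd_ratio == 0))
  # impossible threshold -> validation error
  expect_error(build_ratio_table(runs, inclusion_threshold_pct = 101),
               "threshold")
})

test_that("measured ratios divide product by reference abundances", {
  v <- measure_ratios(1000, c("221" = 380, "392" = 10))
  expect_equal(v$ratios, c(0.38, 0.01))
  expect_true(v$defined)
  expect_equal(measure_ratios(1000, c("221" = 0, "392" = 0))$ratios, c(0, 0))
  v0 <- measure_ratios(0, c("221" = 380))
  expect_false(v0$defined)
  expect_true(all(is.na(v0$ratios)))
})

test_that("noise-free mixtures of pure columns are recovered exactly", {
  A <- elf_tab$mean_ratio[, 1]; B <- elf_tab$mean_ratio[, 2]
  for (alpha in seq(0, 1, by = 0.1)) {
    res <- solve_mixture(elf_tab, alpha * A + (1 - alpha) * B)
    expect_equal(unname(res$fractions), c(alpha, 1 - alpha),
                 tolerance = 1e-9)
    expect_lt(res$residual_ss, 1e-18)
  }
})

test_that("the spec'd 50/50 measured vector is the Table-ordered column mean", {
  r <- 0.5 * elf_tab$mean_ratio[, 1] + 0.5 * elf_tab$mean_ratio[, 2]
  expect_equal(unname(r), c(0.140, 0.080, 0.100, 0.055, 0.060, 0.330))
  res <- solve_mixture(elf_tab, r)
  expect_equal(unname(res$percent), c(50, 50), tolerance = 1e-9)
})

test_that("solver modes agree on interior optima; NNLS stays nonnegative", {
  set.seed(51)
  for (i in 1:20) {
    f_true <- runif(2, 0.2, 0.9)
    r <- as.numeric(elf_tab$mean_ratio %*% f_true) + rnorm(6, 0, 0.01)
    r <- pmax(r, 0)
    nn <- solve_mixture(elf_tab, r, solver = "nonnegative")
    un <- solve_mixture(elf_tab, r, solver = "unconstrained")
    expect_true(all(nn$fractions >= 0))
    if (all(un$fractions >= 0))
      expect_equal(nn$fractions, un$fractions, tolerance = 1e-8)
    expect_gte(nn$residual_ss, un$residual_ss - 1e-12)
  }
})

test_that("indistinguishable isomer columns raise a degenerate-system error", {
  m <- cbind(elf_tab$mean_ratio[, 1], elf_tab$mean_ratio[, 1])
  tab <- ratio_table(c("X", "Y"), elf_tab$pi_mz, m, ri_mz = 604)
  expect_error(solve_mixture(tab, m[, 1]), "X vs Y")
})

test_that("measured vectors are reindexed onto the table order by m/z", {
  # same ratios supplied in scrambled ion order
  v <- measure_ratios(1000, stats::setNames(
    1000 * elf_tab$mean_ratio[c(3, 1, 6, 2, 5, 4), 1],
    sprintf("%g", elf_tab$pi_mz[c(3, 1, 6, 2, 5, 4)])))
  res <- solve_mixture(elf_tab, v)
  expect_equal(unname(res$percent), c(100, 0), tolerance = 1e-9)
})

test_that("grid-search oracle agrees with the least-squares solver", {
  set.seed(52)
  for (i in 1:25) {
    f_true <- runif(2, 0, 1)
    r <- pmax(0, as.numeric(elf_tab$mean_ratio %*% f_true) + rnorm(6, 0, 0.01))
    ls <- solve_mixture(elf_tab, r)
    bf <- brute_force_mixture(elf_tab, r, grid_step = 0.005)
    expect_lt(max(abs(ls$fractions - bf$fractions)), 0.005 + 1e-9)
    expect_lte(bf$residual_ss - ls$residual_ss, 1e-4)
  }
  # zero vector -> zero fractions
  bf0 <- brute_force_mixture(elf_tab, rep(0, 6))
  expect_equal(unname(bf0$fractions), c(0, 0))
})

test_that("fraction scatter under ratio noise matches linear-model theory", {
  reps <- gen_mixture_ratios(elf_tab, c(0.5, 0.5), noise_sd = 0.01,
                             n_replicates = 1000, seed = 53)
  fr <- t(vapply(reps, function(v) solve_mixture(elf_tab, v)$fractions,
                 numeric(2)))
  # per-replicate scatter follows sigma * sqrt(diag((M'M)^-1))
  M <- elf_tab$mean_ratio
  sd_theory <- 0.01 * sqrt(diag(solve(crossprod(M))))
  expect_equal(unname(apply(fr, 2, sd)), unname(sd_theory), tolerance = 0.1)
  expect_equal(colMeans(fr), c(ELF94 = 0.5, ELF96 = 0.5), tolerance = 0.01)
  # six-replicate means reach the 1-2% uncertainty of the validation study
  means6 <- colMeans(matrix(fr[1:996, 1], nrow = 6))
  expect_lt(sd(means6), 0.02)
})

test_that("peak-area deconvolution splits the Ri area by composition", {
  chrom <- gen_chromatogram(elf_tab, c(0.5, 0.5), seed = 54)
  dp <- deconvolve_peak(chrom, elf_tab, c(4, 6))
  expect_equal(unname(dp$result$percent), c(50, 50), tolerance = 1e-6)
  expect_equal(unname(dp$assigned_area), rep(dp$ri_area / 2, 2),
               tolerance = 1e-6)
  # pure run -> full assignment to the present isomer
  chrom96 <- gen_chromatogram(elf_tab, c(0, 1), seed = 55)
  dp96 <- deconvolve_peak(chrom96, elf_tab, c(4, 6))
  expect_equal(unname(dp96$result$percent), c(0, 100), tolerance = 1e-6)
  expect_equal(unname(dp96$assigned_area),
               c(0, dp96$ri_area), tolerance = 1e-6)
  # bounds with no scans -> error
  expect_error(deconvolve_peak(chrom, elf_tab, c(9.9, 9.91)), "scans")
})

test_that("internal-standard-only runs report no analyte scans", {
  chrom <- gen_chromatogram(elf_tab, c(0, 0), seed = 56)
  expect_error(deconvolve_peak(chrom, elf_tab, c(4, 6)), "no analyte scans")
  expect_error(deconvolve_scanwise(chrom, elf_tab), "no Ri scans")
})

test_that("scan-by-scan profiles conserve the interpolated Ri trace", {
  chrom <- gen_chromatogram(elf_tab, c(0.5, 0.5), noise_cv = 0.02, seed = 57)
  prof <- deconvolve_scanwise(chrom, elf_tab)
  ok <- !is.na(prof$ELF94)
  expect_gt(sum(ok), 100)
  expect_equal(prof$ELF94[ok] + prof$ELF96[ok], prof$ri_interpolated[ok],
               tolerance = 1e-9)
})

test_that("noise-free equimolar runs reconstruct two identical profiles", {
  chrom <- gen_chromatogram(elf_tab, c(0.5, 0.5), seed = 58)
  prof <- deconvolve_scanwise(chrom, elf_tab)
  expect_equal(prof$ELF94, prof$ELF96, tolerance = 1e-6)
  a94 <- integrate_peak(prof$time_min, prof$ELF94, c(4, 6))
  a96 <- integrate_peak(prof$time_min, prof$ELF96, c(4, 6))
  expect_equal(a94, a96, tolerance = 1e-6)
})

test_that("a single-isomer run reconstructs a flat absent-isomer profile", {
  chrom <- gen_chromatogram(elf_tab, c(1, 0), seed = 59)
  prof <- deconvolve_scanwise(chrom, elf_tab)
  keep <- prof$ri_interpolated > 1e-6   # numerically meaningful scans
  expect_true(all(abs(prof$ELF96[keep]) <=
                    1e-6 * max(prof$ri_interpolated)))
})

test_that("ratio table CSV writer/reader round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratio_table_csv(elf_tab, path)
  back <- read_ratio_table_csv(path)
  expect_equal(back$mean_ratio, elf_tab$mean_ratio, tolerance = 1e-9)
  expect_equal(back$pi_mz, elf_tab$pi_mz)
  expect_equal(back$ri_mz, elf_tab$ri_mz)
})
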