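test_that("survival yield and product-ion formation arithmetic", {
  expect_equal(compute_sy(75, c(20, 5)), 75)
  expect_equal(compute_pif(75, c(20, 5)), 25)
  expect_equal(compute_sy(50, c(25, 25)), 50)  # the SY/PiF crossing value
  expect_equal(compute_sy(100, numeric(0)), 100)
  expect_equal(compute_pif(0, 10), 100)
  expect_true(is.na(compute_sy(0, c(0, 0))))
  expect_true(is.na(compute_pif(0, 0)))
})

test_that("SY + PiF = 100 at every point with positive total signal", {
  ds <- gen_erms(noise_cv = 0.1, seed = 31)
  prof <- build_energy_profile(ds)
  expect_equal(prof$points$sy_pct + prof$points$pif_pct,
               rep(100, nrow(prof$points)))
  expect_true(all(prof$points$sy_pct >= 0 & prof$points$sy_pct <= 100))
})

test_that("precursor-ion max averages the pre-activation steps", {
  prods <- rbind(0, 0, 0, c(50, 50), c(80, 80))
  colnames(prods) <- c("221", "366")
  ds <- erms_dataset(c(0, 5, 10, 30, 50), c(100, 102, 98, 60, 20), prods,
                     604, 50)
  expect_equal(estimate_precursor_max(ds), 100)
  # all steps fragmenting -> fallback to the lowest-amplitude step
  prods2 <- matrix(50, 3, 1, dimnames = list(NULL, "221"))
  ds2 <- erms_dataset(c(0, 25, 50), c(90, 60, 20), prods2, 604, 50)
  expect_warning(pm <- estimate_precursor_max(ds2), "falling back")
  expect_equal(pm, 90)
  # threshold 0 with an exact-zero PiF plateau -> mean of the plateau
  ds3 <- gen_erms(noise_cv = 0, seed = 32)
  tr <- attr(ds3, "truth")
  plateau_steps <- ds3$exa <= tr$onset
  expect_equal(estimate_precursor_max(ds3, activation_threshold_pct = 0),
               mean(tr$precursor_clean[plateau_steps]))
})

test_that("energy profile recovers the generating logistic midpoint", {
  ds <- gen_erms(sy_midpoint = 30, sy_width = 3, noise_cv = 0,
                 exa = seq(0, 50, by = 1))
  prof <- build_energy_profile(ds)
  # linear interpolation on a 1 a.u. grid: midpoint recovered to grid error
  expect_equal(prof$sy_exa50, 30, tolerance = 1e-3)
  # SY equals the generating logistic at fragmentation-active points
  tr <- attr(ds, "truth")
  act <- prof$points$exa > tr$onset
  expect_equal(prof$points$sy_pct[act],
               100 * plogis((30 - prof$points$exa[act]) / 3),
               tolerance = 1e-12)
})

test_that("interpolated sy_exa50 matches brute-force search on a fine grid", {
  for (seed in c(41, 42)) {
    ds <- gen_erms(sy_midpoint = 25 + seed %% 7, sy_width = 2.5,
                   noise_cv = 0.03, seed = seed)
    prof <- build_energy_profile(ds)
    fine <- seq(min(prof$points$exa), max(prof$points$exa),
                length.out = 1000 * nrow(prof$points))
    sy_fine <- approx(prof$points$exa, prof$points$sy_pct, xout = fine)$y
    cross <- which(diff(sign(sy_fine - 50)) != 0)[1]
    best <- fine[which.min(abs(sy_fine[cross + 0:1] - 50)) + cross - 1]
    expect_lt(abs(prof$sy_exa50 - best), 2 * (fine[2] - fine[1]))
  }
})

test_that("PiY maximum and its amplitude are read off the grid", {
  # ramp built so summed products peak at 78.9% of the precursor plateau
  # at ExA 35, mirroring the measured CID-efficiency optimum
  exa <- seq(0, 50, by = 5)
  piy_frac <- c(0, 0, 0, 0, 0.10, 0.40, 0.70, 0.789, 0.75, 0.72, 0.70)
  prec <- c(100, 100, 100, 100, 70, 45, 25, 10, 5, 3, 2)
  prods <- matrix(100 * piy_frac, ncol = 1, dimnames = list(NULL, "221"))
  ds <- erms_dataset(exa, prec, prods, 604, 50)
  prof <- build_energy_profile(ds)
  expect_equal(prof$precursor_ion_max, 100)
  expect_equal(prof$piy_max_pct, 78.9)
  expect_equal(prof$exa_max, 35)
})

test_that("PiY ties resolve to the lowest amplitude", {
  prods <- matrix(c(0, 0, 50, 50), ncol = 1, dimnames = list(NULL, "221"))
  ds <- erms_dataset(c(0, 10, 30, 40), c(100, 100, 40, 40), prods, 604, 50)
  prof <- build_energy_profile(ds)
  expect_equal(prof$exa_max, 30)
})

test_that("non-fragmenting ramp has zero PiY and no SY crossing", {
  prods <- matrix(0, 4, 1, dimnames = list(NULL, "221"))
  ds <- erms_dataset(c(0, 10, 30, 50), c(100, 101, 99, 100), prods, 604, 50)
  prof <- build_energy_profile(ds)
  expect_true(all(prof$points$piy_pct == 0))
  expect_true(is.na(prof$sy_exa50))
})

test_that("breakdown curves match generator truth on noise-free ramps", {
  ds <- gen_erms(noise_cv = 0, ejection_loss_fraction = 0.1)
  tr <- attr(ds, "truth")
  bc <- build_breakdown_curves(ds, activation_threshold_pct = 0)
  pmax_ <- mean(tr$precursor_clean[ds$exa <= tr$onset])
  for (ion in colnames(tr$products_clean))
    expect_equal(bc$yield_pct[, ion], 100 * tr$products_clean[, ion] / pmax_,
                 tolerance = 1e-9)
  # summed product yields reproduce the PiY curve
  prof <- build_energy_profile(ds, activation_threshold_pct = 0)
  prod_cols <- setdiff(colnames(bc$yield_pct), "604")
  expect_equal(rowSums(bc$yield_pct[, prod_cols]), prof$points$piy_pct,
               tolerance = 1e-9)
})

test_that("precursor ejection depresses PiY below PiF after activation", {
  ds <- gen_erms(ejection_loss_fraction = 0.2, noise_cv = 0)
  prof <- build_energy_profile(ds)
  post <- prof$points$pif_pct > 5
  expect_true(all(prof$points$piy_pct[post] < prof$points$pif_pct[post]))
  # and without loss PiY never exceeds 100
  prof0 <- build_energy_profile(gen_erms(noise_cv = 0))
  expect_true(all(prof0$points$piy_pct <= 100 + 1e-9))
})

test_that("sy_exa50 falls with excitation time on an exponential family", {
  exts <- c(10, 25, 50, 100)
  mids <- 15 + 25 * exp(-0.02 * exts)
  profiles <- lapply(seq_along(exts), function(i)
    build_energy_profile(gen_erms(sy_midpoint = mids[i], ext_ms = exts[i])))
  tab <- compare_sy_exa50_vs_ext(profiles)
  expect_equal(tab$ext_ms, exts)
  expect_true(all(diff(tab$sy_exa50) < 0))
  expect_equal(tab$sy_exa50, mids, tolerance = 1e-2)
  expect_equal(tab$diff_from_prev[-1], diff(tab$sy_exa50))
  # identical profiles at different labels -> zero difference
  p1 <- build_energy_profile(gen_erms(ext_ms = 10))
  p2 <- build_energy_profile(gen_erms(ext_ms = 25))
  expect_equal(compare_sy_exa50_vs_ext(list(p1, p2))$diff_from_prev[2], 0)
  # duplicate excitation times are rejected
  expect_error(compare_sy_exa50_vs_ext(list(p1, p1)), "distinct")
})
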