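# Shared fixtures built in code.

# Characteristic Pi/Ri ratios of the ELF94/ELF96 pure standards
# (six product ions against the precursor reference ion at m/z 604).
elf_tab <- elf_ratio_table()

# Pure-isomer replicate runs whose Pi/Ri ratios reproduce the ELF pair's
# characteristic table exactly (Ri fixed at `ri` counts).
make_pure_runs <- function(table = elf_tab, ri = 1000, n_reps = 2) {
  runs <- lapply(seq_along(table$isomers), function(j) {
    lapply(seq_len(n_reps), function(k)
      list(ri_abundance = ri,
           pi_abundances = stats::setNames(ri * table$mean_ratio[, j],
                                           sprintf("%g", table$pi_mz))))
  })
  names(runs) <- table$isomers
  runs
}

# Random small ERMS dataset for round-trip property tests.
random_erms <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  exa <- sort(sample(seq(0, 50, by = 0.5), n))
  prods <- matrix(runif(n * 3, 0, 1e4), n,
                  dimnames = list(NULL, c("221", "366", "392")))
  erms_dataset(exa, runif(n, 0, 1e5), prods, precursor_mz = 604, ext_ms = 50)
}
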