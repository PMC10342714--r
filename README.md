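# ledams

Isomer recognition and quantitation in ion-trap HPLC–MS/MS without
chromatographic separation.

## The problem

Positional isomers share the same elemental composition, molecular weight
and — often — the same product ions, so they cannot be told apart by a
single MS/MS transition, and resolving them chromatographically can cost
more method-development time than it is worth. An alternative is to let
the isomers co-elute and separate their signals *mathematically*: acquire
full product-ion scans over the unresolved peak and deconvolve the mixed
spectrum against the characteristic fragmentation fingerprints of the
pure compounds.

`ledams` implements this workflow for ion-trap (IT) instruments, where
tandem MS runs "in time" in a single trapping region and the collision
energy is controlled by an excitation amplitude (ExA) applied for an
excitation time (ExT). The package covers:

* **ERMS energetics** — survival-yield (SY), product-ion-formation (PiF)
  and product-ion-yield (PiY) curves from an energy-resolved MS/MS ramp,
  with the summary statistics SY_ExA50 (amplitude at 50% precursor
  survival), PiY_max and ExA_max used to pick MS/MS conditions.
* **Linear-equation deconvolution** of co-eluting isomer signals, in
  peak-area and scan-by-scan modes.
* **Internal-standard quantitation** — peak-area ratios, calibration
  curves, LOD/LOQ, and validation plots scoring deconvolution accuracy
  and precision.
* **First-order plasma-stability kinetics** — degradation rate constants
  and half-lives with the `>120 min` reporting rule for slow kinetics.
* A **seeded synthetic-data generator** for every input above, so the
  whole pipeline is testable without instrument data.

## The core model

Each selected product ion Pi is referenced to a shared reference ion Ri
(the unfragmented precursor acquired in a dedicated low-energy MS/MS
event). For a sample containing `n` isomers, every measured ratio is a
composition-weighted combination of the pure compounds' characteristic
ratios:

    (Pi/Ri)_m = sum_x (Pi/Ri)_x * f_x ,   x = 1..n

where `(Pi/Ri)_x` are the characteristic ratios of pure isomer `x`
(measured on standards) and `f_x` its fraction ("ratio purity") in the
sample. With more product ions than isomers — the shipped ELF94/ELF96
table has six ions for two isomers — the system is overdetermined and is
solved by (by default nonnegative) least squares. The fractions are
deliberately *not* forced to sum to one: an unknown co-eluting
contributor shows up as a residual instead of being silently absorbed.

ERMS curves follow

    SY(%)  = 100 * prec / (prec + sum(Pis))
    PiF(%) = 100 * sum(Pis) / (prec + sum(Pis))
    PiY(%) = 100 * sum(Pis) / precursor_ion_max

with `precursor_ion_max` the mean precursor signal before fragmentation
channels activate; PiY — unlike PiF — is depressed by precursor ejection
and low-mass cut-off losses and therefore measures true CID efficiency.
Degradation kinetics use `ln C = ln C0 + k t`, with half-life
`t_1/2 = ln(0.5)/k`, reported as `>120` whenever `|k| < 0.006` or the
computed half-life exceeds the 120-min incubation horizon.

## Worked example

```r
library(ledams)

tab <- elf_ratio_table()      # six Pi/Ri equations for ELF94/ELF96
tab
#> characteristic ratio table: 6 Pi/Ri equations x 2 isomers (Ri m/z 604)
#>         ELF94 ELF96
#> 392/604  0.01  0.27
#> 384/604  0.09  0.07
#> 366/604  0.19  0.01
#> 279/604  0.10  0.01
#> 253/604  0.01  0.11
#> 221/604  0.38  0.28

# a noise-free 90:10 mixture vector deconvolves exactly
solve_mixture(tab, 0.9 * tab$mean_ratio[, 1] + 0.1 * tab$mean_ratio[, 2])
#> deconvolution (nonnegative solver): ELF94 90.00%, ELF96 10.00%; residual SS 1.008e-32

# a full synthetic equimolar co-elution run, deconvolved from peak areas
chrom <- gen_chromatogram(tab, c(0.5, 0.5), noise_cv = 0.02, seed = 11)
dp <- deconvolve_peak(chrom, tab, c(4, 6))
dp$result
#> deconvolution (nonnegative solver): ELF94 49.78%, ELF96 49.94%; residual SS 3.669e-08
dp$assigned_area                  # dp$ri_area = 502975.7, conserved
#>    ELF94    ELF96
#> 251089.0 251886.7

# plasma-stability panel: a hydrolysed substrate and a stable isomer
panel <- gen_degradation_panel(c(ELF94 = -0.021, ELF96 = 0),
                               cv = 0.05, seed = 11)
panel_report(suppressWarnings(analyze_stability_panel(panel)))
#>   compound             k       k_2sd t_half t_half_2sd r_squared  n
#> 1    ELF94 -0.0209968825 0.000641057     33   1.007888 0.9976751 12
#> 2    ELF96  0.0002489191 0.000412743   >120         NA 0.1270070 12
```

The 90/10 mixture is recognised at its prepared composition; in the
noisy run the assigned percentages stay within a fraction of a percent
of the 50/50 truth; and the kinetics fit recovers the simulated rate
constant (−0.021 ln(µM)/min, half-life ≈ 33 min) while the stable isomer
is correctly reported beyond the incubation horizon.

A command-line wrapper is available for shell use:

```sh
Rscript exec/ledams simulate --scenario run --out run.csv --seed 7
Rscript exec/ledams deconv --in run.csv --table ratios.csv --mode scan --out profiles.csv
```

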