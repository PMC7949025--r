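# pntbiophys

Biophysical characterization of protein self-association interfaces, built
around the SAM-family **PNT (pointed) domain** — a compact helical bundle
that polymerizes head-to-tail through two complementary flat surfaces (the
mid-loop *ML* and end-helix *EH* faces). The package is aimed at structural
biologists and biophysicists who map such interfaces with solution NMR,
surface plasmon resonance (SPR) and molecular-dynamics trajectories, and who
want the whole analysis chain as tested, scriptable R instead of instrument
vendor wizards. The built-in defaults describe the ETV6 PNT domain construct
(residues 40–125, helices H1 63–76, H2 91–94, H3 99–105, H4 110–122), whose
monomerizing variants (A93D on the ML face, V112E/R on the EH face) form a
well-defined heterodimer.

## What it computes

**Chemical shift perturbation (CSP) mapping.** Combined amide perturbations
between free and bound states,

  Δδ = √( (Δδ_H)² + (0.14 Δδ_N)² )  [ppm],

with interface residues flagged strictly above a 0.2 ppm cutoff and overlap
statistics against an interface annotation.

**Amide hydrogen exchange (HX).** Per-residue exchange decays
I_t = I₀ e^(−k_obs t) fitted from serial ¹⁵N-HSQC intensities; intrinsic
random-coil rates k_pred predicted from poly-DL-alanine reference chemistry
with neighbor, terminal, temperature and pH corrections; protection factors
PF = k_pred / k_obs and residue free energies
ΔG_HX = 2.303 · R · T · log₁₀(PF). Amides gone before the first spectrum are
censored with an upper bound on log PF; amides that never decay get a lower
bound equal to the largest measured log PF of the sample.

**SPR 1:1 kinetics and alanine scanning.** Closed-form Langmuir sensorgrams
(association R(t) = R_eq(1 − e^−(k_on C + k_off)t), dissociation
R(t) = R(t_a) e^−k_off(t−t_a)), global (k_on, k_off, R_max) fits across a
concentration series, K_D = k_off/k_on with propagated errors,
ΔΔG = RT ln(K_D,mut / K_D,ref), and hot-spot classification at
ΔΔG > 6 kJ/mol. The fitted kinetic tables for the 18 EH-face and 14 ML-face
alanine mutations ship with the package (`etv6_scan_tables()`).

**Trajectory statistics.** Kabsch superposition, backbone RMSD series over
the core (residues 57–120) or full construct, per-residue all-atom RMSF,
ΔRMSF between heterodimer chains classified at ±0.3 Å, principal component
analysis of the fluctuation covariance, and backbone hydrogen-bond
persistence (amide N within 3.5 Å trajectory-mean distance of a carbonyl O)
for comparison with HX protection.

**Synthetic data.** Deterministic generators for every input kind — ideal
α-helix bundles, Gaussian-fluctuation trajectories, serial-spectra exchange
decays on a realistic acquisition schedule, and noisy sensorgram series —
each returning its ground truth for parameter-recovery studies.

## Worked example

Simulate a five-concentration SPR series at the reference kinetics of the
unmutated interface and fit it globally, then classify the EH-face alanine
scan:

```r
library(pntbiophys)

tg <- seq(0, 900, by = 2)
concs <- c(0.2, 2, 20, 40, 60) * 1e-9
set.seed(1)
sens <- do.call(rbind, lapply(concs, function(C)
  simulate_sensorgram(2.0e5, 1.5e-3, R_max = 100, C = C, t_grid = tg,
                      t_a = 300, noise_sd = 1)))
attr(sens, "t_a") <- 300
fit_spr_global(sens)
#> <spr_fit> 1:1 Langmuir global fit (5 concentrations)
#>   k_on  = 2.01e+05 +/- 6.1e+02 M^-1 s^-1
#>   k_off = 0.0015 +/- 3.1e-06 s^-1
#>   R_max = 99.9 RU
#>   K_D   = 7.49 +/- 0.028 nM   (RMS residual 1 RU)

tab <- etv6_scan_tables()$EH
scan <- classify_scan(data.frame(mutation = tab$mutation, kd = tab$kd_nM))
head(scan[scan$mutation != "None",
          c("mutation", "kd", "ddG", "hotspot", "fold_category")], 8)
#>   mutation    kd    ddG hotspot fold_category
#> 2     S47A   6.9 -0.207   FALSE           ~1x
#> 3     I48A  12.0  1.165   FALSE           ~1x
#> 4     E76A   9.9  0.688   FALSE           ~1x
#> 5     F77A 450.0 10.149    TRUE         ~100x
#> 6     S78A   3.3 -2.035   FALSE           ~1x
#> 7     L79A 200.0  8.139    TRUE          ~10x
#> 8     R80A  32.0  3.596   FALSE          ~10x
#> 9     K99A 930.0 11.949    TRUE         ~100x
attr(scan, "n_hotspots")
#> [1] 6
```

The fit recovers the simulated rate constants within their standard errors
and reproduces the 7.5 nM reference K_D; the scan flags 6 of the 18 EH-face
mutations as hot spots (ΔΔG > 6 kJ/mol), with K99A's salt-bridge removal
costing ~12 kJ/mol (a ~100-fold loss of affinity).

A thin command-line wrapper over the staged runner lives at
`inst/cli/pnt-workbench.R`
(`Rscript pnt-workbench.R simulate kind=hx seed=1 --out runs/hx`).

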