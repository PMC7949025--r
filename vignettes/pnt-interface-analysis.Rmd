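---
title: "Methods: biophysical interface analysis of PNT domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical interface analysis of PNT domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pntbiophys)
```

This vignette documents the models behind each analysis stage, the default
parameters and why they were chosen, what the synthetic-data generators do
and do not emulate, and the numerical decisions a maintainer would want
recorded. The running example is the ETV6 PNT domain construct (residues
40–125): a SAM-family helical bundle whose head-to-tail polymerization
through complementary mid-loop (ML) and end-helix (EH) surfaces can be
dissected with monomerizing point mutations.

## Construct model

All stages join on author residue numbering (40–125); nothing is ever
re-indexed. Helix boundaries default to H1 63–76, H2 91–94, H3 99–105,
H4 110–122 (`etv6_helices()`), and the two interface annotations default to
the alanine-scanned residue sets (18 EH, 14 ML; `etv6_interfaces()`).

`etv6_construct()` supplies a *synthetic stand-in* sequence: roughly fifty
of the 86 positions are pinned to the residue identities fixed by the
described mutation sites, helices and interface residues; the remainder
carry a fixed generic filler pattern. It is not the database ETV6 sequence
and is used only to give the intrinsic-rate and geometry generators a
concrete context. Analyses of real data should pass the real sequence.

PDB I/O is delegated to `bio3d`; the package's reader adds a validation
pass so malformed ATOM records fail with a line number, keeps the first
alternate location, rejects insertion codes (absent from the target
structures), and returns the first model of multi-model files. Which chain
of a heterodimer plays which role (e.g. the A93D-like subunit) is supplied
by the caller, never inferred from sequence.

## Chemical shift perturbations

The combined amide CSP is `sqrt(dH^2 + (0.14 * dN)^2)` ppm, the standard
weighting that scales the ¹⁵N dimension to a comparable ppm range.
Differences are taken bound − free; the combined value is sign-invariant,
but signed components are kept for diagnostics. Residues assigned in only
one state are reported with a `missing` flag rather than dropped, because
real spectra of the free and bound species are often recorded at slightly
different pH and lose assignments asymmetrically. No pH correction is
applied to the shifts; the pH of each state is carried as metadata instead.
Interface classification uses a strict `> 0.2` ppm rule — a value of
exactly 0.2 is background.

## Amide hydrogen exchange

### Intrinsic rates

`predict_intrinsic_rates()` implements the poly-DL-alanine reference
scheme: for the amide of residue *i*,

`k_pred = kA·10^(−pD)·FA + kB·10^(pD − pK_ion)·FB + kW·FB`

with the acid factor `FA` combining the "left" factor of residue *i* and
the "right" factor of residue *i − 1* (base/water terms analogous, the
water term reusing the base factors), extra right/left factors for the
N-terminal ammonium and C-terminal carboxylate, and per-term Arrhenius
corrections from the 293 K reference (activation energies 14, 17 and
19 kcal/mol for acid, base and water catalysis). Reference rates for
protium-out exchange into D₂O are log₁₀ kA = 1.62, log₁₀ kB = 10.05,
log₁₀ kW = −1.5 (min⁻¹ units, molar for the catalyzed terms) with
pK_ion = 15.05; a deuterium-out variant is provided. Ionizable side chains
(Asp, Glu, His) mix their protonated and deprotonated factors by
Henderson–Hasselbalch weighting at the sample pD (pK 4.48, 4.93, 7.42).
The first residue (free α-amine) and prolines (no amide NH) get no
prediction.

pH handling: the meter reading of a D₂O sample (pH\*) is used *uncorrected*
by default, because that is how such readings are conventionally reported;
the fixed +0.4 glass-electrode correction is available as `pD_correction`
but off by default.

### Decay fitting and censoring

Observed rates come from unweighted nonlinear least squares on
`I0 * exp(-k * t)` (no weighting scheme is assumed for peak intensities;
`minpack.lm` supplies the optimizer). Intensities are scaled by the number
of acquisitions per spectrum, a linear-detector assumption.

Censoring is where most of the numerical care sits:

* **Noise floor.** 3× the robust noise scale of the late-time points,
  estimated from successive differences (MAD/√2) so a residual slow decay
  through the tail does not inflate the estimate. It is configurable for
  data with a known spectral noise level.
* **Fast limit.** An exponential decay is maximal at the first spectrum, so
  a series whose first point is at baseline — or with fewer than three
  points above the floor, or whose *fitted* curve is already within 3× the
  floor at the first observation time — cannot be quantified and is
  censored as `fast_limit`. Its upper bound on log PF is
  `log10(k_pred * t_first / ln(I0/I_noise))` with a default detection ratio
  of 20; this reconstruction of the "gone before the first spectrum" limit
  lands near log PF ≈ 3 for typical intrinsic rates and a ~5 min dead time.
* **Slow limit.** A fitted total decay `k * t_last` below 0.2 over the
  observation window is not significant; such amides are censored as
  `slow_limit` with a lower bound equal to the largest measured log PF in
  the same sample — a heuristic bound, so it is guaranteed conservative
  only for true non-exchangers.

Free energies use ΔG_HX = 2.303·R·T·log₁₀(PF) with R = 8.314 J mol⁻¹ K⁻¹
and a default conversion temperature of 298.15 K even though exchange is
typically run near 294 K; 298.15 K is the convention that makes
log PF = 8.5 correspond to ≈48.5 kJ/mol and log PF = 7 to ≈40 kJ/mol, and
both temperatures are explicit arguments. A measured rate more than 10×
the intrinsic prediction triggers a "super-intrinsic" warning (usually a
mis-assignment).

## SPR kinetics and alanine scanning

The binding model is the plain 1:1 Langmuir interaction: association
`R(t) = R_eq (1 − e^{−(k_on C + k_off) t})` with
`R_eq = R_max C/(C + K_D)`, dissociation `R(t_a) e^{−k_off (t − t_a)}`.
Mass-transport limitation, bulk refractive-index jumps and surface
heterogeneity are deliberately not modeled; `R_max` is shared across the
concentration series (single-surface assumption). Global fits return
standard errors from the covariance matrix; `K_D = k_off/k_on` exactly
(never independently fit), with relative errors combined in quadrature —
the propagation rule is a reconstruction, stated here because printed
standard errors in kinetic tables rarely document it.

ΔΔG = RT ln(K_D,mut/K_D,ref) at 298.15 K (experiments at 25 °C); a mutant
is a hot spot when ΔΔG strictly exceeds 6 kJ/mol. Fold categories snap the
K_D ratio to the nearest decade on a log₁₀ scale (~1×, ~10×, ~100×,
~1000×). The shipped kinetic tables reproduce their printed ΔΔG columns
from the printed K_D values within ±0.08 kJ/mol, so rounding of the
printed K_D fully accounts for the residuals.

## Trajectory statistics

* **Superposition** is the Kabsch rotation (SVD with determinant
  correction); degenerate (collinear) geometry errors out.
* **RMSD series** superpose each frame on frame 1 over the selection;
  the default core selection (backbone, residues 57–120) excludes the
  flexible N-terminal (47–56) and C-terminal (121–123) segments whose
  motions otherwise dominate.
* **RMSF** aligns frames to the time-averaged structure in two passes
  (first to frame 1, then to the resulting mean — the reference is
  otherwise arbitrary and this is stable under frame ordering), then
  averages per-atom `sqrt(<|r − <r>|²>)` over each residue's atoms with no
  mass weighting (heavy-atom, unweighted is the common reporting choice;
  the alternative was genuinely open).
* **ΔRMSF** between paired chains is classified at a symmetric ±0.3 Å
  threshold; for a heterodimer with chain *a* the V112R-like and chain *b*
  the A93D-like subunit, values above +0.3 Å mean rigidification of the
  A93D-like chain.
* **PCA** eigen-decomposes the covariance of the aligned, flattened
  selection coordinates (backbone of the core by default; the atom
  selection is an argument because conventions differ). Variance fractions
  sum to one by construction.
* **Hydrogen-bond persistence**: for every amide nitrogen (prolines and
  chain-initial residues excluded) the two carbonyl oxygens with the
  smallest *trajectory-mean* N···O distance are the candidates, excluding
  residues *i* and *i − 1* (the preceding carbonyl is covalently adjacent;
  the exclusion is a reconstruction and is switchable). Bonded means the
  smallest mean distance is ≤ 3.5 Å — inclusive, reading "within 3.5 Å"
  inclusively. A per-frame candidate mode is available because averaging
  order is ambiguous in the usual description.

## Synthetic data: what it emulates, what it does not

The generators produce data with the *statistical structure* each stage
assumes, plus ground truth:

* `gen_helix_bundle()` builds ideal backbone geometry (φ = −57°, ψ = −47°
  in helices, extended elsewhere) by natural-extension internal
  coordinates; mid-helix amides sit ~3.1 Å from the i−4 carbonyl.
* `gen_trajectory()` adds independent per-atom Gaussian displacements with
  a per-residue σ (per component), optionally with rigid-body jitter. A
  frame interval of 100 ps mirrors a typical recording stride. Isotropic σ
  gives the closed-form RMSF √3·σ used in recovery tests.
* `gen_hx_dataset()` derives k_obs = k_pred/10^logPF from the same
  intrinsic-rate model the analysis uses and simulates the serial-spectra
  schedule (`hx_schedule()`: twelve ~5-min spectra, ~20-min spectra
  back-to-back for ~3 h, hourly for a day, intermittent to three months;
  first spectrum ~5 min after transfer). Noise is multiplicative
  (2% default) *plus* an additive baseline term (2% of I₀ default): purely
  multiplicative noise would vanish with the signal and leave nothing for
  a noise floor to measure, which real spectra never do.
* `gen_scan_dataset()` simulates full concentration series
  (0.2–60 nM default, matching a high-affinity assay; weak binders use
  20–6000 nM) at 1 RU Gaussian noise, R_max 100 RU, 300 s association,
  2 s sampling.
* The default truth profile for exchange (`default_logpf_profile()`)
  makes the disordered tails fully unprotected (log PF 0 outside residues
  60–122), loops at most modestly protected (uniform 0–1.5), helices
  measurably protected (uniform 3–6.5), and a core of H1/H4 residues
  non-exchanging — the qualitative profile of a very stable helical
  bundle whose unfolding free energy exceeds 40 kJ/mol.

Passing recovery tests on these fixtures demonstrates that the estimators
are unbiased and the censoring rules consistent *under the stated noise
models*. They do not demonstrate robustness to what the generators omit:
peak overlap and lineshape effects in spectra, EX1 exchange kinetics,
mass-transport or drift artifacts in sensorgrams, anharmonic or
correlated motions in trajectories, and force-field realism generally.

## Problem sizes

The test-suite and acceptance-script simulations use sizes chosen to make
sampling error comfortably smaller than the tolerances they check: 100
replicate SPR series (5 concentrations × 451 time points) at 1 RU noise;
one 84-residue exchange ladder on the 59-spectrum schedule (500 replicate
single-decay fits for the bias check); 500-frame trajectories for RMSF
recovery and 150-frame heterodimer trajectories for ΔRMSF classification;
40-frame deterministic two-mode fixtures for PCA.

## Known limitations

* The intrinsic-rate parameter set is the classic reference-table scheme;
  updated side-chain factors exist and could be added as alternative sets.
  Predictions inherit the usual ~0.2 log-unit systematic uncertainty.
* The fast/slow censoring limits are reconstructions of common practice;
  the slow bound in particular ("largest measured PF in the sample") is a
  heuristic, not a guaranteed bracket for marginally slow residues.
* The SPR model class excludes transport limitation; fitted constants from
  instruments whose wizards include such terms may differ systematically.
* Trajectory readers accept multi-model PDB only; binary trajectory
  formats would need conversion upstream.
* The construct sequence shipped as a default is a labelled synthetic
  stand-in (see above), adequate for generator context but not for
  interpreting real per-residue intrinsic rates.
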