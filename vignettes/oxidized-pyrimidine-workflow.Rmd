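---
title: "Quantifying hydroxyl-radical oxidation of 5-methylcytosine, cytosine and thymine in DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hydroxyl-radical oxidation of 5-methylcytosine, cytosine and thymine in DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrimox)
```

## The measurement problem

When dilute aqueous DNA is irradiated under oxygen, the dominant reactive
species is the hydroxyl radical. It damages pyrimidines by two routes:
addition to the 5,6-double bond, whose peroxyl-radical intermediates decay to
*glycol* (pathway I), *hydantoin* (pathway II) and *imidazolidine*
(pathway III) end products; and, for the methylated bases thymine and
5-methylcytosine (5mC), H-atom abstraction from the exocyclic methyl group,
ending in the *5-hydroxymethyl* and *5-formyl* derivatives (pathway IV).
Because 5mC marks CpG dinucleotides — mutation hotspots and carriers of
epigenetic state — the relative susceptibility of 5mC versus C, and the
spectrum of its products (5hmC and 5fC are also enzymatic demethylation
intermediates), are biologically loaded quantities.

The assay this package models measures 14 pyrimidine lesions plus 8oxoG as
2′-deoxyribonucleosides by targeted LC-MS/MS (multiple reaction monitoring)
after enzymatic digestion, with one stable-isotope-labeled internal standard
per analyte. `pyrimox` implements everything downstream of peak integration:

1. **Isotope dilution** — `amount = area_natural / area_labeled × spike`;
2. **Normalization** — lesions per 10^6 DNA bases via the UV-calibrated
   2′-deoxycytidine content of the digest and the substrate's C fraction;
3. **Deamination correction** — undoing digestion-time conversion of
   5mC-Gly→T-Gly and 5mC-Hyd→T-Hyd;
4. **Dose–response rates** — OLS fits of yield against absorbed dose,
   aggregated over independent replicate experiments;
5. **Distribution, pathway and sensitivity statistics**;
6. **Two-state van't Hoff melting analysis** of the duplex substrates.

## The analyte registry and the correction network

`analyte_registry()` declares each species' parent base, pathway class,
standard spike, and deamination link. Two conventions matter:

* The cytosine glycol and hydantoin are too unstable to survive digestion;
  they convert *quantitatively* to U-Gly and U-Hyd, which are therefore the
  reported species. These quantitative conversions appear as *virtual* edges
  (fraction 1) in `deamination_edges()` and are deliberately not
  back-corrected.
* 5ohC and 5ohU arise by dehydration of the cytosine glycol, so they are
  classified under pathway I: the cytosine glycol family is
  {U-Gly, 5ohC, 5ohU}. This matters for the glycol:hydantoin ratio.

For 5mC-Gly the default transferred fraction is the empirical 20% estimated
from internal-standard loss during digestion, not the ~6–7% that first-order
kinetics (`fraction_converted(2, 20)`) would predict from the ~20 h
nucleoside half-life and a ~2 h digestion: the empirical estimate
supersedes the kinetic one because deamination is faster in the digestion
matrix than in clean buffer. The kinetics helper remains available for
configuring other scenarios. For 5mC-Hyd only an upper bound ("below 5%") is
known; the default is the conservative 0.05, configurable in the registry.

The correction itself inverts the forward transfer exactly: with measured
parent $m_p$ and fraction $f$, the formed amount is $m_p/(1-f)$ and
$m_p f/(1-f)$ is subtracted from the measured child. Per edge the operation
conserves moles; noise-driven negative children are floored at zero with a
warning. The output is flagged and a second application is refused — the
correction is not idempotent and must run exactly once.

## Dose–response model

Yields are assumed linear in dose over the ranges used (0–200 Gy for
isolated DNA, 0–4 kGy for cells — the cellular unit is per kGy throughout).
Each replicate experiment is a full dose series fitted by OLS; the reported
rate is the mean of replicate slopes and its SD the sample SD across
replicates. The pooled-fit r² is attached as a linearity diagnostic with a
0.95 flag threshold — a flag, not a filter, because the threshold describes
the expected quality of the assay rather than a rejection rule. Intercepts
are reported because cellular DNA has genuine non-zero baselines
(constitutive 5hmC from enzymatic oxidation, endogenous 5fU, assay-induced
8oxoG); for isolated DNA an intercept near zero is a quality check.

Total damage at a parent base is the plain sum of member rates, and — by the
assay's own convention — the SD of the total is the *plain sum* of member
SDs. This is a conservative, fully-correlated propagation; the independent
-error quadrature alternative is available (`sd_mode = "quadrature"`) but
off by default so that published totals are reproduced exactly.

The scale of the isolated-DNA rate table (lesions/10^6 bases per unit
exposure) is carried as-is: every cross-substrate statistic in the package
(percentages, pathway ratios, folds) is scale-invariant, so no dose
normalization assumption is ever needed for them.

## Display conventions

Distribution percentages are reported unrounded and as the integer display
value; multi-duplex averages are means of the *display* percentages, rounded
again — this reproduces exactly how such averages are conventionally quoted
(e.g. the 9/25/9% glycol/hydantoin/imidazolidine split of 5mC over the three
methylated duplexes). In the composition analysis the exact discrepancy
`expected/observed` is returned alongside `discrepancy_printed`, the ratio
of the two folds quoted at one decimal place; both are reported because the
exact value (2.76 for the bundled calf-thymus table) and the display-derived
value (2.74 → 2.7) straddle a rounding boundary.

The 1.8-fold mean methylation sensitivity is reconstructed as the mean over
the two fully-methylated/control pairs (12-mer: ODN2:2 vs ODN1:1; 19-mer:
ODN5:6 vs ODN3:4), the hemimethylated duplex excluded. This pairing is the
only one that reproduces the published average from the rate table; it is a
documented reconstruction, not a stated protocol.

## Synthetic data: what it emulates and what it does not

`simulate_mrm_dataset()` inverts the quantification model: linear true
yields (`baseline + slope × dose`), optional forward deamination leak,
conversion to pmol against a configured DNA amount, and emission as
natural/labeled peak-area pairs. Defaults are the study conditions: isolated
DNA at 0–200 Gy with n = 3 replicates and truths equal to the bundled
reference rates; cells at 0–4 kGy with n = 5, per-kGy rates, and the
measured non-irradiated baselines.

**Noise model.** Each record carries a shared per-injection multiplicative
factor on both channels — which cancels in the area ratio, exactly the
variance the internal standard exists to cancel — plus mean-one Gaussian
noise with coefficient of variation `cv_area` on the ratio itself. We chose
ratio-level noise over *independent* multiplicative noise per channel
deliberately: independent noise on the denominator channel makes the
expected ratio `E[1/(1+cv·z)] ≈ 1 + cv²` biased upward (≈1% at cv = 0.1),
which would propagate into every yield and slope. An internal-standard
measurement is unbiased at ratio level to first order, and the
mean-one model preserves that property, which the recovery tests then
verify (200-seed z-scores ~ N(0,1)). The ratio noise is truncated at 0.01
to keep areas positive; at the default CVs the truncation is a > 6σ event
and has no measurable effect.

What the generator does *not* emulate: chromatographic peak shapes,
retention-time drift, matrix interferences, inter-batch calibration drift,
and detection-limit censoring. Passing round-trip and recovery tests
therefore demonstrates the correctness and statistical calibration of the
analysis chain, not the behaviour of the assay on real chromatograms.

The 19-mer duplex compositions bundled in `default_substrates()` are
synthetic reconstructions (the original sequences are unpublished): 19-mers
with four CpG sites per strand plus two non-CpG cytosines so that dC
normalization stays defined. Only the generator's normalization channel
depends on them; the calf-thymus 5mC/C ratio (6.4%), which does enter a
reported number, is exact.

## Melting model and numerics

The melting module assumes two states (duplex, single strand) with
temperature-independent ΔH (kcal/mol) and ΔS (cal/mol/K) of duplex
formation — ΔCp = 0, the standard van't Hoff treatment. Mass action gives a
quadratic in the duplex strand fraction *f*: with
`a = 2·K·Ct` (self-complementary, 2S⇌D) or `a = K·Ct/4 × 2` reduced to
`K·Ct/2` (equimolar heteroduplex, S1+S2⇌D),

$$ a(1-f)^2 = f, \qquad f = \frac{2a}{2a + 1 + \sqrt{4a+1}} , $$

the conjugate form chosen to avoid cancellation at both extremes (it is
checked against a bisection solver to 10⁻¹⁰ in the tests). Tm is defined as
the temperature where f = 1/2 at the experiment's strand concentration,
i.e. `Tm = ΔH·1000 / (ΔS + R ln Ct_eff)` with `Ct_eff = Ct` or `Ct/4`; the
transition is bimolecular, so Tm rises with concentration, and methylation
-scale offsets of 1–3 °C are recovered within 0.2 °C in the tests.

`fit_two_state()` fits absorbance as a duplex-fraction-weighted mix of two
linear baselines, parameterized by (ΔH, Tm) — ΔS is derived, which
conditions the optimization far better than fitting ΔS directly.
Initialization: endpoint linear fits for the baselines, the steepest point
of the lightly smoothed curve for Tm, and a small grid of enthalpy starts
(−30 to −160 kcal/mol) with the best convergent fit kept
(Levenberg–Marquardt via `minpack.lm`). A fit is declared non-convergent
when the fitted transition amplitude is indistinguishable from the residual
scale or Tm falls outside the scan — this is what rejects flat or purely
linear curves. Strand molarity during melting is not recoverable from a
curve and must be supplied; the bundled estimates derive from the
1.2 mg/ml irradiation concentration.

## Problem sizes and verification

The test-suite study conditions are the experimental ones: dose grids of
5–6 points, n = 3 (isolated) or n = 5 (cellular) replicates, 200 seeded
repetitions for the calibration study (a few seconds of compute), melting
scans at 0.5 °C spacing over 10–95 °C. The suite verifies: exact noiseless
round trips through quantification and correction; exact reproduction of
the bundled reference arithmetic (totals, SD sums, shares, ratios, folds);
unbiasedness of fitted slopes and intercepts within two Monte Carlo
standard errors; ΔH/ΔS recovery within 1% from noiseless melting curves;
and the conservation/scale-invariance invariants on randomized inputs.
`scripts/acceptance.R` recomputes the same quantities from scratch against
the installed package.

## Known limitations

* One merged peak table per sample is assumed; reconciling separate
  chromatographic runs of the same digest is upstream of this package.
* No weighted regression, dose-rate effects or high-dose saturation; the
  linear model is asserted, and r² merely flags departures.
* Detection limits are handled as a status flag (`nd`), not as censored
  -likelihood estimation; the single censored reference entry (calf-thymus
  5mC-Imid) is carried at its upper bound with zero SD.
* The melting module does not model ΔCp, non-two-state intermediates, or
  baseline curvature.
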