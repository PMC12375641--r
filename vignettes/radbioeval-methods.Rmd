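---
title: "Models and methods behind radbioeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radbioeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbioeval)
```

# Scope

`radbioeval` evaluates external-beam radiotherapy dose distributions the way
a physicist evaluates competing calculation conditions for the same plan:
dose-volume histograms and plan-quality metrics per structure, equivalent
uniform dose (EUD) and Poisson/LKB outcome probabilities per organ, and a
paired nonparametric comparison (Friedman omnibus, Dunnett-style post-hoc)
across conditions. Because paired clinical DVH sets are rarely shareable, a
synthetic thorax cohort generator stands in for patient data; it emulates the
*statistical signature* of dose-engine and contrast-agent differences, never
the engines themselves.

# Dose grids and DVHs

A `dose_grid` is a regular axis-aligned 3D field of absorbed dose in cGy with
voxel spacing in mm; a `structure_mask` is a congruent boolean field. The
differential DVH bins masked voxel doses into fixed-width bins (default 10
cGy, a typical TPS export resolution) covering `[0, max]`; binning is
right-open with the top edge closed, and bin volumes always sum to the masked
volume exactly. The cumulative DVH is tabulated at bin edges by suffix
summation, so the curve falls linearly across each occupied bin (the
uniform-within-bin assumption shared by TPS exports).

**Dx% tie rule.** `dose_at_volume()` returns the minimum dose received by the
hottest x% of the structure — the largest dose D with V(D) ≥ x%,
interpolated linearly. On a plateau this resolves to the plateau's *upper*
boundary. The alternative ("lowest dose attaining the level") looks symmetric
but degenerates: D100% of a uniformly irradiated structure would be 0 cGy
rather than the delivered dose, because the cumulative curve is flat at 100%
all the way down to zero dose. The chosen rule preserves the identity
Dx% = dose for uniform irradiation at every x and reduces to ordinary
interpolation everywhere the curve is strictly decreasing.

**Conventions fixed once.** Min/Max/Mean/Median are raw masked-voxel
statistics (so "Min" really is the coldest voxel); the standard deviation is
the population (divide-by-n) estimator, matching TPS reports; the mode is the
centre of the most occupied DVH bin. Near-minimum and near-maximum for the
ICRU62 homogeneity window (−5%/+7% of prescription) are D98% and D2% per
ICRU83 practice. Because DVH-derived quantiles inherit the bin width, a
mathematically uniform dose sitting exactly on a bin edge shows margins up to
half a bin (≈ 0.1–0.2% of a typical prescription); tests account for this.

**Conformity and gradient.** The source study never defines its conformity
index, so both common variants are provided: RTOG (prescription isodose
volume over target volume; default, matching single-ratio TPS reports) and
Paddick (coverage-squared over the product). The gradient measure follows the
TPS definition GM = r_eq(V50%) − r_eq(V100%), the difference of
equivalent-sphere radii of the half- and full-prescription isodose volumes,
in cm. For a pure exponential falloff with scale τ this has the closed form
GM = τ·ln 2, which the test suite exploits.

# Radiobiological models

All doses are cGy internally; α/β ratios are accepted in Gy and converted
once.

* **Mechanistic Poisson TCP** for uniform dose: TCP = exp(−N·ps(D)) with
  single-hit survival ps(D) = exp(−αD).
* **Phenomenological Poisson TCP**: TCP(D) = (1/2)^exp[2γ50(1 − D/D50)/ln 2],
  parameterised by the 50%-control dose D50 and normalised slope γ50 (the
  slope normalisation D·dTCP/dD at D50 equals γ50 exactly).
* **Heterogeneous dose**: each DVH subvolume is an independent tumourlet, so
  TCP = Π TCP(Dᵢ)^{vᵢ} = (1/2)^{Σ vᵢ·exp[2γ50(1 − Dᵢ/D50)/ln 2]}; the
  exponent sum is accumulated directly (log-domain) to avoid underflow at
  steep slopes.
* **EUD**: the generalised power mean (Σ vᵢDᵢ^a)^{1/a}, computed via
  log-sum-exp so a = 1000 (the serial-organ limit, → max dose) is exact.
  a = 0 errors rather than silently switching to the geometric mean.
* **LKB NTCP**: DVH → EUD with a = 1/n (the standard Niemierko linkage; the
  parameter table gives a only for the target and n for the organs at risk),
  then NTCP = Φ(t), t = (EUD − TD50)/(m·TD50), with Φ evaluated by `pnorm`.
  Note the probit response has a floor at zero dose, Φ(−1/m) — about 10.6%
  for the steep pneumonitis slope m = 0.8. That is a property of the model
  family, not a bug; claims that NTCP vanishes at zero dose only hold for
  shallow-slope models.
* **Poisson-LQ NTCP**: the same Poisson DVH form read as a complication
  probability for serially-summarised endpoints whose published parameters
  are D50 and α/β only. No normalised slope is published for those rows, so
  `gamma50` is a required configuration value; the default registry stamps
  1.5, a mid-range literature value, and every output carries the value used.

**EQD2 correction.** Model rows labelled "-LQ" carry an α/β ratio, implying
per-bin conversion to equivalent dose in 2-Gy fractions,
EQD2 = D·(d + α/β)/(2 Gy + α/β) with d the per-bin fraction dose. The
correction is a per-model flag: default ON for Poisson-LQ models and OFF for
Lyman models, whose published TD50/m were fitted to physical dose. The map is
the identity exactly at 2 Gy per fraction and in the α/β → ∞ limit. Whether
the source analysis applied the correction before its reported TCPs is not
stated; the flag makes either choice explicit and reproducible.

**Registry.** `default_models()` ships the five thoracic models used
throughout: PTV control (Poisson-LQ, D50 4920 cGy, α/β 10), lung pneumonitis
(Lyman, TD50 2190, m 0.80, n 0.37), lung fibrosis (Lyman, TD50 2880, m 0.5,
n 0.34), esophageal stricture (Poisson-LQ, D50 6800, α/β 3) and esophagitis
(Lyman, TD50 5100, m 0.32, n 0.44, α/β 10 — stored as printed in its source
even though the surrounding text groups the esophagus with α/β = 3).

# The synthetic cohort: what it emulates, and what it does not

The phantom is a parametric thorax (elliptic-cylinder body, two ellipsoidal
lungs, heart, tubular esophagus and cord) with a spherical PTV in the central
right lung; per-patient anatomy jitters the PTV radius (±4 mm around 22 mm)
and centre (±6 mm) from the patient seed. The default grid is 40³ voxels at
5 mm — coarse enough for a laptop cohort, fine enough that the PTV holds a
few hundred voxels.

The plan emulator is *not* a dose engine. It writes a slightly hot plateau
(1.04 × prescription, ±1% smooth low-frequency heterogeneity) inside the
PTV, an isotropic exponential falloff (scale 40 mm, giving gradient measures
near 2.8 cm, the clinical scale) outside, and one Gaussian cold spot
(σ 3.5 mm, amplitude 0.28–0.38 × prescription) seated on a random point of
the PTV surface. The cold spot is what makes the raw minimum dose sit 10–30%
below prescription — as clinical plan minima do — while D98% and V95% remain
compliant; its depth is deliberately large enough that the plan minimum stays
on the surface under several-hundred-cGy peripheral perturbations, which is
what makes injected peripheral shifts recoverable from PTV_Min. Every plan is
verified post hoc against the coverage objective (≥95% of the PTV at ≥95% of
prescription; the emitted plans in fact keep ≥95% at the *full* prescription)
and the −5%/+7% homogeneity window, with up to three regeneration attempts at
reduced heterogeneity.

The prescription is nowhere stated in the source study; 5400 cGy in 30
fractions was chosen once as the conventional centrally-located-lung-cancer
schedule consistent with the reported PTV mean near 5674 cGy (a plan running
≈4–5% hot relative to a 5400 prescription), and is not revisited.

Six calculation conditions (AAA, AAA_C, AXB_Dm, AXB_Dw, AXB_C_Dm, AXB_C_Dw)
perturb each patient's base plan: a global multiplicative bias, an extra bias
below 20% of prescription (the low-dose lung region where engine differences
concentrate), an additive shift confined to the PTV periphery (flat within
6 mm of the surface, fading by 12 mm), and iid Gaussian voxel noise (15 cGy).
Default magnitudes follow the observed directions: contrast raises the
peripheral minimum by ≈450–650 cGy, the convolution-superposition engine runs
≈0.6% hot globally and ≈3% hot in the low-dose region with a ≈110 cGy higher
minimum, and dose-to-medium reports ≈0.6–1% below dose-to-water. These are
calibration knobs, not physics.

A green test on this cohort therefore establishes that the *pipeline*
(DVH → metrics → outcome models → paired statistics) detects and quantifies
effects of the configured kind at the configured scale with the configured
noise. It does not validate any dose engine, nor reproduce the source
cohort's numbers, whose patient DVHs are unpublished.

Determinism: every stochastic step draws from a private seeded stream
(patient and condition seeds derive from the master seed by a fixed affine
scheme recorded in the cohort manifest), so cohorts are bit-reproducible and
never perturb the session RNG.

# Statistics

The Friedman statistic uses within-block midranks with the tie-corrected
denominator n·k·(k+1) − Σ(t³−t)/(k−1) and a χ²_{k−1} reference; it agrees
with `stats::friedman.test` to machine precision and its null rejection rate
at n = 20, k = 6 calibrates to 5% in simulation.

Post-hoc comparisons are paired t statistics per condition pair. The
family-wise adjustment refers the two-sided max-|t| to the classical
equicorrelated (ρ = 0.5) multivariate-t construction — shared χ²_ν
denominator, ν = blocks − 1 — evaluated by seeded Monte-Carlo (2·10⁵ draws by
default) rather than shipped critical-value tables; a family of one reduces
exactly to the raw paired t test, and a Bonferroni fallback is available.
ρ = 0.5 is exact for many-to-one differences of exchangeable conditions,
which is the design the generator produces. Post-hoc p-values are computed
even when the omnibus is non-significant (reported comparisons in this
domain include such pairs) but are flagged. Star labels follow the strict
convention: `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001, `ns`
otherwise, with p = 0.05 exactly labelled `ns`. Families are per metric; no
adjustment is made across the ~20-metric panel, and the output says so by
construction (one `comparison_result` per metric).

# Numerical choices

* Log-domain accumulation for the Poisson DVH exponent and the EUD power
  mean (exact at a = 1000).
* Probit via `pnorm` (erfc relation), no table lookup; matches direct
  quadrature of the probit integral to 10⁻⁸ across t ∈ [−6, 6].
* DVH interpolation is linear in the cumulative domain in both directions;
  `dose_at_volume` and `volume_at_dose` invert each other within one
  interpolation step.
* Dose grids are voxel-centre sampled, axis-aligned, congruence-checked;
  no resampling — masks must share the grid.
* Negative doses after perturbation clip to zero; >1% clipped raises a
  warning.
* Volumetric containers and DVH CSVs serialise doubles as `%.17g`, so
  write→read round trips are bit-identical.

# Known limitations

* The phantom's organ-at-risk doses run hotter than typical clinical lung
  plans (the falloff is isotropic; no beam-direction sparing), so absolute
  NTCP levels on synthetic cohorts are higher than clinic values; paired
  *differences* between conditions, the quantity of interest, are unaffected.
* One spherical target; no multi-lesion or irregular PTV support.
* No DICOM import: the pre-installed stack has no DICOM reader, so the
  package defines its own plain-text volumetric container instead.
* The "ESP" target metric reported in some TPS panels has no public
  definition and is intentionally not implemented.
* Dunnett adjustment assumes the equicorrelated many-to-one structure; for
  arbitrary pair lists with strongly unequal variances it is approximate
  (the Bonferroni fallback is conservative and always available).
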