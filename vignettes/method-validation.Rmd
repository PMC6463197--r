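---
title: "Method validation by standard addition: models, conventions and the synthetic batch generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method validation by standard addition: models, conventions and the synthetic batch generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(halovalid)
```

This vignette documents the statistical model behind `halovalid`, the
conventions it commits to where practice varies, and the semantics of the
synthetic batch generator used to exercise the pipeline end to end.

## 1. Quantification model

### Response ratios and blank correction

Every quantity in the package is built on the blank-corrected
analyte/internal-standard (IS) peak-area ratio

$$r = \frac{A_\text{analyte} - A_\text{blank}}{A_\text{IS}},$$

computed by `response_ratio()`. Blank correction applies to the analyte
area only; the IS is added at a fixed known concentration to every
analysis and is not blank-corrected.

### Single-point standard addition

An unknown extract is analysed once as-is and once after a known addition
$c_\text{ad}$; both analyses come from the *same prepared extract*. With
$r_u$ and $r_a$ the two response ratios,

$$c = c_\text{ad}\,\frac{r_u}{r_a - r_u}
\qquad \text{(`standard_addition_conc()`)}.$$

Any multiplicative factor common to both analyses — matrix suppression or
enhancement, lipid-dependent signal attenuation, injection-volume drift
shared by analyte and IS — cancels in the ratio of ratios. This is the
reason the package treats standard addition as the primary quantification
route and exposes external (solvent or matrix-matched) calibration
separately (`quantify_by_calibration()`): the test suite demonstrates that
standard-addition results are invariant to injected matrix effects while
solvent-calibration results inherit them in full.

When a batch contains replicate injections of the unknown and of the
addition, `quantify_standard_addition()` averages the replicate ratios per
batch *before* forming the ratio of ratios. Averaging ratios (rather than
computing per-injection concentrations and averaging those) keeps the
estimator defined even when an individual injection pair would put
$r_a - r_u$ near zero.

### Calibration and linearity

`fit_calibration()` fits ordinary least squares of ratio on concentration.
Weighted least squares is available through the `weights` argument, but
the default is unweighted: the validation design uses seven levels over
0.1–60 µg/kg with single injections per level, which gives no replicate
information to estimate a variance function from. Linearity is assessed by
the coefficient of determination together with the relative response
factors

$$\mathrm{RRF}_j = \frac{r_j \, c_\text{IS}}{c_j},$$

whose relative standard deviation across levels is reported alongside
$R^2$; a constant-RRF profile is the practically relevant statement of
proportionality.

## 2. Matrix effect

`matrix_effect()` compares matrix-matched and solvent standards at equal
concentration. The default convention puts the **matrix-matched area in
the denominator**:

$$\mathrm{ME}\% = \frac{\bar A_\text{matrix} - \bar A_\text{solvent}}
{\bar A_\text{matrix}} \times 100,$$

selected by `convention = "paper"`; the more widespread
solvent-denominator form is available as `convention = "conventional"`.
The two agree in sign but not magnitude, so the choice is recorded in the
output. With equal replicate counts the comparison is paired and the
replicate spread is reported as the standard deviation of the
per-replicate ME values, in percentage points; with unequal counts it
falls back to a mean-versus-mean comparison.

## 3. Validation metrics

- **Limits** (`limits_from_replicates()`): LOD $= 3s$ and LOQ $= 10s$,
  where $s$ is the sample standard deviation of replicate determinations
  of a low-level spike (design: $n = 10$ at 0.1 µg/kg). The identity
  LOQ $= (10/3)\,$LOD holds exactly and is tested as such.
- **Recovery** (`recovery()`): mean determined over spiked, as percent,
  with the consistency rule that recoveries outside 70–120% remain
  acceptable down to 30% and up to 140% provided the replicate RSD is
  ≤ 20%.
- **Precision**: `precision_intra()` is the sample RSD of one-day
  replicates. `precision_inter()` defaults to the *pooled* RSD of all
  day × replicate values (`method = "pooled"`), i.e. the total standard
  deviation over the grand mean; for a balanced design this equals the
  closed form
  $\sqrt{[\sum_d (n_d{-}1)s_d^2 + \sum_d n_d(\bar x_d - \bar x)^2]/(N-1)}$.
  An ANOVA-based intermediate-precision estimator
  ($\sqrt{s^2_\text{within} + s^2_\text{between}}$ from the one-way mean
  squares, with the between-day component truncated at zero) is provided
  as `method = "anova"` but is not the default, because the pooled total
  RSD is what a QC chart spanning days actually measures.
- **Trueness** (`trueness()`, `srm_compare()`): recovery against a
  certified value, with the identity $R - 100 = B_r$ (relative bias).
  `srm_compare()` flags whether the replicate mean lies inside the
  certified interval $c \pm U$. The check is **boundary-inclusive with a
  floating-point tolerance** (`sqrt(.Machine$double.eps)` scaled by the
  interval edge): a mean exactly on the edge counts as inside. If the
  determined expanded uncertainty is supplied, an interval-overlap rule is
  used instead.
- **Censoring** (`censor_below_loq()`): values below the LOQ are censored
  in the *reported* strings only ("<LOQ"); numeric values are kept
  untouched so downstream statistics are not biased by substitution.

## 4. Top-down uncertainty

The budget (`uncertainty_budget()`, `combine_budget()`) follows the
within-laboratory top-down route with four relative components:

1. $u_{r,\text{repro}}$: the RSD of at least 20 independent QC-chart
   values at the reference level (`u_repro_from_qc()`; warns below 20
   values).
2. $B_r = (\bar c_m - c_\text{ref})/c_\text{ref} \times 100$: relative
   bias of QC replicates (`bias_components()`).
3. $u_{r,\text{cm}} = (s/\sqrt n)/c_\text{ref} \times 100$: the standard
   uncertainty of that mean.
4. $u_{r,\text{ref}}$: the reference-value uncertainty, taken from a
   certificate as $U/k$ when one exists (`u_ref_from_certificate()`,
   $k = 2$ by default) and otherwise from the standard's purity $y$ via a
   rectangular distribution, $0.5\,(100 - y)/\sqrt 3$
   (`u_ref_from_purity()`). `u_ref_for_analyte()` applies the certificate
   with precedence.

These combine by root-sum-of-squares,

$$u_{r,\text{tot}} = \sqrt{u_{r,\text{repro}}^2 + B_r^2 +
u_{r,\text{cm}}^2 + u_{r,\text{ref}}^2}, \qquad
U_{r,\text{tot}} = k\,u_{r,\text{tot}},\ k = 2,$$

with the bias entering *uncorrected and squared*: results are not
bias-corrected; the bias is carried inside the uncertainty instead. This
is a deliberate convention of the implemented approach, not an oversight.

## 5. Eco-Scale

`score_ledger()` totals penalty points over reagent, instrument,
occupational-hazard and waste items and reports $100 - \sum$ penalties,
classified as excellent (> 75), acceptable (> 50) or inadequate green
analysis. Penalty values are *inputs* supplied in the method definition:
deriving them from hazard-pictogram databases is out of scope, so the
packaged ledger ships the assessed values (total 32, score 68).

## 6. The synthetic batch generator

### Area model

`simulate_area()` draws peak areas from

$$A = S_0 \cdot \mathrm{rrf} \cdot
\left(c \cdot \tfrac{R}{100} \cdot (1 + \varepsilon) + c_\text{ad}\right)
\cdot \left(1 + \tfrac{\mathrm{ME}}{100}\right)
\cdot e^{-k_\ell\,( \ell - \ell_\text{ref})} \cdot \eta,$$

with $S_0$ the base scale (counts per µg/kg at unit response factor),
$\mathrm{rrf}$ the per-analyte response factor, $R$ the process recovery,
$\varepsilon \sim N(0, \mathrm{cv}_\text{prep})$ the preparation noise,
ME the signed matrix effect, $\ell$ the sample lipid percentage, and
$\eta$ an optional per-peak instrument noise factor (default off). Matrix
effect and lipid terms apply only to matrix analyses; solvent standards
get neither. Internal standards are always simulated with 100% recovery
(they are added just before analysis).

### Noise semantics: why recovery survives and matrix effects cancel

Three properties must hold simultaneously for the generator to be a
faithful stand-in for the real experiment:

1. a zero-noise batch must round-trip the injected recoveries exactly,
2. the CV of determined concentrations must equal the injected
   preparation CV, and
3. standard-addition results must be invariant to matrix and lipid
   effects.

The generator achieves all three by (a) drawing **one preparation-noise
factor per analyte per prepared sample** and sharing it between the paired
unknown and standard-addition analyses (they are the same extract), and
(b) modelling the **addition as made to the final extract**, fully
recovered and free of preparation noise. The determined concentration then
reduces algebraically to $c_\text{spike} \cdot R/100 \cdot
(1+\varepsilon)$: recovery is *not* cancelled by the addition (the spike
never passes through extraction), while every multiplicative instrumental
term cancels. The acceptance-level tests verify each property over
hundreds of seeded batches against analytic sampling bands.

### Lipid suppression and its reference point

The lipid term is anchored at a reference lipid content
(`lipid_ref_pct`, default the matrix-effect evaluation matrix, 5.2%
lipid): at that content the lipid factor is unity, so the injected
`me_true_pct` is *exactly* what a matrix-versus-solvent comparison
measures there — concretely, a noise-free paper-convention ME table
returns $100\,(1 - 1/(1 + \mathrm{ME}/100))$. Without the anchor the
lipid factor would fold into every measured matrix effect and the
parameter would not mean what its name says. Fattier samples are
attenuated relative to the reference with coefficient
`lipid_suppression_coeff` (default 0.04 per lipid percentage point, such
that a 16%-lipid salmon extract shows roughly 60% of the signal of a
3%-lipid perch extract).

### Default parameters and plan

The defaults of `sim_config()` *are* the emulated study conditions, not
tuning knobs:

- `noise_cv_pct = 8`: replicate preparation CV, the magnitude of typical
  QC-chart RSDs for this method class.
- `instrument_cv_pct = 0`: preparation noise dominates; per-peak noise can
  be switched on for sensitivity studies.
- Plan: 7-level matrix-matched and solvent calibrations (0.1–60 µg/kg),
  3 blanks, 5 matrix-effect replicate pairs at 5 µg/kg, recovery at
  1/5/15/30/60 µg/kg with n = 5, ten limit replicates at 0.1 µg/kg, QC at
  5 µg/kg (10 intra-day, 4 days × 4 inter-day, a 24-point QC chart), and
  triplicate analyses at the certified concentrations when a certified
  material is supplied. Every quantifiable sample is emitted as a paired
  unknown + standard-addition analysis sharing a `batch_id`.
- Sample descriptors: routine batches at 1.9% lipid / 80% moisture, QC at
  5.2% / 75%, certified-material analyses at 10.2% / 71.4%.

### What the generator does not emulate

Chromatographic realities outside the scope of the validation statistics:
retention-time drift and peak-identification errors, signal drift across a
sequence (no IS drift correction is applied — `run_index` is retained in
the records so one could be added downstream), carryover, heteroscedastic
detector noise, interferences producing biased blanks, and censoring at
the detector floor. Measurement records are the model's ground truth plus
multiplicative noise; nothing is truncated except that noise factors are
kept positive.

## 7. Reporting conventions

Computation keeps full precision everywhere. Rounding happens only at the
reporting layer: `summary()` on a validation report rounds limits to two
significant figures and recoveries to whole percent; `write_report()`
writes full-precision JSON alongside the rounded text summary. Tests that
compare against published-style figures use printed-digit tolerances
rather than rounding intermediate results.
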