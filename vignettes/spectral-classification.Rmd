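---
title: "Classifying ELISA absorbance spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ELISA absorbance spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odspectra)
```

`odspectra` compares two ways of classifying colorimetric ELISA
absorbance spectra into three ordinal severity classes
(normal < mild < severe): the conventional single-wavelength optical
density (OD) threshold at 450 nm, and full-spectrum PLS-DA with spectral
preprocessing. This vignette is the package's account of the underlying
models, the choices that were genuinely open, and what the synthetic data
does and does not demonstrate.

## 1. The measurement model

A sandwich ELISA read on a scanning plate reader yields an absorbance
spectrum per well over 300–550 nm at 1 nm steps (251 channels). By the
Beer–Lambert law the absorbance at wavelength $\lambda$ is
$A(\lambda) = \varepsilon(\lambda)\, b\, c$: molar absorptivity times
optical path times analyte concentration. The TMB reaction product
absorbs in a band around 450 nm, so the standard readout is the single
value $A(450)$, proportional to concentration.

The synthetic generator (`generate_dataset()`) implements this forward
model with a Gaussian absorptivity band,

$$A(\lambda) = \varepsilon_{\max}\,
  e^{-(\lambda - 450)^2 / 2s^2}\, b\, c\,(1 + m)
  + \beta\, e^{-(\lambda - 300)/150} + a + \eta(\lambda),$$

where $m \sim N(0, \sigma_{\text{mult}})$ and
$a \sim N(0, \sigma_{\text{add}})$ are drawn once per spectrum
(multiplicative scatter and additive offset), and
$\eta(\lambda) \sim N(0, \sigma_{\text{noise}})$ i.i.d. per channel.

Parameters, units, defaults:

| parameter | meaning | default | why |
|---|---|---|---|
| `peak_center`, `peak_width` | band position/SD, nm | 450, 40 | band peaks at the reporting wavelength and decays substantially by 300/550 nm, so off-peak channels carry attenuated but real signal — the premise of the multivariate analysis |
| class OD bands | noiseless $A(450)$ support, AU | 0.02–0.35, 0.35–0.88, 0.88–1.99 | the class structure of the motivating clinical OD data (each class maximum is the next class minimum; severe maximum 1.99) |
| class sizes | samples per class | 14/5/11 (`"study"`), 10/10/10 (`"balanced"`) | the clinical group sizes; the balanced preset matches the column totals of the motivating univariate confusion matrix, which disagree with the stated group sizes — both are offered, neither privileged |
| `baseline_amplitude` | smooth baseline, AU | 0.04 | a few percent of full scale, typical of buffer/plastic background; fixed exponential decay toward long wavelengths (any smooth fixed shape would serve) |
| `scatter_multiplicative_sd` | per-spectrum gain SD | 0.02 | small pipetting/path-length variation |
| `scatter_additive_sd` | per-spectrum offset SD, AU | 0.01 | small per-well offset |
| `noise_sd` | channel noise SD, AU | 0.005 | photometric noise of a monochromator reader, well below the 0.02 AU smallest class minimum |
| `overlap_fraction` | band stretch past both bounds | 0.05 | the clinical data showed adjacent-class OD overlap; one knob reproduces it qualitatively. Drawn ODs may then cross class boundaries, so even a perfect threshold rule misclassifies some samples — as observed clinically |

The three artifact terms are deliberately distinct because the three
preprocessing methods remove different ones: SNV cancels the
per-spectrum offset $a$ and gain $(1+m)$ exactly; mean centering removes
the fixed baseline and column means but not per-spectrum scatter;
autoscaling additionally equalises channel variance, amplifying
low-signal channels where noise dominates. With a single artifact type
the four methods would be near-indistinguishable.

Concentrations are drawn by inverting the Beer–Lambert relation at the
band peak: uniform on the class OD band (stretched by
`overlap_fraction`), divided by $\varepsilon_{\max} b$. Everything is a
pure function of the configuration, including its mandatory seed; the
caller's RNG stream is left untouched.

**What the generator does not emulate**: ELISA chemistry kinetics,
plate-position effects, standard curves, wavelength-correlated noise,
non-Gaussian product bands, or any real between-subject biology.
Passing tests on this data shows the *algorithms* are correct under a
controlled Beer–Lambert world with realistic artifact structure — not
that either classifier attains any particular accuracy on real clinical
spectra.

## 2. The univariate threshold classifier

The two boundaries are learned as empirical class extremes on the
calibration set: `t_low` = maximum OD among normal samples, `t_high` =
maximum OD among mild samples (each class's maximum is read as the next
class's minimum, which is how a graded OD bar chart is interpreted).
Classification is by band: normal below `t_low`, mild in
[`t_low`, `t_high`), severe at or above `t_high`.

Two decisions here were open:

- **Boundary ties go up-severity.** The boundary value belongs to both
  adjacent classes by construction (it *is* the lower class's maximum),
  so a rule must pick a side; assigning upward is the conservative choice
  for a screening application, where a false escalation is cheaper than
  a missed progression. A consequence worth stating plainly: the
  calibration sample that attains each class maximum sits exactly on its
  own learned boundary and is therefore classified one class up — with
  continuous OD data the univariate rule misclassifies exactly those two
  boundary samples even on overlap-free, noise-free data. The package's
  tests assert this exact behaviour rather than a nominal 100%.
- **Thresholds are learned, not hard-coded.** The canonical 0.35/0.88
  values re-emerge (up to sampling error in the class maxima) when the
  generator uses the default profiles; nothing in the classifier knows
  them.

## 3. PLS-DA

The multivariate route regresses the one-hot class matrix
$Y \in \{0,1\}^{n \times 3}$ (column order fixed: normal, mild, severe)
on the preprocessed spectral matrix $X$ by NIPALS PLS2, extracting
orthogonal score directions that maximise covariance with the class
structure, then assigns the class with the largest predicted response.

Numerical choices:

- **NIPALS over SIMPLS**: component-by-component, verifiable against the
  deflation identities ($X \approx TP^\top$, scores orthogonal), and
  deterministic once the starting vector is fixed. `u` is initialised to
  the $Y$ column of largest variance — deterministic, so identical
  inputs give bit-identical models.
- **Convergence**: the inner loop stops when the score vector changes by
  a relative $10^{-10}$. The iteration is a power method on the deflated
  cross-covariance; its convergence rate degrades as the two leading
  eigenvalues approach each other, which happens routinely in
  noise-dominated late components (autoscaled data especially). The
  iteration cap is therefore 5000; non-convergence is an error naming
  the component, never a silent truncation.
- **Y centering follows X treatment**: under mean centering and
  autoscaling (column-wise affine maps) the dummy matrix is centered
  with calibration means and the means re-added at prediction — standard
  PLS2 practice that makes an all-zero preprocessed row predict the
  calibration class frequencies. Under `none` and SNV (a row-wise map),
  $Y$ is left raw. Overridable via `center_y`.
- **Arg-max assignment** rather than a 0.5 cutoff: with three classes it
  always yields exactly one label; exact ties break toward lower
  severity, mirroring (in the opposite, deliberate direction) the
  univariate tie rule — a tie between *continuous responses* carries no
  evidence of the higher class, unlike an OD sitting on a measured class
  maximum.
- **Component count**: leave-one-out cross-validated misclassification
  over 1..10 components, smallest count achieving the minimum. LOO is
  the natural choice at n = 21 calibration samples. The preprocessing
  statistics are fitted once on the full calibration set before
  selection (not per fold); at these sizes the simplicity was judged
  worth the mild optimism, and the count is overridable.
- **Preprocessing statistics are calibration-only** and frozen for
  validation. Whether the motivating analysis did this is unknowable
  from its report; train-only fitting is the defensible convention
  because anything else leaks validation information.
- **Wavelength range**: the full 300–550 nm grid is used. Sub-ranging is
  available by subsetting columns upstream, but no default sub-range is
  imposed — there is no defensible basis for one.

In the full-rank limit (components = rank of $X$) PLS reproduces the
ordinary least-squares fit of $Y$ on $X$; the test suite asserts this
against a direct normal-equations oracle at $10^{-6}$, and checks the
first scores against an independent PLS implementation (mixOmics) when
available. On overlap-free synthetic data with 251 channels and ~21
samples, a well-supplied component budget lets PLS-DA interpolate the
calibration labels — calibration accuracy 1.0 for every preprocessing
method is an algebraic property of the full-rank limit on separable
data, not evidence of generalisation; validation metrics are the ones
that mean anything.

## 4. Evaluation conventions

Confusion matrices are 3×3 with **rows = predicted, columns = actual**,
in class order — the orientation of the motivating study's tables, and
the one all truth-table arithmetic here is derived from. Per-class
one-vs-rest counts are the standard decomposition
($TP_k$ = diagonal; $FP_k$ = row sum − $TP_k$; $FN_k$ = column sum −
$TP_k$; $TN_k$ = remainder), and the four metrics are
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
precision = TP/(TP+FP), accuracy = (TP+TN)/total.

- **0/0 precision is reported as 1.0** and flagged: a class never
  predicted incurs no false positives, and this is the convention the
  published validation tables require for a class absent from a 9-sample
  validation set. Sensitivity/specificity 0/0 are `NA`, flagged.
- **Two "overall accuracy" variants** are reported: macro (mean of the
  three per-class accuracies — the variant the motivating study's
  printed 0.84 corresponds to) and micro (correct/total — the variant
  its prose defines). They genuinely differ; both are always available.
- **Rounding** in rendered reports is 2-decimal half-to-even; raw
  full-precision values are retained in the JSON artifact.
- **Split arithmetic**: stratified 7:3 with per-class counts from
  round-half-up plus largest-remainder adjustment, so 10/10/10 gives
  exactly 7/7/7 + 3/3/3 and 14/5/11 gives 10/3/8 + 4/2/3.

One published row is knowingly not reproduced: the validation accuracy
row of the no-preprocessing table (0.43/0.38/0.38) is not derivable from
its own confusion matrix under the stated formulas (which give
1.00/0.89/0.89); the package implements the formulas and leaves that row
alone. Similarly, the printed univariate truth table's FP/FN counts are
not the one-vs-rest decomposition of the printed univariate confusion
matrix; the package implements the standard decomposition and treats the
printed counts as data when reproducing the printed metrics.

## 5. Problem sizes and reproducibility

All shipped tests and the acceptance script run on the study-scale
problem: 30 samples × 251 wavelengths, 21/9 splits, up to 15 latent
variables, LOO CV over ≤ 10 components — seconds of compute. Every
stochastic step (generation, splitting) takes an explicit integer seed
and restores the caller's RNG state; `run_experiment()` writes a
manifest from which a run is exactly reproducible, and never overwrites
an existing output directory (it versions a sibling instead).

## 6. Known limitations

- The generator's uniform-OD class model is a deliberate simplification;
  real DSPP distributions are unknown and likely skewed.
- With n = 5 in the mild class, the learned `t_high` (a maximum of 5
  draws) is highly variable; threshold-recovery checks use
  order-statistic quantiles, not a fixed tolerance.
- PLS-DA here deliberately omits VIP scores, orthogonal variants and
  probabilistic posteriors; the comparison is about the classification
  core.
- Published multivariate results can only be reproduced from their
  printed count tables: the underlying spectra and the exact 21/9
  partition were never published, so re-fitting them is impossible by
  construction.
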