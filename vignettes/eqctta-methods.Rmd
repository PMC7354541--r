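---
title: "Filtration-histogram texture analysis of equilibrium CT: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtration-histogram texture analysis of equilibrium CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqctta)
```

## The measurement problem

Diffuse liver fibrosis lays down collagenous extracellular matrix,
expanding the interstitial space. Two imaging consequences are exploited
here. First, at contrast equilibrium the iodine concentration in tissue is
proportional to its extracellular volume, so the attenuation change
between the pre-contrast and equilibrium phases, referenced to blood and
corrected for the plasma fraction, yields the extracellular volume
fraction:

$$\mathrm{ECV} = (1 - \mathrm{haematocrit}) \cdot
  \frac{\Delta HU_\mathrm{liver}}{\Delta HU_\mathrm{blood}}.$$

Second, the *spatial arrangement* of that enhancement — bridging septa,
nodular architecture, subcapsular predominance — lives at characteristic
millimetre scales, and a band-pass decomposition of the image can separate
it from both fine noise and bulk anatomy. `eqctta` quantifies this with
the filtration-histogram approach: filter the slice at a chosen spatial
scale, then summarise the filtered values inside an ROI with six
histogram statistics, and correlate every such feature against reference
fibrosis markers (CPA, ECV, ELF, Ishak stage) with Spearman's rank
correlation.

## The filtration step

### Kernel

For a spatial scale filter (SSF) value $S$ in mm, the kernel is a negated,
scale-normalised Laplacian of Gaussian with

$$\sigma = \frac{S}{2\sqrt{2}},$$

sampled on the pixel grid in physical mm per axis (anisotropic spacing is
handled per axis), truncated at $4\sigma$, weighted by pixel area and then
mean-subtracted so its entries sum to exactly zero.

The $\sigma$ mapping makes the LoG zero-crossing ring diameter
($2\sqrt{2}\sigma$ in 2-D) equal to $S$: "SSF in mm" is the diameter of the
bright feature the scale highlights. Negation makes bright blobs give
*positive* responses, which is what lets the mean-of-positive-pixels and
skewness statistics read as "number and spread of bright features".
Mean-subtraction enforces zero DC gain: a constant image filters to
exactly zero, and the filtered mean over a large interior region is driven
by structure, not by the tissue's baseline attenuation.

### Scale normalisation

The classical scale-space normalisation multiplies the LoG by $\sigma^2$,
which maximises the *centre* response of a matched Gaussian blob at the
matched scale. The quantity this package (and its validation suite) uses
for scale attribution is different: the mean positive response over the
blob footprint. That statistic is biased towards scales slightly above the
matched one, because a larger-scale response is flatter across the
footprint. We therefore normalise by $\sigma^{\gamma}$ with
$\gamma = 1.6$ (the `gamma` argument of `log_kernel()` and
`filter_slice()`), calibrated once on noiseless analytic blob images so
that over the bank $S \in \{2,3,4,5,6\}$ mm the argmax of the in-blob mean
positive response equals the blob diameter for every diameter in
$\{2,\dots,6\}$ mm at 0.5, 0.7 and 1.0 mm pixel spacings. The vendor
implementations of this family of filters are unpublished; this kernel is
our documented interpretation, and $\gamma$ is exposed so the sensitivity
of any result to it can be probed.

### Boundary handling, masking and erosion

Filtering is applied to the **full image** with mirror-reflected
boundaries; the ROI enters only when statistics are sampled. Masking
before filtering would place a huge artificial edge at the ROI boundary.
Even with full-image filtering, the band-pass response rings within
$\sim 4\sigma$ of strong edges (organ boundary, excluded vessels), so by
default the mask is eroded by $\lceil 2\sigma \rceil$ pixels per axis
before sampling (`erode = TRUE`). A minimum of 50 sampled pixels is
enforced (`min_pixels`): third and fourth moments are unstable below that.

## The six statistics

Over the sampled values $V$ (population conventions, divisor $n$):
mean; SD $= \sqrt{m_2}$; Shannon entropy in bits of the 256-bin
equal-width histogram over $[\min V, \max V]$ with $0\log 0 = 0$
(`bins` configurable; a constant region has entropy 0); MPP — the mean of
strictly positive values, returned as a flagged 0 when no positive pixels
exist so feature tables stay rectangular; skewness
$g_1 = m_3 / m_2^{3/2}$; kurtosis, reported as excess
$g_2 = m_4/m_2^2 - 3$ by default (`excess = FALSE` gives the raw ratio).
Zero-variance regions return flagged zeros rather than NaN. Population
rather than sample-corrected moments were chosen for determinism and
oracle simplicity; ROIs here contain thousands of pixels, where the
difference is negligible, and the convention is configurable.

Entropy deserves a note: the field's software does not document whether
entropy is computed on the filtered-value histogram or on a re-quantised
grey-level image. We compute it on the filtered-value histogram with
min–max binning; this makes entropy invariant under affine rescaling of
the filtered values, which is the behaviour wanted of an "irregularity"
measure.

### Subtraction features

The equilibrium-minus-pre ("diff") features are the metric-wise
differences of the six statistics, computed per region and SSF
(`subtract_features()`). The alternative reading — filter the voxel-wise
difference image and summarise that — is available as
`diff_mode = "image"` in `extract_patient()`; the two agree exactly for
the mean (linearity) and differ for the other statistics. Parameter-wise
subtraction is the default because the subtracted texture *parameters*
are the quantities the downstream correlation analysis consumes.

## ECV computation

`compute_ecv()` implements the partition relation exactly, refuses a
non-positive blood enhancement (equilibrium not reached, or the ROIs are
swapped), flags — but never clips — ECV values outside $[0,1]$, and
auto-interprets haematocrit given on the percent scale. ROI attenuation
means are plain means under the mask with **no erosion**: this mirrors the
clinical attenuation measurement, which is not a texture measurement.
When several contiguous sections per phase are supplied, ROI means are
averaged across sections before the formula, matching the clinical
protocol of measuring on three adjacent sections; with the default
phantom noise (10 HU per pixel) this reduces the ECV noise standard
deviation from about 0.009 to about 0.005 and is what makes a ±0.02
recovery bound hold reliably.

## Association analysis

`spearman_cor()` ranks with average-rank ties and takes the Pearson
correlation of ranks; the p-value uses the two-sided t-approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ with $n-2$ df, appropriate at the cohort
sizes this analysis targets ($n \le 30$; on simulated null cohorts of
$n = 29$ the realised type-I rate at $\alpha = 0.05$ is within 0.05 ± 0.02
— the suite checks this). Perfect monotone agreement, where $t$ diverges,
is reported as the permutation bound $2/n!$ and flagged; an exact
permutation option exists for $n \le 10$. Missing phases are handled
pairwise-complete, so diff features simply have a smaller $n$ than
pre-contrast features in a partially imaged cohort.

No multiple-testing correction is applied by default. The filter scales
are strongly dependent (neighbouring SSF values produce overlapping
bands), so independence-based corrections such as Bonferroni are
miscalibrated for this feature family; an optional Benjamini–Hochberg
column (`p_adjust = TRUE`) is provided for sensitivity analysis only.

## The phantom generator

The generator exists so that every stage of the pipeline — including the
planted-effect recovery of the association analysis — can be exercised
without any clinical data. One phantom is a 96 × 96 grid at 1 mm spacing:
a liver disc (radius 40 mm, parenchyma 55 HU over a 20 HU background), a
peripheral segment-VII wedge (radial range 60–100 % of the liver radius,
±50°), an aorta disc of 7 mm radius (area ≈ 1.6 cm², a typical clinical
aortic ROI), and three 2.5 mm vessels. Per-pixel acquisition noise is iid
Gaussian (sd 10 HU), drawn independently per phase and section.

A severity parameter $s \in [0,1]$ controls, with monotone noisy links:

* **fibrotic blobs** — Gaussian bright features of diameter 4 mm
  ($\sigma_b = d/(2\sqrt{2})$, matching the kernel's scale convention),
  Poisson count with density $0.5 + 4s$ per cm², amplitude 12 HU;
* **ECV** — $\mathrm{ecv} = 0.22 + 0.15\,s$ (spanning the range reported
  for chronic hepatitis cohorts), haematocrit from a truncated normal
  $(0.42, 0.03)$, blood enhancement fixed at 40 HU;
* **markers** — $\mathrm{ELF} = 8 + 4s + \varepsilon(0.4)$,
  $\mathrm{CPA} = \max(0,\, 2 + 25 s + \varepsilon(2))$,
  $\mathrm{Ishak} = \mathrm{round}(6s + \varepsilon(0.6))$ clamped to
  $[0,6]$. The ELF noise of 0.4 was set so that the severity–ELF rank
  correlation is ≈ 0.95 at $n = 100$, a deliberately strong link: the
  generator validates *recovery of a planted effect*, not marker biology.

The equilibrium slice adds an enhancement field whose whole-liver ROI mean
is pinned *exactly* to $\mathrm{ecv} \cdot \Delta HU_\mathrm{blood} /
(1 - \mathrm{haematocrit})$, so the ECV relation holds by construction and
recovery error is pure measurement noise. The field is split three ways:
35 % uniform, 15 % painted on the blob component (interstitial
enhancement), 50 % on a subcapsular rim (Gaussian radial profile centred
5 mm deep, width 1.5 mm), reflecting the peripheral predominance of
fibrotic interstitium. The split matters for a subtle reason: the
filtration kernel has zero DC gain, so any spatially *uniform* enhancement
contributes nothing to the filtered mean over an interior region — after
band-pass filtering, the mean over an ROI is carried almost entirely by
structure near the ROI's interaction with real image edges. Concentrating
enhancement at the capsule places that structure inside the peripheral
wedge's sampled band, which is what makes the equilibrium-minus-pre mean
at medium scales a recoverable, monotone readout of severity. Vessels
brighten by the full blood enhancement at equilibrium; their centres are
kept away from the wedge sector, emulating the clinical practice of
drawing the wedge ROI to avoid visible vessels (vessel leak into
subtracted features would otherwise dominate the wedge's variance — the
acknowledged vessel-contamination error mode of subtraction imaging,
which still affects the whole-liver ROI here).

Three contiguous sections per phase (same anatomy, fresh noise) are
generated for the ECV measurement; texture always uses the designated
first section.

**Hepatocyte-loss mode** (`hepatocyte_loss = TRUE`) models the hypothesis
that advancing fibrosis *reduces* pre-contrast background texture through
loss of hepatocytes: the parenchymal mottle becomes coarser and stronger
(σ 2.5 mm, amplitude 12 HU) and fades as $12(1 - 0.8s)$, while
pre-contrast collagen is nearly isodense (blob amplitude 6 HU). This
plants a *negative* coarse-scale SD/entropy/MPP link with severity. With
the ordinary defaults instead, the rising blob density cancels the mottle
decline and no consistent negative link exists — which is why the mode
changes these defaults together. It is a modelling hypothesis for a
qualitative phenomenon, not a claim about any clinical dataset.

### What the phantoms do and do not establish

Passing tests on phantoms establish that the pipeline's mathematics is
correct and that effects *of the planted kind* (monotone, medium-scale,
enhancement-borne) are recovered with the stated power at clinical sample
sizes. They do not establish clinical validity: phantom livers are discs,
enhancement physics is reduced to its first moment, noise is white rather
than reconstruction-kernel-correlated, the severity links are chosen, and
single-slice 2-D analysis is assumed throughout.

## Numerical and degenerate-input conventions

* Convolution is direct (kernel-weighted shifted sums), not FFT, for exact
  reproducibility; kernels are even, so convolution equals correlation.
* Mirror boundary; kernel truncation at $4\sigma$; erosion radius
  $\lceil 2\sigma \rceil$ px per axis.
* HU out of $[-1024, 3071]$, non-finite pixels, non-positive spacing:
  validation errors, never silent repair.
* Registration between phases is *asserted* (equal shapes, spacings within
  $10^{-6}$ mm), never computed; mismatches drop the equilibrium phase
  with a warning rather than aborting a patient.
* Zero-variance regions: flagged zero skewness/kurtosis/entropy. Empty
  positive set: flagged zero MPP. Sub-minimum samples: sampling error.
* All randomness flows from explicit seeds; cohort per-patient seeds
  derive deterministically from the master seed; identical configurations
  give byte-identical CSV reports.

## Problem sizes used by the validation suite

The suite validates the statistics on cohorts of $n = 29$ patients with
the equilibrium phase present in 21 — a realistic partial-availability
pattern — with 100 replicate cohorts for the positive planted effect, 200
for the negative one, 100 phantoms for ECV recovery and 1000 null cohorts
for type-I calibration; phantoms are 96 × 96 px. These sizes put each
Monte-Carlo standard error well below the margins being asserted while
keeping the default suite quick to run.

## Known limitations

* The kernel is an interpretation of an unpublished vendor filter; only
  its documented properties (zero DC, scale selection under $\gamma=1.6$,
  sign convention) should be relied upon, not agreement with any
  proprietary implementation.
* Entropy depends on the binning convention; compare entropies only
  within a fixed configuration.
* 2-D single-slice analysis; no volumetric features.
* The t-approximation p-value is approximate under heavy ties at very
  small $n$; use the exact option there.
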