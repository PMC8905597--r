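---
title: "Methods: multi-atlas normative detection of MD-abnormal brain tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-atlas normative detection of MD-abnormal brain tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdaqp)
```

# The problem

Post-traumatic edema appears on diffusion MRI as mean-diffusivity (MD)
abnormalities: cellular (cytotoxic) edema restricts water diffusion and
lowers MD, vasogenic edema adds extracellular water and raises it. The
package quantifies both — where, which type, and how many millilitres —
by comparing a subject's MD map against normative values built from
control subjects, region by region, across several parcellations of the
same brain.

# The detection model

## Normative model

For each of $N$ parcellations (atlases) $a$ and each region $r$, the MD
values of all brain voxels outside CSF are pooled **voxel-wise across the
control subjects**, giving $\mu_{a,r}$ and $\sigma_{a,r}$ (sample sd,
$n-1$). Pooling voxels rather than per-subject region means is deliberate:
with cohorts as small as 3 controls per site there is no basis for
estimating between-subject variance separately; the pooled spread absorbs
both spatial and inter-subject variation into a single working dispersion.
Regions pooling fewer than 25 voxels are flagged low-confidence.

"Outside the normal range" is formalised as a z-interval:
$z_a(v) = (\mathrm{MD}(v) - \mu_{a,r(v)}) / \sigma_{a,r(v)}$, abnormal when
$|z_a(v)| > z_0$ with $z_0 = 3$ by default. A percentile formulation would
need far more control data than three subjects provide; the Gaussian
interval is the minimal assumption consistent with a "normal range".
Degenerate regions with $\sigma = 0$ give $z = 0$ when the subject matches
the mean and $\pm\infty$ otherwise, so any deviation in an all-identical
region counts as abnormal.

## Voting and typing

A voxel is typed *low* when $z_a(v) < -z_0$ in at least $K$ of $N$ atlases
(default $K = 4$ of $N = 6$) **and** its low votes strictly exceed its high
votes; symmetrically for *high*. Votes are counted per direction, not
pooled: a voxel oscillating between directions across atlases is not a
coherent lesion. For $K \le N/2$ a direction tie is possible; tied voxels
are discarded — an untypeable voxel should not be reported as either edema
class. The multi-atlas vote is the core false-positive control: each atlas
misjudges voxels near its own region boundaries (where a region mixes
tissues), but different atlases have decorrelated boundaries, so real
lesions accumulate votes while boundary artifacts do not.

## Exclusions and size filtering

Exclusions run **before** component labelling (exclusion is defined
voxel-wise; applied after labelling it could leave sub-threshold
fragments):

* CSF/ventricle voxels are removed from both classes;
* high-MD voxels strictly closer than 3 mm (Euclidean, spacing-aware exact
  distance transform) to a CSF voxel are removed — partial-volume CSF
  mimics vasogenic edema; cellular edema (low MD) cannot be mimicked by
  CSF, so the low class keeps its voxels near CSF;
* connected components (26-connectivity by default) below the class
  minimum volume are removed: 0.12 ml (low), 0.16 ml (high). The
  thresholds are **inclusive** — "minimum size" reads as the smallest
  allowed lesion, so a 0.120 ml low-MD component survives.

Volumes are reported in ml (voxel count × voxel volume / 1000) and as a
percentage of the brain-mask volume. In the synthetic setting the full
brain mask stands in for the supratentorial volume (no tentorium is
modelled); a supratentorial mask can be supplied for real data.

# The phantom generator

## What it emulates

`make_brain()` builds an ellipsoidal brain with a cortical grey-matter
shell, white-matter interior and two ellipsoidal lateral ventricles (CSF).
MD per tissue is mean + sd × (0.8 × smooth Gaussian random field + 0.6 ×
white noise); the smooth field (correlation length 6 mm FWHM) mimics slow
biological and coil-profile variation, the white part measurement noise,
and the 0.8/0.6 split keeps the total per-voxel sd equal to the stated
tissue sd. Defaults: WM 0.75·10⁻³ ± 0.03·10⁻³, GM 0.85·10⁻³ ± 0.04·10⁻³,
CSF 3.0·10⁻³ ± 0.2·10⁻³ mm²/s — means are textbook adult values and the
4–7% dispersions match typical regional inter-subject variability of MD.
Controls share the geometry but draw independent fields and a ±3% global
scale jitter (inter-acquisition gain).

`insert_lesions()` follows the insertion protocol: blob-shaped supports
(unions of random spheres, mimicking irregular contusional edema) are
placed in parenchyma — more than 4 mm from CSF and 2 mm from the brain
edge, where a radiologist would draw edema and where the detector's CSF
margin cannot silently erase the ground truth — and MD is multiplied by
$1 + w\,(c-1)$, where $c \sim U(0.41, 0.91)$ for low or $U(1.10, 2.10)$
for high lesions and $w$ is the binary support smoothed by a 3 mm FWHM
Gaussian, rescaled to peak 1. Only MD is modified; tissue masks are
untouched. The ground truth of a lesion is its $w \ge 0.5$ core — the
visually apparent lesion, not the smoothing halo, which is partial volume.
Total core volume is driven to the target lesion load (default 2.2% of
brain volume, at the lower end of a clinically plausible 2–4% load) by growing supports until
the measured core reaches the per-lesion target. Per phantom the default
is 1 low + 2 high lesions with a 30/70 low/high volume split — in trauma
cohorts vasogenic (high-MD) edema dominates the lesion load by a wide
margin, and three lesions is a typical multifocal presentation that still
leaves each lesion well above the minimum-size filters at desk scale.

"3 mm half-width" is read as FWHM ($\sigma = 3/(2\sqrt{2\ln 2}) \approx
1.27$ mm), the usual radiological usage; a half-width-at-half-maximum
reading ($\sigma \approx 2.55$ mm) is selectable via
`phantom_spec(smoothing_width_is = "hwhm")`.

## What it does not emulate

No gyral anatomy, skull, or tentorium; no hemorrhage (explicitly out of
scope), no susceptibility or motion artifacts, no multi-site scanner
heterogeneity; the six parcellations are brain-restricted rectangular
block partitions at two scales (12 and 20 mm) with per-atlas random
offsets — they reproduce the decorrelated-boundary property that makes
multi-atlas voting work, not anatomical homology. A green phantom test
therefore establishes the correctness and calibration of the machinery
under the stated simulation, not clinical performance.

## Stand-in atlases

Block partitions are restricted to the brain mask, regions under 10 voxels
are merged into their most frequent face-neighbour, and each atlas must
retain at least 20 regions (smaller brains raise an error rather than
degrade silently). With one atlas the procedure degenerates gracefully:
`K` is clamped to the atlas count, giving a per-region outlier test.

# Numerical choices

* **Tensor fit**: ordinary (unweighted) log-linear least squares over the
  six unique tensor components, the canonical baseline; weighted or
  nonlinear variants change MD negligibly at the SNRs simulated here.
  Signals ≤ 0 are clamped to $10^{-6} S_0$ before the log; voxels with no
  positive $b_0$ signal are dropped from the fit mask rather than erroring;
  negative MD estimates are clamped to 0 and counted.
* **Distance transforms**: exact anisotropic squared-distance transform
  (three-pass parabolic envelope) in C++; "< 3 mm" is strict, and a voxel
  at exactly 3.0 mm is kept (tested at machine precision).
* **Surface distances**: border voxels are mask voxels with a face
  neighbour outside (grid edge counts as outside); distances are between
  voxel centres. HD is the max of the two directed maxima; ASSD pools both
  directions' surface distances before averaging.
* **STAPLE**: E-step in log space; $p, q$ initialised at 0.9, clamped to
  $[10^{-6}, 1-10^{-6}]$; convergence at max $|\Delta p, \Delta q| <
  10^{-6}$ or 100 iterations; prior $\pi$ = mean rater foreground fraction
  in the ROI. Computation is restricted to the rater union dilated by one
  voxel plus an equal-sized seeded background sample — run over a whole
  agreed-empty brain, specificity saturates at 1 and the fusion degrades
  (the classic STAPLE pitfall). The observed-data log-likelihood is
  asserted non-decreasing at every iteration. The two lesion classes are
  fused independently: they are distinct clinical entities.
* **Empty-mask conventions**: Dice/precision/recall are 1 when both masks
  are empty (needed for lesion-free specificity runs; flagged
  `both_empty`), 0 when exactly one is; surface distances are undefined
  for empty masks and reported as `NA` in batch rows.
* **ICC**: fixed to ICC(2,1), two-way random effects, absolute agreement,
  single measurement — the variant that penalises systematic volume offsets
  between methods, which is what a method-agreement claim needs.
* **Corrupted slices**: a slice's brain-mean intensity is first divided by
  the median of the *same slice* across volumes of the same b-value, which
  cancels anatomy; the robust z (median/MAD across slices of the volume) is
  then thresholded at 4, with an additional minimum relative deviation of
  10%. A within-volume z on raw slice means — the obvious simpler rule —
  false-flags clean edge slices, because slice means vary smoothly and
  strongly across the brain while their MAD stays small; the same-slice
  normalisation is what dropout detectors in DWI practice use. Volumes
  whose b-value has fewer than 3 volumes have no reference and are skipped.
* **Determinism**: every stochastic stage draws from a named substream
  derived from one root seed (`phantom`, `control`, `lesion`, `atlas`,
  `raters`), so adding a stage never perturbs the others and the full
  experiment is a pure function of its config.

# Simulated raters

Each simulated expert is the ground truth degraded by boundary jitter
(blur + smooth noise field, re-thresholded at 0.5), occasional misses of
small lesions (< 0.5 ml — experts overlook small foci, not large edema),
and occasional false components. The jitter amplitude is calibrated per
rater by bisection so the pooled Dice against ground truth lands in a
realistic expert band (0.70–0.80 by default); infeasible bands raise an
error rather than silently missing. A zero error model returns the ground
truth exactly.

# Known limitations

* **Desk-scale geometry inflates relative volume error.** The smoothing
  halo around an inserted lesion has a fixed physical width (set by the
  3 mm kernel and the detection threshold), so the detector's
  overestimation relative to the $w \ge 0.5$ core scales like
  $(1 + h/r)^3 - 1$ for lesion radius $r$. On 64³ phantoms (~100 ml brain,
  lesions of 5–7 mm radius) this ratio is 2–3× larger than for the
  10–20 mm radius lesions that a full-size brain accommodates at the same
  lesion load. Overlap metrics are much less sensitive to the halo than
  the signed volume error; specificity is unaffected (lesion-free phantoms
  yield 0 ml after size filtering).
* Weak lesions are invisible by construction: a coefficient near the top
  of the low range (e.g. 0.9) moves MD by less than the normative spread,
  and no voxel-wise method can detect it; phantom-level metrics average
  over the drawn coefficient mix.
* The normative model assumes the subject's grid already matches the
  controls and atlases; no registration or resampling is performed, and a
  grid mismatch is an error by design.
* STAPLE results depend mildly on the ROI convention; the one used here is
  declared (union + 1 voxel + matched background sample), not inferred
  from any reference implementation.

```{r example, eval = FALSE}
# the full validation experiment, reproducible from one seed
ex <- run_phantom_experiment(experiment_config(seed = 20240101))
ex$summary
```
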