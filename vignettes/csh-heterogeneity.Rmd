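---
title: "Quantifying mid-treatment metabolic heterogeneity with cumulative SUV-volume histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mid-treatment metabolic heterogeneity with cumulative SUV-volume histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cshpet)
```

## The model

`cshpet` analyses paired FDG-PET scans of a primary tumour — a baseline
("week 0") and a mid-radiotherapy ("week 3") acquisition — to quantify how
the tumour's metabolic profile changes early during treatment. The working
assumption, which motivates the whole design, is mechanistic: poorly
responding tumours harbour radioresistant subclones whose uptake declines
less than the rest of the lesion, so heterogeneity *persists* in poor
responders and *resolves* in good ones.

Heterogeneity is scored from the cumulative SUV-volume histogram (CSH).
For a tumour ROI with maximum uptake $M$, the CSH is

$$ y(x) = \frac{\#\{v : \mathrm{SUV}(v) \ge x\,M\}}{\#\text{ROI voxels}},
   \qquad x \in [0, 1], $$

the fraction of tumour volume at or above each fraction of the maximum.
AUC-CSH is $\int_0^1 y(x)\,dx$: a perfectly homogeneous ROI yields exactly
1, and a small, very hot focus on a cooler bulk drags the score far down.
It is deliberately a *first-order* heterogeneity measure — reproducible
across scanners and trivially implementable in clinical software, unlike
higher-order texture features, which are out of scope here.

Alongside AUC-CSH the package extracts SUVmax, SUVmean, MTV (metabolic
tumour volume, mL) and TLG = SUVmean × MTV, and forms the longitudinal
percentage changes $\Delta = (\text{week3} - \text{week0}) / \text{week0}
\times 100\%$ for all five. Two pre-specified binary response rules

- favourable volume response: $\Delta\mathrm{MTV} \le -50\%$ (boundary
  inclusive), and
- favourable heterogeneity response: $\Delta\text{AUC-CSH} > 0\%$ (strict)

drive two three-group risk stratifications, ordered best-to-worst:

| group | p16 × ∆AUC-CSH scheme | ∆MTV × ∆AUC-CSH scheme |
|---|---|---|
| 1 | p16-positive, favourable ∆AUC-CSH | favourable ∆MTV |
| 2 | p16-negative (not subdivided) | unfavourable ∆MTV, favourable ∆AUC-CSH |
| 3 | p16-positive, unfavourable ∆AUC-CSH | both unfavourable |

The survival layer compares the groups by Kaplan-Meier estimation and the
Mantel-Cox log-rank test, reads off 2-year locoregional recurrence-free
survival (LRRFS), and fits Cox regressions of the delta features — in
multivariate mode always adjusted for the a-priori clinical trio
(p16 status, TNM stage, chemotherapy), one imaging feature at a time.

## Parameters that matter

- **Bin width (SUV 0.3, unitless SUV).** SUVs are discretised into
  fixed-width bins before the CSH is formed; a fixed bin size is preferred
  over fixed bin *count* for cross-scan reproducibility, and 0.3 gives a
  workable number of bins over the clinical SUV range (≈ 40 bins for SUVs
  up to 12). Configurable via `discretisation_config()`.
- **Bin anchor (SUV 0).** Bin edges sit at $k \times 0.3$ absolute SUV, so
  bins are comparable across scans and timepoints. The anchor is recorded
  in every run manifest.
- **∆MTV cut-off (50%) and ∆AUC-CSH cut-off (0%).** Pre-specified, not
  data-driven: the package deliberately offers no optimal-cut-point
  search. `stratification_config()` exposes both for sensitivity analyses.
- **Segmentation defaults** (`segmentation_config()`): smoothing scale =
  one voxel spacing, minimum seed SUV 2.5, 200 mL region cap. These are
  pragmatic defaults for FDG-avid head-and-neck primaries and are logged
  with every run.
- **Survival time origin.** LRRFS is measured from diagnosis by default;
  `run_config(time_origin = "treatment_end")` switches to an
  end-of-treatment origin when the cohort table carries the offset column.

## Numerical choices

**"At or above" versus "above".** With discretised values the CSH is a
step function; if the top threshold used a strict "greater than", the last
point would be identically zero and AUC-CSH could never reach 1, breaking
the defining homogeneity limit. The package therefore counts voxels with
uptake **≥** the threshold, so a single-bin ROI gives the two-point curve
{(0, 1), (1, 1)} and AUC-CSH exactly 1.

**Step integration.** Between successive thresholds $x_{i-1} < x \le x_i$
the fraction of voxels at or above $x M$ is constant at $y_i$ (voxel
levels only exist at the thresholds), so the exact area is
$\sum_i y_i (x_i - x_{i-1})$. This equals dense-grid numeric integration
of the threshold sweep (the test suite checks agreement to $10^{-4}$ on
100 random phantoms) and is what `auc_csh()` computes; trapezoidal
integration is available via `discretisation_config(integration =
"trapezoid")` for comparison with tools that interpolate the curve.

**What gets discretised.** The CSH (and hence AUC-CSH) is computed on bin
centres, since discretisation precedes feature extraction; the x-axis is
normalised by the *top occupied bin centre* (switchable to raw values via
`values = "raw"`). SUVmax, SUVmean, MTV and TLG are computed on raw voxel
values — binning a maximum would only add quantisation error to features
that need none.

**Masks are taken literally.** Volumes and masks must share the grid
exactly (shape identical, spacing within $10^{-3}$ mm); the pipeline never
resamples, because silent interpolation of SUVs corrupts both the maximum
and the histogram. Multi-component masks are pooled as one ROI. Week-0 and
week-3 ROIs are treated as independently delineated per-scan masks; no
propagation or registration between timepoints is attempted.

**Kaplan-Meier / log-rank conventions.** Events precede censorings at tied
times; the log-rank statistic uses the hypergeometric (ties-corrected)
variance and, for $k$ groups, the quadratic form over $k-1$ groups with
df $= k-1$. Both are implemented in-package and are verified against
brute-force risk-set/O–E enumeration oracles and cross-checked against
`survival::survfit()`/`survdiff()` in the tests; Cox regression is
delegated to `survival::coxph()`, with non-convergence surfaced rather
than clipped. Significance is two-sided at 0.05 with no multiplicity
correction. Hazard ratios for delta features are per percentage point.

**Gradient segmentation stand-in.** Commercial gradient-edge delineation
tools are proprietary, so `gradient_segment()` implements a documented
analogue: Gaussian smoothing, rays cast from the intensity-weighted
centroid, the boundary at each ray's maximal radial gradient magnitude,
and 26-connected growth from the seed. Because only the *location* of the
gradient maximum matters, the contour is invariant to rescaling image
contrast. It is a stand-in, not a replication — which is why the I/O layer
accepts externally delineated masks, so segmentation quality never gates
feature extraction.

## The synthetic-data generator

Phantoms are built from analytically known geometry: a base lesion sphere
(default SUV ~4–8) on low background (0.4), hot subclone spheres at
2.2–2.8× the base uptake, and additive Gaussian noise (SD 0.3 SUV),
clipped at zero. Discrete subclone spheres — rather than textured random
fields — were chosen because they match the radioresistant-subclone
mechanism the analysis targets and give closed-form volumes to test
against.

The mid-treatment response erodes the lesion support, shell by shell, to
the prescribed volume fraction (the final partial shell is stripped
outermost-first, so the achieved ∆MTV lands within one voxel of the
target), declines the surviving base uptake, and treats each subclone's
*excess* over the declined base separately: week-3 subclone uptake is
$b(1-d) + p\,(v_0 - b)$, where $p$ is the persistence multiplier. $p = 0$
homogenises the subclone (heterogeneity resolves, AUC-CSH rises), $p = 1$
keeps its full hot excess (heterogeneity persists, AUC-CSH falls). A
multiplier on the excess — not on the final value — is the only
formulation in which "full persistence" leaves the subclone hot while the
bulk declines, which is the behaviour being modelled.

Cohorts draw a risk group per patient (default fractions 0.70/0.20/0.10),
group-conditional responses (group 1: shrink 55–75%; groups 2–3: shrink
15–40%, with persistence 0.25–0.50 for group 2 and 1.0–1.2 for group 3),
and exponential recurrence times with monthly hazards derived from target
2-year survivals of 0.93/0.70/0.17, under uniform administrative censoring
over 5–88 months. This calibration — chosen once, recorded in
`cohort_spec()` defaults — reproduces the qualitative cohort structure the
pipeline is meant to resolve (roughly 18% two-year recurrence overall,
with steep inter-group separation, mean volume reductions around one half
and mean heterogeneity decreases of a few tens of percent); it is a
calibration, not patient data. p16 status and the clinical covariates are
drawn with realistic marginal frequencies but independently of the
imaging response, which is the conservative choice for testing the
imaging-driven stratifications.

What the generator does **not** emulate: scanner physics (point-spread
function, reconstruction artefacts, partial-volume effects), respiratory
motion, nodal disease, delineation variability, or any correlation
between clinical covariates and response. Passing tests therefore
demonstrate the *computational* correctness of the pipeline and its
statistical behaviour under the assumed response model — not clinical
performance on real imaging.

## Validation design and problem sizes

Every operation with a defined ground truth is tested against an
independent oracle: all-voxel loops for first-order features ($10^{-12}$
relative, 100 random phantoms), dense-grid threshold sweeps for AUC-CSH
($10^{-4}$, 100 phantoms), risk-set enumeration for Kaplan-Meier
($10^{-12}$, 100 small samples), and O–E table enumeration for the
log-rank statistic (an exhaustive sweep of two-group samples of size 4 on
a binary time grid plus 300 random samples up to $n = 8$). Distributional
properties use seeded simulation: exponential-cohort self-consistency at
$n = 5000$, Cox log-HR recovery at $n = 2000$ over 50 seeds, and the full
phantom-to-log-rank pipeline at the default cohort size of 114 over 100
seeds. These sizes keep each suite deep enough to be meaningful while the
whole validation runs in a few minutes on one core.

## Limitations

- AUC-CSH is a global first-order summary; two differently organised
  tumours with the same uptake histogram are indistinguishable.
- The segmentation module approximates, and cannot replicate, the
  consensus expert delineation workflow of clinical practice.
- The synthetic response model is spherical-shell erosion plus uniform
  decline; real response geometry is irregular.
- Stratification results on synthetic cohorts validate the machinery, not
  the clinical cut-offs; the pre-specified thresholds ship as defaults
  precisely so external cohorts can be analysed without re-tuning.
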