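---
title: "Fractal measurement and the posterior-fossa scoring system: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal measurement and the posterior-fossa scoring system: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracvox)
```

This vignette is the package's account of its science: the measurements it
implements, the statistical procedure behind the scoring system, the choices
made where the design was genuinely open, and the limits of what the test
suite demonstrates.

## The measurement model

### Box-counting fractal dimension

A binary tumor mask on a uniform grid is measured by tiling its tight
bounding box with cubic windows of edge $s$ voxels and counting the windows
that contain at least one occupied voxel, $N(s)$. For a set with fractal
scaling $N(s) \propto s^{-D}$, so the dimension is estimated as the ordinary
least-squares slope of $\log N(s)$ against $\log(1/s)$:

$$\widehat{FD} = \mathrm{slope}\;\big(\log N(s) \sim \log 1/s\big).$$

Anchors with known dimension calibrate the estimator exactly: a filled cube
(3), a one-voxel slab (2), a line (1), and the level-$k$ Menger sponge,
whose grid-mode box counts at scales $3^j$ are exactly $20^{k-j}$, giving
slope $\log 20 / \log 3 = 2.7268\ldots$ to machine precision.

Conventions. Measurement is grid-native: the NIfTI affine is carried but
never interpreted, indices are 0-based half-open, and no resampling is
performed — volumes are expected on a harmonized grid (e.g. 1 mm³), and a
mask/volume pair with unequal shape or spacing is rejected. In grid mode the
tiling starts at the ROI bounding box's low corner and partial edge windows
are kept (clipped), which makes the count translation invariant and lets
flat objects (a slab of thickness 1) be measured; for that reason the
default scale ladder — powers of two from 2 up to half the grid extent — is
bounded by the *largest* extent in grid mode and by the smallest in gliding
mode, where a window must fit the grid. Axes shorter than $s$ collapse to a
single clipped window in either mode. At least three scales are required
for any slope fit; a degenerate all-equal curve is reported as slope 0 with
$R^2 = 1$.

### Lacunarity

Lacunarity quantifies gappiness at each scale. The per-scale coefficient
implemented as the default ("literal") statistic is the mean, over windows
whose voxel-value mean $\mu_w$ is positive, of the squared coefficient of
variation inside the window,

$$\Lambda(s) = 1 + \frac{1}{|W^+|}\sum_{w \in W^+}
  \left(\frac{\sigma_w}{\mu_w}\right)^2,$$

with population $\sigma_w$ (a window is a complete enumeration, not a
sample) and gliding (stride-1) windows by default. The $+1$ normalization
makes the homogeneous limit exactly $\Lambda = 1$ so that logs are always
defined and a uniform mask has lacunarity index exactly 0; `normalize =
FALSE` recovers the raw mean CV². For a binary window with fill fraction
$p$ the statistic has the closed form $(1-p)/p$, which the tests verify to
1e-12. The **lacunarity index** is the log-log slope of $\Lambda(s)$
against $1/s$, fitted like the fractal dimension.

The classical gliding-box alternative — CV² of window *masses* across
window positions — is available via `statistic = "glidingbox"`. The two
conventions measure different things and can even order fixtures
differently: a clustered mask has uniformly higher gliding-box $\Lambda(s)$
and a higher gliding-box index than a dispersed mask of equal fill (the
textbook contrast), while under the literal statistic the clustered mask's
large-scale windows that barely graze a cluster have tiny means and
enormous CV², making $\Lambda$ *rise* with $s$ and the index more negative.
The test suite asserts the clustering contrast under the gliding-box
statistic for exactly this reason.

### 4D intensity lacunarity

Intensity texture is folded into geometry by treating the voxel value as a
fourth coordinate: ROI intensities are linearly quantized to
$L$ levels (default: the largest ROI extent clamped into $[16, 256]$, so
fourth-axis cells stay commensurate with spatial cells; a constant ROI maps
to level 0), and ROI voxel $(x,y,z)$ with level $\ell$ occupies the single
4D cell $(x,y,z,\ell)$. The same window engine then measures $\Lambda(s)$
over 4D hypercubic windows. Because quantization is range-normalized, the
result is invariant to affine intensity rescaling.

Full 4D enumeration is expensive, so each window of $n$ cells may be
estimated from $k = \min(n, \max(\texttt{min\_cells}, \lfloor
\texttt{rate}\cdot n\rfloor))$ cells drawn uniformly without replacement
(default rate 0.01). The draw for each window is keyed to (seed, window
index) by a counter-based generator, so results are bit-reproducible and
independent of the worker count or chunking. Windows whose sample contains
no occupied cell are dropped — the sampled analogue of the empty-window
rule. At `rate = 1` the computation routes to the exact integral-image
engine; the sampling path at rate 1 enumerates every cell and agrees with
the exact path to 1e-12, which the tests check as a dual-route identity.

**Known limitation — small-sample bias of the subsampled CV².** The sampled
occupancy mean $\hat\mu_w$ is unbiased (verified over hundreds of seeds),
but CV² is a nonlinear function of $\mu_w$, and for small windows the
default rate yields $k$ of only 1–2 cells, whose population variance is
(near-)identically zero: at $s = 2$ every kept window reports CV² $= 0$ and
$\Lambda(2) \equiv 1$ regardless of the data. Exact $\Lambda$ at larger
scales is additionally dominated by near-empty "grazing" windows whose tiny
means cannot be resolved at 1:100 sampling ($\hat\mu_w$ has resolution
$1/k$). On a 48³ smooth-gradient phantom the subsampled index therefore
deviates from the exact index by tens of percent, consistently across
seeds — a bias, not noise. Users who need fidelity at small scales should
raise `min_cells` (or `rate`); the defaults reproduce the published
operating point (rate 0.01), and the acceptance suite reports the deviation
rather than hiding it.

### Per-patient features

`measure_patient()` composes the three automated features consumed by the
scoring system — mask FD, FLAIR LI inside the mask, and the physical volume
(occupied voxels × voxel volume / 1000, in cm³) — and leaves the cystic
flag, a radiological reading, for manual entry.

## The scoring system

Each class $c$ (other tumor, medulloblastoma, pilocytic astrocytoma) has a
linear score $T_c = \sum_i w_{ci} x_i$ over raw-unit features
{FD, FLAIR LI, cystic ∈ {0,1}, volume in cm³} and a threshold $\theta_c$.
A class is eligible when $T_c > \theta_c$ (strictly); among eligible
classes the largest delta $T_c - \theta_c$ wins, with exact ties broken by
the fixed class order (other, medulloblastoma, pilocytic astrocytoma) —
ties are measure-zero and the rule only pins determinism. When no class is
eligible the system abstains. Within physiologic feature ranges the
pilocytic threshold (−5.682) is almost always exceeded, so abstention is
nearly unreachable with the published weights; the rule is implemented as
published and this behavior is simply flagged here.

`published_model()` returns the published weights and thresholds;
`odds_ratio()` (= exp(weight), displayed to 3 decimals) reproduces all 12
published odds ratios.

## The fitting procedure

`fit_scoring_system()` regenerates a scoring system of the same form from a
cohort table:

1. **Scaling.** Continuous features are min-max scaled to [0, 1]; the
   (min, range) factors are retained.
2. **Screening.** A candidate passes if it separates at least one class
   from the rest at p < 0.05 — Fisher's exact test for binaries, pooled
   t-test for continuous features.
3. **Selection.** A two-stage greedy exhaustive search maximizes the mean
   out-of-bootstrap AUC: all non-empty subsets of the fractal candidates
   first, then, with the fractal winners fixed, all subsets (including the
   empty one) of the clinical candidates. Staging avoids the combinatorial
   explosion of a joint search; ties prefer the smaller subset, then
   lexicographic order.
4. **Bootstrap.** For each of $n = 100$ resamples (with replacement, cohort
   size), one unpenalized maximum-likelihood logistic model per class is
   fit one-vs-rest on the scaled features (IRLS fallback with a 1e-6 ridge
   on the slopes when the fit separates or fails to converge; convergence
   tolerance 1e-8; a class with fewer than 3 members in a resample skips
   the replicate, logged). Each replicate is evaluated on its
   out-of-bootstrap patients: tie-corrected rank AUC per class, plus macro
   accuracy/precision/recall of the threshold-and-delta classifier at the
   0.5-probability thresholds, with abstentions counted as errors.
   Replicates with an empty or one-class out-of-bootstrap set contribute
   the fit but no evaluation. Confidence intervals are 2.5/97.5 percentiles
   across replicates.
5. **Absorption.** Weights are averaged across replicates (the averaging
   reading of "mean regression weights across the bootstrapped samples"),
   then mapped to raw units: $w^{raw} = w / \mathrm{range}$, intercept
   shifted by $-\sum_i w_i\,\mathrm{min}_i/\mathrm{range}_i$, and the class
   threshold set to the negated absorbed intercept — the unique choice that
   makes "total > threshold" coincide with "logit > 0", i.e. probability
   one half. Raw-unit scoring is algebraically identical to scaled-form
   scoring, which the tests verify to 1e-10 on random patients.

Design notes. One-vs-rest with per-class thresholds is inferred from the
three separate published models; out-of-bootstrap means patients absent
from the resample; scaling factors are computed once on the full cohort
(the factors are part of the published artifact, not per-replicate
estimates).

## Interobserver agreement

`cohens_kappa()` computes voxel-wise chance-corrected agreement between two
segmentations over a support region. Whole-volume evaluation would inflate
agreement with shared empty background, so the default support is the union
bounding box padded by 5 voxels (configurable). `icc_2_1()` implements the
two-way random-effects, absolute-agreement, single-rater ICC from the
mean-squares decomposition; absolute agreement penalizes systematic rater
shifts. Both offer seeded nonparametric bootstrap percentile CIs (1000
draws by default over voxels/subjects).

## Synthetic data: what it emulates and what it does not

Patient MRIs behind the published cohort are not deposited, so the package
generates its own study material:

- **Analytic shapes** (cube, slab, line, Menger sponge) pin the estimators
  to exact mathematics.
- **Porous vs clustered masks** (equal fill, i.i.d. Bernoulli vs Gaussian
  blobs) provide the lacunarity contrast.
- **Gradient intensity phantoms** (linear ramp ± Gaussian noise) exercise
  the 4D path with a smooth, controllable intensity structure.
- **`make_cohort()`** draws per-patient feature rows {FD, FLAIR LI, cystic,
  volume, sex, class} from class-conditional distributions chosen once to
  mirror the published cohort's structure: 14/13/17 patients per class,
  pilocytic astrocytoma with lower FD (2.10 ± 0.30 vs 2.30/2.50) and
  frequent cysts (p = 0.65 vs 0.40/0.15), medulloblastoma with distinctly
  lower FLAIR LI (0.65 ± 0.40 vs 1.00), "other" histologies with smaller
  volumes (log-normal medians 24 vs 40/44 cm³, overall median near the
  published 36 cm³), and sex assigned by exact stratified counts (25 of 44
  female). These effect sizes put the fitted out-of-bootstrap AUC in the
  published 0.7–0.8 operating regime; they are configuration, not truth
  claims.
- **`make_logit_cohort()`** draws features from class-agnostic marginals
  and labels from the softmax of three *known* linear class scores, so the
  fitting pipeline can be checked against ground truth: sign recovery of
  every generating weight and out-of-bootstrap AUC within a small gap of
  the generator's simulated true AUC (`true_model_auc()`, 1e5 draws).

Passing tests on this material shows the estimators and the fitting
machinery are correct and calibrated on known structure. It does not show
that FD/LI separate real histologies — that evidence lives in the clinical
data the package cannot ship — nor does it reproduce the published
real-cohort AUCs, which are out of scope by construction.

## Numerical choices

- Window sums via N-dimensional integral images (inclusion–exclusion over
  $2^d$ corners); binary masks make the integral sums exact integers, and
  the engine agrees with a brute-force nested-loop oracle to 1e-12 on
  every fixture tried.
- Work is chunked over window-index ranges; per-window results never depend
  on the chunking, so any worker count gives identical results (bit-exact
  counts; lacunarity partial sums combined in fixed chunk order, agreeing
  to 1e-12).
- Problem sizes in the tests and acceptance script (masks ≤ 16³ against
  the brute-force oracle, a 48³ phantom for the 4D path, a 300-patient
  recovery cohort with 100 bootstrap replicates) were chosen as the
  smallest sizes at which each property is informative.
- OLS slope fits are unweighted with no scale-range auto-selection; every
  curve point must be finite and positive before logs are taken.
- The subsampler's RNG is a splitmix64-style counter mix keyed by
  (seed, window index); Lemire's method maps 64-bit draws to bounded
  integers, and partial Fisher–Yates with O(k) undo keeps per-window
  sampling linear in the sample size.

## Known limitations

- The literal lacunarity statistic is dominated by near-empty windows on
  sparse inputs (see above); the gliding-box statistic is provided for the
  classical behavior.
- The subsampled 4D index is biased at scales where the per-window sample
  is only a few cells; defaults reproduce the published operating point
  rather than maximal fidelity.
- Whether the published fractal dimension used grid tiling or stride-1
  sliding, whether its lacunarity included the +1 normalization, and the
  exact scale ladder are not stated in the source material; all variants
  are implemented and the defaults documented here were chosen for exact
  analytic anchors (grid tiling for counts, gliding for lacunarity,
  normalized Λ).
- Abstention is nearly unreachable with the published weights (above).
- No preprocessing is included: coregistration, bias correction and
  resampling to a common grid must happen upstream.
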