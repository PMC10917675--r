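---
title: "Group-level DBS dysfunction mapping: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level DBS dysfunction mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsmap)
```

## The scientific problem

Deep brain stimulation (DBS) electrodes implanted in or near the subthalamic
nucleus treat several disorders — dystonia, Parkinson's disease, Tourette's
syndrome, obsessive-compulsive disorder — with outcomes that depend strongly
on exactly *where* the stimulation field falls. Because surgical targeting
varies incidentally across patients and centres, a cohort of stimulated
patients constitutes a natural experiment: correlating, across patients, the
local stimulation "dose" with clinical improvement maps which tissue (and
which axonal pathways) must be modulated for benefit.

`dbsmap` implements the two group-level mapping models used for this:

* **Sweet-spot mapping** (voxel level). Each patient-hemisphere contributes
  an electric-field (E-field) magnitude volume $E_i(v)$ in V/m on a common
  template grid. Within a *coverage mask* — voxels where at least a fraction
  $c$ (default 0.5) of fields exceed a magnitude threshold $T$ (default
  200 V/m, a conventional estimate of the magnitude needed to activate
  axons) — the per-voxel vector $(E_1(v), \dots, E_N(v))$ is Spearman
  rank-correlated with the vector of percent clinical improvements. Positive
  peaks form the sweet spot, negative ones the sour spot.

* **Fiber filtering** (streamline level). Given a normative connectome
  (a set of streamlines in the same template space), the stimulation impact
  of field $i$ on streamline $s$ is the *peak* magnitude sampled along the
  streamline, $P_{si} = \max_t E_i(x_s(t))$. Candidate streamlines — those
  with $P_{si} > 0.8$ V/mm in strictly more than 0.5 % of fields — are each
  tagged with the Spearman correlation $R_s$ between $(P_{s1},\dots,P_{sN})$
  and the improvements. The *sweet streamlines* are the top 1 % of the
  candidate $R$ distribution (positive only).

Outcome estimation inverts the models: a patient's **Sweet Spot Score** is
the mask-average of $E(v)\,r(v)$, and their **Fiber R score** ("weighted
peak 5 %") is, per hemisphere, the sum of the largest
$\lceil 0.05\,m \rceil$ values of $R_s \times P_s$ over the $m$ sweet
streamlines that the field touches; both are averaged over the two
hemispheres. Improvement itself is the percent reduction from baseline,
$100\,(b - f)/b$, since all scales involved are severity scales.

The mass-univariate $R$ and $p$ maps are descriptive: no voxel-wise or
streamline-wise multiple-testing correction is applied, by design. Model
validity is instead established by fivefold cross-validation with
permutation inference, cross-disorder specificity, and electrode-placement
control analyses.

## Model assumptions

1. **Monotone dose-response.** Spearman correlation assumes only that more
   stimulation of the relevant tissue relates monotonically to outcome —
   not linearity. All maps are therefore invariant under strictly increasing
   transforms of the outcome (a property the tests check).
2. **Shared space.** All fields and streamlines live in one template space;
   the package performs no registration. Hemispheres may be pooled directly
   (bilateral mask) or folded across the mid-sagittal plane
   (`mirror = "left"`/`"right"`, an exact sign flip of world x about 0).
3. **Compact fields.** E-fields decay quickly with distance from the active
   contact, so points outside a field's grid sample as 0 rather than
   erroring.
4. **Observation unit.** Group maps are built from E-fields pooled across
   hemispheres, each paired with its patient's improvement (the
   pooled-electrode convention of group mapping practice);
   `aggregate = "patient"` switches to one
   voxel-wise-maximum observation per patient for sensitivity analyses.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `magnitude_threshold` | 200 | V/m | coverage-mask field threshold (robustness checked at 180/200/220) |
| `coverage_fraction` | 0.5 | — | fraction of fields that must exceed it (inclusive) |
| `candidate_magnitude` | 800 | V/m | peak along streamline needed to count a field (0.8 V/mm) |
| `candidate_fraction` | 0.005 | — | fraction of fields required, strict |
| `sweet_top_fraction` | 0.01 | — | upper tail of candidate R kept as sweet |
| `score_peak_fraction` | 0.05 | — | fraction of weighted values summed when scoring |
| `step_mm` | 0.5 | mm | arclength sampling step along streamlines (below voxel size so peaks are not missed) |
| `k` | 5 | — | CV folds |
| `n_permutations` | 5000 | — | permutation iterations |

Boundary conventions follow the stated rules: the coverage rule is
*inclusive* ("at least"), the candidate rule is *strict* ("more than"), the
peak-fraction count is `ceiling` with a floor of one so sparse intersections
still score, and the sweet threshold is the 99th percentile of the
*candidate* R distribution (the only streamlines with a defined R).
Certainty weights for uncertainty visualisation are $-\log_{10} p$ (base
configurable).

## Inference: cross-validation and permutations

`sweet_spot_cv()` performs fivefold CV with fold models fitted on training
patients only — coverage masks included, so no information leaks from
held-out patients — and tests the out-of-sample Spearman correlation with
**full-refit permutation inference**: outcomes are permuted and *every fold
model is refitted* under each permutation. This is tractable because the
only outcome-dependent part of a fold refit is a rank correlation against
cached, outcome-free fold matrices (one matrix product per fold).

We implemented and measured the cheaper alternative first — permuting
outcomes against *fixed* cross-validated estimates (`kfold_cv()` default) —
and found it anti-conservative for this pipeline: over 100–200 null phantom
cohorts it rejected at 10–15 % instead of 5 %, at both n = 20 and n = 56,
because a held-out patient's estimate depends on the *other* folds' training
outcomes, inflating the variance of the observed correlation by ~1.3×
relative to the exchangeable permutation null. The fixed-estimate scheme
remains available (and `refit_permutations = TRUE` gives generic slow-mode
refitting for arbitrary models), but the calibrated refit scheme is what the
pipeline reports. Two-sided p-values use the add-one convention
$p = (1 + \#\{|\rho_\pi| \ge |\rho_{obs}|\})/(1 + B)$, so $p \in (0, 1]$.

Scalar Spearman p-values use the t approximation for $n \ge 10$, exact
enumeration of all $n!$ permutations for $n \le 7$, and 10,000 Monte-Carlo
permutations for $n = 8, 9$.

## Compromise power analysis

When the sample size is fixed by data availability, `compromise_power()`
chooses the critical sample correlation so that $\beta/\alpha$ equals a
stated ratio (default 1) for testing $\rho = 0$ against $\rho_1 = 0.4$ under
a bivariate-normal model, and reports the implied $\alpha$ and power. Two
routes are implemented: the exact sampling density of the correlation
coefficient (a hypergeometric-series form, the default) and the
bias-corrected Fisher-z approximation with mean
$\operatorname{atanh}\rho + \rho/(2(n-1))$ and sd $1/\sqrt{n-3}$. They agree
to two decimals at all sample sizes used here; the tests assert both.

```{r power}
compromise_power(94)
```

## The synthetic phantom: what it emulates and what it does not

Because patient imaging cannot be shared, every stage is exercised on a
synthetic cohort generator whose statistical structure matches what the
mapping methods assume:

* a 1 mm isotropic template grid (x-symmetric about the midline) around a
  bilateral ellipsoidal nucleus at (±11, −13, −7) mm, semi-axes 4×3×3 mm;
* three mirrored streamline bundle groups of 40 streamlines per hemisphere —
  one through the nucleus (`bundleA`), a decoy offset 3 mm (`bundleB`), and
  a `background` group ~8 mm away — built as smooth quadratic curves from a
  subcortical start through a jittered waypoint to a cortical patch
  (adjacent-segment turning angles stay below 60°);
* bilateral 4-contact linear leads (2 mm spacing) aimed at the nucleus with
  3D Gaussian placement jitter (SD 1.5 mm), the second-to-lowest "standard"
  contact active at a patient-specific amplitude drawn from 1.5–3.5 mA;
* an analytic inverse-square E-field,
  $E(x) = \kappa\,A / \max(r, 0.5\,\text{mm})^2$ with
  $\kappa = 1225$ V/m·mm²/mA calibrated so a 2 mA contact crosses 200 V/m at
  3.5 mm — a monotone compact-decay stand-in for a tissue model, not a
  physics claim;
* outcomes `improvement = 50 + effect_size · z(engagement) + noise`, where
  engagement is the field magnitude at a planted spot or the mean peak over
  a planted bundle, `effect_size = 15` percent-points and noise SD 15 % of
  the signal SD; follow-up scores are back-computed from a fixed 40-point
  baseline so percent improvement is linear in the signal. Zero-effect
  (null) cohorts draw pure Gaussian noise with a 10-point SD. Outcomes are
  never clipped; worsening is possible.

All randomness flows from explicit integer seeds; regenerating with the same
parameters reproduces cohort files byte-identically.

What the phantom does *not* emulate: tissue heterogeneity and anisotropy,
directional-lead current steering, realistic nucleus somatotopy,
registration error, scale-specific outcome floors/ceilings, or
centre-to-centre protocol variability. Passing recovery tests on the phantom
therefore demonstrates that the estimators recover the targets their model
class assumes — not that real cohorts satisfy those assumptions.

Since the phantom is mirror-symmetric, its analyses fold all fields onto the
left hemisphere (`mirror = "left"`): with bilateral pooling and no
mirroring, a 50 % coverage rule can never be met by fields that each cover
only their own hemisphere, and every unilateral streamline's observation
vector would carry structural zeros from the opposite side's fields.

## Validation experiments the test suite runs

* **Oracle equivalence**: vectorised Spearman maps, peak matrices and both
  scoring rules match plain-loop brute-force implementations to 1e-9 on
  random small instances.
* **Spot recovery**: on n = 60 cohorts with a planted spot and 15 % noise,
  the peak-|R| voxel falls within 2 mm of the planted centre in ≥ 18/20
  seeds.
* **Bundle recovery**: the planted bundle's mean candidate R exceeds the
  decoy's in ≥ 19/20 seeds, and ranking planted vs background streamlines by
  model weight gives AUC ≥ 0.9 (non-candidates carry weight 0).
* **Calibration and power**: with zero effect, the refit-permutation CV
  rejects at 5 % within the binomial 95 % interval over 200 null cohorts
  (n = 20, on a 1.5 mm grid for runtime); with a planted effect at n = 100
  the CV detects it (p < 0.05) in ≥ 90 % of seeds.
* **Specificity**: two synthetic disorders driven by disjoint bundles yield
  a diagonally dominant cross-disorder estimation matrix in ≥ 19/20 seeds.
* **Threshold robustness**: coverage masks and candidate sets shrink
  monotonically over 180/200/220 V/m.

The null-calibration cohorts use n = 20 on the coarse grid: with the exact
refit scheme the rejection rate does not depend on n, so the size is purely
a runtime choice. No empirical number appears in this vignette that the test
suite or the acceptance script does not itself compute.

## Numerical choices and degenerate inputs

* World mm coordinates throughout; 0-based continuous voxel indices; a
  voxel's centre maps through the affine (NIfTI convention); trilinear
  interpolation; out-of-grid samples are 0.
* Volumes are float32 on disk, double in memory; NaN backgrounds become 0
  with a warning at load time. TRK voxel-mm conventions are resolved against
  the header transform at load; an all-zero transform is an error, never a
  guess.
* Ties get average ranks everywhere. Constant magnitude vectors yield
  R = 0, p = 1 (no measurable association); constant outcome vectors are an
  error.
* Streamline resampling keeps original vertices and subdivides segments to
  at most `step_mm`; density maps rasterise at half the smallest voxel size.
* Gaussian smoothing is separable with per-axis sigma
  `fwhm / (2 sqrt(2 ln 2)) / voxel_size`, normalised kernels (mass-preserving
  up to boundary truncation), truncated at 4σ; `fwhm = 0` is the identity.
* Singular contact covariances in the Gaussian-seeding control are
  ridge-regularised with a logged epsilon; a cross-disorder mean R of zero
  makes the specificity ratio NA (undefined), never infinite.
* The compromise solver brackets the critical value in (0, 1) with
  `uniroot` and verifies `beta/alpha` to 1e-4; non-convergence is an error
  with the bracket reported.

## Known limitations

* The E-field generator is geometric; absolute score magnitudes are not
  comparable to FEM-based pipelines (rank-based statistics are).
* One field per hemisphere is assumed; multi-lead hemispheres must be
  pre-combined.
* The generic `kfold_cv()` fixed-estimate permutation p remains available
  for arbitrary models but is approximate (see above); use
  `sweet_spot_cv()` or `refit_permutations = TRUE` when calibration matters.
* Streamline files are read fully into memory; tested up to a few hundred
  thousand points, not full-brain multi-million-streamline connectomes.
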