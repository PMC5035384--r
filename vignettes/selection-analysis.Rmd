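---
title: "Estimating pre- and post-copulatory selection on size and shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pre- and post-copulatory selection on size and shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`shapeselect` estimates how two episodes of sexual selection — mating
success and fertilization success — act on a male's body size and genital
form, with form measured by geometric morphometrics. This vignette is the
package's account of the methods: the models and their assumptions, the
conventions and defaults, what the synthetic-data generator does and does
not emulate, and the design decisions that were genuinely open.

## The trait set

Genital form enters the analysis as a 2-D landmark outline (by default 29
points, 3 of them fixed anatomical landmarks and 26 sliding semilandmarks
defined by a slider file). `gpa_align()` removes position, orientation, and
scale by generalized Procrustes analysis, interleaving bending-energy
sliding of the semilandmarks; `relative_warps()` then extracts shape
principal components. The trait vector for selection analysis is

* **PW** — pronotum width (body size index, mm),
* **CS** — genital centroid size (the square root of summed squared
  landmark distances from the centroid),
* **RW1..RWr** — the leading relative warps, with r chosen by
  `select_rw_count()` as the smallest set whose cumulative variance
  exceeds 80%. Later warps each explain little variance, and every added
  trait inflates the quadratic model by p + 1 terms, so a cumulative
  cutoff is the pragmatic default.

Alignment is always run on the pooled specimen set (all episodes
together, `run_pipeline()` enforces this by default) so that centroid size
and warp scores live in one geometric space and per-episode gradients are
comparable.

Morphometric conventions, all deterministic:

* Rotations are restricted to proper rotations; specimens are assumed
  digitized in a consistent orientation, so reflections would be
  artifacts.
* The sliding tangent at each semilandmark is the chord between its two
  neighbors; sliding minimizes thin-plate-spline bending energy against
  the current consensus, and GPA/slide cycles repeat up to 5 times or
  until the relative change in total bending energy drops below 1e-6.
  Sliding against bending energy (rather than Procrustes distance) is the
  classical default for outline semilandmarks.
* GPA convergence: relative consensus change below 1e-8, hard cap 100
  iterations (non-convergence is an error, never a silent result). On
  return the sample is jointly rescaled so the consensus is exactly the
  mean of the aligned configurations with unit centroid size.
* Relative warps use weighting exponent zero with the uniform (affine)
  component retained, which makes them exactly the principal components of
  the aligned coordinates. Component signs are fixed by making each
  component's largest-magnitude loading positive; 2k - 4 components are
  retained (two coordinates per landmark minus translation, rotation, and
  scale).
* TPS `SCALE=` factors are stored but never applied to coordinates:
  Procrustes analysis is scale-invariant, and physical units matter only
  if centroid size is to be reported in mm. Unknown `KEY=value` lines in
  TPS records are preserved-and-ignored because the dialect drifts across
  digitizer versions.

## Selection gradients

With traits standardized to mean 0, sd 1 (sample sd, n − 1 denominator)
and fitness divided by its episode mean, the Lande–Arnold regressions are
ordinary least squares:

* first-order model: w = a + β′z, giving the directional gradients β;
* full second-order model: w = a + b′z + ½ z′γz, fitted with all linear,
  squared, and pairwise product terms simultaneously. The reported
  quadratic gradients are **twice** the squared-term coefficients (the ½
  in the surface means the raw coefficient understates curvature by half);
  off-diagonal entries are the product-term coefficients, and γ is
  returned symmetric.

OLS is used even for binary mating fitness: on the relative-fitness scale
the coefficients are the evolutionary-genetic gradients, and inference
comes from randomization rather than Gaussian theory. `permutation_test()`
shuffles fitness across individuals (traits standardized once on the full
sample, before any shuffling), refits, and reports two-tailed per-
coefficient p-values with the add-one correction
p = min(1, 2·min(#≤ + 1, #≥ + 1)/(N + 1)), so p = 0 is impossible and the
attainable floor is 2/(N + 1). The first- and second-order models are
randomized in separate runs. All permutation engines are vectorized
through a single QR factorization of the fixed design, so the default
N = 9999 is cheap even at n ≈ 500.

One estimand subtlety is worth stating because the recovery harness
depends on it. When the trait distribution is skewed (genital size is
log-normal-ish) and γ ≠ 0, the first-order β̂ converges not to the linear
coefficient of the generating surface but to that coefficient plus the
projection of the quadratic part onto the linear terms — a property of
the directional-gradient *definition*, not an estimation error. The
correctly specified second-order model's linear coefficients do estimate
the generating coefficients, so `end_to_end_recovery()` scores β recovery
against those (and reports both).

## Canonical analysis

`canonical_decompose()` eigendecomposes γ; rows of M are the axes m_i,
ordered by signed eigenvalue (descending), with the same
largest-loading-positive sign rule as the warps. `double_regression()`
rotates the standardized traits into canonical scores y = zM′ and fits
w on (y, y²) jointly — no cross-products, since the rotation exists
precisely to remove them — giving θ_i (linear gradient along each axis)
and a regression-based λ_i (doubled squared coefficient) that equals the
eigenvalue whenever the fitted surface is exactly quadratic. θ is taken
from this joint fit, not from projecting the first-order β, because the
two differ whenever linear and quadratic terms are correlated in sample.

### The eigenvalue permutation test

How to get a null distribution for λ_i was the one place where a
plausible-looking design failed under test. Holding the observed rotation
M fixed and re-estimating λ along those fixed axes for each fitness
shuffle looks attractive (it avoids re-sorting), but it compares an
*order-selected* observed value — λ₅ is the minimum over directions —
against permuted values along one fixed direction, which are not subject
to that selection. In this package's null simulations (500 replicates,
n = 500, 999 permutations) that variant rejected at ≈70% for the extreme
eigenvalues at nominal 5%. `eigen_permutation_test()` therefore re-runs
the full second-order fit *and* the eigendecomposition in every permutation
replicate and compares the observed i-th ranked eigenvalue with the
permutation distribution of the i-th ranked eigenvalue; both sides of the
comparison then carry the same selection effect, and the same simulation
shows the nominal level is held. Because eigenvector sign (and hence the
sign of θ along a permuted axis) is arbitrary, θ_i is tested on magnitude:
the p-value is the add-one proportion of replicates whose |θ| along the
i-th ranked axis reaches the observed |θ_i|.

## Comparing selection episodes

`sequential_model_comparison()` pools the two episodes — each standardized
and relativized *within* episode, so each contributes its own gradient
scale — with an episode indicator, and tests blocks of
episode-by-term interactions cumulatively: linear interactions against the
pooled linear model; quadratic interactions with all linear terms and
interactions retained; cross-product interactions with the full quadratic
block retained. Each block's statistic is the partial F
((SSE_r − SSE_f)/Δdf)/(SSE_f/df_f) with p from the F distribution; a
permutation option (shuffling episode labels) is available but off by
default. With p = 5 traits and a pooled n = 1008 this yields the
denominator df sequence 996, 986, 966 (12-, 22-, 42-parameter full
models). Per-trait quadratic differences come from single-interaction-term
deletion out of the quadratic-block full model (F with 1 numerator df),
rather than from separate per-trait models, so each term is judged in the
context of the full surface.

## Fitness surfaces

`fit_tps_surface()` fits a penalized thin-plate spline of relative fitness
over two canonical scores, with knots at the (duplicate-aggregated) data
points. At smoothing 0 it interpolates exactly; as the penalty grows it
tends to the least-squares plane (the solver switches to a rescaled,
well-conditioned form of the system for large penalties). With
`smoothing = "gcv"` the penalty minimizes GCV = n·RSS/(n − tr H)² over 40
log-spaced values spanning 1e-6 to 1e3 times a kernel-scale normalization.
Surfaces are descriptive visualization only — all inference lives in the
permutation tests — matching how such plots are used in selection studies.

## Repeatability

`icc_repeatability()` implements the one-way-ANOVA intraclass correlation
R = (MSB − MSW)/(MSB + (m − 1)MSW) for balanced repeated digitizations,
with the exact F-distribution 95% interval. Negative point estimates are
reported as computed: truncating at zero would bias simulation averages,
and a negative estimate is itself informative about a null subject effect.

## The synthetic-data generator

`synthetic_truth()` fixes the study conditions the generator emulates:

* 29-point outlines, fixed landmarks {1, 16, 17}, 26 sliders on a closed
  tapered reference outline;
* a low-rank shape covariance: eight planted axes with variance fractions
  0.653, 0.114, 0.067, 0.060, 0.042, 0.030, 0.020, 0.014 of a total
  2e-3 (squared Procrustes units), plus isotropic digitizing noise of sd
  5e-4 per coordinate. The leading three fractions mirror the ~65/11/7%
  pattern a three-warp analysis retains (cumulative just over 80%); the
  five minor axes carry the residual spread that real outlines have.
* genital centroid size log-normal (meanlog log 0.95 mm, sdlog 0.05 —
  genitalia are strongly canalized), pronotum width normal
  (1.45 ± 0.06 mm) with correlation 0.2 to log size;
* a mating episode of n = 500 with target success rate 245/500 = 0.49,
  binary fitness from P(mate) = logistic(a + β′z + ½z′γz) with the
  intercept solved numerically for the target rate;
* a fertilization episode of n = 508 with 20% structural zeros and a
  positive part 1 + negative binomial (dispersion 0.9, mean 12 linked to
  exp(β′z + ½z′γz)) capped at 80, spanning the 1–80 offspring range;
* per-episode β and γ defaulting to the published gradient tables bundled
  in `example_gradients()`.

Two design points deserve explanation. First, planted shape axes are
displacement fields *normal* to the outline, additionally projected into
the slide-invariant subspace range(I − U(U′LU)⁻¹U′L), where U spans the
tangential slide directions and L the bending-energy metric of the
reference. Deviations in that subspace are exactly untouched by a
bending-energy sliding step; axes planted outside it would be obliquely
projected (and digitizing noise tangential to the outline is amplified)
by sliding, so naive planted axes are not recoverable even in principle.
This is a real property of semilandmark analysis, not an artifact: only
the slide-stable component of outline variation is "shape" to this method.
Second, the generator's nonlinear fitness links (logistic, exponentiated
mean) attenuate regression-scale gradients relative to the link-scale
parameters, so exact-recovery checks use a third model, `"gaussian"`, in
which expected relative fitness *is* the planted quadratic surface
(intercept 1 − tr γ/2, so its mean is one); `end_to_end_recovery()` also
generates fitness from the pipeline's own estimated standardized traits,
which isolates the estimation machinery from digitizing-noise attenuation.

What the generator does **not** emulate: male–male and sperm competition
(absent from the emulated design by construction), measurement drift
between digitizing sessions, landmark-placement error that is correlated
along the outline, allometric curvature of shape on size, and any genetic
structure. Passing tests on synthetic data therefore demonstrate that the
estimation machinery is correct under the stated generating model — not
that real beetle data satisfy that model.

## Problem sizes and determinism

Every stochastic function takes an explicit seed and is a pure function of
(inputs, seed); the pipeline log records the configuration hash and seed.
The test suite exercises null-distribution calibration with 500 replicates
at n = 500 and 999 permutations per replicate, coverage simulations with
300–500 replicates, and parameter recovery at n = 5000 — sizes chosen to
put Monte-Carlo error comfortably below the tolerances being asserted
while keeping the full suite to a couple of minutes. The acceptance script
uses n = 5000 for rate and recovery checks.

## Known limitations

* The episode comparison supports exactly two episodes, and its default
  inference is parametric (F distribution); the permutation option is the
  conservative fallback when residuals are grossly non-normal (binary
  fitness at extreme rates).
* TPS surface fitting solves dense systems at the unique data points; it
  is intended for the n ≤ a-few-thousand scale of mating experiments.
* The ICC is the balanced one-way estimator; unbalanced designs are
  rejected rather than approximated.
* `read_tps()` supports the 2-D dialect only (no 3-D landmark blocks or
  curve records).
* Relative warps are reported for the pooled sample only; per-episode
  alignment, where episodes must not share a shape space, is available
  via separate `gpa_align()` calls but is deliberately not the pipeline
  default.
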