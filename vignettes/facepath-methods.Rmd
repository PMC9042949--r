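---
title: "Methods: from landmarks to a layered Bayesian path model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from landmarks to a layered Bayesian path model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facepath)
```

`facepath` analyses how measured facial properties relate to perceived
dominance and sex-typicality.  This vignette is the package's account of
its methods: the superimposition and shape statistics, the reliability
and colour-handling rules, the path model with its priors and sampler,
the synthetic-study generator that underwrites all validation, and the
numerical and design choices a user should know about.

## 1. Superimposition

Landmark configurations (72 points per face in the packaged scheme: 36
fixed landmarks, 36 semi-landmarks on four curves) are superimposed by
generalized Procrustes analysis: each configuration is centred, scaled to
unit centroid size, and rotated — rotation only, reflections are never
allowed, because faces have a consistent orientation — onto the current
consensus; the consensus is recomputed as the mean of the aligned set and
the loop repeats.  Convergence is declared when the root-mean-square
change of the unit-size consensus falls below `tol` (default `1e-6`) or
after `max_iter = 20` outer iterations; typical samples converge in well
under ten.

**Scaling convention.**  Every configuration is kept at unit centroid
size (classical full-Procrustes alignment).  Orthogonal projection onto
the tangent space at the consensus is available as a switch
(`project_tangent = TRUE`); at facial-variation magnitudes (Procrustes
distances of order 0.05) the projection changes downstream scores
negligibly, so it is off by default.

**Sliding semi-landmarks.**  With `slide = TRUE`, each outer iteration
slides every semi-landmark along its local tangent — the normalised chord
between its curve neighbours, one-sided at curve endpoints — before
re-superimposition.  Two criteria are implemented:

* `"procrustes"` (default): the slide is the 1-D projection of the
  residual to the consensus onto the tangent, i.e. the position
  minimising that specimen's squared Procrustes distance to the
  consensus, solved in closed form;
* `"bending"`: all slides of a specimen are solved jointly to minimise
  the thin-plate-spline bending energy of its deformation from the
  consensus.

The default follows the distance-minimising description of the
superimposition; the bending-energy form is the common toolkit
alternative, and which one was active is recorded in the result.  Two
safeguards matter in practice.  Displacements are capped at half the
distance to the nearer curve neighbour, preventing curve inversion.  And
sliding is applied only during the first `slide_iters = 5` outer
iterations: sliding gains essentially all of its improvement in the first
few passes, while unbounded re-sliding lets points creep along their
curves indefinitely — under the bending criterion the creep is
essentially unresisted, because tangential redistribution is close to the
bending-energy null space.  For sliding runs, convergence is additionally
declared when the relative per-iteration decrease of the total squared
distance to the consensus drops below `slide_tol = 1e-3`, since the
consensus itself keeps drifting at numerically irrelevant rates.

The total squared distance to the consensus is recorded after every outer
iteration and is non-increasing (each rotation step minimises it given
the consensus; the consensus update minimises it given the rotations;
distance-criterion slides move each coordinate toward its 1-D minimiser).

## 2. Shape statistics

With the pooled two-sex sample aligned (the inter-sex axis only exists in
a joint superimposition), flattened configurations live in a
144-dimensional shape space.

* **SShD** projects each face onto the unit vector from the female to the
  male mean shape, centred at the midpoint of the two means.  The
  midpoint centring gives the sign symmetry seen in real samples (female
  means around −0.02, male means around +0.02 Procrustes units); the unit
  axis keeps scores in Procrustes units.
* **DIST** is the Procrustes distance from the sample consensus; with
  realistic digitising noise it lands around 0.05–0.06.
* **Shape-trait scores** regress each of the 144 centred coordinates on a
  standardized perceived rating and score each face by the dot product of
  its centred coordinates with the raw coefficient vector.  The
  coefficient vector is deliberately *not* normalised: raw-unit scores
  then have the characteristically tiny spread (SDs of order 1e-4), and
  since every variable is standardized before modelling, the scaling
  convention is irrelevant downstream.  Scores are computed within the
  sex-and-sample subset in which the ratings were collected; ratings for
  one sex say nothing about the other.

All three statistics are invariant (to numerical precision) under
similarity transforms of the raw input, which the test suite checks
end-to-end through the full superimposition.

## 3. Reliability, measurements, colour

* **ICC(3,k)** — two-way consistency, average-score form, raters fixed —
  quantifies interrater agreement on stimulus means:
  `(MS_stimuli − MS_error) / MS_stimuli` from the stimuli-by-raters
  ANOVA.  The consistency (not absolute-agreement) form is used because
  ratings are averaged within raters' frames of reference; it is
  invariant to rater main effects.
* **Repeated measurements** of facial width and height pass a quality
  gate: two measurement passes are accepted only if they correlate above
  0.9, then averaged.  fWHR is width/height; BMI is weight/height².
* **Colour.**  The three CIELab channels enter the mediator block
  separately *unless* (a) Horn's parallel analysis — observed correlation
  eigenvalues against the mean eigenvalues of `n_random` standard-normal
  datasets of the same shape — retains exactly one factor, and (b) the
  channels are strongly collinear (max pairwise |r| > 0.8).  When both
  hold, a single-factor model is fitted to the standardized channels by
  iterated principal-axis factoring (communalities clipped at 0.995 in
  Heywood cases, with a warning) and specimens are scored by the
  regression (Thurstone) method; the factor is oriented so its loading on
  L\* is positive.  The two-condition rule reproduces, by rule rather
  than by fiat, the empirical asymmetry between heavily collinear channel
  regimes (where a single "colour" variable is the only stable choice)
  and weakly correlated ones.  With three variables and one factor the
  model is just-identified, so the extraction method barely matters; the
  mean (rather than 95th-percentile) random-eigenvalue criterion is the
  common toolkit default and is switchable.

## 4. The path model

On standardized variables (z-scored within each sex-by-population
sample): age is exogenous; BMI is univariate normal given age; the q
mediators are jointly multivariate normal given age and BMI with residual
covariance `D R D` (per-mediator SDs `D`, correlation matrix `R`); the
two perceived outcomes are bivariate normal given age, BMI and all
mediators, with a residual correlation reported as the non-directed
association between perceived sex-typicality and dominance (no direction
is imposed between the outcomes).

Priors: `Normal(0, 0.2)` intercepts, `Normal(0, 0.5)` slopes — weakly
regularising on the standardized scale — `Exponential(1)` residual SDs,
and `LKJ(eta = 2)` on both correlation matrices, mildly favouring
correlations near zero.  The default channel model therefore carries
9 intercepts (every variable except age), 29 slopes, 6 + 15 mediator
(co)variance parameters and 2 + 1 outcome parameters; variants add
shape-trait mediators (extended: 11/37/8/28; the two partial variants add
exactly one mediator each).  The BMI equation's residual SD is a further
necessary parameter that sits outside these block counts.

**Sampler.**  The posterior is sampled by a blocked Gibbs/slice scheme
targeting exactly the joint density exposed by `log_density()`:

1. all intercepts and slopes have exact multivariate-normal full
   conditionals (normal priors, multivariate-normal likelihood), drawn
   blockwise from their closed forms;
2. residual SDs and correlations are updated by univariate slice sampling
   (stepping-out with shrinkage) on log-SD and atanh canonical
   partial-correlation (CPC) coordinates.  Under the C-vine construction,
   LKJ(eta) makes the CPCs independent scaled Beta variables, so the
   prior is exact and cheap in these coordinates; two algebraic
   reductions (a quadratic form in 1/SD while correlations are fixed; a
   single-row Cholesky update plus one triangular solve while SDs are
   fixed) keep each slice evaluation at small constant cost.

Slice sampling is rejection-free and tuning-free, and the Gibbs blocks
decorrelate quickly; a prior-only fit (zero specimens) reproduces every
prior margin (Kolmogorov–Smirnov distance below 0.05 at 10,000 draws,
including the analytic `2·Beta(eta−1+d/2, ·)−1` LKJ marginals), and a
50-replicate simulation study at n = 300 gives pooled 95%-interval
coverage of the generative slopes within [0.92, 0.99] with per-slope bias
below 0.05 — both are enforced by the test suite.  Fits run 2 chains by
default from prior-drawn starts; half of each chain's sweeps are
discarded as warm-up unless specified.  Convergence is flagged when every
split-R̂ is at most 1.01 and every effective sample size at least 400;
non-converged fits are returned (with their diagnostics), not discarded.
Posterior summaries report means with central equal-tailed 95%
compatibility intervals.  Rows with any missing model variable are
dropped with a message; missingness is not modelled.

## 5. The synthetic-study generator

The generator is first-class, tested code: it draws complete studies
(landmark files, specimen table, two rating matrices, and a persisted
truth record) from a known ground truth, so that every downstream stage
has a recoverable target.

* **Path layer.**  Standardized variables are drawn exactly from the
  model of section 4; residual SDs are set so every variable has unit
  total variance, keeping "standardized slope" exact rather than
  approximate.
* **Landmarks.**  Each specimen sits at `sex centre ± separation/2 +
  within-sex SD × z_SShD` along a fixed dimorphism axis (a deterministic
  male-ward displacement field on the packaged 72-point template: wider
  jaw and zygia, lower brows, thinner lips, longer chin), plus isotropic
  digitising noise and tangential jitter on semi-landmarks, then a random
  rotation (uniform), scale (log-uniform on [0.5, 2]) and translation so
  that superimposition is genuinely exercised.  The per-specimen noise SD
  is modulated by the generative DIST variable, tying measured
  distinctiveness to its model-level counterpart.
* **Ratings.**  The latent rating is the anchor mean plus anchor SD times
  the latent outcome; each rater adds Normal noise (rater main effects
  exist as an option but default to zero — the residual-only model is the
  simplest one producing the observed reliability levels), and the result
  is rounded and clamped to the 1–7 scale.  An affine map plus
  rounding/clamping is the simplest response model that produces integer
  Likert data; nothing finer-grained is identifiable from stimulus means
  anyway.
* **Presets** encode the four published study conditions (Czech and
  Cameroonian women and men) once: sample sizes (106/89/50/49), the
  age/BMI/fWHR/CIELab/rating moments, per-sex SShD levels around
  ∓0.01–0.02 with within-sex SDs in the 0.01–0.02 band, the reported
  outcome residual correlations (0.31, 0.77, −0.24, 0.42), the reported
  non-zero slopes, and the channel regime — collinear single-factor
  colour for the Cameroonian samples (channel loadings set from the
  reported per-channel R² values), separate channels for the Czech
  samples.  Values the source does not report (age/BMI-to-mediator
  slopes, most mediator correlations, rater counts per matrix) are set
  once to realistic magnitudes for this literature: weak covariate
  effects of |0.1–0.35| (BMI→fWHR 0.35 the largest, matching the
  well-established adiposity–face-width link), modest mediator
  correlations, 100 raters (the published mean rater count is ~102), and
  rater noise of 1.0 rating-scale units, which lands ICC(3,k) in the
  ≥0.91 region reported for such studies.

**What the generator does not emulate:** photograph acquisition, colour
calibration, and rating-session artefacts (rater drift, stimulus-order
effects); real landmark error is neither isotropic nor independent across
points; real mediator correlations are not exactly the preset constants;
and measured shape-trait scores arise from the landmark geometry rather
than from the preset correlation block, so extended-model recoveries of
the shape-score correlation structure use the generative record, not the
landmark-derived scores.  Passing tests therefore demonstrate that the
pipeline recovers truths under its own assumptions — not that those
assumptions exhaust real photographic data.

## 6. Numerical choices and degenerate inputs

* Rotation fits use the SVD with the determinant sign forced positive
  (no reflections); coincident-point configurations are rejected.
* TPS coordinates are parsed as decimal text with spaces or tabs; the
  stored y-axis convention is kept as digitised (no flip) — alignment
  excludes reflections, so the convention only affects plots.
  `SCALE=` records, when present, multiply coordinates on read.
* The Cholesky-factor CPC transform never leaves the positive-definite
  cone, so correlation draws are positive definite by construction;
  non-positive-definite correlation *inputs* (in `log_density()` or the
  generator) return `-Inf` with a reason or an error naming the matrix.
* Exactly singular channel correlation matrices (a noiseless rank-one
  colour factor) are handled by a tiny ridge in the factor-scoring solve.
* Slice sampling uses width 0.5 with stepping-out capped at 50 steps;
  results are insensitive to both (the slice is exact regardless).
* Zero-noise degeneracies (all generator SDs zero) produce exactly
  repeated shapes and deterministic integer ratings, and are covered by
  tests.

## 7. Problem sizes used in validation

The automated checks run at deliberately chosen sizes: the coverage study
uses 50 replicates of n = 300 specimens with 600 retained draws over two
chains (quantile error at 600 draws is well inside the coverage band's
width); prior recovery uses 10,000 draws; pipeline recoveries run at the
published sample sizes (106 + 89 and 50 + 49) with 2,000 draws.  Larger
sizes change none of the conclusions, only the Monte-Carlo margins.

## 8. Known limitations

* The sampler is single-site in the covariance coordinates; for very
  high mediator counts (far beyond the 8 used here) a gradient-based
  sampler would scale better.
* Bending-energy sliding is a local, capped, few-iteration scheme; it is
  faithful to common practice but not a global optimiser of bending
  energy.
* Missing data are dropped, not modelled; rating measurement error is
  absorbed into stimulus means rather than modelled per rater.
* The colour-mode rule is a binary decision; borderline collinearity
  (max |r| near 0.8) flips it, and users studying such regimes should fit
  both forms and compare.
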