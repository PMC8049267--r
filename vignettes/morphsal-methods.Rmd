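---
title: "Detecting geographically differentiated morphology with morphsal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting geographically differentiated morphology with morphsal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Fish populations that live in separated habitats often develop
population-specific body forms (morphotypes). The classical way to
quantify such differentiation places homologous landmarks on specimen
images, removes nuisance variation (position, size, orientation) with a
generalized Procrustes analysis (GPA), and asks whether the aligned shape
coordinates predict the population of origin. Modern image-based machine
learning promises to find discriminative features without landmarks — but
powerful models will happily exploit *technical* image content (background
gradients, fixation pins, dirt) that happens to correlate with the label,
producing a "Clever Hans" predictor whose excellent accuracy has no
biological meaning.

`morphsal` implements a complementary analysis chain that makes such
failures visible and quantifiable:

1. **GPA** of 2-D landmark configurations into shape space and a flattened
   N × 2M feature matrix;
2. unsupervised image-feature extraction with a **sparse variational
   Gaussian process latent variable model (GP-LVM)** whose automatic
   relevance determination (ARD) weights rank latent dimensions;
3. origin classification with two ARD-equipped Bayesian classifiers — a
   one-vs-rest **Gaussian process classifier (GPC)** and a **hybrid Monte
   Carlo multi-layer perceptron (HMC-MLP)** — whose relevance profiles rank
   features and landmarks;
4. a pixel-wise **permutation significance test for saliency maps** built
   on a marked-point-process null, used both to display trustworthy
   saliency and to screen GP-LVM dimensions for artifact contamination;
5. paired **cross-testing metrics**: generalization accuracy, mutual
   information in bit, and the exact McNemar test against a majority-label
   baseline, repeated over reshuffles.

A built-in synthetic-data generator renders fish-like silhouettes with
known class effects and injectable class-correlated artifacts, so every
claim the pipeline makes can be checked against ground truth.

## Models and procedures

### Generalized Procrustes analysis

A configuration is a 2 × M matrix of landmarks. GPA (i) translates each
centroid to the origin, (ii) rescales to unit centroid size
S(Y) = sqrt(trace(Y'C'CY)) with C the centering matrix, and (iii) rotates
each shape into agreement with the mean shape, iterating rotation against
the re-estimated mean. The rotation subproblem is solved by the SVD
orthogonal-Procrustes closed form restricted to proper rotations
(determinant correction), so mirror-image configurations are *not*
aligned onto each other. Numerical choices: convergence when the
Frobenius change of the mean shape drops below `tol = 1e-10` (at most
`max_iter = 100` iterations); the mean shape is not re-normalized between
iterations — scale is fixed in step (ii) only, a point on which published
implementations differ. The feature matrix stores landmark m as the
column pair (x_m, y_m).

### Sparse variational GP-LVM

Each pixel column of the N × D image matrix is modeled as a zero-mean
Gaussian process over shared latent inputs X (N × L) with the
squared-exponential ARD covariance
k(x, x') = σ_f² exp(−½ Σ_l α_l (x_l − x'_l)²) plus noise of precision λ.
X carries a standard-normal prior; the posterior is approximated by a
factorized Gaussian with means μ_n and diagonal covariances S_n, and M
inducing inputs Z make the model sparse. The collapsed variational lower
bound (the classic inducing-point bound built from kernel expectation
"psi statistics") is maximized jointly over {μ, S, Z, α, σ_f², λ} with
L-BFGS-B and analytic gradients; the gradient implementation is verified
against numerical differentiation in the test suite. Because the data
enter the bound only through Y Y' and tr(Y Y'), an evaluation costs
O(N M² L + M³) regardless of the pixel count D.

Numerical choices that matter:

* **Initialization.** Latent means start at the leading principal
  components, standardized per dimension; inducing inputs are a jittered
  subsample of them; kernel variance and noise precision start at 1.
  This unit-scale start proved far more robust than data-variance-scaled
  alternatives, which can fall into two degenerate optima — an "all noise"
  solution (signal variance → 0) and an over-pruned solution with a
  single live dimension. It presumes data values of order one, which
  holds for grayscale images in [0, 1] and for aligned shape coordinates.
* **Box bounds** on the log-parameters (log-variances in [−15, 15],
  log posterior variances in [−15, 5]) keep the line search out of
  overflow regions; a transiently infeasible evaluation receives a finite
  penalty, and only a persistent failure aborts.
* **ARD ranking.** Dimensions are ordered by α_l descending, ties broken
  by index. Attenuated dimensions approach the lower box bound.

Desk-scale defaults (image side 64, L = 12, M = 40, a few hundred
optimizer iterations) keep a full fit on ~200 specimens in the minutes
range on one CPU; the corresponding full-scale analysis (224² pixels,
L = 100, M = 100, 10⁴ iterations) is reached purely through arguments.

Model size selection (`select_model()`) sweeps the inducing count at a
fixed latent dimension until the optimized bound plateaus (relative
improvement below 1%), then picks the latent dimension maximizing the
bound at that inducing count.

### Latent dimensions in image space, and artifact screening

The generative direction of the GP-LVM turns a latent dimension into a
saliency map: all coordinates are fixed at the sample mean while
dimension l sweeps an 11-point grid spanning mean ± 2 sd of its posterior
means; each grid point is decoded through the posterior predictive mean
and the per-pixel standard deviation across the sweep is the saliency
value. (The sweep definition — symmetric, scale-aware, cheap — is this
package's concrete choice for "the variability of a dimension".)

`screen_dimensions()` automates the judgment "does this dimension respond
to the specimen or to the background": each top-ranked dimension's
saliency map goes through the permutation significance test, and the
dimension is flagged as artifact-driven when more than
`out_frac_threshold = 0.10` of its significant pixels fall outside a
foreground mask. The default mask marks pixels whose across-specimen mean
intensity deviates from the background median by more than 3 background
MADs, dilated by 2 px — the dilation matters, because genuine shape
variation touches pixels just outside the mean silhouette under pose
variation. A manual keep-list can override the automated screen, which
mirrors the fact that such exclusions are ultimately a judgment call.

### ARD classifiers

**GPC.** One binary GP classifier per class (one-vs-rest), logistic link,
SE-ARD covariance, Laplace approximation for the latent posterior
(Newton mode finding) and marginal-likelihood maximization for the
hyperparameters with analytic gradients; predictive probabilities use the
moment-matched logistic integral, and the C binary probabilities are
normalized to 1-of-C posteriors. Inputs are standardized internally; the
ARD profile reports per-dimension α averaged over the C machines
(documented choice — the machines are independent). The Laplace
approximation is this package's inference choice for GP classification;
it is deterministic, fast, and its marginal-likelihood gradients are
exact, which the test suite verifies numerically.

**HMC-MLP.** A Bayesian MLP with one tanh hidden layer (20 units by
default), softmax outputs, and direct input-to-output connections. Each
input owns two Gaussian prior scales — σ_{l,1} for its input→hidden
weights and σ_{l,2} for its direct input→output weights — with conjugate
gamma hyperpriors on the precisions (shape 0.5, rate 0.05). Sampling
alternates Gibbs updates of the group precisions with leapfrog HMC
updates of all weights; the step size adapts during burn-in (25%
discarded). Predictions average the softmax over retained samples.
Desk-scale default: 500 samples; the full-scale setting of 2500 is an
argument. The ARD profile reports the posterior *median* of each scale:
for weight groups the likelihood does not constrain, the Gibbs/HMC chain
has a heavy-tailed funnel whose excursions would inflate a posterior
mean.

A subtlety worth knowing when interpreting MLP relevances: under the full
Bayesian treatment, inputs that are merely *unused* sit at the prior
fixed point of the scale hierarchy, while inputs that are actively
counterproductive are shrunk *below* it. A zero-variance input is
therefore reliably ranked below necessary inputs, but not necessarily
below weakly-informative ones. The GPC's evidence-maximized α does not
share this behavior.

**Relevance aggregation.** MLP scales combine by summed squares,
σ_l = sqrt(σ_{l,1}² + σ_{l,2}²), and the same rule pools the x/y
coordinate pair of a landmark. GPC inverse squared length scales act
nonlinearly inside the covariance, so a group of inputs is summarized by
the single inverse length scale whose isotropic covariance best matches
the anisotropic one over the observed samples; the least-squares optimum
has the closed form
α̂ = Σ_n (η_n'Lη_n)(η_n'η_n) / Σ_n (η_n'η_n)², L = diag(α), which the
tests verify against a numerical minimizer.

### The saliency significance test

A saliency map is read as a sample of a marked spatial point process:
pixel locations carrying nonnegative importance marks. Under the null
hypothesis of no spatially structured importance, the locations form a
homogeneous process, so a null sample is obtained by reshuffling all
pixel coordinates — equivalently, permuting the marks over the grid,
which preserves the mark distribution exactly. Observed and null maps are
compared through local averages: a k × k Gaussian convolution (k = 5 by
default) with bandwidth σ = 0.3·((k−1)/2 − 1) + 0.8 (the default
bandwidth convention of common image-convolution routines) and
reflect-type border handling. The per-pixel p-value is the fraction of N
null samples whose smoothed value at that pixel is at least the observed
one; ties count toward the null, which makes the test conservative (a
constant map yields p = 1 everywhere) and means p = 0 is attainable — no
continuity correction is applied, a deliberate fidelity choice. The
default N = 10⁴ and mask threshold p < 0.001 follow standard use; tests
run at N ≤ 10³ for speed. No multiple-testing correction is applied
across pixels by default; a Benjamini–Hochberg switch exists for users
who want it. The permutation is taken over the full grid (not a region
of interest).

Calibration is checked empirically in the test suite: over hundreds of
i.i.d. exponential-mark maps the per-pixel rejection rate at level α
stays at or below α (conservative, never anti-conservative), and power
against a planted Gaussian cluster of marks is monotone in the cluster
amplitude.

### Cross-testing and metrics

`make_plan()` builds, per reshuffle, a stratified near-equal partition
into folds (round-robin over a class-blocked shuffled order), so 209
specimens in 10 folds give nine folds of 21 and one of 20, and every
class appears in every training split. All pipelines evaluated on a plan
see specimens in the same order, which makes predictions exactly
pairable. Stratification and the majority-baseline tie-break (lowest
class index) are this package's documented choices.

* **Accuracy**: 100 × mean agreement.
* **Mutual information** between posterior and labels in bit:
  the average over evaluated samples of Σ_y P(y|x) log2(P(y|x)/P(y)),
  with the marginal P(y) taken from the evaluated set's empirical
  frequencies (documented choice); an input-independent predictor scores
  exactly 0 bit, a perfect one log2(C).
* **Exact McNemar**: from the discordant counts (n_a, n_b),
  p = 2·P(X ≤ min(n_a, n_b)) with X ~ Bin(n_a + n_b, ½), capped at 1
  (the two-sided doubling can exceed 1); no discordance gives p = 1 with
  a warning. For display, p-values are truncated at 0.99 and
  logit-transformed; an exact zero is refused by `logit_truncate()` so
  the caller must handle it consciously.
* **Rank summaries**: per rank position, the relative frequency with
  which each feature occupies that rank across reshuffles; the
  frequencies weight per-dimension saliency maps into pooled displays.

### The synthetic-data generator

`generate_dataset()` renders, per specimen, a parametric fish-like
silhouette — body ellipse with independently deformable dorsal, ventral,
frontal and caudal extents, dorsal/caudal/anal/pelvic fin polygons, plus
interior detail (eye, operculum arc, pectoral fin, mouth line) so the
image model has texture. Rasterization uses hard region tests (no
anti-aliasing), so difference masks are exact. The 14 standard landmarks
are placed on the corresponding parametric outline points; pixel
coordinates are 0-based, (x = column, y = row), origin top-left,
everywhere in the package.

Class effects deform named regions: a *dorsal* effect raises a hump whose
profile peaks at the anterior dorsal-fin insertion (so AOD carries most
of the displacement, POD some); *belly*, *snout* and *caudal* effects
move the corresponding semi-axes or insertion points. Ground-truth effect
masks are computed by differencing reference renders with and without
each region's maximum amplitude (dilated by 2 px). Technical artifacts —
background gradient, fixation-pin blob, dirt specks — are drawn with
per-class Bernoulli presence probabilities, which supports both perfectly
confounded (probability 1 vs 0) and unconfounded regimes, and each
records its exact pixel mask.

Default study conditions mirror the six-lake design: per-class counts
36/38/31/26/38/40 (N = 209), image side 64 (224 supported), a dorsal
deformation graded linearly over the classes up to 5 px, pixel noise
sd 0.02, and a within-class variability control `jitter_sd` (default
0.75 px) that drives individual geometric jitter, a random similarity
pose (translation sd 1.5·j px, log-scale sd 0.015·j, rotation sd
0.025·j rad) and landmark annotation noise (sd 0.4·j px). Setting
`jitter_sd` to zero makes the specimens of a class bit-identical, which
is the regime in which the effect-locality invariants hold exactly and
which the tests exploit. Images are
quantized to 8-bit grays at generation, so the PNG round trip is
bit-exact.

What the generator does *not* emulate: photorealistic texture, lighting,
camera geometry, allometry, or landmark placement ambiguity beyond
isotropic noise. Tests passing on this generator therefore demonstrate
that the pipeline recovers localized, class-linked shape signal and
detects label-confounded technical artifacts under controlled conditions
— not that it handles every failure mode of field photographs.

## The two headline studies

The acceptance suite runs two synthetic studies end to end.

**Morphotype recovery.** On the default dataset (graded dorsal effect,
no artifacts), both GPA+GPC and GPA+HMC-MLP beat the 19% majority
baseline by a wide margin in every one of 10 reshuffles of a 10-fold
cross test (exact McNemar p far below 0.05), and the top-ranked landmark
under both classifiers' ARD profiles is a dorsal-fin insertion (AOD or
POD) in at least 8 of 10 reshuffles.

**Rogue-feature reproduction.** The same dataset plus a background
gradient present only for two of the six classes: the GP-LVM picks the
artifact up as a high-ARD latent dimension; `screen_dimensions()` flags
exactly that dimension (its significant saliency pixels lie almost
entirely outside the foreground and overlap the ground-truth artifact
mask), and a classifier fed the *top-ranked* dimensions outperforms one
fed the *screened* dimensions — the accuracy inflation that motivates
screening in the first place.

Problem sizes in the shipped tests and in `scripts/acceptance.R` are the
desk-scale defaults above (N = 209 specimens, 64² images, L = 12,
M = 25–40 inducing points, a few hundred GP-LVM iterations, 500 HMC
samples, saliency tests at N = 500–1000 resamples); these are the
package's chosen defaults for a single-CPU workflow.

## Known limitations

* The GP-LVM bound is non-convex; different seeds can reach different
  optima. The unit-scale initialization is robust on the data families
  the package targets, but data far from unit scale should be rescaled.
* Laplace-approximated GPC posteriors are known to be conservative for
  well-separated classes; argmax predictions are unaffected.
* The HMC-MLP relevance caveat above: interpret low MLP relevances as
  "not needed", not as "independent of the label".
* The saliency test treats pixels independently under the null;
  cluster-level inference (joint significance of regions) is out of
  scope.
* The CNN comparison arm of the original study design (transfer-learned
  image classifiers and their saliency methods) is intentionally not part
  of this package; externally produced saliency maps can still be tested
  by reading them with `read_saliency()`.
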