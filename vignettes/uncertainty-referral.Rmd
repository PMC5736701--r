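---
title: "Model uncertainty and decision referral: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model uncertainty and decision referral: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrefer)
```

## The model

A feed-forward classifier with parameters $\theta$ maps features
$\mathbf{x}$ to class scores $f(\mathbf{x}, \theta)_k$ and softmax
probabilities
$p(y = k \mid \mathbf{x}, \theta) = e^{f_k} / \sum_j e^{f_j}$.
Point-estimate training (cross-entropy plus L2, i.e. a MAP fit under a
Gaussian prior) produces a single parameter vector and, with it, a single
decision surface. Bernoulli dropout gives a cheap approximation to the
Bayesian alternative: treating the per-unit dropout masks as random
variables defines a variational family over weight matrices, and minimising
the dropout cross-entropy with an L2 term is approximate variational
inference in that family. Sampling masks *at test time* therefore samples
sub-networks from an approximate parameter posterior, and the spread of
their outputs measures how strongly the data constrain the decision at
$\mathbf{x}$.

`mcrefer` implements this with small multi-layer perceptrons
(`net_spec()`, `train_net()`): per-hidden-layer Bernoulli dropout,
rectifier activations, mini-batch SGD with Nesterov momentum, and an L2
penalty $\lambda \sum \|\theta\|^2$ with $\lambda = 0.001$ by default.
Class imbalance is handled by reweighting the batch cross-entropy with
inverse within-batch class frequencies,
$-\tfrac{1}{Kn}\sum_i \log p_i(y_i) / \hat p(y_i)$, which macro-averages
the per-class losses; on a balanced batch it reduces exactly to the plain
mean cross-entropy.

### Predictive posterior summaries

`mc_predict()` keeps dropout on and performs $T$ forward passes, each under
one freshly drawn mask per hidden layer shared across all inputs (one
sampled sub-network per pass). Per sample we report
(`uncertainty_summary()`):

* `mu_pred` — the mean of the $T$ diseased probabilities; the quantity
  thresholded (at 0.5) for the actual prediction;
* `sigma_pred` — their Bessel-corrected standard deviation, the
  uncertainty proxy;
* `entropy` — the binary entropy of `mu_pred` in bits (base 2, so the
  maximum is exactly 1);
* `p_standard` — the deterministic dropout-off softmax output, the
  conventional baseline.

$T$ defaults to 100, which suffices for stable `mu_pred` estimation; the
estimator variance follows $\mathrm{Var}(\hat\mu) = \sigma^2 / T$, a
relation the test suite checks against an exact oracle.
`enumerate_posterior()` provides that oracle: for networks with at most 20
droppable units it enumerates all $2^D$ masks and accumulates the exact
first two moments under the product-Bernoulli measure.

Two numerical conventions are worth flagging. First, *inverted dropout*:
sampled activations are scaled by $1/(1-p_\mathrm{drop})$, so the
deterministic pass is the unmodified forward pass and needs no weight
rescaling. Second, the predictive standard deviation is the conventional
sample standard deviation with $1/(T-1)$ *inside* the square root; a
variant with the factor outside the root is dimensionally inconsistent with
a standard deviation and is not used. Log-probabilities are clamped at
$10^{-12}$ before logs so saturated softmax outputs cannot produce infinite
losses.

## Decision referral and its evaluation

Given per-sample uncertainties, `referral_curve()` sorts predictions by
uncertainty (stable sort, ties broken by sample index), refers the
$\lceil (1-f) N \rceil$ most-uncertain samples at each retained fraction
$f$, and evaluates accuracy or rank-based AUC on the rest. Uncertainty
fields: `sigma_pred`, the entropy of `mu_pred`, or the entropy of
`p_standard` (the standard-dropout baseline). Confidence intervals are
percentile-bootstrap (default $B = 10^4$, 95%); `random_referral_baseline()`
refers the same number of samples uniformly at random (100 draws by
default; whether a single draw or an average is used is a free choice, an
average being the more stable control). Conventions: `mu_pred = 0.5`
counts as diseased (the conservative call for screening); AUC ties are
credited 1/2 (equivalent to trapezoidal ROC integration); metrics that are
undefined on a single-class retained set are recorded as missing rather
than imputed.

`split_by_tolerated_uncertainty()` offers the dual parameterisation: retain
everything with $u \le \tau$. `level_composition()` reports the ordinal
grade distribution among referred samples per $\tau$ (at $\tau = 0$ it is
the empirical prior whenever every uncertainty is positive), and
`ambiguity_report()` the fraction of contra-lateral-ambiguous images —
images whose binarised label disagrees with the same patient's other eye —
in the referred and retained buckets. The default $\tau$ grid is 50 even
steps over $[0, \max u]$.

Density summaries (`density_summary()`) use a Gaussian kernel with Scott's
bandwidth $n^{-1/5}\,\mathrm{sd}$ on a grid covering the data range plus
three bandwidths each side.

## Synthetic data: what it emulates, and what it does not

**Two moons** (`make_toy2d()`): two interleaving half-circles of radius 1,
unit horizontal separation, vertical offset 0.5, with isotropic Gaussian
noise (default sd 0.15, $n = 1000$, stratified 50/50 train/test). The
generative form of the 2D illustration is otherwise unconstrained; half
moons were chosen because they produce a curved boundary whose uncertainty
lobes extend orthogonally into input space, which is the qualitative
geometry the boundary-uncertainty picture needs.

**Graded cohort** (`make_graded_cohort()`): each patient's two eyes receive
latent severities from a standard bivariate normal with correlation
$\rho$ (`eye_correlation`), thresholded at the cumulative quantiles of the
level prior into grades 0–4, so the marginal grade distribution matches the
prior exactly in expectation. Features are the grade mean (grades spaced
1.0 apart along one axis) plus isotropic noise (`class_overlap`, default
0.75), giving ordinal classes with genuinely diffuse boundaries. Defaults:

* `level_prior = (0.735, 0.07, 0.15, 0.025, 0.02)` — the ~73% healthy
  proportion of public retinopathy grading cohorts, with the diseased mass
  concentrated at the moderate grade;
* `eye_correlation = 0.985` — calibrated so that, among binarised-diseased
  images, 5–10% disagree with their contra-lateral label (the disagreement
  rate is a function of $\rho$ and the prior only; $\rho$ in roughly
  [0.98, 0.995] spans the band, and 0.985 sits mid-band at ~8.5%);
* `dim = 2` for inspectability.

The default referral experiment (`run_config()`) uses 2000 patients (4000
images, 60/40 patient-level train/test split), a 2–32–32–2 classifier with
$p_\mathrm{drop} = 0.3$, 40 epochs at learning rate 0.05, $T = 100$,
$B = 10^4$ bootstrap resamples. The two-moons study uses the 3×100-unit
network with $p_\mathrm{drop} = 0.5$ for 150 epochs and a 100×100
evaluation grid. These sizes were chosen so the whole suite runs in minutes
on a single core while keeping every Monte Carlo margin comfortable.

What the simulator does *not* emulate: image content and preprocessing,
per-grade differences in visual difficulty, label noise from graders, and
high-dimensional feature geometry. Passing tests therefore demonstrate that
the uncertainty and referral machinery behaves as the theory predicts on
data with the right *label* structure — not that any particular clinical
performance would be attained on real fundus photographs.

One structural consequence of the 1-D ordinal feature geometry is worth
recording. With equally spaced grade means and a common overlap, the
learned diseased probability rises smoothly across roughly two grade
spacings, and its steepest stretch — where `sigma_pred` peaks — lies
slightly to the *diseased* side of the 0.5-crossing (the balanced
posterior's logit steepens with severity). For disease onset 1 the
top-uncertainty decile therefore contains a noticeable admixture of
grade-2 images: grade 1 is strongly enriched relative to its prior, but
the *combined* share of grades {0, 1} can stay below its (already 80%+)
prior share. For onset 2 the boundary grades {1, 2} dominate the referred
pool by a wide margin. The per-level enrichment direction is the mechanism
of interest; the combined-share comparison at onset 1 is a known
limitation of this feature geometry.

## Anomaly scoring

`train_dae()` fits a fully-connected autoencoder (default geometry
512–128–32–128–512, rectifier hidden layers, linear output since features
are unbounded) by seeded mini-batch SGD with momentum on mean squared
reconstruction error; `anomaly_score()` returns each vector's
reconstruction MSE. Intended input are `penultimate_features()` — the
deterministic last-hidden-layer activations of a trained classifier — or
any user feature matrix. The optimiser and error metric are declared
package defaults, not values inherited from elsewhere. Note that a
rectified code layer splits each signed latent coordinate into positive and
negative channels, so a $k$-dimensional subspace needs a code of at least
$2k$ rectified units to be reconstructed exactly.

## Reproducibility

Every generator and estimator is a pure function of an integer seed.
Pipelines use one master seed with per-component streams derived by a
stable string hash (`derive_seed()`), so no two stages share a stream and
identical configurations produce byte-identical CSV outputs. Serialisation
is plain text throughout: cohorts, prediction tables and curves as CSV
(numerics written to 17 significant digits, which round-trip exactly),
models as JSON.

## Known limitations

* Dropout-mask sampling approximates a particular variational posterior;
  it can be over-confident far from the data, which is why the
  reconstruction-error detector exists as a complement.
* The simulator's grade difficulty is uniform by construction (see above);
  real cohorts concentrate uncertainty differently across grades.
* Training is plain R; the networks are deliberately small. Users with
  external classifiers should produce a prediction table and use the
  evaluation layer directly.
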