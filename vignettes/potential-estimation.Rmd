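---
title: "Estimating performance potential and progression typologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating performance potential and progression typologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipotential)
```

## The problem

Alpine-skiing results (FFS/FIS race points, and any comparable
lower-is-better score) arrive as an irregular longitudinal record: many
results per athlete per season, heavy contamination by atypically bad
races ("counter-performances"), and wildly different numbers of
observations per athlete. Coaches want two things from such data: an
estimate of each athlete's *potential* — the curve their best possible
performance traces over age, with honest uncertainty — and a sense of
the athlete's *progression typology*: does this skier look like an
average developer, a fast starter who plateaus, a slow starter with a
steep trajectory, or simply a weaker performer?

`skipotential` answers both with a single hierarchical model plus a
clustering layer on top of it.

## The curve model

The age–performance relationship is the Moore double-exponential. For
a minimized score,

$$p(t) = a\,e^{-bt} + c\,e^{dt}, \qquad a, b, c, d > 0,$$

a U-shaped curve: the first term is the progression phase, the second
the decline phase, and the interior minimum is the performance peak at

$$t^* = \frac{\log\!\big(ab/(cd)\big)}{b + d}.$$

The classical maximizing orientation $a(1 - e^{-bt}) + c(1 - e^{dt})$
is also implemented (`moore(..., orientation = "maximize")`); the two
differ by a reflection and share the same closed-form peak. The
`moore_peak()` closed form is exact; a grid search survives only as a
test oracle.

Each individual $i$ perturbs every population parameter:

$$p_i(t) = (a + a_i)\,e^{-(b + b_i)t} + (c + c_i)\,e^{(d + d_i)t}.$$

### Preprocessing

The model is trained on the *best score per individual per integer age
year* (ages binned by `floor`, bounds [10, 25] by default, ties to the
first record seen). Taking the per-age minimum is what neutralizes
counter-performances: one-sided bad noise cannot move a minimum much.
Ages are then centered and reduced; scores are centered, reduced, and
shifted by $-\min(z) + 10^{-3}$ so all training values are strictly
positive — the double exponential cannot cross zero, so the shift is a
model-adequacy requirement, not cosmetics. The shift is global (one
transform for the whole training set); both transforms invert exactly
and `best_per_age` ordering is preserved because the score transform is
strictly monotone.

### Likelihood, priors, and sampling

Residuals on the standardized score scale are Gaussian with scale
$\sigma$. Sampling parameterization and priors:

* fixed effects $(a, \log b, c, \log d)$: Normal priors centered at a
  pooled nonlinear-least-squares prefit (`ols_prefit()`, multistart +
  Levenberg–Marquardt), sd 1.0 on the standardized scale. The log
  scale for the rates enforces the U shape.
* individual offsets: non-centered, $z \sim N(0,1)$ with
  half-Normal(1) scales $\tau_a, \tau_b, \tau_c, \tau_d$. Amplitude
  offsets are additive ($a_i = \tau_a z_{ai}$); rate offsets are
  multiplicative ($b + b_i = e^{\log b + \tau_b z_{bi}}$), so every
  retained quadruplet defines a valid U-shaped curve by construction.
  Offsets are independent across parameters; no cross-parameter
  covariance is modelled.
* $\sigma$: half-Normal(1), sampled on the log scale.

The posterior is drawn with a No-U-Turn sampler (tree doubling with a
slice variable, dual-averaging step-size adaptation targeting 0.9
acceptance, diagonal mass-matrix estimation in a mid-warmup window,
maximum tree depth 10), implemented in C++ with analytic gradients.
Defaults are 4 chains × 200 retained draws — 800 quadruplets per
individual — after 500 warmup iterations per chain, which are separate
from the retained draws because adaptation-free Hamiltonian sampling is
not credible. Chains are seeded from R's RNG, so a seed fully
determines the output. Split R-hat and a Geyer-style effective sample
size are reported per global parameter; parameters with R-hat above
1.05 are flagged, and more than 2% divergent transitions triggers a
warning.

### What the fit reports

`summarize_fixed()` prints the conventional table (posterior median,
sd, 2.5%/97.5% quantiles) for $a, b, c, d$ on the natural scale.
`r_squared()` computes $1 - SS_{res}/SS_{tot}$ on the standardized
training table, either with each individual's posterior-median
quadruplet (the hierarchical fit) or with the pooled OLS curve (the
no-random-effects baseline); on any heterogeneous cohort the former
exceeds the latter, often dramatically — the hierarchy is doing the
work. An adjusted variant penalizes by the number of free curve
parameters ($4(N+1)$ with random effects).

## Potential curves and peaks

`potential_curve()` evaluates one curve per retained quadruplet on a
0.1-year age grid ("continuous in age" needs a concrete step; 0.1 year
is far below any interpretable resolution), destandardizes, and
summarizes per age with the median and a quantile envelope — default
(0.025, 0.975) for the population curve and (0.05, 0.95) for
individual curves, both configurable, as the two conventions serve
different displays. The envelope is an *estimate interval* for the
curve of potential, not a prediction interval for single race results:
single results include counter-performances the model deliberately
ignores.

Peaks are computed draw-wise (the closed form applied to each sampled
quadruplet, then destandardized), not as the extremum of the median
curve; the two agree when the draw spread is small, which is checked in
the tests. The "±" reported is the half-width of the central 95%
interval of per-draw peaks (posterior sd selectable). Draws without an
interior peak are excluded and counted; more than 50% excluded is an
error rather than a silent summary of a different estimand.

## Progression typologies

Clustering operates on each individual's component-wise posterior
median quadruplet $(a + a_i, b + b_i, c + c_i, d + d_i)$ — a fixed-
length representation of a trajectory that never requires complete
observation of it. Gaussian mixtures are fitted over the 14-member
covariance parameterization family (the volume/shape/orientation
decomposition, EII through VVV) with mclust's constrained M-steps.
Each EM run starts from both a model-based agglomerative partition and
a multi-restart k-means partition, keeping the higher likelihood: a
single hierarchical initialization is easily trapped when one cluster
holds most of the cohort, which is exactly the regime this method
targets.

### The overlap score

Clusterings of curves should be judged by what separates *curves*:
their slopes. For each cluster and each scoring age $t \in \{10,
\dots, 20\}$, the members' curve derivatives with respect to raw age
(chain rule through the standardization) are smoothed into a kernel
density (Gaussian kernel, Silverman bandwidth with a floor of
$10^{-6}$ times the slope scale as a zero-variance guard; a shared
grid spanning the pooled support plus five bandwidths, refined until
the spacing resolves the narrowest bandwidth — trapezoid quadrature of
a spike narrower than the grid step overshoots). The overlap of two
densities is $\int \min(f'_i, f'_j)\,dx \in [0, 1]$, and the score of
a clustering is the mean overlap over all (age, cluster-pair) terms —
the normalization by $11 \cdot K(K-1)/2$ keeps scores comparable
across candidates. Lower is better: distinct typologies have disjoint
slope distributions. The score is symmetric under relabeling, and the
numeric integral is validated against the Gaussian closed form
$2\Phi(-\delta/2\sigma)$ and against Monte-Carlo estimates.

### Selecting the model — a design decision

Two selection questions exist: which covariance structure, and how
many clusters. The overlap score answers the first well. It cannot
answer the second: minimizing between-cluster overlap structurally
rewards coarse partitions, because merging two clusters removes their
pair from the score entirely while diluting what remains across the
merge boundary. In experiments with well-separated synthetic
typologies, overlap-driven K selection collapsed to $K = 2$ at every
separation scale tried. The package therefore selects K *within* each
parameterization by BIC — the standard model-based-clustering route,
and the criterion the overlap score is positioned as complementing
rather than replacing — and lets the overlap score arbitrate among the
14 resulting candidates. Ties break to fewer free parameters, then
smaller K. The fully overlap-driven mode remains available
(`K_by = "overlap"`) for comparison. Candidates with a singleton
cluster cannot be slope-scored (one point has no spread to smooth) and
are dropped; BIC is also reported per candidate for information.

## Membership with uncertainty

A hard assignment wastes the posterior. For each of an individual's
800 quadruplets the mixture responsibilities (weighted component
densities, normalized with a log-sum-exp guard; own Cholesky-based
Gaussian densities, cross-checked against mclust's E-step in the
tests) are computed; the membership profile is their mean, with
per-cluster marginal quantile intervals (default 95%) of the per-draw
probabilities. Profiles sum to one, are equivariant under relabeling,
and collapse to the median-quadruplet responsibilities as the draw
spread shrinks. This is decision support — "this athlete is 41%
cluster 1" — not a selection threshold.

## The synthetic cohort generator

No real federation data ships with the package, so the generator is a
first-class module producing cohorts with known truth: per-individual
quadruplets (additive Gaussian perturbations for amplitudes,
multiplicative log-normal for rates — valid curves by construction, and
the same family the fit assumes), integer ages 10–25, several results
per individual-age, Gaussian residuals (sd 0.1 standardized), and —
with probability 0.3 — an exponential *worse-score* shift of mean 0.5
standardized units: one-sided contamination is what makes the
best-per-age filter meaningful, so the generator must produce it. Raw
units come from a fixed transform (age 17.5 ± 4.6 years; score sd 20
points, location chosen so the reference population curve bottoms out
at 141.37 points) purely to exercise unit handling.

`four_typology_preset()` encodes four archetypes — dominant average
(85%), high-young-level/low-progression, low-young-level/strong-
progression, and lower-performance — differing mainly along the
early-amplitude direction with equal gaps many within-sds wide, so EM,
BIC and the slope densities all see four unambiguous groups. That is
deliberate: the preset exists to verify recovery, and recovery claims
are only meaningful when the truth is recoverable.

What the generator does *not* emulate: FIS/FFS points-calculation
rules, race-level covariates (wind, altitude, field strength), injury
and schooling effects, dropout and unbalanced observation patterns, or
heavy-tailed residuals. Passing the parameter-recovery and
cluster-recovery tests therefore shows the machinery is correct under
its own assumptions — not that real race data satisfies them.

## Numerical choices and degenerate inputs

* OLS prefit: the curve is linear in $(a, c)$ given $(b, d)$, so a
  grid of rate pairs is profiled by linear least squares and the best
  starts polished by Levenberg–Marquardt on the log scale; flat data
  triggers a degeneracy warning, under-determined data (fewer than 8
  records or 4 distinct ages) an error.
* Standardization refuses zero-variance input; the positivity margin
  is $10^{-3}$ on the standardized scale.
* NUTS divergences are defined by a 1000-unit drop in the Hamiltonian;
  the mass matrix is regularized toward unity (Stan-style) before
  inversion.
* Identifiability: with the default age span the early-amplitude
  regressor $e^{-bt}$ is numerically large, so $a_i$ (and $\tau_a$)
  are estimated very sharply, while the late-amplitude regressor
  $e^{dt}$ is $O(1)$ and $\tau_c$ can only shrink to the
  per-individual standard-error floor ($\approx \sigma/\sqrt{n_i}$) on
  pooled cohorts. Tests assert accordingly.
* Peak equivariance: destandardizing $t^*$ equals the peak of the
  curve recomposed in raw units, because the age transform is affine.

## Problem sizes in the test suite

The checks run at desk scale, chosen so the full suite completes in
minutes while every claim is still exercised end to end: recovery
studies use 60 individuals × 16 ages over 20 seeded replicates with
2 chains × 150 retained draws after 300 warmup; typology recovery uses
a 240-individual preset cohort through the complete fit–cluster–
membership path; the pipeline determinism check reruns a 40–60
individual cohort twice. The defaults users see (4 × 200 draws, 500
warmup) are unchanged by any of this.

## Known limitations

* The Gaussian residual model ignores the skewness that remains even
  in best-per-age data; a one-sided residual would be more faithful
  but would complicate the likelihood for little gain on minima.
* The curve family forces a single interior peak; multi-peak careers
  (injury comebacks) are outside the model.
* Clustering on posterior medians discards within-individual
  correlation between parameters; membership profiles reintroduce
  posterior uncertainty but still condition on the fitted mixture.
* With very short individual histories the individual curve shrinks
  heavily toward the population mean — by design, but worth
  remembering when reading a 14-year-old's "potential curve".
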