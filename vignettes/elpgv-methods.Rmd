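---
title: "Ensemble prediction of genetic values: model, optimizer, and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble prediction of genetic values: model, optimizer, and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic prediction estimates an individual's genetic merit (a breeding value,
or a disease liability) from genome-wide marker genotypes. The workhorse
methods — GBLUP and the Bayesian alphabet (BayesA, BayesB, BayesCπ) — differ
in the prior they place on marker effects, and none dominates: GBLUP's
equal-variance kinship model suits dense polygenic architectures, while the
spike-and-slab priors of BayesB/BayesCπ suit traits driven by a few large
QTL. This package implements an ensemble that combines the predictions of
several such base methods into a single weighted average, with weights
trained by a hybrid differential-evolution / particle-swarm (DE-PSO)
optimizer. Only the base methods touch genotypes; the ensemble itself
consumes nothing but their prediction vectors, which is what makes it cheap
and generic.

## The ensemble model

Given $n$ base methods with prediction vectors $p_1, \dots, p_n$ for the same
individuals, the ensemble prediction is the unnormalized weighted sum

$$\hat g = \sum_{j=1}^{n} W_j \, p_j .$$

The fitness of a weight vector $W$ is the Pearson correlation between
$\hat g$ and a target vector. Two targets are supported:

* **phenotype mode** — the observed phenotypes of the individuals being
  fitted (usable only when those phenotypes are known);
* **reference mode** — for a test cohort with unknown phenotypes, the
  predictions of a *reference method*: the base method whose fitted genetic
  values correlate best with the observed phenotypes of the training set
  (its "fitting effect"). The ensemble weights are then trained on the test
  cohort's prediction vectors against those reference values.

Because Pearson correlation is invariant to positive affine rescaling, the
weights are meaningful only up to a common positive factor; no sum-to-one
normalization is applied. Degenerate candidates (zero-variance ensemble
output) are given a $-\infty$ sentinel so they lose every selection
comparison rather than scoring a spurious 0.

Reference mode has a known structural wrinkle, which we deliberately keep: a
weight vector with all mass on the reference method achieves fitness 1
exactly. The trained ensemble improves on the reference only through the
bounded search (25 iterations) and the averaging of weights over 100
independent runs, which together leave small, stabilizing weights on the
other methods. See *Limitations* for when this helps and when it does not.

## The DE-PSO optimizer

Each of $m = 20$ particles is a candidate weight vector. Per run:

1. **Initialize** weights uniformly on $[W_{\min}, W_{\max}] = [0, 1]$ and
   velocities uniformly on $[V_{\min}, V_{\max}] = [-0.01, 0.01]$; the best
   particle becomes the incumbent.
2. **Mutation** builds two candidates per particle $i$: the velocity shift
   $P_i = W_i + V_i$ (the PSO move) and the differential candidate
   $H_i = W_k + F\,(W_p - W_q)$ with $F = 0.5$ and partners $k, p, q$ drawn
   uniformly without replacement from the other particles. Both are clamped
   back into the weight box.
3. **Crossover** keeps $H_i$ with probability $CR = 0.3$ (one uniform draw
   per particle, switching the whole vector) and otherwise reverts to the
   particle's previous weights.
4. **Greedy selection** keeps the fitter of the trial and $P_i$, and then the
   fitter of that winner and the particle's previous weights, with ties
   favouring the newer candidate. A particle's fitness therefore never
   decreases, and neither does the incumbent's.
5. **Velocity update** applies the PSO rule
   $V_i \leftarrow \varepsilon V_i + c_1 r_1 (W_i^{new} - W_i^{old}) +
   c_2 r_2 (W^{inc} - W_i^{old})$ with $\varepsilon = 1$, $c_1 = c_2 = 2$,
   clamped to the velocity bounds. Without clamping, acceleration factors of
   2 would immediately dwarf the stated bounds, so the bounds are enforced
   run-long.

A run stops after `max_iterations = 25` iterations (an optional early-stop —
incumbent improvement below $10^{-8}$ over 5 iterations — is off by
default, keeping the iteration budget fixed and comparable). A full training
repeats the run 100 times with per-repeat seeds `seed + r` and averages the
returned weight vectors component-wise; the averaged vector defines the
ensemble. All random draws (initialization, partner indices, crossover,
velocities) come from the repeat's seeded stream, so training is
bit-reproducible.

Tunable parameters, defaults, and meaning:

| parameter | default | role |
|---|---|---|
| `w_min`, `w_max` | 0, 1 | weight search box (clamped after mutation) |
| `v_min`, `v_max` | −0.01, 0.01 | velocity bounds (clamped after update) |
| `m` | 20 | particles; ≥ 4 because DE needs three distinct partners |
| `f` | 0.5 | DE scaling of the difference vector |
| `cr` | 0.3 | crossover probability |
| `epsilon` | 1 | PSO inertia |
| `c1`, `c2` | 2, 2 | PSO acceleration (cognitive / social) |
| `max_iterations` | 25 | iteration budget per run |
| `repeats` | 100 | independent runs averaged into the final weights |

Design choices where the algorithm statement left room: crossover uses one
uniform draw per particle (vector-level switching), matching the per-particle
subscript of the rule as stated; a component-wise variant is available via
`crossover_per_dimension`. Partner indices are resampled each iteration.
Argmax ties break to the lowest particle index.

## Base learners

* **GBLUP.** The genomic relationship matrix is VanRaden method 1:
  markers centered by twice the allele frequency and the cross-product scaled
  by $2\sum_k p_k(1-p_k)$. Variance components are REML estimates obtained by
  profiling the restricted likelihood over $\delta = \sigma_e^2/\sigma_g^2$
  after an eigendecomposition of the training-block kinship; genetic values
  of unphenotyped individuals are the BLUP conditional mean through the
  kinship cross-block. Rank-deficient kinship needs no repair on this path
  (the variance ratio shifts every eigenvalue); a $10^{-6}$ diagonal ridge is
  added only if the matrix is genuinely indefinite.
* **BayesA / BayesB / BayesCπ.** Single-site Gibbs samplers (implemented in
  C++ with R's RNG, so chains are seed-reproducible). BayesA gives every
  marker its own variance with a scaled-inverse-χ² prior; BayesB is a
  spike-and-slab with per-marker slab variances and fixed prior inclusion
  probability π = 0.1; BayesCπ shares a single slab variance and samples π
  from its Beta full conditional under a uniform prior. Chain defaults —
  5000 iterations, 1000 burn-in, prior degrees of freedom 5, prior scales
  splitting the phenotypic variance evenly between markers and residual —
  are conventional choices, not values taken from any particular analysis,
  and are all configurable. The fixed part is an intercept; covariate columns
  are accepted by the GBLUP path.

Missing genotype codes are imputed with the per-marker mean by default
(configurable to a hard failure). Binary 0/1 dominant markers are handled by
the same additive machinery.

## The trait simulator

The simulator generates the study conditions the package is tested under:
599 individuals × 1279 binary dominant markers (the shape of the public
CIMMYT wheat panel), marker presence frequencies uniform on 0.1–0.9 (a
realistic polymorphic range for a filtered dominant-marker panel; the
published design does not state one), QTL positions sampled uniformly
without replacement, effect magnitudes from Gamma(shape 0.4, scale 1.66)
with signs flipped with probability ½ (the gamma is positive by
construction and the literature convention is symmetric effects; all-positive
is available by flag), and residual noise
$\sigma_e^2 = \mathrm{Var}(g)\,(1-h^2)/h^2$ computed against the *empirical*
variance of the simulated genetic values, so every replicate is calibrated
to its target heritability in expectation.

What the generator does **not** emulate: linkage disequilibrium between
markers, family/pedigree relatedness, population structure, epistasis.
Markers are drawn independently, so the genomic relationship matrix of a
simulated panel is close to the identity. Consequences for interpreting
results are discussed under *Limitations*.

## Evaluation protocol

Monte-Carlo cross-validation: either 9:1 random splits, or a random partition
into 5 near-equal parts with one part (chosen at random) held out. In every
replicate the same splits and the same base-learner fits feed every method's
predictive ability — the Pearson correlation between predictions and held-out
phenotypes — which makes the per-replicate abilities paired across methods
and justifies the paired-sample *t*-test
$t = \bar d / (s_d/\sqrt{R})$ with $R-1$ degrees of freedom. Two-sided
*p*-values are reported by default (the more conservative choice; one-sided
is available). For simulated traits the ability against the true genetic
values is reported alongside the ability against phenotypes.

The simulation benchmark (`run_simulation_study()`) draws a fresh trait per
replicate on a fixed genotype panel, splits 4:1, fits the four base
learners, selects the reference method on the training set, trains the
ensemble in reference mode on the test cohort's predictions, and aggregates.
The scaled-down defaults used in the package's own checks — 20 replicates
and 2000/500 Gibbs chains on the 599 × 1279 fixture — keep a full two-scenario
study within minutes on one core while leaving the Monte-Carlo error of the
mean abilities near 0.01–0.03.

## Numerical choices

* Degenerate (zero-variance) fitness is $-\infty$, never 0; a swarm whose
  every initial candidate is degenerate aborts with a diagnostic.
* Weight and velocity clamping are applied after every mutation / velocity
  update, so all iterates stay in their boxes.
* REML is maximized over $\log_{10}\delta \in [-12, 10]$, wide enough that
  the noiseless limit ($\sigma_e^2 \to 0$) reproduces phenotypes to ~$10^{-6}$.
* Ties in reference-method selection and in the particle argmax break
  deterministically to the earlier method / lower index.
* Gibbs samplers use R's RNG stream end to end; a monomorphic (zero-variance)
  marker column is skipped rather than divided by.

## Limitations

* **Reference mode inherits the reference method's mistakes.** Training
  against reference genetic values has a degenerate optimum at "all weight on
  the reference"; the ensemble's gain comes only from the bounded search and
  repeat-averaging keeping small weights on the other methods. When the
  training-set fitting effect identifies a method that also predicts well —
  the typical case in real panels with linkage disequilibrium and
  relatedness, where the published comparisons report the spike-and-slab
  methods fitting best — the ensemble adds a small, consistent margin on top
  of the best method. On this package's LD-free simulated panels, however,
  the kinship matrix is near identity and GBLUP (and dense BayesA) can
  near-interpolate the training phenotypes, so the best *fitting* method is
  often a poor *predictor*; reference-mode ensembling then tracks that poor
  reference. The package's own benchmark on the synthetic fixture shows
  exactly this: large, significant gains over GBLUP and a GBLUP deficit that
  shrinks from the 5-QTL to the 1000-QTL architecture, but no consistent
  advantage over the sparse Bayesian learners. Passing tests on the
  simulated panel therefore demonstrate the machinery and the GBLUP-relative
  ordering, not a universal advantage over every base method on real data.
* Phenotype mode (available when the target cohort's phenotypes are known)
  does not have this failure mode, and on constructed problems where each
  base prediction is truth plus independent noise it recovers at least the
  best single method.
* The Bayesian samplers are standard formulations with conventional
  hyperpriors; no convergence diagnostics beyond seed-reproducibility are
  built in, and short chains trade accuracy for speed in the benchmark
  defaults.
* Binary disease phenotypes are treated as 0/1 continuous responses under
  the linear model, as in the comparisons this package mirrors; no threshold
  or logistic model is provided.
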