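---
title: "Methods: case-based reasoning for restoration choice and longevity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-based reasoning for restoration choice and longevity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices
made where the design was genuinely open, and what the synthetic-data
tests do and do not demonstrate.

## The case model

A case is one restored posterior tooth: 41 problem attributes and a
2-attribute solution (restoration type in {amalgam, composite},
restoration longevity in years). Attribute 1 (patient number) is an
identifier and never enters a model. Dates are carried internally as
`Date` and converted to fractional years with a 365.25-day year; model
encodings never see a raw date, only durations (patient age at
restoration, years of prior-restoration longevity). Restorations without
an observed failure are right-censored: their recorded longevity is the
duration to the case-base's reference date, and they enter averages and
training at that value — a deliberate simplification (see *Limitations*).

Dental-sickness severities are recorded as 0 (absent) or 1–10. For the
clustering and network models they are encoded as 11-level categorical
attributes rather than reals: the variable is zero-inflated, and a
per-cluster Gaussian factor would reward variance-collapsed splits on
the zero mass over genuine patient-profile structure — we observed
exactly this failure before switching. The same reasoning moves the
1–10 restoration level into the categorical block. The perceptron,
whose inputs are min–max scaled anyway, consumes both as plain numerics.

## EM clustering of the case memory

Each mixture component factorizes naively across attributes: category
probability tables (Laplace smoothing α = 1) for discrete attributes and
univariate Gaussians (variance floor 1e-6) for continuous ones. The
E-step computes Bayes-rule responsibilities in log space; the M-step
re-estimates all parameters from responsibility-weighted counts.

Two implementation choices matter:

* **Initialization.** Random hard assignment of records to clusters
  initializes every component at (approximately) the marginal
  distribution — a symmetric saddle point EM cannot leave at realistic
  sample sizes. Each restart therefore seeds the K components from K
  randomly drawn records (categorical tables tilted toward the seed's
  categories, Gaussians centred on the seed with the global variance)
  followed by one E-step. Restarts use a short-run strategy: every
  restart runs a 15-iteration burn-in, the best training objective wins,
  and only the winner iterates to convergence.
* **The monotone trace.** With smoothing active, the quantity the M-step
  maximizes is the log-likelihood plus the Dirichlet smoothing
  log-prior; that penalized objective — not the raw likelihood — carries
  the EM monotonicity guarantee (the variance floor preserves it too,
  being a constrained M-step). `loglik_trace` records this objective; at
  α = 0 it is the plain training log-likelihood.

The number of clusters is chosen by 10-fold cross-validation on the mean
held-out per-record log-likelihood: k grows until the relative
improvement (L_k − L_{k−1}) / |L_{k−1}| no longer exceeds 1e-6. The
threshold is read as *relative* improvement; an absolute reading would
make the stopping rule depend on the arbitrary scale of the total
likelihood. Held-out likelihoods are finite by construction (smoothing
bounds every categorical mass away from zero).

## Bayesian networks

Structure is learned by constraint-based search: starting from the
complete undirected graph, an edge (a, b) is removed when some
conditioning set S from the neighbourhoods of a or b (|S| ≤ 3) renders
them independent under a G² likelihood-ratio test (α = 0.05, degrees of
freedom (|a|−1)(|b|−1) per nonempty stratum, strata with no records
skipped). Fewer than 5·df records flag the pair independent — the
standard small-sample rule, chosen over an exception so that structure
learning is total. V-structures are oriented from the separating sets,
Meek's rules propagate orientations, and any still-undirected edge is
oriented from the lower to the higher attribute index so runs are
reproducible; orientations that would close a cycle are refused. CPTs
are Laplace-smoothed conditional frequencies; unseen parent
configurations get a uniform row. Posteriors are computed by exact
enumeration — the networks here are small by design.

Where a network serves as a *predictor* (the cluster classifier in
retrieval; the longevity expert in the mixture), the class node is
attached as a parent of every screened attribute on top of the learned
attribute-to-attribute structure. Pure constraint-based output can
disconnect the class node entirely — the small-sample rule prunes
aggressively around high-cardinality attributes — which collapses the
posterior to the class marginal; the augmented form keeps the classifier
discriminative while leaving `learn_structure` itself untouched.
Before learning, descriptor attributes are screened to the 10 with the
strongest G² association with the class, keeping exact enumeration and
CI testing cheap; the cluster classifier and the longevity expert are
two separately trained networks. Continuous attributes are discretized
by equal-frequency binning into 4 bins; the longevity target uses 2-year
intervals from 0 to 20 with an open top interval whose midpoint is its
lower edge plus half the median bin width.

## The perceptron

One hidden layer of 2n+1 sigmoid units (n = number of inputs), biases
everywhere, inputs and targets min–max scaled into [0.2, 0.8] so the
sigmoids never saturate (constant dimensions map to 0.5; out-of-range
query values clamp). Training is online backpropagation with momentum,
per-pattern updates in shuffled order each epoch:

* output layer: Δw_kj = η (d_k − y_k)(1 − y_k) y_k y_j + μ Δw_kj^prev
* hidden layer: Δw_ji = η (1 − y_j) y_j [Σ_k (d_k − y_k)(1 − y_k) y_k
  w_kj] x_i + μ Δw_ji^prev

with both layers' deltas computed from the pattern's pre-update weights;
with μ = 0 a step is exactly gradient descent on half that pattern's
squared error, which the tests verify against central finite
differences to 1e-6. Weights initialize Uniform(−0.5, 0.5). Defaults
η = 0.1, μ = 0.9; the training loop accepts η = 0 (a legal null update)
and rejects negative values. Early stopping holds out 20% of patterns
and stops after 50 epochs (experts: 20) without validation improvement,
restoring the best weights. The per-pattern loop is compiled (C++), as
is conventional for this model family; the update rule itself is
implemented here, not delegated.

## Mixture of experts and the CBR cycle

Per cluster, two experts map the descriptor plus a *candidate*
restoration type to longevity: the augmented Bayesian network (posterior
expectation over longevity bins) and the perceptron regressor. Their two
outputs feed a 2-5-1 combiner perceptron. The combiner trains on
out-of-fold expert predictions from an internal 5-fold split — training
it on resubstitution outputs would let it learn the experts' optimism
rather than their information. Clusters with fewer than 20 cases fall
back to retrieved-case per-type averages, flagged.

Retrieval classifies the probe with the cluster network (ties broken by
the higher EM responsibility, then the lower cluster index) and ranks
the cluster's cases by a per-attribute match score: equality indicator
for categoricals, 1 − |Δ|/range for reals, equally weighted; the top
m = 20 are returned. The similarity is the cycle's major open design
choice: nothing in the method's description pins one down once
nearest-neighbour retrieval is replaced by clustering, and the equal-
weight match score is the simplest defensible option. Revision clamps
raw estimates into per-cluster, per-type mean ± 2 sd. Two headline
longevity estimates coexist deliberately — the retrieved-case same-type
average and the revised mixture output — because the cycle's reuse step
and its evaluation are described in terms of different estimators; the
configuration picks which one drives the recommendation (average by
default), and predictions report both.

Retention appends the case, invalidates the affected cluster's mixture
cache, recomputes confidence limits, and refreshes the EM model and
classifier after every 50 retained cases.

## Evaluation machinery

The exact Mann–Whitney U test uses U = #{(i, j) : x_i > y_j} and
p = P(U ≤ U_obs) under the full null distribution of rank arrangements,
computed by the classic counting recursion and checked against
brute-force enumeration. Only ties *across* the two samples break the
exact null and trigger the error (or the seeded mid-rank Monte-Carlo
permutation fallback); ties within one sample are harmless — the
published error table this machinery must reproduce contains one.
5×2 cross-validation stratifies its random half splits by restoration
year and pools both directions of each repetition into one mean absolute
error. Leave-one-out keeps the EM model and classifier fixed and
excludes the probe from retrieval only; refitting the clustering per
held-out case would be quadratic and changes nothing about the
retrieval-level question the estimate answers. The failure-rate report
uses a strict threshold: a restoration fails if it lasted strictly less
than 50% of its type's overall mean duration. Reports keep full
precision; percentages are rounded to integers only for display.

## The synthetic generator

No clinical records ship with the package, so every claim is exercised
on synthetic case-bases with known structure. The default configuration
emulates the study conditions: three latent patient profiles
(young/low-wear, middle-aged, older/high-wear) with weights
(0.45, 0.35, 0.20), separated in age (28/45/63 ± 7 years), smoking,
drinking, gingivitis, abrasion, attrition, multicaries, blood pressure,
restoration level, tooth distribution and severity profile; composite
prevalence ≈ 93%; longevity ~ Normal truncated at zero with means
14/15/16 years (amalgam) and 8/9.5/11 years (composite) across clusters
and a 1.3-year standard deviation — the within-type spread is the
package's choice of a clinically plausible value, set once. 60% of
cases are censored. Censored cases get their restoration date
synthesized backward from the reference date (2014-06-30) so the
recorded duration-to-present equals the drawn longevity; failed cases
draw a uniform restoration date in 1993–2003 and fail `longevity`
later. Prior-restoration history depends on the cluster only — tying it
to the case's own solution type would leak the solution into the
problem descriptor and hand the clustering an artifact to find.

What passing tests show: the pipeline recovers known cluster structure
(the cross-validated selection returns K = 3 in at least 9 of 10 seeds
at n = 3000), predicts held-out longevity within 1.5 years MAE at these
noise levels, orders amalgam above composite, and the combiner never
degrades the better expert by more than 10% MSE. What they cannot show:
performance on real clinical data, whose cluster structure, attribute
dependencies, censoring mechanism and noise are unknown; the published
leave-one-out errors of a few tenths of a year belong to the original
clinic records and are not reproducible without them.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: n = 3000
for cluster-count selection (ten seeds), 3000 training / 500 held-out
cases for end-to-end recovery, 2000 for the mixture property — sizes at
which every statistic involved is stable. Numerical safeguards:
responsibilities and held-out likelihoods in log space with
log-sum-exp; Laplace α = 1 and a 1e-6 variance floor; similarity ranges
floored at 1e-12; mixture outputs clamped at 0 years; all stochastic
components seeded from one master seed through a deterministic
label-hash fan-out.

## Limitations

* Censored durations are treated as observed values, as the case model
  defines; a survival-analysis treatment (e.g. Kaplan–Meier adjusted
  averages) is out of scope by design.
* Per-cluster attribute independence is a modelling convenience; real
  dental records will violate it, and the cross-validated K then
  absorbs dependence into extra components.
* The augmented class node makes the predictor networks deliberately
  naive-Bayes-like around the class; their structure among attributes is
  still learned, but class-attribute edges are not pruned.
* Exact network inference by enumeration requires the screened,
  small-network regime; the screening width (10) bounds it.
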