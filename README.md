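# dentalcbr

Case-based reasoning (CBR) for restorative dentistry: given a posterior
tooth to restore, recommend a material — silver **amalgam** (durable,
unaesthetic) or **composite** resin (aesthetic, shorter-lived) — and
predict how many years the restoration will last.

The package is aimed at clinical-informatics researchers who want a fully
reproducible, testable implementation of a CBR decision-support pipeline
over tabular clinical records with right-censored outcomes, and at
methodologists who need its building blocks (mixed-type EM clustering,
constraint-based Bayesian networks, a from-scratch perceptron, exact
small-sample Mann–Whitney comparison) individually.

## The model

A *case* is one restored tooth: a 41-attribute problem descriptor
(patient demographics and habits, eight dental sicknesses scored 0–10,
seventeen systemic conditions, tooth number, prior restoration history,
failure-cause flags, aesthetic importance, restoration date) plus a
2-attribute solution (restoration type, restoration longevity in years).
Restorations that never failed are right-censored: their longevity runs
to the present (reference) date.

The reasoning cycle is:

1. **Retrieve.** The case memory is organized by an
   expectation–maximization mixture over the mixed categorical/continuous
   descriptor, with per-cluster naive factorization — category tables
   P(x_a = c | k) for discrete attributes, univariate Gaussians
   N(mu_ak, sigma_ak^2) for continuous ones — and Bayes-rule
   responsibilities. The number of clusters K is selected by 10-fold
   cross-validated held-out log-likelihood with a relative-improvement
   threshold of 1e-6. A Bayesian-network classifier (structure from
   conditional-independence G² tests in the Verma–Pearl style, class node
   augmenting the learned attribute graph) assigns a new case to a
   cluster, and the m most similar cluster cases are retrieved.
2. **Reuse.** A per-cluster *mixture of experts* predicts longevity from
   the descriptor plus a candidate type: a discretized-longevity Bayesian
   network and a one-hidden-layer sigmoid perceptron (2n+1 hidden
   neurons, biases, inputs and targets scaled into [0.2, 0.8], online
   backpropagation with momentum, Δw_kj = η (d_k − y_k)(1 − y_k) y_k y_j
   + μ Δw_kj^prev), whose two outputs feed a second 2-5-1 perceptron
   trained on out-of-fold expert predictions.
3. **Revise.** Raw estimates are clamped into per-cluster, per-type
   confidence limits (mean ± 2 sd).
4. **Retain.** Solved cases are stored; the affected cluster's mixture is
   invalidated and the EM model refreshed every 50 retentions.

Competing predictors are compared by 5×2 cross-validation (year-stratified
half splits) and the **exact** one-sided Mann–Whitney U test, whose
p-value is computed from the full null distribution of rank arrangements
— no normal approximation.

## Worked example

```r
library(dentalcbr)

# a synthetic case-base with three latent patient profiles
gen <- generate_casebase(default_casebase_config(seed = 11, n_cases = 3500))
cb  <- gen$casebase
print(cb)
#> Dental restoration case-base: 3500 cases, 1512 patients
#> Reference date: 2014-06-30
#> Restoration types: amalgam=263, composite=3237
#> Censored (no observed failure): 2067 (59%)

kb <- build_knowledge_base(
  casebase(cb$cases[-(1:500), ], cb$reference_date, validate = FALSE),
  cbr_config(), seed = 2)
kb$K
#> [1] 3

predict_restoration(kb, cb$cases[1, , drop = FALSE])
#> Recommended restoration: amalgam
#>   amalgam   expected longevity 14.2 y (retrieved-case average 14.2, mixture 14.1, interval [11.9, 16.6])
#>   composite expected longevity 7.9 y (retrieved-case average 7.9, mixture 8.1, interval [5.5, 10.7])
#>   cluster 1, 20 retrieved cases, reuse by mixture
```

The recommendation maximizes the expected longevity (here amalgam, 14.2
vs 7.9 years); both the retrieved-case average and the revised
mixture-of-experts estimate are reported, with the cluster's confidence
interval. On 500 held-out synthetic cases this pipeline attains a mean
absolute longevity error of about 1.1 years against generative means of
8–16 years.

A command-line surface over the same functions lives in
`inst/cli/dentalcbr`:

```sh
dentalcbr simulate --seed 7 --out cb.csv --n 3000
dentalcbr train    --casebase cb.csv --out kb.json --seed 3
dentalcbr predict  --kb kb.json --case probe.csv
dentalcbr evaluate --casebase cb.csv --mode compare --methods cbr,type_mean
dentalcbr report   --casebase cb.csv --table usage
```

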