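---
title: "Multi-modal genomic prediction: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal genomic prediction: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mmgp compares two families of genomic-prediction models for multi-environment
plant-breeding trials (METs) on one shared data pipeline: a Bayesian GBLUP
linear mixed model and a multi-modal deep-learning (DL) regressor fed with
Cholesky-encoded relationship features. This vignette is the package's own
account of the science: the models and their assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open.

```{r setup}
library(mmgp)
```

## The data model

A MET records a quantitative trait `Y_ij` for line `j` (of `J`) in environment
`i` (of `I`), plus a SNP panel for the lines. Genotypes arrive either in the
TASSEL numeric coding (1 homozygous major, 0.5 heterozygous, 0 homozygous
minor) or already recoded to `{-1, 0, +1}`. The QC pipeline mirrors standard
practice: markers with at least 50% missing calls are removed first, then
markers whose folded minor allele frequency — computed on the non-missing
calls of the survivors, treating `{-1, 0, +1}` as dosage 0/1/2 of the `+1`
allele — falls below 5%; remaining gaps are mean-imputed per marker, which
preserves per-marker means exactly. Both thresholds are arguments of
`filter_markers()`; the defaults are the conventional cut-offs. The MAF
formula itself had to be chosen (dosage counting with folding at 0.5), as did
the reading of "less than 50% missing" as *remove at* 50%; both choices are
stated in the `QCReport` so downstream marker counts are auditable.

The genomic relationship matrix is VanRaden method 1,
`G = W W' / c` with `W` the column-centered marker matrix and
`c = sum_k 2 p_k (1 - p_k)`. Nothing downstream depends on this particular
kernel beyond positive definiteness, but the scaling gives `mean(diag(G))`
near 1 for a panel in Hardy–Weinberg proportions, which keeps variance
components interpretable on the trait scale. A relative diagonal jitter of
`1e-6 * mean(diag(G))` guarantees factorability even when the panel contains
duplicated lines.

## The Bayesian GBLUP model

The linear mixed model is

    Y_ij = mu + E_i + g_j + gE_ij + e_ij

with flat priors on `mu` and the environment effects `E_i`, line effects
`g ~ N(0, sigma_g^2 G)`, interaction effects
`gE ~ N(0, sigma_gE^2 (I kron G))` — independent per-environment genetic
effects with shared kinship — and iid Gaussian errors. Each variance gets a
scaled-inverse-chi-squared prior with `df0 = 5` degrees of freedom; the prior
scales are set so the prior *mode* of each variance matches an equal split of
`R2 = 0.5` of the phenotypic variance among the random terms, the remainder
going to the residual. These are weak priors: with hundreds of observations
the data contribute two orders of magnitude more degrees of freedom.

`fit_gblup()` is a Gibbs sampler. For efficiency the random effects are
reparameterized through the eigendecomposition `G = U D U'`: with
`B = U D^(1/2)` and `g = B u`, the prior on `u` is iid, and the Gram matrix
of each term's observed feature block (`B` rows indexed by the design) is
eigendecomposed **once**, after which every full-conditional update is a pair
of `J x J` matrix-vector products — no per-iteration factorization. The
interaction term is updated per environment, exploiting the block-diagonal
structure of `I kron G`; no `(I*J)^2` array is ever formed. Fixed effects use
an intercept plus `I - 1` treatment contrasts to avoid rank deficiency and
are re-expressed as `mu` plus centered full environment effects in the
output. Chain defaults (6000 iterations, 1000 burn-in, thinning 5) are desk-
scale choices; the tests that compare two independent chains use longer
chains (9000/1000/2) because the quantity compared — posterior-mean
predictions including cell-level interaction effects — has Monte-Carlo error
that only shrinks with the number of retained draws.

`blup_closed_form()` solves Henderson's mixed-model equations at fixed
variances and is the deterministic oracle for the sampler: at the sampler's
posterior-mean variances the two prediction vectors correlate above 0.99 on
synthetic data, and under `G = I` the sampler reproduces ridge regression
with `lambda = var_e / var_g`.

**Identifiability of the interaction variance.** With one observation per
(environment, line) cell, `gE` and the residual live on the same cells and
are distinguished *only* through the kinship structure of `G`. If the
simulated panel has many more markers than lines, sample relatedness
vanishes, `G` approaches the identity, and the `sigma_gE^2` / `sigma_e2`
split becomes unidentifiable — any sampler recovers their sum but not the
split. The package's variance-recovery experiments therefore simulate 400
markers for 200–300 lines, which keeps the realized relatedness spectrum
wide. This is an experimental-design fact worth knowing before interpreting
interaction variances on real data from weakly related panels.

## The multi-modal deep-learning model

The DL regressor consumes up to three modality blocks built by
`build_modality_inputs()`:

* `X_E` — one-hot environment design (`n x I`), environments ordered
  lexicographically;
* `X_L` — genomic features `Z_L F` (`n x J`): the observation's line row of a
  triangular factor `F` of `G`;
* `X_EL` — interaction features `Z_EL (I kron F)` (`n x I*J`): the `X_L` row
  placed in the observation's environment block, zero elsewhere. The block
  structure is materialized row-wise; the `(I*J) x (I*J)` interaction
  relationship matrix itself is never allocated.

**Cholesky orientation.** Writing the features as `Z_L L_G` with
`G = L_G' L_G` (the upper factor) gives feature Gram `L_G L_G'`, which is
*not* `G`. The default orientation is therefore `gram`: `F` with `F F' = G`
(the transpose of the upper factor), under which a linear model on the
features reproduces the mixed-model covariances exactly —
`X_L X_L' = Z_L G Z_L'` and likewise for the interaction block. The literal
upper-factor reading remains available via
`chol_factor(G, orientation = "upper_GtLL")` for anyone wanting the verbatim
encoding; the tests demonstrate that the covariance identity then fails.

Each modality passes through its own residual MLP; one hidden "level" is one
residual block:

    dense(width) -> batch norm -> ReLU -> dense(width) -> batch norm
      -> add skip (linear projection when widths differ) -> ReLU -> dropout

Batch normalization precedes every activation. Widths follow the halving
rule `N(l) = floor(N(1) / 2^(l-1))`, clamped at 1. The modality
representations are concatenated (late fusion) and passed through an optional
fusion MLP of the same block design — fusion depth 0 means the concatenation
feeds the single linear output neuron directly, a configuration that tuning
does select in practice. L2 penalties apply to all dense and output weights
(not biases or batch-norm parameters), dropout to each block output.

Training follows a fixed protocol: Adam on mean squared error plus L2, batch
size 32, at most 48 epochs, learning rate `lr0 * exp(-wd * (epoch - 1))`, and
early stopping that halts after `patience` consecutive epochs without
improvement of the *training* loss (a validation-loss monitor is available as
a config switch). Responses are standardized to zero mean and unit variance
on the training fold and de-standardized at prediction; the learning-rate
search ranges presuppose O(1) targets. Everything — initialization, batch
shuffling, dropout — flows from one seed, so training is bit-reproducible on
one device. The whole network, including backpropagation through the
residual/batch-norm blocks, is implemented in base R; the gradients are
verified against finite differences in the test suite.

Open readings resolved here, deliberately: the residual block's exact
ordering around the skip connection (stated above, with a linear projection
on the skip path when widths change); "one hidden layer level = one residual
block" rather than counting dense layers, for symmetry with the halving rule;
and the exponential form of the "adaptive exponential decay" learning-rate
schedule.

## Hyperparameter optimization

`bayes_optimize()` minimizes inner-validation MSE over a 13-dimensional box:
per-modality depths (1–4, 1–6, 1–6), fusion depth (0–4), first-level widths
(up to 128 / 1024 / 1024 / 200), the L2 penalty (1e-8 to 1e-2), dropout
(1e-4 to 0.5), patience (up to 128), and log-scale learning rate and decay.
Integer dimensions are rounded then clamped (widths and patience to at least
1; fusion depth may be 0); log-scale dimensions are exponentiated. The inner
split is ten seeded folds of the training set with two folds (20%) held out
for validation. The optimizer is a Gaussian process with Matérn-5/2 kernel on
the unit-scaled box (shared lengthscale chosen by marginal likelihood over a
small grid) and expected improvement maximized over seeded candidate sets; a
budget of 50 counts *all* objective evaluations including the 10
space-filling initial points. A `strategy = "random"` fallback runs pure
random search with the same budget; a sign test in the suite checks the GP
actually earns its keep on a smooth 2-D objective.

## Evaluation protocols

* **5FCV** — five balanced folds stratified by environment; each fold is the
  test set once. "Balanced subsets" is read as balanced within environment.
* **LOEO** — each environment in turn is predicted from all others. No
  interaction term can be trained for the held-out environment, so LOEO fits
  use the `G` or `E+G` predictors only, and the held-out environment
  contributes neither an environment effect (GBLUP) nor a design column (its
  `X_E` row is zero).
* **Inverted k-fold** — training on one fold and testing on the other k-1,
  for small-training-fraction studies (k = 20 trains on 5%).

Metrics are `nrmse()` — RMSE divided by the mean of the observed test values,
with range- and SD-normalizers available since the normalizer is a genuine
convention choice (mean normalization is consistent with the magnitudes of
published tables for strictly positive traits) — and `pearson_cor()`, which
errors on constant inputs rather than silently returning 0.
`compare_models()` counts strict wins (ties favor neither model) and reports
relative differences as `100 * (x / y - 1)` in both directions.

The package bundles transcriptions of the 5FCV and LOEO accuracy tables of a
published large wheat MET study (`published_5fcv_metrics()`,
`published_loeo_metrics()`) as worked examples: the aggregation utilities
reproduce their printed grand means, win counts, and relative-difference
ranges. Those tables are inputs to the comparison code, not results of this
package.

## The synthetic generator

`simulate_met()` draws a MET with exactly the mixed-model structure above:
binomial genotypes at configured allele frequencies, environment effects
`N(0, env_effect_sd^2)`, line effects with covariance `sigma_g2 * G`,
interaction effects drawn independently per environment (the `I kron G`
structure; the model has no cross-environment genetic correlation parameter,
so neither does the generator), and iid noise. Defaults — J = 300, I = 3,
M = 2000, variances (1, 0.5, 0.5), hence realized heritability near 0.5 —
are the desk-scale study conditions: large enough for stable moments, about a
minute to simulate and fit.

One mechanism choice matters: line and interaction effects are drawn through
*marker effects* (`g = W alpha` with `alpha ~ N(0, sigma_g2 / c I)`), not
through a triangular factor of `G`. Conditional on the markers the law is
identical — `cov(g) = sigma_g2 W W' / c = sigma_g2 G` — but the marker-effect
draw commutes exactly with any relabeling of lines, whereas
`chol(P G P') != P chol(G)`: the generator is exactly equivariant, which the
exchangeability tests exploit.

What the generator does **not** emulate: linkage disequilibrium and haplotype
structure, dominance and epistasis, selection, unbalanced or sparse testing
designs beyond random cell dropout, heteroscedastic environments, and
genotype-calling error. Passing tests on synthetic data therefore certify the
statistical machinery — estimation, encoding, protocols — not field-data
performance.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale, the
package's own choice of study size: QC and encoding properties on matrices up
to 500 lines; sampler validation at J = 200–300 with 2500–9000 iterations;
network checks on 20–60 observations; the end-to-end two-model comparison as
a full 5FCV at J = 300, I = 3, heritability 0.5, with 2000-iteration chains
and a small fixed DL configuration (first-level widths 8/64/64, one block per
modality, one fusion block of 32; lr0 = 0.01, decay 0.02, L2 = 1e-4). At
these sizes GBLUP reaches mean test correlations near 0.75 and the DL model
near 0.70 — the two families perform similarly, which is the property-level
analogue of the published finding; exact accuracy values depend on the
normalizer, the kernel and the synthetic regime and are not reproduction
targets.

Numerical details fixed once: batch-norm epsilon 1e-3 and momentum 0.99;
Glorot-uniform initialization; eigenvalues of `G` clamped at
`max(eigenvalue) * 1e-12` before taking square roots; minibatch remainders of
size 1 merged into the previous batch so batch statistics are always defined;
hyperparameter ties in integer modes resolved toward the smallest value.

## Known limitations

Single-trait analyses only; no REML point estimation (the closed form
requires variances as inputs); no pedigree, dominance or Gaussian kernels; no
GPU path — the network is deliberately a transparent base-R implementation,
suitable for the desk-scale studies the package targets, not for panels of
thousands of lines with full-width tuned architectures; and the GP optimizer
is serial (no asynchronous or multi-fidelity scheduling).
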