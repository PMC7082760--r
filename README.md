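# dlvmcf

Personalized causal effects of binary genomic aberrations on an ordinal
tumor grade, inferred from noisy discrete and continuous proxy features
with a deep latent variable model.

## What problem this solves, and for whom

In observational cancer cohorts (the motivating setting is prostate
adenocarcinoma), a patient either carries a genomic aberration — an ERG
fusion, a somatic or germline mutation, a copy-number alteration — or
does not, and only the corresponding one of the two potential Gleason
Scores y(0), y(1) is observed. Estimating the missing arm is confounded
by unmeasured biology that influences both aberration status and tumor
aggressiveness. `dlvmcf` is for biostatisticians and computational
biologists who want per-patient counterfactual grade estimates, and
group-level effect comparisons (e.g. between European-American and
African-American patients, per grade stratum), from tabular multi-omics +
clinical data in which the observed features are treated as noisy proxies
of latent confounders.

## The model

Twin variational autoencoders with a joint confounder layer, following
the causal structure of inference with proxies:

```
p(Z, z1, z2, x1, x2, t, y)
  = p(z1) p(z2) p(x1|z1) p(x2|z2) p(Z|z1,z2) p(t|Z) p(y|t,Z)
```

* z1 ~ Bernoulli prior — discrete latent confounder behind the discrete
  proxies x1 (aberration indicators, categorical clinical fields);
* z2 ~ Gaussian prior — continuous latent confounder behind the
  continuous proxies x2 (expression, continuous clinical fields);
* Z — joint Gaussian confounder mixing both, parent of the binary
  intervention t and the outcome y (Gleason Score).

All conditionals and approximate posteriors are multilayer perceptrons,
trained jointly by ADAM on an evidence lower bound (closed-form KL terms,
reparameterized Gaussian and relaxed-Bernoulli sampling) plus auxiliary
predictors of t and y from the proxies. A fitted model reconstructs the
factual outcome ŷ(t) and estimates the counterfactual ŷ(1−t) from
posterior draws of Z.

Estimands, per patient and per (race × grade) group:

* **ICE** (individual causal effect): `y − ŷ(0)` for carriers,
  `ŷ(1) − y` for non-carriers;
* **AICE**: `sqrt(sum(ice²) / n)` (root convention; a mean-of-squares
  variant is a flag away) — the group effect magnitude;
* **RMSE**: factual-arm reconstruction error, the precision of the
  inference machinery.

The experiment driver runs the full evaluation protocol — per racial
group, 10 replications of 3-fold cross-validation with ≈47/20/33%
train/validation/test splits stratified by grade (low GS ≤ 6,
intermediate GS = 7, high GS ≥ 8) — and compares groups with two-sided
paired t-tests (α = 0.05, 95% CI, pairing by replication). A
multilayer-perceptron imputer fills in missing race labels; a monotone
logistic stand-in maps estimated GS to a [0, 1] genomic risk score. A
synthetic cohort generator simulates the model's own causal graph with
known potential outcomes, which is how the package verifies itself.

Everything, including the neural-network machinery, is implemented in
base R with no compiled code or deep-learning runtime; gradients are
hand-derived and checked against finite differences in the test suite.

## Worked example

Simulate a confounded cohort with a constant +1 GS effect, fit the model,
and infer counterfactuals on held-out patients:

```r
library(dlvmcf)

cohort <- generate_cohort(dgp_params(n = 1000, tau = 1, seed = 1))
set.seed(1)
idx <- sample(1000)
fit <- fit_dlvm(cohort[idx[1:470], ], cohort[idx[471:670], ],
                dlvm_config_desk(seed = 1))
est <- infer_counterfactual(fit, cohort[idx[671:1000], ])
head(est, 3)
#>     y_hat_0 y_hat_1 t_factual y_factual   ice
#> 80     7.45    8.47         0         7 1.474
#> 477    8.40    9.19         0         8 1.191
#> 916    9.23    9.73         1        10 0.773
mean_ice(est)   # 0.89  -- signed mean effect; the cohort's true ATE is 0.906
aice(est)       # 0.998 -- root-mean-square effect magnitude
rmse(est)       # 0.441 -- factual reconstruction error
                #          (predicting the training mean scores 1.232)
```

`y_hat_0`/`y_hat_1` are posterior-mean Gleason Scores under no
aberration / aberration; `ice` follows the two-branch definition above.
The estimated mean effect (0.89) recovers the simulated +1 effect after
rounding into the GS scale (true ATE 0.906), and factual reconstruction
is ~2.8× more precise than the constant-predictor baseline.

The full protocol — CV replications, per-grade AICE/RMSE/GRS tables,
race comparisons — runs from one config file:

```sh
Rscript inst/cli/dlvmcf.R simulate --config sim.yml
Rscript inst/cli/dlvmcf.R impute   --config impute.yml
Rscript inst/cli/dlvmcf.R run      --config run.yml --aberration ERG_fusion
```

(`system.file("cli", "dlvmcf.R", package = "dlvmcf")` after
installation.) Each output directory receives an append-only
`manifest.yml` with the resolved config, seeds, input fingerprints and
package version.

See `vignettes/counterfactual-inference.Rmd` for the model, its
assumptions, the synthetic data-generating process, and design decisions.

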