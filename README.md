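# cryptophen

Cryptic phenotype analysis for binary symptom matrices.

Rare Mendelian diseases are diagnosed as binary entities, but the biology
underneath them is a continuous spectrum: many undiagnosed people carry
milder, sub-clinical versions of the same symptom constellation. `cryptophen`
infers that spectrum — a quantitative latent severity trait, the *cryptic
phenotype* — directly from sparse binary patient-by-diagnosis-code matrices
of the kind produced by electronic health records, and provides the
downstream statistics needed to validate the trait against rare-variant
carrier status and polygenic scores. The intended users are statistical
geneticists and clinical informaticians who have coded clinical data and
want a severity phenotype they can feed into association analyses.

## The model

For `N` subjects and the `K` binary symptoms annotated to a disease, let
`S` be the N×K symptom matrix and `Z` an N×L matrix of latent phenotype
severities. The generative model is

    P(S, Z | θ) = f(Z; θ) · P(Z),
    f(Z; θ)_{ij} = logistic(Σ_l Z_{il} W_{jl} + b_j),     P(Z_il) = N(0, 1)

where `f` is the *symptom risk function* with loadings `W` (K×L) and
intercepts `b`. Fitting maximizes an evidence lower bound (ELBO) on the
marginal likelihood `P(s|θ) = ∫ P(s, Z|θ) dZ` by amortized variational
inference: a shared encoder maps each symptom vector to a Gaussian
approximate posterior, trained jointly with `θ` by stochastic gradient
ascent. An automatic-relevance (ARD) prior on the columns of `W` zeroes out
unneeded components; the number of surviving columns is the model's
*effective rank* `L_eff`. When `L_eff > 1`, the component that best predicts
the disease's diagnostic labels (by average precision) is selected as the
cryptic phenotype, and it is validated by a capture / replication /
consistency pipeline (bootstrap severity tests plus cross-model r²) and by
OLS regressions on carrier status, annotation-flag class, and PGS-by-carrier
interactions.

Everything is testable without any external data: the `sim_config` /
`generate_cohort` simulator produces cohorts with known latent severities,
ascertainment-biased diagnosis labels, carrier genotypes, polygenic scores
and covariates.

## Worked example

```r
library(cryptophen)

cfg <- sim_config(N = 20000, K = 20, L_true = 1, seed = 11)
co  <- generate_cohort(cfg)
d   <- labeled_dataset(co$S, co$labels)
sp  <- split_train_test(d, train_frac = 0.75, seed = 1)

fit <- cpa_fit(sp$train, L = 10, seed = 3)
fit
#> <cpa_fit> K=20, L=10 (effective rank 2), 80 epochs, converged=TRUE

sel <- select_cryptic(infer_latent(sp$test$matrix, fit), sp$test$labels)
sel
#> <cryptic_assignment> component component_9 (best_classifier), AP=0.6377, orientation +1

bootstrap_severity_test(sel$scores, sp$test$labels, n_boot = 1e5, seed = 5)
#> <severity_test> effect=2.1678 [2.1057, 2.2272], p=1e-05 (m=1), PASSED

est <- fit_pgs_interaction(co$Z[, 1], co$genotypes, co$pgs,
                           covariate_table(co$covariates$sex, co$covariates$age))
effect_term(est, "pgs_x_carrier")[, c("term", "beta", "se", "p")]
#>            term      beta         se            p
#> 4 pgs_x_carrier 0.2057893 0.05528195 0.0001977695
```

The model started with 10 components and pruned itself to an effective rank
of 2: the cohort was simulated with one severity axis, but the genetic
layers (carrier shifts, polygenic load) add enough extra structure that a
weak second component survives pruning — exactly the situation the
average-precision selection step exists for. The selected component is
strongly elevated among withheld diagnosed cases (mean case-control
difference 2.17 latent-SD units, bootstrap p at the floor of 1/(n_boot+1)),
its average precision for the diagnosis (0.64) is ~64x the 1% prevalence,
and the regression recovers the simulated PGS-by-carrier interaction (true
value 0.15) within one standard error.

## Command line

A thin CLI over the same functions ships in `inst/cli/cryptophen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cryptophen.R", package="cryptophen"))')" \
    simulate --n 10000 --k 20 --rank 1 --seed 7 --out cohort/
# ... fit --matrix cohort/ --components 10 --seed 1 --out model.json
# ... impute --model model.json --matrix cohort/ --out scores.tsv
```

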