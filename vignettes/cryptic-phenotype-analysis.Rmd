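---
title: "Cryptic phenotype analysis: model, inference, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cryptic phenotype analysis: model, inference, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mendelian diseases are coded in clinical data as present/absent diagnoses,
yet their underlying pathology is graded: carriers of pathogenic variants
range from severely affected to symptom-free, and many undiagnosed patients
express partial symptom constellations. `cryptophen` treats a disease's
annotated symptom set as noisy binary read-outs of a continuous latent
severity trait and infers that trait per subject. The inferred score — the
*cryptic phenotype* — can then be used as a quantitative outcome in genetic
association models, where diagnosis itself would be underpowered and
ascertainment-biased.

## Generative model and assumptions

For subject $i$ and symptom $j$,

$$P(\mathbf{S}, \mathbf{Z} \mid \theta) = f(\mathbf{Z};\theta)\,P(\mathbf{Z}),
\qquad
f(\mathbf{Z};\theta)_{ij} = \sigma\!\Big(\textstyle\sum_l Z_{il} W_{jl} + b_j\Big),$$

with $\sigma$ the logistic function, $\mathbf{W} \in \mathbb{R}^{K\times L}$
the symptom loadings, $\mathbf{b}$ intercepts, and independent standard
normal priors on each latent component. The assumptions this encodes:

* **Binary, permanent symptoms.** Each symptom is collapsed by
  at-least-one binarization; resolution over time is not modeled.
* **Conditional independence.** Given severity, symptoms are independent
  Bernoulli draws; residual symptom-symptom dependence must be absorbed by
  additional latent components.
* **Monotone severity.** The link is monotone, so along a component with
  positive loadings, a larger latent value always means higher symptom
  risk. After fitting, each retained component's sign is flipped so its
  loading sum is positive — "severity points up" — resolving the
  sign non-identifiability of factor models.
* **Gaussian prior.** The latent trait is unbounded. Zero-inflated or
  floored severity distributions (plausible when most of the population is
  simply unaffected) are not assumed; the prior is a pluggable field of
  `latent_model` should a different choice be needed.

The linear-logistic risk function is the simplest member of the admissible
family (any map into $[0,1]^{N\times K}$). It keeps loadings interpretable
as per-symptom log-odds slopes; the decoder interface would admit a monotone
nonlinear replacement without touching the rest of the pipeline.

## Inference

`cpa_fit()` maximizes the evidence lower bound

$$\mathcal{L} = \mathbb{E}_{q}\big[\log P(\mathbf{s}\mid \mathbf{Z},\theta)\big]
  - \mathrm{KL}\big(q(\mathbf{Z}) \,\|\, P(\mathbf{Z})\big)
  \;\le\; \log P(\mathbf{s}\mid\theta)$$

with a per-subject factorized Gaussian $q$ amortized through a shared
one-hidden-layer encoder (tanh hidden units, width `max(2L, 16)`; softplus
scales, floored at $10^{-4}$). Gradients use the reparameterization trick
(one Monte-Carlo sample per minibatch element) and Adam. The KL term is
closed-form. All gradients are hand-derived matrix algebra — at the scale
this package targets (tens of symptoms) a tensor runtime would be overhead.

Parameters that matter, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `L` | 10 | components at initialization; pruning removes the excess |
| `lr` | 0.01 | Adam step size |
| `batch_size` | 512 | minibatch rows |
| `tol` | 1e-4 | relative ELBO change defining convergence |
| `patience` | 10 | epochs per convergence window |
| `alpha_max` | 1e6 | ARD precision cap for pruned columns |
| `polish_epochs` | 15 | final epochs at `lr/10` |
| `restarts` | 3 | fresh-seed retries if convergence fails |

**Rank pruning.** Each loading column $l$ carries an ARD-style Gaussian
prior $W_{jl} \sim N(0, \alpha_l^{-1})$ whose precision is updated between
epochs by the fixed point $\alpha_l = K / \lVert W_l \rVert^2$ (capped at
`alpha_max`, first updated after `ard_warmup = 25` epochs so real signal can
establish itself). Columns the data do not support collapse toward zero.
The *effective rank* is the count of columns whose norm is at least 1% of
the largest column norm **and** above an absolute floor of 0.05. The floor
is an addition to the relative rule: when the data carry no signal at all
(an all-zero matrix) every column shrinks to the same tiny noise norm and a
purely relative cutoff would keep all of them; the floor makes the rank 0,
as it should be. Both thresholds are arguments of `effective_rank()`.

**Convergence and the polish phase.** Convergence is declared when the
epoch-averaged ELBO improves by less than `tol` (relatively) between two
consecutive `patience`-epoch windows. Adam's stationary fluctuation scales
with the learning rate, so after convergence a short phase at `lr/10` is run:
it drops pruned-column norms by roughly an order of magnitude (well clear of
the rank thresholds) and sharpens the encoder, at negligible cost. A fit
that fails to converge is retried from fresh seeds (`restarts`); if all
retries fail the best run is returned with `converged = FALSE` — in real
clinical data some diseases simply do not fit, and that outcome must be
reportable rather than fatal.

**Oracles.** For $L \le 2$ the marginal likelihood and the exact posterior
means are computed by Gauss–Hermite quadrature (`exact_marginal_loglik()`,
`posterior_mean_quadrature()`; nodes via Golub–Welsch). These are
independent of the variational path and anchor the test suite: the ELBO must
sit below the exact marginal (within Monte-Carlo error), and amortized
posterior means must correlate with exact posterior means at $r \ge 0.99$.

## Selecting and validating the cryptic phenotype

With `L_eff = 1` the surviving component is the cryptic phenotype by
definition. Otherwise each retained component is scored as a ranking
classifier of the diagnosis labels by average precision and the best one
wins. Average precision here is the step-interpolated precision-recall sum
with tied scores treated as a single step (every positive in a tied block
receives the block-end precision): deterministic, order-independent, exactly
1 for a perfect ranking and exactly the prevalence for a constant score.

Validation mirrors a three-stage filter:

1. **Capture** — on a withheld test split, mean cryptic phenotype among
   diagnosed cases minus undiagnosed controls, with significance from
   bootstrap resampling (cases and controls resampled independently with
   replacement; percentile 95% CI; one-sided $p = (1 + \#\{\Delta^* \le 0\})
   / (n_{boot}+1)$, Bonferroni-scaled by the number of diseases). The raw
   mean difference is the reported effect; a pooled-SD standardized variant
   sits behind `standardized = TRUE`. One-sided because the filter is
   directional — the trait must be *higher* in cases; the add-one correction
   keeps $p$ off zero.
2. **Replication** — a model fitted on an independent dataset must
   reproduce the elevation when its scores are imputed into the same test
   split.
3. **Consistency** — squared Pearson correlation between the two models'
   scores on the same subjects, with the conventional cutoff $r^2 \ge 0.2$,
   plus a component-match check. Components of independently fitted models
   do not share indices, so "same component" is operationalized as: the
   second model's selected component is the one among its retained
   components most correlated with the first model's selected score.

## The synthetic cohort generator

`generate_cohort()` samples the full causal stack: loadings
($|N(0,1)| + 0.5$, one symptom block per component when the rank exceeds 1,
giving well-separated components), latent severities, additive genetic
shifts on a designated severity component (carrier effect 1.0 latent-SD by
default, attenuated to 0 for annotation-flagged variants, PGS effect 0.2,
PGS-by-carrier interaction 0.15, ~1.4% carriers), covariate effects, Bernoulli
symptom emission (intercept −2, i.e. ~12% baseline symptom prevalence), and
diagnosis as a 99th-percentile threshold on realized severity. Effect sizes
mirror the magnitudes reported for real biobank analyses of this design
(interaction coefficients near 0.15 at ~35,000 subjects with ~500 carriers);
cohort sizes default to what one CPU fits in seconds-to-minutes.

The threshold diagnosis rule builds *diagnosis-level ascertainment bias*
into the cohort: severer subjects — including genetically shifted carriers —
are likelier to be labeled, so genetic modifiers of severity associate with
the diagnosis itself. This is the structure that makes cryptic phenotypes
informative, and it is what the end-to-end tests exercise.

In tests that exercise component *selection* in isolation (without a fitted
model in the loop), estimated latent scores are emulated as the true
severities plus independent Gaussian noise at half the prior SD — roughly
the estimation error observed for well-determined fits — so that selection
is evaluated under realistic score degradation rather than on noiseless
truth.

What the generator does **not** emulate: real ICD/HPO code semantics and
their frequency profile, time-resolved diagnoses, linkage disequilibrium or
SNP-level genotypes (the PGS is drawn directly as a score), relatedness, or
missing data. A green end-to-end test therefore establishes that the
algorithms are correct on data obeying the model's assumptions — not that
any particular clinical dataset obeys them.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods are computed on the logit scale
  ($S\eta - \mathrm{softplus}(\eta)$), stable for large $|\eta|$.
* Quadrature uses 64 Gauss–Hermite nodes per dimension by default
  (node range far beyond ±6 prior SD); doubling the order moves tiny-model
  log-likelihoods by less than $10^{-8}$.
* Ties: average ranks in the inverse-normal transform (Blom offsets,
  $(r - 3/8)/(N + 1/4)$); tied-block averaging in average precision; ties in
  component selection break to the lowest index.
* Degenerate inputs are rejected with named errors: mixed terminologies,
  maps with no usable pairs, datasets without cases, all-flagged carrier
  sets, rank-deficient designs (naming the collinear term), constant
  vectors in `rank_inverse_normal()` and `consistency_r2()` (the latter
  returns `NA` with a warning — an undefined $r^2$, not a zero).
* An all-zero symptom matrix fits to a silent model: maximum risk below
  1%, effective rank 0.
* Stratified splits assign rounding leftovers to the training side, making
  the partition deterministic given the seed.

## Known limitations

* The variational family is mean-field Gaussian; posterior correlations
  between components are not represented, and the amortization gap is
  bounded only empirically (via the quadrature oracle at $L \le 2$).
* ARD pruning with the fixed-point update is aggressive at small sample
  sizes; components supported by few symptoms and weak loadings can be
  removed. `ard = FALSE` disables pruning when the rank is known.
* At low information content (few symptoms per component) the latent-score
  correlation with truth is ceiling-limited — the exact posterior itself
  correlates with the true severities at only ~0.78 for 10 binary symptoms
  per component — so evaluation of recovery quality should target loadings,
  not scores, in that regime.
* Code-frequency filtering criteria for real EHR extracts are accepted as
  user-supplied maps/thresholds (`min_prevalence`), not reproduced.
* Firth logistic and Cox proportional-hazards outcome models are out of
  scope; the simulator's outputs are compatible with the standard
  implementations in `logistf`/`survival`.
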