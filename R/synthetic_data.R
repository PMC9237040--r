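# Fully synthetic EHR-style cohorts with known ground truth.  The simulator
# reproduces the premise the whole package rests on: a disease's severity is
# a continuous latent spectrum; symptoms are noisy Bernoulli emissions of
# that spectrum; clinical diagnosis is an ascertainment-biased threshold on
# severity; and rare-variant carriers / polygenic load shift the latent
# scale itself, not individual symptoms.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort generator. Genetic and covariate
#' effects act additively on the designated latent severity component, so a
#' carrier is shifted along the entire symptom spectrum. Diagnosis labels are
#' a quantile threshold on realized severity (optionally XOR label noise),
#' which builds diagnosis-level ascertainment bias into the cohort: severer
#' subjects — including shifted carriers — are likelier to be labeled.
#'
#' @param N cohort size (default 20000).
#' @param K symptom count (default 20).
#' @param L_true true latent rank (default 1). For `L_true > 1` the symptoms
#'   are split into blocks, one per component, giving well-separated
#'   components.
#' @param loading_shift,loading_sd loadings are drawn as
#'   `|N(0, loading_sd)| + loading_shift` (defaults 0.5 and 1).
#' @param b symptom intercept (default -2, i.e. baseline symptom
#'   probability ~ 12%).
#' @param diagnosis_component which latent component drives diagnosis.
#' @param diagnosis_quantile severity quantile above which a subject is
#'   diagnosed (default 0.99: 1% prevalence).
#' @param label_noise probability of flipping a label (default 0).
#' @param carrier_frac P/LP carrier fraction (default 0.0143, ~500 carriers
#'   at N = 35000).
#' @param carrier_effect additive latent-scale severity shift for unflagged
#'   carriers (default 1).
#' @param flagged_frac fraction of carriers whose variant carries annotation
#'   flags (default 0.3).
#' @param flag_attenuation multiplier on `carrier_effect` for flagged
#'   carriers (default 0: flagged variants behave as annotation noise).
#' @param pgs_effect main polygenic-score effect on severity (default 0.2).
#' @param pgs_carrier_interaction PGS-by-carrier interaction effect
#'   (default 0.15).
#' @param sex_effect,age_effect covariate effects on severity (defaults 0.1
#'   and 0.2, age standardized).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(N = 20000, K = 20, L_true = 1,
                       loading_shift = 0.5, loading_sd = 1, b = -2,
                       diagnosis_component = 1, diagnosis_quantile = 0.99,
                       label_noise = 0, carrier_frac = 0.0143,
                       carrier_effect = 1, flagged_frac = 0.3,
                       flag_attenuation = 0, pgs_effect = 0.2,
                       pgs_carrier_interaction = 0.15,
                       sex_effect = 0.1, age_effect = 0.2, seed = 1L) {
  cfg <- list(N = N, K = K, L_true = L_true, loading_shift = loading_shift,
              loading_sd = loading_sd, b = b,
              diagnosis_component = diagnosis_component,
              diagnosis_quantile = diagnosis_quantile,
              label_noise = label_noise, carrier_frac = carrier_frac,
              carrier_effect = carrier_effect, flagged_frac = flagged_frac,
              flag_attenuation = flag_attenuation, pgs_effect = pgs_effect,
              pgs_carrier_interaction = pgs_carrier_interaction,
              sex_effect = sex_effect, age_effect = age_effect,
              seed = as.integer(seed))
  stopifnot(cfg$N >= 1, cfg$K >= 1, cfg$L_true >= 1,
            cfg$diagnosis_component <= cfg$L_true,
            cfg$diagnosis_quantile > 0, cfg$diagnosis_quantile < 1,
            cfg$label_noise >= 0, cfg$label_noise <= 1,
            cfg$carrier_frac >= 0, cfg$carrier_frac <= 1,
            cfg$flagged_frac >= 0, cfg$flagged_frac <= 1)
  class(cfg) <- "sim_config"
  cfg
}

sim_loadings <- function(cfg, rng) {
  W <- matrix(0, cfg$K, cfg$L_true)
  block <- rep(seq_len(cfg$L_true), length.out = cfg$K)
  draws <- with_rng(rng, abs(stats::rnorm(cfg$K, sd = cfg$loading_sd)) +
                      cfg$loading_shift)
  W[cbind(seq_len(cfg$K), block)] <- draws
  W
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples the full generative stack: loadings and latent severities,
#' genotype and polygenic layers shifting the designated severity component,
#' Bernoulli symptom emission, and quantile-threshold diagnosis labels.
#' Bitwise reproducible from `(config, seed)`.
#'
#' @param cfg a `sim_config`.
#' @param seed overrides `cfg$seed` when given.
#' @return A `cohort_truth`: `Z` (true latent severities), `S` (a
#'   `symptom_matrix`), `labels`, `genotypes` (a `genotype_vector`), `pgs`,
#'   `covariates` (raw data.frame), `model` (the true `latent_model`), and
#'   the `config` echo.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- local_rng(seed)
  N <- cfg$N; L <- cfg$L_true
  W <- sim_loadings(cfg, rng)
  model <- latent_model(W, rep(cfg$b, cfg$K),
                        col_ids = sprintf("HP:%07d", seq_len(cfg$K)))

  carrier <- with_rng(rng, stats::rbinom(N, 1L, cfg$carrier_frac))
  unflagged <- carrier
  nc <- sum(carrier)
  if (nc > 0 && cfg$flagged_frac > 0) {
    flag <- with_rng(rng, stats::rbinom(nc, 1L, cfg$flagged_frac))
    unflagged[carrier == 1] <- 1L - flag
  }
  per_carrier_effect <- cfg$carrier_effect *
    ifelse(unflagged == 1, 1, cfg$flag_attenuation) * carrier
  pgs <- with_rng(rng, stats::rnorm(N))
  sex <- with_rng(rng, stats::rbinom(N, 1L, 0.5))
  age <- with_rng(rng, stats::rnorm(N, 57, 8))
  platform <- with_rng(rng, sample(c("axiom", "bileve"), N, replace = TRUE,
                                   prob = c(0.9, 0.1)))
  pcs <- with_rng(rng, matrix(stats::rnorm(N * 10), N, 10))
  ever_smoked <- with_rng(rng, stats::rbinom(N, 1L, 0.45))
  pack_years <- ever_smoked *
    with_rng(rng, stats::rgamma(N, shape = 2, scale = 10))

  Z <- with_rng(rng, matrix(stats::rnorm(N * L), N, L))
  dc <- cfg$diagnosis_component
  Z[, dc] <- Z[, dc] + per_carrier_effect +
    cfg$pgs_effect * pgs +
    cfg$pgs_carrier_interaction * carrier * pgs +
    cfg$sex_effect * (sex - 0.5) +
    cfg$age_effect * as.numeric(scale(age))

  emit_seed <- with_rng(rng, sample.int(.Machine$integer.max %/% 2, 1))
  samp <- sample_cohort(model, N, seed = emit_seed, Z = Z)
  thr <- stats::quantile(Z[, dc], cfg$diagnosis_quantile, type = 7)
  labels <- as.integer(Z[, dc] > thr)
  if (cfg$label_noise > 0) {
    flips <- with_rng(rng, stats::rbinom(N, 1L, cfg$label_noise))
    labels <- as.integer(xor(labels, flips))
  }
  if (sum(labels) == 0)
    stop("diagnosis rule yielded zero cases; lower diagnosis_quantile")

  row_ids <- sprintf("subj%06d", seq_len(N))
  S <- symptom_matrix(samp$S, row_ids = row_ids, col_ids = model$col_ids,
                      terminology = "HPO", sort = FALSE)
  covariates <- data.frame(subject_id = row_ids, sex = sex, age = age,
                           platform = platform, pcs,
                           ever_smoked = ever_smoked,
                           pack_years = pack_years)
  names(covariates)[5:14] <- paste0("pc", 1:10)
  structure(list(Z = Z, S = S, labels = labels,
                 genotypes = genotype_vector(carrier, unflagged),
                 pgs = pgs, covariates = covariates, model = model,
                 config = cfg, seed = as.integer(seed)),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "<cohort_truth> N=%d, K=%d, L_true=%d, %d cases (%.2f%%), %d carriers\n",
    x$config$N, x$config$K, x$config$L_true, sum(x$labels),
    100 * mean(x$labels), sum(x$genotypes$carrier)))
  invisible(x)
}

#' Write a synthetic cohort as a plain-text fixture set
#'
#' Emits the complete file set the other modules consume: the symptom matrix
#' as MatrixMarket plus sidecars, genotype / covariate / PGS / label TSVs,
#' the true latent severities as TSV, and a `truth.json` carrying the config
#' echo verbatim. Everything round-trips losslessly through
#' [read_fixture()].
#'
#' @param cohort a `cohort_truth`.
#' @param dir target directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_symptom_matrix(cohort$S, dir, "symptoms")
  wt(data.frame(subject_id = cohort$S$row_ids, label = cohort$labels),
     "labels.tsv")
  wt(cbind(subject_id = cohort$S$row_ids, as.data.frame(cohort$genotypes)),
     "genotypes.tsv")
  wt(data.frame(subject_id = cohort$S$row_ids, pgs = cohort$pgs), "pgs.tsv")
  wt(cohort$covariates, "covariates.tsv")
  zt <- as.data.frame(cohort$Z)
  names(zt) <- paste0("z", seq_len(ncol(zt)))
  wt(cbind(subject_id = cohort$S$row_ids, zt), "latent_truth.tsv")
  write_model(cohort$model, file.path(dir, "true_model.json"))
  jsonlite::write_json(list(schema = "cryptophen-fixture/1",
                            config = unclass(cohort$config),
                            seed = cohort$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture set written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return A `cohort_truth` reconstructed from the files.
#' @export
read_fixture <- function(dir) {
  rt <- function(f, ...) utils::read.table(file.path(dir, f), sep = "\t",
                                           header = TRUE, ...)
  S <- read_symptom_matrix(dir, "symptoms")
  labels <- rt("labels.tsv")$label
  g <- rt("genotypes.tsv")
  pgs <- rt("pgs.tsv")$pgs
  covariates <- rt("covariates.tsv", colClasses = c(platform = "character"))
  zt <- rt("latent_truth.tsv")
  Z <- as.matrix(zt[, -1, drop = FALSE])
  dimnames(Z) <- NULL
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  cfg <- do.call(sim_config, truth$config)
  structure(list(Z = Z, S = S, labels = labels,
                 genotypes = genotype_vector(g$carrier, g$unflagged),
                 pgs = pgs, covariates = covariates,
                 model = read_model(file.path(dir, "true_model.json")),
                 config = cfg, seed = as.integer(truth$seed)),
            class = "cohort_truth")
}

#' Closed-form expected symptom prevalences for a model
#'
#' Marginal symptom probabilities under the latent prior,
#' `P(S_j = 1) = E[link(Z . W_j + b_j)]`, by one-dimensional Gauss-Hermite
#' quadrature per symptom (each symptom loads on a linear combination of
#' independent normals, itself normal). Used to check that generated
#' prevalences match theory.
#'
#' @param model a `latent_model`.
#' @param order quadrature order (default 64).
#' @return Numeric K-vector of expected prevalences.
#' @export
expected_prevalence <- function(model, order = 64) {
  gh <- gauss_hermite_normal(order)
  sdj <- sqrt(rowSums(model$W^2))  # Z.W_j ~ N(0, ||W_j||^2)
  vapply(seq_len(model$K), function(j) {
    sum(gh$w * sigmoid(sdj[j] * gh$z + model$b[j]))
  }, numeric(1))
}
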