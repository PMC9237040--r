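# Generative model: binary symptoms emitted from continuous latent
# phenotypes.  Each subject i carries an L-vector Z_i of latent severities
# with independent standard-normal priors; symptom j is Bernoulli with
# probability link(Z_i . W_j + b_j).  The joint factorizes as
# P(S, Z | theta) = P(S | Z, theta) * P(Z), with theta = (W, b).

#' Latent phenotype model
#'
#' The generative parameters of the symptom risk function: a K x L loading
#' matrix `W` (symptom j, component l), a K-vector of intercepts `b`, a
#' monotone link from the real line to (0,1) (logistic by default), and an
#' independent standard-normal prior on each latent component.
#'
#' @param W numeric K x L loading matrix.
#' @param b numeric K intercept vector.
#' @param link link name; only `"logistic"` is implemented.
#' @param prior prior name; only `"normal"` (independent standard normal).
#' @param col_ids optional symptom identifiers (length K) so fitted models can
#'   be matched to matrices by column name.
#' @return An object of class `latent_model`.
#' @export
latent_model <- function(W, b, link = "logistic", prior = "normal",
                         col_ids = rownames(W)) {
  W <- as.matrix(W)
  b <- as.numeric(b)
  if (nrow(W) != length(b)) stop("nrow(W) must equal length(b)")
  link <- match.arg(link, "logistic")
  prior <- match.arg(prior, "normal")
  if (is.null(col_ids) || length(col_ids) == 0) {
    col_ids <- NULL
  } else {
    col_ids <- as.character(col_ids)
    if (length(col_ids) != nrow(W)) stop("col_ids must have length K")
  }
  structure(list(W = W, b = b, link = link, prior = prior,
                 K = nrow(W), L = ncol(W), col_ids = col_ids),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> K=%d symptoms, L=%d components, %s link\n",
              x$K, x$L, x$link))
  invisible(x)
}

sigmoid <- function(x) stats::plogis(x)
# log(1 + exp(x)) without overflow
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Symptom risk function
#'
#' Maps latent phenotype values onto per-symptom Bernoulli probabilities:
#' element (i, j) is `link(sum_l Z[i,l] * W[j,l] + b[j])`, strictly inside
#' (0, 1) for finite inputs.
#'
#' @param model a `latent_model`.
#' @param Z numeric N x L matrix of latent severities.
#' @return N x K matrix of probabilities.
#' @export
symptom_risk <- function(model, Z) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("Z must be finite")
  if (ncol(Z) != model$L)
    stop(sprintf("Z has %d columns but the model has L=%d components",
                 ncol(Z), model$L))
  eta <- Z %*% t(model$W)
  eta <- sweep(eta, 2, model$b, "+")
  sigmoid(eta)
}

#' Ancestral sampling of a synthetic cohort
#'
#' Draws `Z` from the latent prior and emits symptoms via independent
#' Bernoulli draws from the risk matrix, i.e. samples the stated joint
#' `P(S, Z | theta) = P(S | Z, theta) * P(Z)`.
#'
#' @param model a `latent_model`.
#' @param N number of subjects.
#' @param seed integer seed; fixed seed reproduces `(Z, S)` exactly.
#' @param Z optional N x L matrix of latent values to use instead of a prior
#'   draw (e.g. shifted severities from a genotype layer).
#' @return A list with `Z` (N x L) and `S` (N x K binary matrix).
#' @export
sample_cohort <- function(model, N, seed = 1L, Z = NULL) {
  stopifnot(N >= 1)
  rng <- local_rng(seed)
  if (is.null(Z)) {
    Z <- with_rng(rng, matrix(stats::rnorm(N * model$L), N, model$L))
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == N, ncol(Z) == model$L)
  }
  p <- symptom_risk(model, Z)
  S <- with_rng(rng, matrix(stats::rbinom(length(p), 1L, p), N, model$K))
  if (!is.null(model$col_ids)) colnames(S) <- model$col_ids
  list(Z = Z, S = S)
}

# per-subject Bernoulli log-likelihood, computed on the logit scale:
# sum_j S*eta - softplus(eta); stable for large |eta|
bernoulli_loglik_rows <- function(S, eta) {
  rowSums(S * eta - softplus(eta))
}

#' Per-subject joint log-probability
#'
#' `log P(S_i | Z_i, theta) + log P(Z_i)` under the Bernoulli emission model
#' and the standard-normal latent prior.
#'
#' @param model a `latent_model`.
#' @param S binary N x K matrix.
#' @param Z numeric N x L matrix.
#' @return Numeric vector of length N.
#' @export
joint_log_prob <- function(model, S, Z) {
  S <- as.matrix(S); Z <- as.matrix(Z)
  if (!all(S %in% c(0, 1))) stop("S must be binary")
  if (nrow(S) != nrow(Z) || ncol(S) != model$K || ncol(Z) != model$L)
    stop("shape mismatch between S, Z and the model")
  eta <- sweep(Z %*% t(model$W), 2, model$b, "+")
  bernoulli_loglik_rows(S, eta) +
    rowSums(stats::dnorm(Z, log = TRUE))
}

# Gauss-Hermite nodes/weights for E[f(z)], z ~ N(0,1), via Golub-Welsch on
# the Jacobi matrix of the (physicists') Hermite polynomials.
gauss_hermite_normal <- function(n) {
  if (n == 1) return(list(z = 0, w = 1))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- e$vectors[1, ]^2  # sum to 1 after normalization by sqrt(pi)
  ord <- order(x)
  list(z = sqrt(2) * x[ord], w = w[ord])
}

# grid of quadrature points over the L-dim standard normal prior
prior_quadrature_grid <- function(L, order) {
  gh <- gauss_hermite_normal(order)
  if (L == 1) return(list(Z = matrix(gh$z, ncol = 1), logw = log(gh$w)))
  g <- expand.grid(gh$z, gh$z)
  lw <- log(outer(gh$w, gh$w))
  list(Z = as.matrix(g), logw = as.vector(lw))
}

#' Exact marginal log-likelihood by quadrature (low-rank oracle)
#'
#' Numerically integrates the joint over the latent prior,
#' `P(s | theta) = integral P(s, Z | theta) dZ`, using Gauss-Hermite
#' quadrature. Restricted to L <= 2: this is an oracle for validating the
#' variational lower bound, not a general-purpose fitting device.
#'
#' @param model a `latent_model` with `L <= 2`.
#' @param S binary N x K matrix.
#' @param order quadrature order per dimension (default 64; node range covers
#'   well beyond +/- 6 prior SD).
#' @return Numeric vector: per-subject marginal log-likelihood.
#' @export
exact_marginal_loglik <- function(model, S, order = 64) {
  if (model$L > 2) stop("quadrature oracle supports L <= 2 only")
  S <- as.matrix(S)
  if (!all(S %in% c(0, 1))) stop("S must be binary")
  if (ncol(S) != model$K) stop("S has wrong number of columns")
  q <- prior_quadrature_grid(model$L, order)
  eta <- sweep(q$Z %*% t(model$W), 2, model$b, "+")   # G x K
  # log p(s_i | z_g) for all grid points g and subjects i:  G x N
  ll <- eta %*% t(S) - rowSums(softplus(eta))
  ll <- ll + q$logw
  # logsumexp over the grid, per subject
  mx <- apply(ll, 2, max)
  mx + log(colSums(exp(sweep(ll, 2, mx, "-"))))
}

#' Posterior moments by quadrature (low-rank oracle)
#'
#' Exact (to quadrature accuracy) posterior means `E[Z | s, theta]` for each
#' subject, used as the independent oracle against which amortized posterior
#' means are validated.
#'
#' @inheritParams exact_marginal_loglik
#' @return N x L matrix of posterior means.
#' @export
posterior_mean_quadrature <- function(model, S, order = 64) {
  if (model$L > 2) stop("quadrature oracle supports L <= 2 only")
  S <- as.matrix(S)
  q <- prior_quadrature_grid(model$L, order)
  eta <- sweep(q$Z %*% t(model$W), 2, model$b, "+")
  ll <- eta %*% t(S) - rowSums(softplus(eta)) + q$logw  # G x N
  mx <- apply(ll, 2, max)
  w <- exp(sweep(ll, 2, mx, "-"))
  w <- sweep(w, 2, colSums(w), "/")                     # posterior weights
  t(w) %*% q$Z
}

#' Serialize a latent model (and optional encoder) to JSON
#'
#' Versioned schema: a JSON header with `K`, `L`, `link`, `prior` and dense
#' arrays for `W` and `b`; fitted objects additionally carry the encoder
#' parameters and retained-component indices so imputation survives a
#' round-trip.
#'
#' @param model a `latent_model` or `cpa_fit`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "cpa_fit")) {
    obj <- list(schema = "cryptophen-model/1", kind = "fit",
                K = model$model$K, L = model$model$L,
                link = model$model$link, prior = model$model$prior,
                W = model$model$W, b = model$model$b,
                col_ids = model$model$col_ids,
                encoder = lapply(model$encoder, identity),
                retained = model$retained,
                effective_rank = model$effective_rank,
                converged = model$converged, seed = model$seed)
  } else {
    stopifnot(inherits(model, "latent_model"))
    obj <- list(schema = "cryptophen-model/1", kind = "model",
                K = model$K, L = model$L, link = model$link,
                prior = model$prior, W = model$W, b = model$b,
                col_ids = model$col_ids)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON path.
#' @return A `latent_model` or `cpa_fit` depending on what was written.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "cryptophen-model/1"))
    stop("unrecognized model schema: ", x$schema)
  W <- matrix(as.numeric(x$W), x$K, x$L)
  m <- latent_model(W, as.numeric(x$b), x$link, x$prior, col_ids = x$col_ids)
  if (identical(x$kind, "model")) return(m)
  enc <- lapply(x$encoder, function(p) {
    if (is.matrix(p)) p else as.numeric(p)
  })
  structure(list(model = m, encoder = enc,
                 retained = as.integer(x$retained),
                 effective_rank = as.integer(x$effective_rank),
                 converged = isTRUE(x$converged),
                 seed = x$seed, elbo_trace = numeric(0),
                 hyperparameters = list()),
            class = "cpa_fit")
}
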