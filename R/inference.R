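# Amortized variational inference for the Bernoulli latent-factor model.
#
# The variational family is a fully factorized Gaussian per subject,
# q(Z_i) = N(mu(S_i), diag(sigma(S_i)^2)), amortized through a single
# hidden-layer encoder shared across subjects:
#
#   h      = tanh(S W1 + c1)
#   mu     = h Wm + cm
#   sigma  = softplus(h Ws + cs) + floor
#
# The ELBO  E_q[log p(S|Z)] - KL(q || N(0, I))  is maximized by stochastic
# gradient ascent (Adam) with the reparameterization trick; the KL term is
# closed-form.  Unneeded loading columns are removed by automatic-relevance
# (ARD) per-column Gaussian scale hyperparameters on W, updated by fixed
# point between gradient epochs, which drives the loadings of unsupported
# components toward zero ("zeroing out").  Gradients are hand-derived and
# applied with plain matrix algebra; the model sizes this package targets
# (K <= a few dozen symptoms) do not justify a tensor runtime.

inv_softplus <- function(y) log(expm1(y))
SIGMA_FLOOR <- 1e-4

encoder_forward <- function(enc, S) {
  H1 <- tanh(sweep(S %*% enc$W1, 2, enc$c1, "+"))
  mu <- sweep(H1 %*% enc$Wm, 2, enc$cm, "+")
  sraw <- sweep(H1 %*% enc$Ws, 2, enc$cs, "+")
  list(H1 = H1, mu = mu, sraw = sraw,
       sigma = softplus(sraw) + SIGMA_FLOOR)
}

init_params <- function(K, L, hidden, S, rng) {
  pbar <- pmin(pmax(colMeans(S), 1e-4), 1 - 1e-4)
  with_rng(rng, list(
    W  = matrix(stats::rnorm(K * L, sd = 0.1), K, L),
    b  = stats::qlogis(pbar),
    W1 = matrix(stats::rnorm(K * hidden, sd = sqrt(1 / K)), K, hidden),
    c1 = rep(0, hidden),
    Wm = matrix(stats::rnorm(hidden * L, sd = sqrt(1 / hidden)), hidden, L),
    cm = rep(0, L),
    Ws = matrix(stats::rnorm(hidden * L, sd = 0.01), hidden, L),
    cs = rep(inv_softplus(1), L)
  ))
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    par[[nm]] <- par[[nm]] +
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, st = st)
}

# one minibatch: ELBO value (sum over batch) and ascent gradients
vi_batch <- function(par, Sb, eps_draw, alpha, batch_weight) {
  B <- nrow(Sb); L <- ncol(par$W)
  enc <- list(W1 = par$W1, c1 = par$c1, Wm = par$Wm, cm = par$cm,
              Ws = par$Ws, cs = par$cs)
  f <- encoder_forward(enc, Sb)
  Z <- f$mu + f$sigma * eps_draw
  eta <- sweep(Z %*% t(par$W), 2, par$b, "+")
  P <- sigmoid(eta)
  recon <- sum(Sb * eta - softplus(eta))
  kl <- 0.5 * sum(f$mu^2 + f$sigma^2 - 2 * log(f$sigma) - 1)
  elbo <- recon - kl

  dEta <- Sb - P                                  # d recon / d eta
  gW <- t(dEta) %*% Z - batch_weight * sweep(par$W, 2, alpha, "*")
  gb <- colSums(dEta)
  dZ <- dEta %*% par$W
  dMu <- dZ - f$mu                                # KL grad wrt mu is -mu
  dSigma <- dZ * eps_draw - (f$sigma - 1 / f$sigma)
  dSraw <- dSigma * sigmoid(f$sraw)               # softplus derivative
  dH1 <- dMu %*% t(par$Wm) + dSraw %*% t(par$Ws)
  dPre <- dH1 * (1 - f$H1^2)
  grad <- list(
    W = gW, b = gb,
    W1 = t(Sb) %*% dPre, c1 = colSums(dPre),
    Wm = t(f$H1) %*% dMu, cm = colSums(dMu),
    Ws = t(f$H1) %*% dSraw, cs = colSums(dSraw)
  )
  list(elbo = elbo, grad = grad)
}

vi_run_once <- function(S, L, hidden, hp, seed) {
  N <- nrow(S); K <- ncol(S)
  rng <- local_rng(seed)
  par <- init_params(K, L, hidden, S, rng)
  st <- adam_init(par)
  alpha <- rep(hp$alpha0, L)
  trace <- numeric(0)
  converged <- FALSE
  bs <- min(hp$batch_size, N)
  run_epoch <- function(lr) {
    ord <- sample_rng(rng, seq_len(N), N)
    starts <- seq(1, N, by = bs)
    acc <- 0
    eps_all <- with_rng(rng, matrix(stats::rnorm(N * L), N, L))
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1, N)]
      Sb <- S[idx, , drop = FALSE]
      res <- vi_batch(par, Sb, eps_all[idx, , drop = FALSE], alpha,
                      batch_weight = length(idx) / N)
      upd <- adam_step(par, res$grad, st, lr)
      par <<- upd$par; st <<- upd$st
      acc <- acc + res$elbo
    }
    acc / N  # per-subject MC ELBO for this epoch
  }
  update_alpha <- function() {
    if (hp$ard) {
      nrm2 <- colSums(par$W^2)
      alpha <<- pmin(K / (nrm2 + 1e-8), hp$alpha_max)
    }
  }
  for (epoch in seq_len(hp$max_epochs)) {
    trace <- c(trace, run_epoch(hp$lr))
    if (epoch >= hp$ard_warmup) update_alpha()
    w <- hp$patience
    if (epoch >= max(2 * w, hp$min_epochs)) {
      recent <- mean(trace[(epoch - w + 1):epoch])
      prev <- mean(trace[(epoch - 2 * w + 1):(epoch - w)])
      if (abs(recent - prev) < hp$tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
  }
  # polish: Adam's stationary noise floor scales with the step size, so a
  # short low-rate phase collapses pruned columns and sharpens the encoder
  for (epoch in seq_len(hp$polish_epochs)) {
    trace <- c(trace, run_epoch(hp$lr * 0.1))
    update_alpha()
  }
  list(par = par, trace = trace, converged = converged, alpha = alpha)
}

#' Fit the latent phenotype model by amortized variational inference
#'
#' Maximizes a reparameterized Monte-Carlo evidence lower bound (ELBO) on the
#' marginal likelihood of a binary symptom matrix by minibatched stochastic
#' gradient ascent, jointly over the symptom risk parameters (W, b) and a
#' shared amortization encoder. A sparsity-inducing per-column ARD prior on W
#' prunes unneeded latent components; the count of surviving columns is the
#' model's effective rank.
#'
#' Convergence is declared when the epoch-averaged ELBO improves by less than
#' `tol` (relatively) across two consecutive `patience`-epoch windows. If the
#' run does not converge, up to `restarts` fresh-seed restarts are attempted;
#' the best run by final ELBO is returned with `converged = FALSE` if none
#' converged — non-convergence is a reportable outcome, not an error.
#'
#' @param S a `symptom_matrix`, `labeled_dataset`, or plain binary matrix.
#' @param L number of latent components to initialize (default 10; the ARD
#'   mechanism removes unsupported ones).
#' @param hidden encoder hidden-layer width, default `max(2L, 16)`.
#' @param seed integer seed; identical seed + data + hyperparameters
#'   reproduce the fit to floating-point noise.
#' @param batch_size minibatch size (default 512).
#' @param lr Adam step size (default 0.01).
#' @param max_epochs maximum training epochs (default 500).
#' @param tol relative ELBO tolerance for convergence (default 1e-4).
#' @param patience window width (epochs) for the convergence check.
#' @param min_epochs do not test convergence before this epoch.
#' @param ard enable ARD column pruning (default TRUE).
#' @param ard_warmup first epoch at which ARD scales update.
#' @param alpha0 initial per-column prior precision on W.
#' @param alpha_max precision cap for pruned columns.
#' @param polish_epochs epochs of a final low-step-size polish phase.
#' @param restarts fresh-seed restarts permitted on non-convergence.
#' @param rank_rel_threshold relative column-norm threshold passed to
#'   [effective_rank()].
#' @return A `cpa_fit`: fitted `latent_model`, encoder parameters, per-epoch
#'   `elbo_trace`, `effective_rank` and retained component indices,
#'   `converged` flag, seed and hyperparameter record.
#' @export
cpa_fit <- function(S, L = 10, hidden = max(2 * L, 16), seed = 1L,
                    batch_size = 512, lr = 0.01, max_epochs = 500,
                    tol = 1e-4, patience = 10, min_epochs = 60,
                    ard = TRUE, ard_warmup = 25, alpha0 = 0.01,
                    alpha_max = 1e6, polish_epochs = 15, restarts = 3,
                    rank_rel_threshold = 0.01) {
  col_ids <- NULL
  if (inherits(S, "labeled_dataset")) S <- S$matrix
  if (inherits(S, "symptom_matrix")) {
    col_ids <- S$col_ids
    S <- as.matrix(S$values)
  } else {
    S <- as.matrix(S)
    col_ids <- colnames(S)
  }
  if (ncol(S) == 0) stop("K = 0: no symptom columns")
  if (!all(S %in% c(0, 1))) stop("S must be binary")
  stopifnot(L >= 1)
  hp <- list(batch_size = batch_size, lr = lr, max_epochs = max_epochs,
             tol = tol, patience = patience, min_epochs = min_epochs,
             ard = ard, ard_warmup = ard_warmup, alpha0 = alpha0,
             alpha_max = alpha_max, polish_epochs = polish_epochs)

  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    run <- vi_run_once(S, L, hidden, hp, seed = seed + 7919L * (r - 1L))
    if (is.null(best) ||
        mean(utils::tail(run$trace, hp$patience)) >
          mean(utils::tail(best$trace, hp$patience))) best <- run
    if (run$converged) { best <- run; break }
  }
  par <- best$par
  model <- latent_model(par$W, par$b, col_ids = col_ids)
  encoder <- list(W1 = par$W1, c1 = par$c1, Wm = par$Wm, cm = par$cm,
                  Ws = par$Ws, cs = par$cs)
  fit <- structure(list(model = model, encoder = encoder,
                        elbo_trace = best$trace,
                        converged = best$converged, seed = seed,
                        hyperparameters = c(hp, list(L = L, hidden = hidden,
                                                     restarts = restarts))),
                   class = "cpa_fit")
  fit <- orient_components(fit)
  fit$retained <- retained_components(fit$model$W, rank_rel_threshold)
  fit$effective_rank <- length(fit$retained)
  fit
}

# sign convention: each component's loading sum is positive, so larger
# latent scores always mean more symptoms ("severity" points up)
orient_components <- function(fit) {
  s <- ifelse(colSums(fit$model$W) < 0, -1, 1)
  fit$model$W <- sweep(fit$model$W, 2, s, "*")
  fit$encoder$Wm <- sweep(fit$encoder$Wm, 2, s, "*")
  fit$encoder$cm <- fit$encoder$cm * s
  fit
}

retained_components <- function(W, rel_threshold = 0.01, abs_floor = 0.05) {
  nrm <- sqrt(colSums(W^2))
  if (!length(nrm) || max(nrm) <= abs_floor) return(integer(0))
  which(nrm >= pmax(rel_threshold * max(nrm), abs_floor))
}

#' @export
print.cpa_fit <- function(x, ...) {
  cat(sprintf(
    "<cpa_fit> K=%d, L=%d (effective rank %d), %d epochs, converged=%s\n",
    x$model$K, x$model$L, x$effective_rank, length(x$elbo_trace),
    x$converged))
  invisible(x)
}

#' Effective rank of a fitted model
#'
#' Counts the loading columns whose Euclidean norm is at least
#' `rel_threshold` times the largest column norm (and above a small absolute
#' floor, so an all-pruned model reports rank 0). The retained component
#' indices are attached as the `retained` attribute.
#'
#' @param fit a `cpa_fit`, `latent_model`, or loading matrix.
#' @param rel_threshold relative column-norm cutoff, default 0.01.
#' @param abs_floor absolute column-norm floor, default 0.05.
#' @return Integer effective rank, with attribute `retained`.
#' @export
effective_rank <- function(fit, rel_threshold = 0.01, abs_floor = 0.05) {
  W <- if (inherits(fit, "cpa_fit")) fit$model$W
       else if (inherits(fit, "latent_model")) fit$W
       else as.matrix(fit)
  r <- retained_components(W, rel_threshold, abs_floor)
  structure(length(r), retained = r)
}

#' Monte-Carlo ELBO estimate
#'
#' Evaluates the evidence lower bound for a given model and encoder on a
#' symptom matrix, with `n_mc` reparameterized samples. The KL term is exact;
#' only the reconstruction expectation is sampled. Returns the estimate and
#' its Monte-Carlo standard error so bound checks against the quadrature
#' marginal can account for sampling noise.
#'
#' @param S binary matrix or `symptom_matrix`.
#' @param model a `latent_model`.
#' @param encoder encoder parameter list (as in a `cpa_fit`).
#' @param n_mc number of Monte-Carlo samples (>= 1).
#' @param seed integer seed.
#' @return List with `estimate` (total over subjects), `se` (MC standard
#'   error of the total), and `per_subject` mean.
#' @export
elbo <- function(S, model, encoder, n_mc = 100, seed = 1L) {
  if (inherits(S, "symptom_matrix")) S <- as.matrix(S$values)
  S <- as.matrix(S)
  if (n_mc < 1) stop("n_mc must be >= 1")
  N <- nrow(S); L <- model$L
  f <- encoder_forward(encoder, S)
  kl <- 0.5 * sum(f$mu^2 + f$sigma^2 - 2 * log(f$sigma) - 1)
  rng <- local_rng(seed)
  draws <- numeric(n_mc)
  for (m in seq_len(n_mc)) {
    epsd <- with_rng(rng, matrix(stats::rnorm(N * L), N, L))
    Z <- f$mu + f$sigma * epsd
    eta <- sweep(Z %*% t(model$W), 2, model$b, "+")
    draws[m] <- sum(S * eta - softplus(eta))
  }
  est <- mean(draws) - kl
  se <- if (n_mc > 1) stats::sd(draws) / sqrt(n_mc) else NA_real_
  list(estimate = est, se = se, per_subject = est / N)
}

#' Impute latent phenotypes into a (new) symptom matrix
#'
#' Applies the fitted amortization encoder to each row and returns the
#' variational posterior means restricted to the retained components.
#' Deterministic: subjects with identical symptom vectors receive identical
#' estimates. When both the fit and the matrix carry column identifiers the
#' columns are order-normalized by identifier; a set mismatch is an error
#' naming the missing/extra symptoms.
#'
#' @param S_new a `symptom_matrix` (or binary matrix with K columns).
#' @param fit a `cpa_fit`.
#' @param components which components to return: `"retained"` (default) or
#'   `"all"`.
#' @return N x L_eff matrix of posterior-mean latent scores, with retained
#'   component indices as column names.
#' @export
infer_latent <- function(S_new, fit, components = c("retained", "all")) {
  components <- match.arg(components)
  row_ids <- NULL
  if (inherits(S_new, "labeled_dataset")) S_new <- S_new$matrix
  if (inherits(S_new, "symptom_matrix")) {
    row_ids <- S_new$row_ids
    M <- as.matrix(S_new$values)
  } else {
    M <- as.matrix(S_new)
    row_ids <- rownames(M)
  }
  ids <- fit$model$col_ids
  if (!is.null(ids) && !is.null(colnames(M))) {
    missing <- setdiff(ids, colnames(M))
    extra <- setdiff(colnames(M), ids)
    if (length(missing) || length(extra))
      stop("symptom columns do not match the fitted model; missing: [",
           paste(missing, collapse = ", "), "]; extra: [",
           paste(extra, collapse = ", "), "]")
    M <- M[, ids, drop = FALSE]
  } else if (ncol(M) != fit$model$K) {
    stop(sprintf("matrix has %d columns; the fitted model expects %d",
                 ncol(M), fit$model$K))
  }
  mu <- encoder_forward(fit$encoder, M)$mu
  keep <- if (components == "retained") fit$retained else seq_len(fit$model$L)
  out <- mu[, keep, drop = FALSE]
  if (length(keep)) colnames(out) <- paste0("component_", keep)
  if (!is.null(row_ids) && length(keep)) rownames(out) <- row_ids
  out
}
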