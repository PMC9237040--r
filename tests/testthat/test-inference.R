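test_that("effective rank follows the relative-norm rule", {
  expect_equal(as.integer(effective_rank(matrix(0, 5, 3))), 0L)
  W1 <- cbind(c(0, 0, 2), 0, 0)
  expect_equal(as.integer(effective_rank(W1)), 1L)
  expect_equal(attr(effective_rank(W1), "retained"), 1L)
  # norms (10, 5, 0.01): cutoff = rel * max, so 2 at both 0.01 and 0.1
  W <- rbind(c(10, 5, 0.01))
  expect_equal(as.integer(effective_rank(W, rel_threshold = 0.01)), 2L)
  expect_equal(as.integer(effective_rank(W, rel_threshold = 0.1)), 2L)
  expect_equal(as.integer(effective_rank(W, rel_threshold = 1e-4,
                                         abs_floor = 0)), 3L)
})

test_that("single-column fit recovers the Bernoulli marginal MLE", {
  set.seed(5)
  p_emp <- 0.31
  S <- matrix(rbinom(4000, 1, p_emp), ncol = 1)
  fit <- cpa_fit(S, L = 1, seed = 2, batch_size = 256, max_epochs = 150,
                 restarts = 1)
  p_fit <- expected_prevalence(fit$model)
  expect_lt(abs(p_fit - mean(S)), 0.02)
})

test_that("all-zero matrix yields a silent model with rank 0", {
  S <- matrix(0L, 400, 3)
  fit <- cpa_fit(S, L = 2, seed = 1, batch_size = 128, restarts = 1)
  expect_equal(fit$effective_rank, 0L)
  expect_error(select_cryptic(infer_latent(S, fit), rep(0, 400)),
               "no retained components")
  risk <- symptom_risk(fit$model, matrix(0, 1, 2))
  expect_lt(max(risk), 0.01)
})

test_that("fits are deterministic given seed, data and hyperparameters", {
  m <- random_small_model(K = 4, L = 1, seed = 3)
  co <- sample_cohort(m, 300, seed = 4)
  f1 <- cpa_fit(co$S, L = 1, seed = 11, batch_size = 128, max_epochs = 80,
                restarts = 1)
  f2 <- cpa_fit(co$S, L = 1, seed = 11, batch_size = 128, max_epochs = 80,
                restarts = 1)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$encoder$W1, f2$encoder$W1)
})

test_that("ELBO is exact when the encoder is the true posterior (W = 0)", {
  b <- c(-0.8, 0.5)
  m0 <- latent_model(matrix(0, 2, 1), b)
  S <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
  # encoder emitting mu = 0, sigma = 1: exactly the prior, which is the
  # true posterior when W = 0, so the bound is tight sample-by-sample
  enc <- list(W1 = matrix(0, 2, 4), c1 = rep(0, 4),
              Wm = matrix(0, 4, 1), cm = 0,
              Ws = matrix(0, 4, 1), cs = log(expm1(1 - 1e-4)))
  got <- elbo(S, m0, enc, n_mc = 3, seed = 1)
  expect_equal(got$estimate, sum(exact_marginal_loglik(m0, S)),
               tolerance = 1e-9)
  expect_error(elbo(S, m0, enc, n_mc = 0), "n_mc")
})

test_that("degrading the encoder scale strictly decreases the ELBO", {
  m <- random_small_model(K = 4, L = 1, seed = 6)
  co <- sample_cohort(m, 400, seed = 7)
  fit <- cpa_fit(co$S, L = 1, seed = 3, batch_size = 128, restarts = 1)
  good <- elbo(co$S, fit$model, fit$encoder, n_mc = 200, seed = 42)
  bad_enc <- fit$encoder
  bad_enc$cs <- bad_enc$cs + log(10)  # roughly x10 on the scale
  bad <- elbo(co$S, fit$model, bad_enc, n_mc = 200, seed = 42)
  expect_lt(bad$estimate, good$estimate)
})

test_that("ELBO stays below the quadrature marginal (bound property)", {
  for (i in 1:4) {
    L <- 1 + i %% 2
    m <- random_small_model(K = 5, L = L, seed = 50 + i)
    co <- sample_cohort(m, 300, seed = i)
    fit <- cpa_fit(co$S, L = L, seed = i, batch_size = 128, ard = FALSE,
                   restarts = 1)
    ex <- sum(exact_marginal_loglik(fit$model, co$S))
    el <- elbo(co$S, fit$model, fit$encoder, n_mc = 100, seed = 500 + i)
    expect_lt(el$estimate, ex + 3 * el$se)
  }
})

test_that("amortized posterior means track the quadrature posterior", {
  m <- random_small_model(K = 6, L = 1, seed = 70)
  co <- sample_cohort(m, 500, seed = 71)
  fit <- cpa_fit(co$S, L = 1, seed = 5, batch_size = 128, ard = FALSE,
                 restarts = 1)
  mu <- infer_latent(co$S, fit, components = "all")
  pm <- posterior_mean_quadrature(fit$model, co$S)
  expect_gte(abs(stats::cor(mu[, 1], pm[, 1])), 0.99)
})

test_that("infer_latent is amortized, order-normalized, and strict", {
  set.seed(9)
  S <- matrix(rbinom(200 * 4, 1, 0.3), 200, 4,
              dimnames = list(NULL, paste0("H", 1:4)))
  S[2, ] <- S[1, ]  # two identical subjects
  sm <- symptom_matrix(S, row_ids = sprintf("r%03d", 1:200),
                       terminology = "HPO")
  fit <- cpa_fit(sm, L = 2, seed = 2, batch_size = 128, max_epochs = 80,
                 restarts = 1)
  Zh <- infer_latent(sm, fit)
  i1 <- which(sm$row_ids == "r001"); i2 <- which(sm$row_ids == "r002")
  expect_identical(Zh[i1, ], Zh[i2, ])
  # reordering columns by identifier changes nothing
  perm <- symptom_matrix(sm$values[, c(3, 1, 4, 2)],
                         terminology = "HPO", sort = FALSE)
  expect_equal(unname(infer_latent(perm, fit)), unname(Zh))
  # mismatched columns are named in the error
  bad <- symptom_matrix(sm$values[, 1:3], terminology = "HPO", sort = FALSE)
  expect_error(infer_latent(bad, fit), "H4")
})

test_that("fitted models round-trip through JSON with scores intact", {
  m <- random_small_model(K = 4, L = 1, seed = 15)
  co <- sample_cohort(m, 300, seed = 16)
  sm <- symptom_matrix(co$S, row_ids = sprintf("r%03d", 1:300),
                       col_ids = paste0("H", 1:4), terminology = "HPO")
  fit <- cpa_fit(sm, L = 2, seed = 8, batch_size = 128, max_epochs = 80,
                 restarts = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  fit2 <- read_model(path)
  expect_equal(unname(fit2$model$W), unname(fit$model$W), tolerance = 1e-12)
  expect_equal(infer_latent(sm, fit2), infer_latent(sm, fit),
               tolerance = 1e-12)
})

test_that("non-binary or empty input is rejected", {
  expect_error(cpa_fit(matrix(2, 5, 2)), "binary")
  expect_error(cpa_fit(matrix(numeric(0), 5, 0)), "K = 0")
})
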