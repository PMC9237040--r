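test_that("rank inverse normal uses Blom offsets and respects ties", {
  # closed-form quantile evaluation at N = 3
  x <- c(10, 2, 7)
  expect_equal(rank_inverse_normal(x),
               qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4)))
  # monotone on strictly increasing input
  y <- sort(rnorm(50))
  expect_true(all(diff(rank_inverse_normal(y)) > 0))
  # ties share average ranks, hence equal outputs
  z <- rank_inverse_normal(c(1, 5, 5, 9))
  expect_equal(z[2], z[3])
  expect_lt(abs(mean(rank_inverse_normal(rnorm(101)))), 1e-10)
  expect_error(rank_inverse_normal(rep(2, 5)), "constant")
  expect_error(rank_inverse_normal(1), "at least 2")
})

test_that("OLS matches the closed-form normal-equation solution", {
  set.seed(33)
  n <- 60
  g <- genotype_vector(rbinom(n, 1, 0.3))
  cov <- covariate_table(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 5),
                         pcs = matrix(rnorm(n * 2), n, 2))
  cp <- rnorm(n)
  est <- fit_carrier_effect(cp, g, cov)
  # independent oracle: solve the normal equations by hand
  X <- cbind(1, g$carrier, cov$sex, cov$age, cov$pc1, cov$pc2)
  beta <- solve(t(X) %*% X, t(X) %*% cp)
  resid <- cp - X %*% beta
  s2 <- sum(resid^2) / (n - ncol(X))
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  p <- 2 * pt(abs(beta / se), df = n - ncol(X), lower.tail = FALSE)
  expect_equal(est$beta, as.vector(beta), tolerance = 1e-10)
  expect_equal(est$se, se, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(est$p, as.vector(p), tolerance = 1e-10)
})

test_that("degenerate carrier designs are rejected by name", {
  cp <- rnorm(20)
  expect_error(fit_carrier_effect(cp, rep(0L, 20)), "no carriers")
  # carrier == unflagged for everyone: interaction collinear with carrier
  g <- genotype_vector(rep(c(0L, 1L), 10))
  expect_error(fit_flag_decomposition(cp, g), "unflagged")
})

test_that("cp identical to G gives beta 1 with zero residual", {
  g <- rep(c(0L, 1L), each = 25)
  est <- suppressWarnings(fit_carrier_effect(as.numeric(g), genotype_vector(g)))
  expect_equal(effect_term(est, "carrier")$beta, 1, tolerance = 1e-12)
  expect_lt(sum(residuals(attr(est, "fit"))^2), 1e-20)
})

test_that("flag decomposition recovers both effects and nests the marginal", {
  set.seed(34)
  n <- 5000
  carrier <- rbinom(n, 1, 0.1)
  unflag <- carrier * rbinom(n, 1, 0.6)
  g <- genotype_vector(carrier, unflag)
  cp <- 0 * carrier + 0.8 * unflag + rnorm(n)
  est <- fit_flag_decomposition(cp, g)
  b_base <- effect_term(est, "carrier")
  b_unfl <- effect_term(est, "carrier_unflagged")
  expect_lt(abs(b_base$beta - 0), 2 * b_base$se)
  expect_lt(abs(b_unfl$beta - 0.8), 2 * b_unfl$se)
  # algebraic identity: marginal effect = baseline + frac_unflagged * increment
  marg <- effect_term(fit_carrier_effect(cp, g), "carrier")$beta
  frac <- sum(unflag) / sum(carrier)
  expect_equal(marg, b_base$beta + frac * b_unfl$beta, tolerance = 1e-10)
})

test_that("carrier effect is recovered under covariate confounding", {
  set.seed(35)
  n <- 5000
  g <- genotype_vector(rbinom(n, 1, 0.05))
  sex <- rbinom(n, 1, 0.5); age <- rnorm(n, 55, 8)
  cov <- covariate_table(sex, age)
  cp <- 0.5 * g$carrier + 0.2 * sex + 0.1 * rank_inverse_normal(age) + rnorm(n)
  est <- effect_term(fit_carrier_effect(cp, g, cov), "carrier")
  expect_lt(abs(est$beta - 0.5), 3 * est$se)
})

test_that("an orthogonal covariate leaves the carrier estimate unchanged", {
  n <- 40
  g <- genotype_vector(rep(c(0L, 1L), each = n / 2))
  set.seed(36)
  cp <- rnorm(n)
  # residualize against span{1, G}: exactly orthogonal covariates
  ortho1 <- residuals(lm(rnorm(n) ~ g$carrier))
  ortho2 <- residuals(lm(rnorm(n) ~ g$carrier))
  b1 <- effect_term(fit_carrier_effect(cp, g), "carrier")$beta
  cov <- covariate_table(sex = ortho1, age = ortho2, transform_age = FALSE)
  b2 <- effect_term(fit_carrier_effect(cp, g, cov), "carrier")$beta
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("PGS interaction model recovers effects and rejects degeneracy", {
  set.seed(37)
  n <- 8000
  carrier <- rbinom(n, 1, 0.05)
  pgs <- rnorm(n)
  cp <- 0.3 * pgs + 0.8 * carrier + 0.25 * carrier * pgs + rnorm(n)
  est <- fit_pgs_interaction(cp, genotype_vector(carrier), pgs)
  ia <- effect_term(est, "pgs_x_carrier")
  expect_lt(abs(ia$beta - 0.25), 3 * ia$se)
  expect_error(fit_pgs_interaction(cp, rep(0L, n), pgs), "no carriers")
  expect_error(fit_pgs_interaction(cp, genotype_vector(carrier), rep(1, n)),
               "vary")
  expect_error(fit_pgs_interaction(cp, genotype_vector(carrier), pgs,
                                   smoking_interaction = TRUE), "smoking")
})

test_that("smoking-by-genotype interaction terms enter when requested", {
  set.seed(38)
  n <- 4000
  carrier <- rbinom(n, 1, 0.1)
  pgs <- rnorm(n)
  smoke <- rgamma(n, 2, 0.2)
  cov <- covariate_table(sex = rbinom(n, 1, 0.5), age = rnorm(n, 55, 8),
                         smoking = smoke)
  cp <- 0.5 * carrier + 0.02 * smoke + 0.03 * smoke * carrier + rnorm(n)
  est <- fit_pgs_interaction(cp, genotype_vector(carrier), pgs, cov,
                             smoking_interaction = TRUE)
  expect_true("smoking_x_carrier" %in% est$term)
  sx <- effect_term(est, "smoking_x_carrier")
  expect_lt(abs(sx$beta - 0.03), 3 * sx$se)
})
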