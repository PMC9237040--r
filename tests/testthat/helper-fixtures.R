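# Fixtures are built in code; nothing on disk.

# a tiny 2x2 record set: {(A,X),(A,X),(B,Y),(A,Y)}
tiny_records <- function(terminology = "ICD10CM") {
  coded_records(c("A", "A", "B", "A"), c("X", "X", "Y", "Y"), terminology)
}

# small random latent model with loadings strong enough that every
# component is identifiable
random_small_model <- function(K, L, seed, b_mean = -1) {
  set.seed(seed)
  W <- matrix(sample(c(-1, 1), K * L, replace = TRUE) *
                (0.5 + abs(stats::rnorm(K * L))), K, L)
  latent_model(W, stats::rnorm(K, b_mean, 0.7))
}

# labeled dataset with n0 controls / n1 cases and pure-noise symptoms
noise_labeled_dataset <- function(n0, n1, K = 4, seed = 1) {
  set.seed(seed)
  n <- n0 + n1
  S <- matrix(stats::rbinom(n * K, 1, 0.3), n, K,
              dimnames = list(sprintf("s%04d", 1:n), paste0("c", 1:K)))
  labeled_dataset(symptom_matrix(S, terminology = "HPO"),
                  c(rep(0, n0), rep(1, n1)))
}

# greedy sign/permutation alignment: best |cor| fitted column per true column
aligned_cors <- function(true_mat, fit_mat) {
  cc <- abs(stats::cor(true_mat, fit_mat))
  apply(cc, 1, max)
}
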