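# Regression-based genetic validation of cryptic phenotypes: rare-variant
# carrier effects, annotation-flag decomposition, and polygenic-score
# interaction models, all ordinary least squares with two-sided T-tests.

#' Rank-based inverse normal transform
#'
#' Maps ranks through the standard normal quantile function with the Blom
#' offset convention, `qnorm((r - 3/8) / (N + 1/4))`; used to remove skew
#' from age (and any other continuous covariate) before regression. Ties get
#' average ranks, hence equal transformed values. Monotone; mean ~ 0.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Transformed vector of the same length.
#' @export
rank_inverse_normal <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (length(unique(x)) == 1) stop("constant vector cannot be rank-transformed")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Genotype vector for rare-variant analyses
#'
#' Carrier status plus an "unflagged" indicator meaningful only among
#' carriers: unflagged carriers hold a pathogenic/likely-pathogenic variant
#' without annotation caveats; flagged carriers hold one with weaker
#' evidence. `unflagged == 1` implies `carrier == 1`.
#'
#' @param carrier binary vector of P/LP carrier status.
#' @param unflagged binary vector; defaults to `carrier` (all carriers
#'   unflagged).
#' @return A `genotype_vector` data.frame.
#' @export
genotype_vector <- function(carrier, unflagged = carrier) {
  carrier <- as.integer(carrier); unflagged <- as.integer(unflagged)
  stopifnot(length(carrier) == length(unflagged),
            all(carrier %in% 0:1), all(unflagged %in% 0:1))
  if (any(unflagged == 1 & carrier == 0))
    stop("unflagged == 1 requires carrier == 1")
  structure(data.frame(carrier = carrier, unflagged = unflagged),
            class = c("genotype_vector", "data.frame"))
}

#' Covariate table for validation regressions
#'
#' Standard covariate set: sex, age (inverse rank-transformed by default),
#' genotyping platform, the leading genetic principal components, and an
#' optional smoking measure (pack-years or ever-smoked, set per disease).
#'
#' @param sex binary vector.
#' @param age numeric vector (years).
#' @param platform optional factor/character of array platform.
#' @param pcs optional numeric matrix of principal components (e.g. 10 cols).
#' @param smoking optional numeric (pack-years) or binary (ever-smoked).
#' @param transform_age apply [rank_inverse_normal()] to age (default TRUE,
#'   the convention used throughout).
#' @return A `covariate_table` data.frame (complete cases only; excluded
#'   row count attached as attribute `n_excluded`).
#' @export
covariate_table <- function(sex, age, platform = NULL, pcs = NULL,
                            smoking = NULL, transform_age = TRUE) {
  n <- length(sex)
  tab <- data.frame(sex = as.numeric(sex),
                    age = if (transform_age) rank_inverse_normal(age)
                          else as.numeric(age))
  if (!is.null(platform)) tab$platform <- factor(platform)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
    tab <- cbind(tab, pcs)
  }
  if (!is.null(smoking)) tab$smoking <- as.numeric(smoking)
  cc <- stats::complete.cases(tab)
  if (!all(cc))
    message(sprintf("covariate_table: excluding %d incomplete case(s)",
                    sum(!cc)))
  out <- tab[cc, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!cc)
  attr(out, "kept") <- which(cc)
  class(out) <- c("covariate_table", "data.frame")
  out
}

# shared OLS core: builds the frame, checks rank, returns term/beta/se/p
ols_effects <- function(df, formula) {
  mm <- stats::model.matrix(formula, df)
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(formula, data = df)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  class(out) <- c("effect_estimates", "data.frame")
  out
}

covariate_terms <- function(cov) {
  if (is.null(cov)) character(0) else setdiff(colnames(cov), character(0))
}

assemble_frame <- function(cp, extra, cov) {
  df <- data.frame(cp = cp, extra, check.names = FALSE)
  if (!is.null(cov)) {
    kept <- attr(cov, "kept")
    if (!is.null(kept) && length(kept) < nrow(df)) {
      df <- df[kept, , drop = FALSE]
    } else if (nrow(cov) != nrow(df)) {
      stop("covariate table not aligned to the cohort")
    }
    df <- cbind(df, as.data.frame(cov))
  }
  df
}

#' Average carrier effect on the cryptic phenotype
#'
#' Fits `CP = b0 + b_carrier * G + a * X` by ordinary least squares, where G
#' is pathogenic/likely-pathogenic carrier status and X the covariates, and
#' tests each parameter with a two-sided T-test.
#'
#' @param cp numeric cryptic phenotype scores.
#' @param g a `genotype_vector` (or binary carrier vector).
#' @param cov optional `covariate_table`.
#' @return An `effect_estimates` data.frame: term, beta, se, t, p.
#' @export
fit_carrier_effect <- function(cp, g, cov = NULL) {
  carrier <- if (inherits(g, "genotype_vector")) g$carrier else as.integer(g)
  stopifnot(length(cp) == length(carrier))
  if (sum(carrier) == 0) stop("no carriers: carrier term is degenerate")
  df <- assemble_frame(cp, data.frame(carrier = carrier), cov)
  ols_effects(df, stats::reformulate(setdiff(names(df), "cp"), "cp"))
}

#' Decompose carrier effects by annotation-flag status
#'
#' Fits `CP = b0 + b_carrier * G + b_unflagged * G * U + a * X`, splitting
#' the P/LP contribution into a baseline effect shared by all carriers and
#' an increment for carriers of unflagged (higher-confidence) variants.
#'
#' @inheritParams fit_carrier_effect
#' @return An `effect_estimates` data.frame; the `carrier_unflagged` term is
#'   the unflagged increment.
#' @export
fit_flag_decomposition <- function(cp, g, cov = NULL) {
  stopifnot(inherits(g, "genotype_vector"), length(cp) == nrow(g))
  gu <- g$carrier * g$unflagged
  n_flagged <- sum(g$carrier == 1 & g$unflagged == 0)
  n_unflagged <- sum(gu)
  if (n_flagged == 0 || n_unflagged == 0)
    stop("flag decomposition needs both flagged and unflagged carriers ",
         sprintf("(flagged: %d, unflagged: %d)", n_flagged, n_unflagged))
  df <- assemble_frame(cp, data.frame(carrier = g$carrier,
                                      carrier_unflagged = gu), cov)
  ols_effects(df, stats::reformulate(setdiff(names(df), "cp"), "cp"))
}

#' Polygenic score interaction model
#'
#' Fits `CP = b0 + b_pgs * PGS + b_carrier * G + b_pgs_x_carrier * G * PGS +
#' a * X` by ordinary least squares. The smoking covariate (when present in
#' `cov`) can optionally interact with carrier status, mirroring the
#' per-disease branching between pack-years-with-interaction and plain
#' ever-smoked adjustment.
#'
#' @inheritParams fit_carrier_effect
#' @param pgs numeric polygenic scores.
#' @param smoking_interaction add a smoking-by-carrier interaction term
#'   (requires a `smoking` column in `cov`).
#' @return An `effect_estimates` data.frame; the interaction term is
#'   `pgs_x_carrier`.
#' @export
fit_pgs_interaction <- function(cp, g, pgs, cov = NULL,
                                smoking_interaction = FALSE) {
  carrier <- if (inherits(g, "genotype_vector")) g$carrier else as.integer(g)
  stopifnot(length(cp) == length(carrier), length(pgs) == length(cp))
  if (sum(carrier) == 0)
    stop("no carriers: interaction term is absent; fit a PGS-only model")
  if (stats::var(pgs[carrier == 1]) == 0 || stats::var(pgs[carrier == 0]) == 0)
    stop("PGS must vary among both carriers and non-carriers")
  extra <- data.frame(pgs = pgs, carrier = carrier,
                      pgs_x_carrier = pgs * carrier)
  df <- assemble_frame(cp, extra, cov)
  if (smoking_interaction) {
    if (is.null(df$smoking))
      stop("smoking_interaction requires a smoking covariate")
    df$smoking_x_carrier <- df$smoking * df$carrier
  }
  ols_effects(df, stats::reformulate(setdiff(names(df), "cp"), "cp"))
}

#' Look up one term of an effect-estimate table
#'
#' @param est an `effect_estimates` data.frame.
#' @param term term name.
#' @return One-row data.frame for the term.
#' @export
effect_term <- function(est, term) {
  row <- est[est$term == term, , drop = FALSE]
  if (nrow(row) == 0)
    stop("term not present: ", term, " (have: ",
         paste(est$term, collapse = ", "), ")")
  row
}
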