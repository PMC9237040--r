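# Cryptic phenotype selection and the capture / replication / consistency
# evaluation pipeline.

#' Average precision of a ranking score
#'
#' Step-interpolated precision-recall summation: items are sorted by
#' decreasing score and each positive contributes the precision at its rank.
#' Tied blocks are treated as a single step — every positive in a block of
#' equal scores receives the precision at the block's end — which is
#' deterministic and order-independent. A perfect ranking scores 1; a
#' constant score yields exactly the prevalence.
#'
#' @param scores numeric ranking scores (higher = more case-like).
#' @param labels binary labels aligned to scores.
#' @return Average precision in \[0, 1\].
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0) stop("average precision undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # tied-score blocks (descending order); each block is one PR step
  ends <- cumsum(rle(s)$lengths)
  tp_end <- cumsum(y)[ends]
  pos_in_block <- diff(c(0, tp_end))
  sum(pos_in_block * (tp_end / ends)) / P
}

#' Select the cryptic phenotype component
#'
#' When a single component was retained it is selected automatically; with
#' several, each latent component is used separately as a classifier for the
#' rare-disease diagnosis labels and the one with the highest average
#' precision wins (ties broken by lowest component index). A component that
#' correlates negatively with the labels is ranked — and reported — with its
#' orientation flipped, so the returned score always points toward severity.
#'
#' @param Zhat N x L_eff matrix of latent scores (retained components).
#' @param labels binary diagnosis labels, aligned to rows.
#' @param component_ids optional identifiers for the columns of `Zhat`
#'   (defaults to its column names, else 1..L_eff).
#' @return A `cryptic_assignment`: `component_index` (position in `Zhat`),
#'   `component_id`, `orientation` (+1/-1), `average_precision`,
#'   `selection_mode`, and the oriented `scores` vector.
#' @export
select_cryptic <- function(Zhat, labels, component_ids = colnames(Zhat)) {
  Zhat <- as.matrix(Zhat)
  if (ncol(Zhat) == 0) stop("no retained components to select from")
  stopifnot(nrow(Zhat) == length(labels), all(labels %in% c(0, 1)))
  if (is.null(component_ids)) component_ids <- as.character(seq_len(ncol(Zhat)))
  if (ncol(Zhat) > 1 && sum(labels) < 1)
    stop("need at least one case to rank multiple components")
  orient_one <- function(z) {
    r <- suppressWarnings(stats::cor(z, labels))
    if (!is.na(r) && r < 0) -1 else 1
  }
  signs <- apply(Zhat, 2, orient_one)
  aps <- vapply(seq_len(ncol(Zhat)), function(l) {
    if (sum(labels) < 1) return(NA_real_)
    average_precision(signs[l] * Zhat[, l], labels)
  }, numeric(1))
  if (ncol(Zhat) == 1) {
    best <- 1L
    mode <- "single_component"
  } else {
    best <- which.max(aps)  # which.max takes the first (lowest index) on ties
    mode <- "best_classifier"
  }
  structure(list(component_index = best,
                 component_id = component_ids[best],
                 orientation = signs[best],
                 average_precision = aps[best],
                 all_average_precision = aps,
                 selection_mode = mode,
                 scores = signs[best] * Zhat[, best]),
            class = "cryptic_assignment")
}

#' @export
print.cryptic_assignment <- function(x, ...) {
  cat(sprintf("<cryptic_assignment> component %s (%s), AP=%.4f, orientation %+d\n",
              x$component_id, x$selection_mode, x$average_precision,
              x$orientation))
  invisible(x)
}

#' Bootstrap test for cryptic phenotype elevation among diagnosed cases
#'
#' Compares the mean cryptic phenotype between diagnosed cases and
#' undiagnosed controls. Cases and controls are resampled independently with
#' replacement; the 95% confidence interval is percentile-based and the
#' one-sided p-value (cases higher) is `(1 + #\{resampled difference <= 0\}) /
#' (n_boot + 1)`. The test passes when `p * m < alpha` (Bonferroni over `m`
#' diseases).
#'
#' @param cp numeric cryptic phenotype scores.
#' @param labels binary diagnosis labels aligned to `cp`.
#' @param n_boot bootstrap resamples (default 1e5).
#' @param alpha significance level (default 0.05).
#' @param m Bonferroni correction factor (default 1).
#' @param seed integer seed.
#' @param standardized divide the mean difference by the pooled SD (off by
#'   default: the raw severity increase is the reported effect).
#' @return A `severity_test`: `effect`, `ci95`, `p_boot`, `n_boot`,
#'   `bonferroni_m`, `passed`.
#' @export
bootstrap_severity_test <- function(cp, labels, n_boot = 1e5, alpha = 0.05,
                                    m = 1, seed = 1L, standardized = FALSE) {
  stopifnot(length(cp) == length(labels), all(labels %in% c(0, 1)))
  ca <- cp[labels == 1]; co <- cp[labels == 0]
  if (length(ca) < 2 || length(co) < 2)
    stop("need at least 2 cases and 2 controls")
  scale_by <- if (standardized) {
    sqrt(((length(ca) - 1) * stats::var(ca) + (length(co) - 1) * stats::var(co)) /
           (length(ca) + length(co) - 2))
  } else 1
  effect <- (mean(ca) - mean(co)) / scale_by
  rng <- local_rng(seed)
  # chunked so n_boot = 1e5 never allocates more than ~40 MB at once
  chunk <- max(1L, min(n_boot, floor(5e6 / (length(ca) + length(co)))))
  boot <- numeric(n_boot)
  done <- 0L
  while (done < n_boot) {
    nb <- min(chunk, n_boot - done)
    bca <- with_rng(rng, matrix(ca[sample.int(length(ca), nb * length(ca),
                                              replace = TRUE)], nb))
    bco <- with_rng(rng, matrix(co[sample.int(length(co), nb * length(co),
                                              replace = TRUE)], nb))
    boot[done + seq_len(nb)] <- (rowMeans(bca) - rowMeans(bco)) / scale_by
    done <- done + nb
  }
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  p <- (1 + sum(boot <= 0)) / (n_boot + 1)
  structure(list(effect = effect, ci95 = ci, p_boot = p,
                 n_boot = as.integer(n_boot), bonferroni_m = as.integer(m),
                 alpha = alpha, passed = (p * m) < alpha,
                 standardized = standardized),
            class = "severity_test")
}

#' @export
print.severity_test <- function(x, ...) {
  cat(sprintf(
    "<severity_test> effect=%.4f [%.4f, %.4f], p=%.3g (m=%d), %s\n",
    x$effect, x$ci95[1], x$ci95[2], x$p_boot, x$bonferroni_m,
    if (x$passed) "PASSED" else "not significant"))
  invisible(x)
}

#' Consistency between two cryptic phenotype score vectors
#'
#' Coefficient of determination, computed as the squared Pearson correlation
#' between scores produced for the same subjects by two independently fitted
#' models. Affine rescalings (including sign flips — orientation is handled
#' upstream) leave it unchanged.
#'
#' @param cp_a,cp_b numeric score vectors for the same subjects, same order.
#' @return Squared correlation in \[0, 1\]; `NA` with a warning when either
#'   vector has zero variance (undefined).
#' @export
consistency_r2 <- function(cp_a, cp_b) {
  stopifnot(length(cp_a) == length(cp_b))
  if (stats::var(cp_a) == 0 || stats::var(cp_b) == 0) {
    warning("consistency r2 undefined: zero variance in a score vector")
    return(NA_real_)
  }
  stats::cor(cp_a, cp_b)^2
}

#' Capture / replication / consistency evaluation for one disease
#'
#' Runs the three-stage filter on a pair of independently fitted models
#' sharing a symptom encoding:
#' \enumerate{
#'   \item \strong{capture} — model A's cryptic phenotype is significantly
#'     elevated among diagnosed cases of the withheld test split;
#'   \item \strong{replication} — model B's scores, imputed into the same
#'     test split, reproduce the elevation;
#'   \item \strong{component match} — the component selected for model B is
#'     the model-B component most correlated with model A's selection;
#'   \item \strong{consistency} — squared correlation between the two score
#'     vectors on the same subjects meets the `r2_cutoff`.
#' }
#' Components are selected per model on the training split (or the test split
#' when no training data is supplied).
#'
#' @param fit_a,fit_b `cpa_fit` objects over the same symptom columns.
#' @param test `labeled_dataset` used for evaluation (withheld from fitting).
#' @param train optional `labeled_dataset` used for component selection.
#' @param alpha,m,r2_cutoff filter parameters (defaults 0.05, 1, 0.2).
#' @param n_boot bootstrap resamples for the severity tests.
#' @param seed integer seed.
#' @return A `consistency_result` with per-filter outcomes and `passed`.
#' @export
evaluate_disease <- function(fit_a, fit_b, test, train = NULL,
                             alpha = 0.05, m = 1, r2_cutoff = 0.2,
                             n_boot = 1e4, seed = 1L) {
  stopifnot(inherits(test, "labeled_dataset"))
  sel_data <- if (is.null(train)) test else train
  sel_a <- select_cryptic(infer_latent(sel_data$matrix, fit_a), sel_data$labels)
  sel_b <- select_cryptic(infer_latent(sel_data$matrix, fit_b), sel_data$labels)

  Za <- infer_latent(test$matrix, fit_a)
  Zb <- infer_latent(test$matrix, fit_b)
  cp_a <- sel_a$orientation * Za[, sel_a$component_index]
  cp_b <- sel_b$orientation * Zb[, sel_b$component_index]

  capture <- bootstrap_severity_test(cp_a, test$labels, n_boot = n_boot,
                                     alpha = alpha, m = m, seed = seed)
  replication <- bootstrap_severity_test(cp_b, test$labels, n_boot = n_boot,
                                         alpha = alpha, m = m, seed = seed + 1L)
  # model B's components don't index-align with model A's; the B component
  # carrying A's signal is the one maximally correlated with A's selection
  cors <- abs(stats::cor(cp_a, Zb))
  same_component <- which.max(cors) == sel_b$component_index
  r2 <- consistency_r2(cp_a, cp_b)
  passed <- capture$passed && replication$passed && same_component &&
    !is.na(r2) && r2 >= r2_cutoff
  structure(list(assignment_a = sel_a, assignment_b = sel_b,
                 capture = capture, replication = replication,
                 same_component_selected = same_component,
                 replicated_severity = replication$passed,
                 r2 = r2, passed_cutoff = !is.na(r2) && r2 >= r2_cutoff,
                 r2_cutoff = r2_cutoff, passed = passed),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    paste0("<consistency_result> capture=%s replication=%s ",
           "component_match=%s r2=%.3f (cutoff %.2f) => %s\n"),
    x$capture$passed, x$replication$passed, x$same_component_selected,
    x$r2, x$r2_cutoff, if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}
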