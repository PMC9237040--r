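#' Coded clinical records
#'
#' A tidy container for raw coded diagnoses: one row per (subject, code)
#' occurrence. Pairs may repeat (multiple encounters); binarization collapses
#' them. The terminology must be uniform within one record set.
#'
#' @param subject_id character vector of subject identifiers.
#' @param code character vector of terminology codes, same length.
#' @param terminology one of `"ICD10CM"`, `"ICD10UKBB"`, `"HPO"`; either a
#'   single value recycled to all records or a vector per record.
#' @return A `data.frame` with class `coded_records`.
#' @export
coded_records <- function(subject_id, code, terminology = "ICD10CM") {
  stopifnot(length(subject_id) == length(code), length(subject_id) >= 1)
  terminology <- as.character(terminology)
  if (length(terminology) == 1L) terminology <- rep(terminology, length(code))
  stopifnot(length(terminology) == length(code))
  bad <- setdiff(unique(terminology), c("ICD10CM", "ICD10UKBB", "HPO"))
  if (length(bad) > 0)
    stop("unknown terminology: ", paste(bad, collapse = ", "))
  out <- data.frame(subject_id = as.character(subject_id),
                    code = as.character(code),
                    terminology = terminology,
                    stringsAsFactors = FALSE)
  class(out) <- c("coded_records", "data.frame")
  out
}

#' Binary patient-by-symptom matrix
#'
#' Wraps a sparse binary N x K matrix together with unique row (subject) and
#' column (code/symptom) identifiers and the coding terminology. Rows and
#' columns are stored in lexicographic order so that serialized matrices are
#' bit-stable across runs.
#'
#' @param values an N x K matrix coercible to `Matrix::sparseMatrix`; entries
#'   must be 0/1.
#' @param row_ids,col_ids unique identifiers for rows and columns; defaults
#'   to the dimnames of `values`.
#' @param terminology coding terminology of the columns.
#' @param sort sort rows/columns lexicographically (default `TRUE`).
#' @return An object of class `symptom_matrix`.
#' @export
symptom_matrix <- function(values, row_ids = rownames(values),
                           col_ids = colnames(values),
                           terminology = "ICD10CM", sort = TRUE) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "dMatrix"), "CsparseMatrix")
  if (is.null(row_ids) || is.null(col_ids))
    stop("row_ids and col_ids are required")
  row_ids <- as.character(row_ids); col_ids <- as.character(col_ids)
  if (anyDuplicated(row_ids)) stop("duplicate row identifiers")
  if (anyDuplicated(col_ids)) stop("duplicate column identifiers")
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids))
    stop("identifier lengths do not match matrix dimensions")
  if (nrow(values) < 1 || ncol(values) < 1) stop("need N >= 1 and K >= 1")
  v <- values@x
  if (length(v) && !all(v %in% c(0, 1)))
    stop("matrix entries must be binary (0/1)")
  dimnames(values) <- list(row_ids, col_ids)
  if (sort) {
    values <- values[order(row_ids), order(col_ids), drop = FALSE]
  }
  values <- Matrix::drop0(values)
  structure(list(values = values,
                 row_ids = rownames(values),
                 col_ids = colnames(values),
                 terminology = terminology),
            class = "symptom_matrix")
}

#' @export
dim.symptom_matrix <- function(x) dim(x$values)

#' @export
print.symptom_matrix <- function(x, ...) {
  cat(sprintf("<symptom_matrix> %d subjects x %d codes [%s], %d nonzero\n",
              nrow(x$values), ncol(x$values), x$terminology,
              Matrix::nnzero(x$values)))
  invisible(x)
}

#' At-least-one binarization of coded records
#'
#' Collapses repeated (subject, code) occurrences into a single binary entry:
#' the matrix entry is 1 iff the subject has at least one occurrence of the
#' code. Rows and columns are sorted lexicographically. Subjects supplied via
#' `all_subjects` but carrying no code are retained as all-zero rows.
#'
#' @param records a `coded_records` object (or equivalent data.frame).
#' @param all_subjects optional superset of subject ids to retain as rows.
#' @param min_prevalence drop codes carried by fewer than this fraction of
#'   subjects (default 0: no filtering; code-frequency filtering is an
#'   input-preparation concern).
#' @return A `symptom_matrix`.
#' @export
binarize_records <- function(records, all_subjects = NULL,
                             min_prevalence = 0) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  terms <- unique(records$terminology)
  if (length(terms) > 1) {
    off <- unique(records$code[records$terminology != terms[1]])
    stop("mixed terminologies in record set; offending codes: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  subs <- sort(unique(c(as.character(records$subject_id),
                        as.character(all_subjects))))
  codes <- sort(unique(as.character(records$code)))
  i <- match(as.character(records$subject_id), subs)
  j <- match(as.character(records$code), codes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(subs), length(codes)),
                            dimnames = list(subs, codes))
  m@x[] <- 1  # at-least-one: any repeat count collapses to 1
  out <- symptom_matrix(m, terminology = terms[1], sort = FALSE)
  if (min_prevalence > 0) {
    keep <- Matrix::colMeans(out$values) >= min_prevalence
    if (!any(keep)) stop("min_prevalence filter removed every code")
    out <- symptom_matrix(out$values[, keep, drop = FALSE],
                          terminology = terms[1], sort = FALSE)
  }
  out
}

#' Ontology map between code systems
#'
#' Many-to-one (or many-to-many) alignment pairs between a source terminology
#' and a target vocabulary, e.g. ICD10-CM codes to HPO terms, or fine ICD10-CM
#' codes to the coarser ICD10 dialect. A source code may map to several
#' targets; source codes absent from the map are permitted and are dropped
#' (with a report) when the map is applied.
#'
#' @param source,target equal-length character vectors of alignment pairs.
#' @param source_terminology,target_terminology terminology labels.
#' @return An object of class `ontology_map`.
#' @export
ontology_map <- function(source, target,
                         source_terminology = "ICD10CM",
                         target_terminology = "HPO") {
  stopifnot(length(source) == length(target), length(source) >= 1)
  pairs <- unique(data.frame(source = as.character(source),
                             target = as.character(target),
                             stringsAsFactors = FALSE))
  structure(list(pairs = pairs,
                 source_terminology = source_terminology,
                 target_terminology = target_terminology),
            class = "ontology_map")
}

apply_ontology_map <- function(m, map, what) {
  stopifnot(inherits(m, "symptom_matrix"), inherits(map, "ontology_map"))
  if (!identical(m$terminology, map$source_terminology))
    stop(sprintf("matrix terminology '%s' does not match map source '%s'",
                 m$terminology, map$source_terminology))
  usable <- map$pairs[map$pairs$source %in% m$col_ids, , drop = FALSE]
  if (nrow(usable) == 0)
    stop("ontology map has zero usable pairs for the matrix columns")
  dropped <- setdiff(m$col_ids, unique(usable$source))
  targets <- sort(unique(usable$target))
  # indicator source-code x target-term matrix; target column = OR of sources
  A <- Matrix::sparseMatrix(i = match(usable$source, m$col_ids),
                            j = match(usable$target, targets),
                            x = 1,
                            dims = c(length(m$col_ids), length(targets)),
                            dimnames = list(m$col_ids, targets))
  v <- methods::as((m$values %*% A) > 0, "CsparseMatrix") * 1
  out <- symptom_matrix(v, terminology = map$target_terminology, sort = FALSE)
  attr(out, "dropped_codes") <- dropped
  attr(out, "n_dropped") <- length(dropped)
  if (length(dropped))
    message(sprintf("%s: dropped %d unmapped source code(s)",
                    what, length(dropped)))
  out
}

#' Map coded columns onto symptom terms
#'
#' Translates a code matrix into a symptom-term matrix using OR semantics:
#' a target term is 1 for a subject iff at least one source code mapping to
#' it is 1 (at-least-one again). Source codes with no mapping are dropped and
#' recorded in the `dropped_codes` attribute of the result.
#'
#' @param m a `symptom_matrix` in the map's source terminology.
#' @param map an `ontology_map`.
#' @return A `symptom_matrix` in the target terminology; row count preserved.
#' @export
map_to_symptoms <- function(m, map) apply_ontology_map(m, map, "map_to_symptoms")

#' Translate between coding dialects
#'
#' Collapses fine-grained codes into a less granular dialect (e.g. ICD10-CM
#' into the ICD10 subset used by population biobanks): each coarse column is
#' the OR of its fine children. Fine codes absent from the collapse map are
#' dropped with a report.
#'
#' @param m a `symptom_matrix` of fine-grained codes.
#' @param collapse_map an `ontology_map` from fine to coarse codes.
#' @return A `symptom_matrix` in the coarse terminology.
#' @export
translate_dialect <- function(m, collapse_map)
  apply_ontology_map(m, collapse_map, "translate_dialect")

#' Disease annotation
#'
#' The set of symptom terms associated with a rare disease plus the diagnostic
#' code group defining case status. The two sets must be disjoint: diagnostic
#' codes are labels, never predictors.
#'
#' @param disease_id identifier string.
#' @param symptom_terms nonempty character vector of symptom identifiers.
#' @param diagnostic_codes character vector of code identifiers.
#' @return An object of class `disease_annotation`.
#' @export
disease_annotation <- function(disease_id, symptom_terms, diagnostic_codes) {
  symptom_terms <- unique(as.character(symptom_terms))
  diagnostic_codes <- unique(as.character(diagnostic_codes))
  if (length(symptom_terms) == 0) stop("symptom_terms must be nonempty")
  clash <- intersect(symptom_terms, diagnostic_codes)
  if (length(clash) > 0)
    stop("diagnostic codes overlap symptom terms: ",
         paste(clash, collapse = ", "))
  structure(list(disease_id = disease_id,
                 symptom_terms = symptom_terms,
                 diagnostic_codes = diagnostic_codes),
            class = "disease_annotation")
}

#' Build a labeled dataset for one disease
#'
#' Restricts a symptom matrix to the disease's annotated symptom terms and
#' derives binary diagnosis labels by at-least-one over the annotation's
#' diagnostic codes, read from the (un-restricted) code matrix. The code
#' matrix defaults to `m` but is typically the raw code matrix when `m` has
#' already been mapped to symptom terms.
#'
#' @param m `symptom_matrix` whose columns include (some of) the disease's
#'   symptom terms.
#' @param ann a `disease_annotation`.
#' @param code_matrix `symptom_matrix` carrying the diagnostic codes, rows
#'   aligned by subject id to `m` (default `m`).
#' @return A `labeled_dataset`: list with `matrix` (restricted
#'   `symptom_matrix`), `labels` (binary, aligned to rows), `disease_id`,
#'   and a `missing_terms` attribute.
#' @export
build_labeled_dataset <- function(m, ann, code_matrix = m) {
  stopifnot(inherits(m, "symptom_matrix"), inherits(ann, "disease_annotation"))
  present <- intersect(ann$symptom_terms, m$col_ids)
  if (length(present) == 0)
    stop("no annotated symptom term is present among the matrix columns")
  missing_terms <- setdiff(ann$symptom_terms, m$col_ids)
  sub <- symptom_matrix(m$values[, sort(present), drop = FALSE],
                        terminology = m$terminology, sort = FALSE)
  dx <- intersect(ann$diagnostic_codes, code_matrix$col_ids)
  labels <- stats::setNames(integer(length(m$row_ids)), m$row_ids)
  if (length(dx) > 0) {
    idx <- match(m$row_ids, code_matrix$row_ids)
    if (anyNA(idx)) stop("code_matrix is missing subjects present in m")
    hit <- Matrix::rowSums(code_matrix$values[idx, dx, drop = FALSE]) > 0
    labels[] <- as.integer(hit)
  }
  out <- structure(list(matrix = sub, labels = unname(labels),
                        disease_id = ann$disease_id),
                   class = "labeled_dataset")
  attr(out, "missing_terms") <- missing_terms
  if (length(missing_terms))
    message(sprintf("build_labeled_dataset: %d annotated term(s) absent",
                    length(missing_terms)))
  out
}

#' Construct a labeled dataset directly
#'
#' @param matrix a `symptom_matrix`.
#' @param labels binary vector aligned to matrix rows.
#' @param disease_id optional identifier.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(matrix, labels, disease_id = NA_character_) {
  stopifnot(inherits(matrix, "symptom_matrix"),
            length(labels) == nrow(matrix$values),
            all(labels %in% c(0, 1)))
  structure(list(matrix = matrix, labels = as.integer(labels),
                 disease_id = disease_id),
            class = "labeled_dataset")
}

#' Stratified train/test split
#'
#' Randomly partitions a labeled dataset into training and testing subsets
#' while maintaining an equal ratio of diagnosed cases in each (within integer
#' rounding). Leftover rounding subjects are assigned to the training split so
#' the partition is deterministic given the seed.
#'
#' @param d a `labeled_dataset` with at least one case.
#' @param train_frac training fraction, strictly in (0, 1); default 0.75.
#' @param seed integer RNG seed.
#' @return A list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
split_train_test <- function(d, train_frac = 0.75, seed = 1L) {
  stopifnot(inherits(d, "labeled_dataset"),
            train_frac > 0, train_frac < 1)
  n_cases <- sum(d$labels == 1)
  if (n_cases < 1) stop("dataset has no cases; stratified split undefined")
  idx_tr <- integer(0)
  rng <- local_rng(seed)
  for (lv in c(0L, 1L)) {
    rows <- which(d$labels == lv)
    if (length(rows) == 0) next
    n_tr <- ceiling(train_frac * length(rows))  # leftovers go to training
    if (lv == 1L && (n_tr < 1 || n_tr >= length(rows)))
      stop("too few cases to place at least one in each split")
    idx_tr <- c(idx_tr, sample_rng(rng, rows, n_tr))
  }
  idx_tr <- sort(idx_tr)
  idx_te <- setdiff(seq_along(d$labels), idx_tr)
  take <- function(idx) labeled_dataset(
    symptom_matrix(d$matrix$values[idx, , drop = FALSE],
                   terminology = d$matrix$terminology, sort = FALSE),
    d$labels[idx], d$disease_id)
  list(train = take(idx_tr), test = take(idx_te))
}

# -- scoped RNG helpers: draw from a private stream without touching the
#    caller's .Random.seed ------------------------------------------------
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

sample_rng <- function(rng, x, size)
  with_rng(rng, x[sample.int(length(x), size)])

#' Write a symptom matrix to MatrixMarket plus sidecars
#'
#' Serializes the sparse binary matrix as a MatrixMarket coordinate file with
#' `rows.tsv` (subject_id) and `cols.tsv` (code, terminology) sidecars.
#'
#' @param m a `symptom_matrix`.
#' @param dir target directory (created if absent).
#' @param stem file stem, default `"matrix"`.
#' @return Invisibly, the paths written.
#' @export
write_symptom_matrix <- function(m, dir, stem = "matrix") {
  stopifnot(inherits(m, "symptom_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, paste0(stem, ".mtx"))
  Matrix::writeMM(m$values, mtx)
  rows <- file.path(dir, paste0(stem, ".rows.tsv"))
  cols <- file.path(dir, paste0(stem, ".cols.tsv"))
  utils::write.table(data.frame(subject_id = m$row_ids), rows,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(code = m$col_ids,
                                terminology = m$terminology), cols,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx = mtx, rows = rows, cols = cols))
}

#' Read a symptom matrix written by [write_symptom_matrix()]
#'
#' @param dir directory holding the `.mtx` file and sidecars.
#' @param stem file stem, default `"matrix"`.
#' @return A `symptom_matrix`.
#' @export
read_symptom_matrix <- function(dir, stem = "matrix") {
  mtx <- file.path(dir, paste0(stem, ".mtx"))
  if (!file.exists(mtx)) stop("missing MatrixMarket file: ", mtx)
  v <- Matrix::readMM(mtx)
  rows <- utils::read.table(file.path(dir, paste0(stem, ".rows.tsv")),
                            sep = "\t", header = TRUE,
                            colClasses = "character")
  cols <- utils::read.table(file.path(dir, paste0(stem, ".cols.tsv")),
                            sep = "\t", header = TRUE,
                            colClasses = "character")
  symptom_matrix(v, row_ids = rows$subject_id, col_ids = cols$code,
                 terminology = cols$terminology[1], sort = FALSE)
}

#' Read an ontology map from a two-column TSV
#'
#' @param path TSV with header columns `source` and `target`.
#' @param source_terminology,target_terminology terminology labels.
#' @return An `ontology_map`.
#' @export
read_ontology_map <- function(path, source_terminology = "ICD10CM",
                              target_terminology = "HPO") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  ontology_map(tab$source, tab$target, source_terminology, target_terminology)
}

#' Read a disease annotation from JSON
#'
#' @param path JSON file with fields `disease_id`, `symptom_terms`,
#'   `diagnostic_codes`.
#' @return A `disease_annotation`.
#' @export
read_disease_annotation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  disease_annotation(x$disease_id, x$symptom_terms, x$diagnostic_codes)
}
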