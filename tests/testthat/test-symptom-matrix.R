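test_that("binarize_records collapses repeats and keeps zero rows", {
  m <- binarize_records(tiny_records())
  expect_equal(m$row_ids, c("A", "B"))
  expect_equal(m$col_ids, c("X", "Y"))
  expect_equal(as.matrix(m$values),
               matrix(c(1, 0, 1, 1), 2, 2,
                      dimnames = list(c("A", "B"), c("X", "Y"))))
  # subject with zero codes is retained as an all-zero row
  m2 <- binarize_records(tiny_records(), all_subjects = c("A", "B", "C"))
  expect_equal(m2$row_ids, c("A", "B", "C"))
  expect_equal(unname(Matrix::rowSums(m2$values)["C" == m2$row_ids]), 0)
})

test_that("binarize is idempotent on already-binary data", {
  set.seed(7)
  recs <- coded_records(sample(letters[1:8], 60, TRUE),
                        sample(LETTERS[1:5], 60, TRUE), "HPO")
  m1 <- binarize_records(recs)
  # rebuild records from the binary matrix and binarize again
  idx <- Matrix::which(m1$values == 1, arr.ind = TRUE)
  recs2 <- coded_records(m1$row_ids[idx[, 1]], m1$col_ids[idx[, 2]], "HPO")
  m2 <- binarize_records(recs2)
  expect_identical(as.matrix(m1$values), as.matrix(m2$values))
})

test_that("mixed terminologies are rejected naming the codes", {
  recs <- coded_records(c("A", "B"), c("X", "H1"),
                        c("ICD10CM", "ICD10CM"))
  recs$terminology[2] <- "HPO"
  expect_error(binarize_records(recs), "H1")
})

test_that("map_to_symptoms uses OR semantics and reports drops", {
  recs <- coded_records(c("A", "B", "B"), c("X1", "X2", "X3"))
  m <- binarize_records(recs, all_subjects = c("A", "B", "C"))
  map <- ontology_map(c("X1", "X2"), c("H", "H"))
  out <- suppressMessages(map_to_symptoms(m, map))
  expect_equal(out$col_ids, "H")
  # A has X1 only -> H = 1; C has neither -> H = 0
  v <- as.vector(out$values)
  expect_equal(v[out$row_ids == "A"], 1)
  expect_equal(v[out$row_ids == "B"], 1)
  expect_equal(v[out$row_ids == "C"], 0)
  expect_equal(attr(out, "dropped_codes"), "X3")
  expect_equal(out$terminology, "HPO")
  # row count preserved; mapped symptom count never exceeds source count
  expect_equal(nrow(out$values), nrow(m$values))
  expect_true(all(Matrix::rowSums(out$values) <= Matrix::rowSums(m$values)))
})

test_that("map with zero usable pairs is rejected", {
  m <- binarize_records(tiny_records())
  expect_error(map_to_symptoms(m, ontology_map("Q1", "H1")), "zero usable")
  expect_error(map_to_symptoms(
    binarize_records(tiny_records("HPO")),
    ontology_map("X", "H")), "terminology")
})

test_that("translate_dialect collapses children; identity is a no-op", {
  recs <- coded_records(c("A", "B"), c("C1", "C2"))
  m <- binarize_records(recs)
  out <- translate_dialect(m, ontology_map(c("C1", "C2"), c("P", "P"),
                                           target_terminology = "ICD10UKBB"))
  expect_equal(as.vector(out$values), c(1, 1))  # each subject has one child
  idm <- ontology_map(m$col_ids, m$col_ids, target_terminology = "ICD10UKBB")
  expect_equal(as.matrix(translate_dialect(m, idm)$values),
               as.matrix(m$values))
  # surjective map never increases K
  expect_lte(ncol(out$values), ncol(m$values))
})

test_that("disease_annotation enforces symptom/diagnostic disjointness", {
  expect_error(disease_annotation("d", c("H1", "H2"), c("H2", "X")),
               "overlap")
  expect_error(disease_annotation("d", character(0), "X"), "nonempty")
})

test_that("build_labeled_dataset restricts columns and derives labels", {
  set.seed(3)
  S <- matrix(rbinom(50, 1, 0.4), 10, 5,
              dimnames = list(sprintf("s%02d", 1:10), paste0("H", 1:5)))
  m <- symptom_matrix(S, terminology = "HPO")
  codes <- matrix(0, 10, 2, dimnames = list(sprintf("s%02d", 1:10),
                                            c("DXA", "DXB")))
  codes[c(2, 5), 1] <- 1
  cm <- symptom_matrix(codes, terminology = "ICD10CM")
  ann <- disease_annotation("dz", c("H1", "H3", "H4", "H9", "H7"),
                            c("DXA"))
  d <- suppressMessages(build_labeled_dataset(m, ann, code_matrix = cm))
  expect_equal(d$matrix$col_ids, c("H1", "H3", "H4"))
  expect_equal(sort(attr(d, "missing_terms")), c("H7", "H9"))
  expect_equal(which(d$labels == 1), c(2L, 5L))
  expect_error(build_labeled_dataset(m, disease_annotation("dz", "Z9", "DXA"),
                                     cm), "no annotated symptom")
})

test_that("stratified split matches the forced 100/8 example", {
  d <- noise_labeled_dataset(92, 8, seed = 11)
  sp <- split_train_test(d, train_frac = 0.75, seed = 5)
  expect_equal(length(sp$train$labels), 75)
  expect_equal(length(sp$test$labels), 25)
  expect_equal(sum(sp$train$labels), 6)
  expect_equal(sum(sp$test$labels), 2)
  # reproducible and a true partition
  sp2 <- split_train_test(d, train_frac = 0.75, seed = 5)
  expect_identical(sp$train$matrix$row_ids, sp2$train$matrix$row_ids)
  expect_equal(sort(c(sp$train$matrix$row_ids, sp$test$matrix$row_ids)),
               sort(d$matrix$row_ids))
  expect_length(intersect(sp$train$matrix$row_ids,
                          sp$test$matrix$row_ids), 0)
})

test_that("split case counts always sum exactly (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n1 <- sample(4:20, 1)
    d <- noise_labeled_dataset(sample(30:100, 1), n1, seed = seed)
    sp <- split_train_test(d, train_frac = runif(1, 0.5, 0.9), seed = seed)
    expect_equal(sum(sp$train$labels) + sum(sp$test$labels), n1)
    expect_equal(length(sp$train$labels) + length(sp$test$labels),
                 length(d$labels))
  }
})

test_that("splits without cases (or too few) are rejected", {
  d <- noise_labeled_dataset(50, 0)
  expect_error(split_train_test(d), "no cases")
  d1 <- noise_labeled_dataset(50, 1)
  expect_error(split_train_test(d1), "too few cases")
})

test_that("symptom matrix round-trips bitwise through MatrixMarket", {
  m <- binarize_records(tiny_records("HPO"))
  dir <- withr::local_tempdir()
  write_symptom_matrix(m, dir)
  m2 <- read_symptom_matrix(dir)
  expect_identical(as.matrix(m$values), as.matrix(m2$values))
  expect_identical(m$col_ids, m2$col_ids)
  expect_identical(m$terminology, m2$terminology)
})
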