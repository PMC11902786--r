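test_that("confusion_matrix counts and validates", {
  expect_equal(unclass(confusion_matrix(c(0, 1), c(0, 1), 2)),
               matrix(c(1L, 0L, 0L, 1L), 2, 2,
                      dimnames = list(true = c("0", "1"),
                                      predicted = c("0", "1"))))
  cm <- confusion_matrix(c(0, 0, 1), c(1, 1, 1), 2)
  expect_equal(as.vector(cm), c(0L, 0L, 2L, 1L))
  # permutation invariance
  set.seed(2)
  yt <- sample(0:3, 60, replace = TRUE)
  yp <- sample(0:3, 60, replace = TRUE)
  ix <- sample(60)
  expect_identical(confusion_matrix(yt, yp, 4),
                   confusion_matrix(yt[ix], yp[ix], 4))
  expect_equal(sum(confusion_matrix(yt, yp, 4)), 60)
  expect_error(confusion_matrix(c(0, 4), c(0, 1), 4), "lie in")
  expect_error(confusion_matrix(0:2, 0:1, 3), "length")
  expect_error(confusion_matrix(integer(0), integer(0), 2), "no samples")
})

test_that("OA, AA and kappa reproduce hand-computed values", {
  cm <- matrix(c(8, 3, 2, 7), 2, 2)  # rows true, cols predicted
  expect_equal(overall_accuracy(cm), 0.75)
  expect_equal(average_accuracy(cm), 0.75)
  expect_equal(cohen_kappa(cm), 0.5)

  expect_equal(overall_accuracy(diag(c(5, 9, 2))), 1)
  expect_equal(cohen_kappa(diag(c(5, 5))), 1)
  expect_equal(overall_accuracy(matrix(c(0, 3, 4, 0), 2, 2)), 0)

  # everything predicted class 0 on balanced truth: chance agreement
  chance <- matrix(c(5, 5, 0, 0), 2, 2)
  expect_equal(cohen_kappa(chance), 0)

  # unbalanced: AA and OA differ; balanced: identical
  unb <- matrix(c(10, 9, 0, 1), 2, 2)
  expect_equal(overall_accuracy(unb), 0.55)
  expect_equal(average_accuracy(unb), 0.55)  # both classes have 10 samples
  unb2 <- matrix(c(30, 9, 0, 1), 2, 2)
  expect_false(isTRUE(all.equal(overall_accuracy(unb2),
                                average_accuracy(unb2))))
})

test_that("metric edge cases raise the documented errors", {
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
  expect_error(average_accuracy(matrix(c(3, 0, 1, 0), 2, 2)), "zero true")
  expect_error(cohen_kappa(matrix(c(4, 0, 0, 0), 2, 2)), "Pe = 1")
  expect_error(overall_accuracy(matrix(1, 2, 3)), "square")
})

test_that("metrics obey their algebraic invariants on random matrices", {
  set.seed(33)
  for (i in 1:200) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 4), C, C) + diag(C)  # ensure nonzero rows
    oa <- overall_accuracy(cm)
    aa <- average_accuracy(cm)
    expect_gte(oa, 0); expect_lte(oa, 1)
    expect_gte(aa, 0); expect_lte(aa, 1)
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (pe < 1) expect_lte(cohen_kappa(cm), oa + 1e-12)
    # OA is the count-weighted mean of per-class accuracies
    r <- metrics_report(cm)
    expect_equal(oa, sum(r$per_class_accuracy * rowSums(cm)) / sum(cm),
                 tolerance = 1e-12)
    expect_equal(aa, mean(r$per_class_accuracy), tolerance = 1e-12)
  }
  # balanced class sizes: AA == OA exactly
  cmb <- matrix(c(7, 2, 1, 3, 6, 1, 0, 2, 8), 3, 3, byrow = TRUE)
  expect_equal(rowSums(cmb), rep(10, 3), ignore_attr = TRUE)
  expect_equal(overall_accuracy(cmb), average_accuracy(cmb))
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(44)
  worst <- 0
  for (i in 1:120) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 3), C, C) + diag(C)
    ours <- cohen_kappa(cm)
    ref <- e1071::classAgreement(cm)$kappa
    worst <- max(worst, abs(ours - ref))
  }
  expect_lt(worst, 1e-12)
})

test_that("metrics_report aggregates consistently and serializes", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0), 3)
  r <- metrics_report(cm)
  expect_equal(r$OA, overall_accuracy(cm))
  expect_equal(r$AA, average_accuracy(cm))
  expect_equal(r$Kappa, cohen_kappa(cm))
  expect_equal(r$Po, r$OA)
  g <- glance(r)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n, 6L)
  td <- tidy(r)
  expect_equal(nrow(td), 3)

  json <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(r, json)
  back <- jsonlite::read_json(json)
  expect_equal(back$OA, r$OA, tolerance = 1e-12)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, csv)
  back_cm <- read.csv(csv, row.names = 1)
  expect_equal(unname(as.matrix(back_cm)), unclass(cm), ignore_attr = TRUE)
})
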