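test_that("stratified folds partition every class evenly and reproducibly", {
  set.seed(1)
  labels <- rep(0:4, times = c(30, 30, 20, 20, 10))
  f1 <- stratified_folds(labels, k = 10, seed = 5)
  f2 <- stratified_folds(labels, k = 10, seed = 5)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  # each class spread over folds as evenly as possible
  for (cl in 0:4) {
    counts <- table(f1[labels == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  # union of test folds = all samples, pairwise disjoint (by construction of
  # a single assignment vector)
  expect_length(f1, length(labels))
  f3 <- stratified_folds(labels, k = 10, seed = 6)
  expect_false(identical(f1, f3))
  expect_error(stratified_folds(rep(0:1, c(5, 30)), k = 10), "fewer than")
})

test_that("crossvalidate averages folds and pools confusions", {
  ds <- tiny_dataset(n_per_class = 12, n_bands = 16)
  tc <- train_config(epochs = 3, batch_size = 16, seed = 3)
  cv <- crossvalidate(ds, tc, k = 3, net_config = tiny_net_config(n_bands = 16))
  expect_length(cv$per_fold, 3)
  oas <- vapply(cv$per_fold, `[[`, numeric(1), "OA")
  expect_equal(cv$mean_report$OA, mean(oas), tolerance = 1e-12)
  expect_equal(sum(cv$pooled_confusion), n_spectra(ds))
  td <- tidy(cv)
  expect_identical(nrow(td), 3L)
  g <- glance(cv)
  expect_equal(g$OA, mean(oas), tolerance = 1e-12)
  expect_equal(g$pooled_OA, overall_accuracy(cv$pooled_confusion))
})

test_that("crossvalidate can save one checkpoint per fold", {
  ds <- tiny_dataset(n_per_class = 6, n_bands = 16)
  dir <- withr::local_tempdir()
  cv <- crossvalidate(ds, train_config(epochs = 1, batch_size = 12, seed = 1),
                      k = 2, net_config = tiny_net_config(n_bands = 16),
                      checkpoint_dir = dir)
  expect_setequal(list.files(dir), c("fold1.rds", "fold2.rds"))
  fit1 <- load_checkpoint(file.path(dir, "fold1.rds"), expect_bands = 16)
  expect_s3_class(fit1, "mbnet_fit")
})

test_that("10-fold stratification on a balanced set gives balanced folds", {
  labels <- rep(0:5, each = 100)
  f <- stratified_folds(labels, 10, seed = 2)
  tab <- table(f)
  expect_true(all(tab == 60))
  per_class <- table(f, labels)
  expect_true(all(per_class == 10))
})

test_that("ablation runs all variants on identical folds", {
  ds <- tiny_dataset(n_per_class = 9, n_bands = 16)
  tc <- train_config(epochs = 2, batch_size = 12, seed = 4)
  ab <- run_ablation(ds, tc, k = 3, net_config = tiny_net_config(n_bands = 16))
  expect_named(ab$results, c("bidirectional", "sequential_only",
                             "reverse_only", "no_mamba"), ignore.order = TRUE)
  folds <- lapply(ab$results, `[[`, "folds")
  for (f in folds) expect_identical(f, ab$folds)   # paired comparison
  tab <- ablation_table(ab)
  expect_identical(nrow(tab), 3L)                   # OA, AA, Kappa rows
  expect_identical(ncol(tab), 5L)                   # metric + 4 variants
  expect_identical(tab$metric, c("OA", "AA", "Kappa"))
})

test_that("baselines share folds, share metrics, and tolerate failures", {
  skip_if_not_installed("class")
  skip_if_not_installed("MASS")
  ds <- tiny_dataset(n_per_class = 10, n_bands = 16)
  tc <- train_config(epochs = 1, seed = 5)
  bl <- suppressWarnings(   # tiny fixture makes LDA collinear
    run_baselines(ds, tc, k = 2, baselines = c("knn", "lda")))
  expect_named(bl$results, c("knn", "lda"))
  for (r in bl$results) expect_identical(r$folds, bl$folds)
  expect_identical(nrow(bl$report), 2L)
  # report carries per-class accuracy (percent), OA, AA, Kappa
  expect_true(all(c("OA", "AA", "Kappa") %in% names(bl$report)))
  expect_true(all(ds$class_names %in% names(bl$report)))
  expect_error(run_baselines(ds, tc, k = 2, baselines = "quantum"), "unknown")
})

test_that("1-NN on its own training set is a perfect degenerate classifier", {
  skip_if_not_installed("class")
  ds <- tiny_dataset(n_per_class = 8, n_bands = 16, noise_sd = 0.05)
  pred <- class::knn(ds$spectra, ds$spectra, factor(ds$labels), k = 1)
  expect_equal(as.integer(as.character(pred)), ds$labels)
})
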