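#' Stratified k-fold assignment
#'
#' Shuffles each class's indices (seeded) and deals them round-robin into k
#' folds, so every fold contains all classes in near-equal proportion. The
#' same `(labels, k, seed)` always yields the identical assignment.
#'
#' @param labels Integer class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_folds <- function(labels, k = 10, seed = 0) {
  stopifnot(k >= 2)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    small <- names(tab)[tab < k]
    stop(sprintf(paste0("stratified %d-fold split impossible: class(es) %s ",
                        "have fewer than %d samples; reduce k or add data"),
                 k, paste(small, collapse = ", "), k), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subseed(seed, "folds"))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.mean_report <- function(reports) {
  tibble::tibble(
    OA = mean(vapply(reports, `[[`, numeric(1), "OA")),
    AA = mean(vapply(reports, `[[`, numeric(1), "AA")),
    Kappa = mean(vapply(reports, `[[`, numeric(1), "Kappa"))
  )
}

#' Stratified k-fold cross-validation of the network
#'
#' Splits the dataset into k stratified folds (seeded by `cfg$seed`), trains
#' on k-1 folds and evaluates on the held-out fold, and reports the
#' fold-averaged OA/AA/Kappa as the headline numbers alongside the pooled
#' (summed) confusion matrix. Per-band standardization, when enabled, is
#' fitted inside each training fold only (it travels with the fitted model),
#' so no test information leaks into preprocessing.
#'
#' @param dataset A [spectral_dataset]; every class needs at least `k`
#'   samples.
#' @param cfg A [train_config].
#' @param k Number of folds (default 10).
#' @param net_config Optional [mbnet_config] (defaults sized to the data).
#' @param folds Optional precomputed fold assignment (from
#'   [stratified_folds()]); used by the ablation/baseline runners to share
#'   identical splits across models.
#' @param checkpoint_dir Optional directory; when given, each fold's fitted
#'   model is saved there as `fold<k>.rds` via [save_checkpoint()].
#' @return An object of class `mbnet_cv`: `per_fold` (list of
#'   [metrics_report()]s), `mean_report` (tibble of averaged OA/AA/Kappa),
#'   `pooled_confusion`, `folds`, and the fits' final losses.
#' @export
crossvalidate <- function(dataset, cfg = train_config(), k = 10,
                          net_config = NULL, folds = NULL,
                          checkpoint_dir = NULL) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (is.null(folds)) {
    folds <- stratified_folds(dataset$labels, k, cfg$seed)
  }
  k <- max(folds)
  C <- length(dataset$class_names)
  per_fold <- vector("list", k)
  pooled <- matrix(0L, C, C)
  final_losses <- numeric(k)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (f in seq_len(k)) {
    train_ds <- dataset[folds != f]
    test_ds <- dataset[folds == f]
    fit <- mbnet_train(train_ds, cfg, net_config)
    pred <- predict(fit, test_ds)
    cm <- confusion_matrix(test_ds$labels, pred, C)
    per_fold[[f]] <- metrics_report(cm)
    pooled <- pooled + unclass(cm)
    final_losses[f] <- fit$history$loss[nrow(fit$history)]
    if (!is.null(checkpoint_dir)) {
      save_checkpoint(fit, file.path(checkpoint_dir,
                                     sprintf("fold%d.rds", f)))
    }
  }
  structure(list(
    per_fold = per_fold,
    mean_report = .mean_report(per_fold),
    pooled_confusion = pooled,
    folds = folds,
    final_losses = final_losses,
    variant = cfg$variant,
    seed = cfg$seed,
    dataset_hash = dataset_hash(dataset)
  ), class = "mbnet_cv")
}

#' @export
print.mbnet_cv <- function(x, ...) {
  m <- x$mean_report
  cat(sprintf("<mbnet_cv> %d folds, variant=%s\n", length(x$per_fold),
              x$variant))
  cat(sprintf("  mean OA = %.2f%%  AA = %.2f%%  Kappa = %.4f\n",
              100 * m$OA, 100 * m$AA, m$Kappa))
  invisible(x)
}

#' @method tidy mbnet_cv
#' @export
tidy.mbnet_cv <- function(x, ...) {
  purrr::map_dfr(seq_along(x$per_fold), function(f) {
    r <- x$per_fold[[f]]
    tibble::tibble(fold = f, OA = r$OA, AA = r$AA, Kappa = r$Kappa)
  })
}

#' @method glance mbnet_cv
#' @export
glance.mbnet_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$mean_report,
    tibble::tibble(pooled_OA = overall_accuracy(x$pooled_confusion),
                   k = length(x$per_fold), variant = x$variant,
                   seed = x$seed)
  )
}

#' Ablation study over the network variants
#'
#' Cross-validates the four variants — `no_mamba` (Mamba blocks removed,
#' the network collapses to an MLP-like pipeline), `sequential_only`,
#' `reverse_only`, and `bidirectional` — on *identical* folds and seeds, so
#' the comparison is paired: every variant sees exactly the same train/test
#' partitions and the same initialisation stream.
#'
#' @inheritParams crossvalidate
#' @param variants Character vector of variants to run (default all four).
#' @return An object of class `mbnet_ablation`: named list of [crossvalidate()]
#'   results plus a `report` tibble (variant x OA/AA/Kappa).
#' @export
run_ablation <- function(dataset, cfg = train_config(), k = 10,
                         net_config = NULL, variants = .mbnet_variants) {
  stopifnot(all(variants %in% .mbnet_variants))
  folds <- stratified_folds(dataset$labels, k, cfg$seed)
  results <- lapply(variants, function(v) {
    cfg_v <- cfg
    cfg_v$variant <- v
    crossvalidate(dataset, cfg_v, k, net_config, folds = folds)
  })
  names(results) <- variants
  report <- purrr::map_dfr(variants, function(v) {
    dplyr::bind_cols(tibble::tibble(variant = v), results[[v]]$mean_report)
  })
  structure(list(results = results, report = report, folds = folds,
                 seed = cfg$seed),
            class = "mbnet_ablation")
}

#' Ablation report in the conventional wide layout
#'
#' Three metric rows (OA and AA in percent, Kappa as a fraction) by one
#' column per variant.
#'
#' @param x An `mbnet_ablation`.
#' @return A tibble with columns `metric` and one column per variant.
#' @export
ablation_table <- function(x) {
  stopifnot(inherits(x, "mbnet_ablation"))
  long <- x$report |>
    tidyr::pivot_longer(c("OA", "AA", "Kappa"), names_to = "metric") |>
    dplyr::mutate(value = ifelse(.data$metric == "Kappa", .data$value,
                                 100 * .data$value))
  tidyr::pivot_wider(long, names_from = "variant", values_from = "value")
}

#' @export
print.mbnet_ablation <- function(x, ...) {
  cat("<mbnet_ablation>\n")
  print(as.data.frame(ablation_table(x)), row.names = FALSE)
  invisible(x)
}

#' @method tidy mbnet_ablation
#' @export
tidy.mbnet_ablation <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(v) {
    dplyr::bind_cols(tibble::tibble(variant = v), tidy(x$results[[v]]))
  })
}

# ---- baseline registry -----------------------------------------------------

.baseline_registry <- function(opts = list()) {
  o <- function(name, default) if (!is.null(opts[[name]])) opts[[name]] else default
  list(
    knn = function(xtr, ytr, xte) {
      as.integer(as.character(class::knn(xtr, xte, factor(ytr),
                                         k = o("knn_k", 5))))
    },
    svm = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, factor(ytr), kernel = o("svm_kernel", "radial"),
                        cost = o("svm_cost", 10), scale = FALSE)
      as.integer(as.character(predict(fit, xte)))
    },
    rf = function(xtr, ytr, xte) {
      fit <- ranger::ranger(y = factor(ytr), x = as.data.frame(xtr),
                            num.trees = o("rf_trees", 300),
                            seed = o("rf_seed", 1), num.threads = 1)
      as.integer(as.character(predict(fit, as.data.frame(xte),
                                      num.threads = 1)$predictions))
    },
    gbm = function(xtr, ytr, xte) {
      fit <- xgboost::xgboost(data = xtr, label = ytr,
                              nrounds = o("gbm_rounds", 60),
                              params = list(objective = "multi:softmax",
                                            num_class = max(ytr) + 1L,
                                            max_depth = o("gbm_depth", 4),
                                            eta = o("gbm_eta", 0.3),
                                            nthread = 1),
                              verbose = 0)
      as.integer(predict(fit, xte))
    },
    lda = function(xtr, ytr, xte) {
      fit <- MASS::lda(xtr, grouping = factor(ytr))
      as.integer(as.character(predict(fit, xte)$class))
    },
    mlp = function(xtr, ytr, xte) {
      yy <- nnet::class.ind(factor(ytr))
      fit <- nnet::nnet(xtr, yy, size = o("mlp_size", 64),
                        softmax = TRUE, maxit = o("mlp_maxit", 200),
                        decay = o("mlp_decay", 1e-4),
                        MaxNWts = 1e6, trace = FALSE)
      pr <- predict(fit, xte)
      as.integer(colnames(yy)[max.col(pr)])
    }
  )
}

#' Benchmark standard classifiers under the shared CV harness
#'
#' Runs each baseline under exactly the same stratified folds (and the same
#' per-band standardization, fitted on training folds only) as the network,
#' and evaluates with the same metrics. The learners themselves are the
#' established implementations: `class::knn`, `e1071::svm`, `ranger`,
#' `xgboost`, `MASS::lda`, `nnet`; this function's contract is the harness,
#' not the learners. A baseline that errors is reported as failed rather
#' than aborting the run. Optionally include `"mbnet"` to add the network
#' itself to the same table.
#'
#' @inheritParams crossvalidate
#' @param baselines Character vector of registry names (any of `"knn"`,
#'   `"svm"`, `"rf"`, `"gbm"`, `"lda"`, `"mlp"`, `"mbnet"`).
#' @param opts Named list of baseline hyperparameter overrides (e.g.
#'   `knn_k`, `svm_cost`, `rf_trees`, `gbm_rounds`, `mlp_size`).
#' @return An object of class `mbnet_baselines`: per-model [crossvalidate()]
#'   -style results, a Table-shaped `report` tibble (per-class accuracy in
#'   percent, OA, AA, Kappa per model), the shared `folds`, and any
#'   `failures`.
#' @export
run_baselines <- function(dataset, cfg = train_config(), k = 10,
                          baselines = c("knn", "svm", "rf", "gbm", "lda",
                                        "mlp"),
                          net_config = NULL, opts = list()) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  registry <- .baseline_registry(opts)
  unknown <- setdiff(baselines, c(names(registry), "mbnet"))
  if (length(unknown) > 0) {
    stop("unknown baseline(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  folds <- stratified_folds(dataset$labels, k, cfg$seed)
  kk <- max(folds)
  C <- length(dataset$class_names)
  results <- list()
  failures <- character()

  for (b in baselines) {
    if (b == "mbnet") {
      results[[b]] <- crossvalidate(dataset, cfg, kk, net_config,
                                    folds = folds)
      next
    }
    res <- tryCatch({
      per_fold <- vector("list", kk)
      pooled <- matrix(0L, C, C)
      for (f in seq_len(kk)) {
        tr <- folds != f
        scaler <- if (cfg$standardize) .fit_scaler(dataset$spectra[tr, ]) else NULL
        xtr <- .apply_scaler(dataset$spectra[tr, , drop = FALSE], scaler)
        xte <- .apply_scaler(dataset$spectra[!tr, , drop = FALSE], scaler)
        old <- .Random.seed_save()
        set.seed(subseed(cfg$seed, paste0("baseline.", b, ".", f)))
        pred <- registry[[b]](xtr, dataset$labels[tr], xte)
        .Random.seed_restore(old)
        cm <- confusion_matrix(dataset$labels[!tr], pred, C)
        per_fold[[f]] <- metrics_report(cm)
        pooled <- pooled + unclass(cm)
      }
      structure(list(per_fold = per_fold, mean_report = .mean_report(per_fold),
                     pooled_confusion = pooled, folds = folds,
                     variant = b, seed = cfg$seed,
                     dataset_hash = dataset_hash(dataset)),
                class = "mbnet_cv")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, setNames(conditionMessage(res), b))
    } else {
      results[[b]] <- res
    }
  }

  report <- purrr::map_dfr(names(results), function(b) {
    r <- results[[b]]
    per_class <- colMeans(do.call(rbind, lapply(r$per_fold, function(p)
      p$per_class_accuracy)))
    dplyr::bind_cols(
      tibble::tibble(model = b),
      tibble::as_tibble(setNames(as.list(100 * per_class),
                                 dataset$class_names)),
      tibble::tibble(OA = 100 * r$mean_report$OA, AA = 100 * r$mean_report$AA,
                     Kappa = r$mean_report$Kappa)
    )
  })
  structure(list(results = results, report = report, folds = folds,
                 failures = failures, seed = cfg$seed),
            class = "mbnet_baselines")
}

#' @export
print.mbnet_baselines <- function(x, ...) {
  cat("<mbnet_baselines>\n")
  print(as.data.frame(x$report), row.names = FALSE, digits = 4)
  if (length(x$failures) > 0) {
    cat("failed:", paste(names(x$failures), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method tidy mbnet_baselines
#' @export
tidy.mbnet_baselines <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(b) {
    dplyr::bind_cols(tibble::tibble(model = b), tidy(x$results[[b]]))
  })
}
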