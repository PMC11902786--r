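test_that("class templates are distinct, smooth and correctly dipped", {
  cfg <- synthetic_config()
  expect_length(class_template(cfg, 0), 260)
  wl <- synthetic_wavelengths(cfg)
  expect_true(all(diff(wl) > 0))
  # all pairs of class templates differ
  tmpl <- sapply(0:5, function(k) class_template(cfg, k))
  d <- as.matrix(dist(t(tmpl)))
  expect_true(all(d[upper.tri(d)] > 0))
  # dip depth decreases with temperature: the 600-700 nm minimum rises
  win <- wl > 600 & wl < 700
  dips <- apply(tmpl[win, ], 2, min)
  expect_true(all(diff(dips) > 0))
  # zero dip depth -> no local minimum inside the window
  cfg0 <- synthetic_config(dip_depth_by_class = rep(0, 6))
  t0 <- class_template(cfg0, 0)
  inner <- which(win)
  expect_true(all(diff(t0[inner]) > 0))  # monotone rise, no dip
  expect_error(class_template(cfg, 6), "class_index")
  expect_error(class_template(cfg, -1), "class_index")
})

test_that("adjacent temperature classes are the closest template pairs", {
  cfg <- synthetic_config()
  tmpl <- sapply(0:5, function(k) class_template(cfg, k))
  d <- as.matrix(dist(t(tmpl)))
  diag(d) <- Inf
  for (k in 1:6) {
    nn <- which.min(d[k, ])
    expect_true(abs(nn - k) == 1)
  }
})

test_that("generation is seeded, labeled and clipped", {
  cfg <- synthetic_config(samples_per_class = 8, seed = 3)
  ds1 <- generate_spectra(cfg)
  ds2 <- generate_spectra(cfg)
  expect_identical(ds1$spectra, ds2$spectra)       # bit-identical
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(dim(ds1$spectra), c(48L, 260L))
  expect_equal(as.vector(table(ds1$labels)), rep(8, 6))
  expect_true(all(ds1$spectra >= 0 & ds1$spectra <= 1.2))
  ds3 <- generate_spectra(synthetic_config(samples_per_class = 8, seed = 4))
  expect_false(identical(ds1$spectra, ds3$spectra))
  expect_error(synthetic_config(noise_sd = -1), "non-negative")
  expect_error(synthetic_config(dip_depth_by_class = seq(0, 0.3, length.out = 6)),
               "non-increasing")
})

test_that("zero noise reproduces the templates exactly", {
  cfg <- synthetic_config(samples_per_class = 3, noise_sd = 0,
                          illum_scale_sd = 0, seed = 1)
  ds <- generate_spectra(cfg)
  for (k in 0:5) {
    rows <- which(ds$labels == k)
    tmpl <- class_template(cfg, k)
    for (r in rows) expect_equal(ds$spectra[r, ], tmpl, tolerance = 1e-14)
  }
})

test_that("class-conditional means converge to the templates", {
  cfg <- synthetic_config(samples_per_class = 2000, seed = 9)
  ds <- generate_spectra(cfg)
  for (k in c(0, 3, 5)) {
    rows <- ds$labels == k
    m <- colMeans(ds$spectra[rows, ])
    tmpl <- class_template(cfg, k)
    se <- apply(ds$spectra[rows, ], 2, sd) / sqrt(sum(rows))
    # clipping can bias a handful of bands; nearly all must sit within 3 SE
    frac_in <- mean(abs(m - tmpl) <= 3 * se + 1e-12)
    expect_gt(frac_in, 0.95)
  }
})

test_that("difficulty sweep shares templates and degrades accuracy", {
  cfg <- synthetic_config(samples_per_class = 25, n_bands = 60,
                          illum_scale_sd = 0, seed = 5)
  levels <- c(0, 0.05, 0.25)
  sets <- difficulty_sweep(cfg, levels)
  expect_length(sets, 3)
  # level 0 equals the zero-noise generator under the same seed
  cfg0 <- cfg; cfg0$noise_sd <- 0
  expect_identical(sets[[1]]$spectra, generate_spectra(cfg0)$spectra)
  # template distances identical across levels (same class means)
  # and a fixed classifier degrades monotonically in noise (median of seeds)
  skip_if_not_installed("class")
  acc <- sapply(sets, function(ds) {
    folds <- stratified_folds(ds$labels, 3, 1)
    mean(sapply(1:3, function(f) {
      pr <- class::knn(ds$spectra[folds != f, ], ds$spectra[folds == f, ],
                       factor(ds$labels[folds != f]), k = 1)
      mean(as.integer(as.character(pr)) == ds$labels[folds == f])
    }))
  })
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1)  # zero-noise separability
  expect_error(difficulty_sweep(cfg, c(0.2, 0.1)), "increasing")
  expect_error(difficulty_sweep(cfg, c(-1, 0)), "non-negative")
})
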