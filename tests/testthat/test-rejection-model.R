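test_that("build_features masks the right visits and orders columns", {
  co <- generate_cohort(small_config(), seed = 51)
  ft <- build_features(co, mode = "causal")
  expect_true(all(ft$visit_index >= 1))
  expect_true(all(ft$n_g0_prior >= 2))
  expect_equal(colnames(ft$X), ev_affected_markers())
  expect_equal(length(ft$y), nrow(ft$X))

  # supplied marker order is preserved
  mk <- rev(ev_affected_markers())[1:5]
  expect_equal(colnames(build_features(co, markers = mk)$X), mk)
  expect_error(build_features(co, markers = c("CD2", "NOPE")), "missing")

  # a G0 visit at the patient's running median gives a near-zero row
  cfg <- small_config()
  cfg$noise_cv <- 0
  cfg$effect_table[] <- 1
  cfg$pre_effect_table[] <- 1
  ft0 <- build_features(generate_cohort(cfg, seed = 52), mode = "causal")
  expect_true(all(abs(ft0$X[ft0$y == 0, ]) < 1e-9))
})

test_that("oversampling equalizes counts per method definition", {
  withr::with_seed(53, {
    X <- matrix(rnorm(285 * 3), ncol = 3)
    y <- c(rep(0, 261), rep(1, 24))
  })
  for (method in c("RO", "SMOTE")) {
    os <- oversample(X, y, method, seed = 3)
    expect_equal(sum(os$y == 0), 261)
    expect_equal(sum(os$y == 1), 261)
    # originals preserved as a prefix
    expect_equal(os$X[seq_len(285), ], X)
  }
  # RO duplicates existing minority rows only
  os_ro <- oversample(X, y, "RO", seed = 3)
  extra <- os_ro$X[-seq_len(285), , drop = FALSE]
  minority <- X[y == 1, , drop = FALSE]
  expect_true(all(apply(extra, 1, function(r)
    any(colSums(abs(t(minority) - r)) < 1e-12))))

  # SMOTE synthetics lie on segments between minority points
  os_sm <- oversample(X, y, "SMOTE", seed = 3)
  synth <- os_sm$X[-seq_len(285), , drop = FALSE]
  on_segment <- apply(synth, 1, function(s) {
    for (i in seq_len(nrow(minority) - 1)) {
      for (j in seq(i + 1, nrow(minority))) {
        a <- minority[i, ]; b <- minority[j, ]
        ab <- b - a
        t <- sum((s - a) * ab) / sum(ab^2)
        if (t > -1e-9 && t < 1 + 1e-9 &&
            sqrt(sum((a + t * ab - s)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))

  # balanced input unchanged under every method
  yb <- rep(c(0, 1), each = 20)
  Xb <- X[1:40, ]
  for (method in c("NONE", "RO", "SMOTE", "SMOTE_NN")) {
    os <- oversample(Xb, yb, method, seed = 1)
    expect_equal(os$X, Xb)
    expect_equal(os$y, yb)
  }

  # tiny minority: SMOTE falls back to RO with a warning
  expect_warning(os_fb <- oversample(X[1:24, ], c(rep(0, 20), rep(1, 4)),
                                     "SMOTE", seed = 1, k = 5),
                 "falling back to RO")
  expect_equal(sum(os_fb$y == 1), 20)
})

test_that("the capped forest fits, predicts in [0,1], and is deterministic", {
  # separable identical points
  X <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  y <- c(rep(0, 10), rep(1, 10))
  m <- fit_rrf(X, y, rf_config(), seed = 2)
  pr <- predict(m, matrix(c(0, 1), ncol = 1))
  expect_lt(pr$coefficient[1], 0.05)
  expect_gt(pr$coefficient[2], 0.95)

  withr::with_seed(54, {
    Xr <- matrix(rnorm(200 * 5), ncol = 5)
    yr <- rbinom(200, 1, plogis(Xr[, 1]))
  })
  m1 <- fit_rrf(Xr, yr, rf_config(), seed = 7)
  m2 <- fit_rrf(Xr, yr, rf_config(), seed = 7)
  expect_equal(predict(m1, Xr), predict(m2, Xr))
  expect_true(all(predict(m1, Xr)$coefficient >= 0 &
                    predict(m1, Xr)$coefficient <= 1))

  # split cap: every tree has at most 10 internal nodes
  for (tr in m1$forest$trees)
    expect_lte(sum(!vapply(tr, `[[`, logical(1), "leaf")), 10)

  # constant features: coefficient equals the training positive fraction
  Xc <- matrix(1, nrow = 50, ncol = 3)
  yc <- rep(c(0, 1), 25)
  mc <- fit_rrf(Xc, yc, rf_config(), seed = 1)
  expect_equal(mean(predict(mc, Xc[1:5, ])$coefficient), 0.5,
               tolerance = 0.12)

  expect_error(fit_rrf(Xr, rep(1, 200), rf_config()), "single-class")
  expect_error(predict(m1, Xr[, 1:3]), "marker list")
})

test_that("calls follow the threshold contract", {
  cfg <- rf_config(threshold = 0.5)
  X <- matrix(c(rep(0, 6), rep(1, 6)), ncol = 1, dimnames = list(NULL, "x"))
  y <- c(rep(0, 6), rep(1, 6))
  fit <- fit_rrf(X, y, cfg, seed = 1)
  pr <- predict(fit, X)
  expect_equal(pr$call, as.integer(pr$coefficient >= 0.5))
})

test_that("grid search honors argmax and tie-breaking contracts", {
  co <- generate_cohort(small_config(), seed = 55)
  ft <- build_features(co, mode = "retrospective")

  # singleton grid returns that configuration
  g1 <- grid_search(ft$X, ft$y, ft$groups,
                    list(oversampler = "RO", n_trees = 5L,
                         max_splits = 3L), seed = 1)
  expect_equal(g1$n_trees, 5L)
  expect_equal(g1$max_splits, 3L)
  expect_equal(g1$oversampler, "RO")

  # determinism (SMOTE falls back to RO on this tiny minority: expected)
  grid <- list(oversampler = c("RO", "SMOTE"), n_trees = c(5L, 10L))
  g2 <- suppressWarnings(grid_search(ft$X, ft$y, ft$groups, grid, seed = 9))
  g3 <- suppressWarnings(grid_search(ft$X, ft$y, ft$groups, grid, seed = 9))
  expect_equal(unclass(g2)[c("oversampler", "n_trees", "max_splits")],
               unclass(g3)[c("oversampler", "n_trees", "max_splits")])
  expect_error(grid_search(ft$X, ft$y, ft$groups, list(), seed = 1),
               "empty grid")
})

test_that("LOPO validates one fold per patient without leakage", {
  co <- generate_cohort(small_config(), seed = 56)
  lopo <- lopo_validate(co, rf_config(), seed = 4)
  expect_equal(lopo$n_folds, n_patients(co))
  # every evaluable visit predicted exactly once
  key <- paste(lopo$predictions$patient_id, lopo$predictions$visit_index)
  expect_false(anyDuplicated(key) > 0)
  ft <- build_features(co, mode = "causal")
  expect_equal(sort(key), sort(paste(ft$groups, ft$visit_index)))

  # determinism of the full validation
  lopo2 <- lopo_validate(co, rf_config(), seed = 4)
  expect_identical(lopo$predictions, lopo2$predictions)
  expect_equal(lopo$mean_accuracy, lopo2$mean_accuracy)

  # leakage: fold p's model is exactly reproducible from the other
  # patients' data alone (the held-out patient's labels and marker
  # values play no role in training)
  pats <- unique(as.data.frame(co)$patient_id)
  f <- 2L
  pid <- pats[f]
  co_minus <- as_ev_cohort(as.data.frame(co)[co$patient_id != pid, ])
  co_only <- as_ev_cohort(as.data.frame(co)[co$patient_id == pid, ])
  tr <- build_features(co_minus, mode = "retrospective")
  os <- oversample(tr$X, tr$y, "RO", seed = 4L + f)
  model <- fit_rrf(os$X, os$y, rf_config(), seed = 4L + f)
  te <- build_features(co_only, mode = "causal")
  pr <- predict(model, te$X)
  got <- lopo$predictions[lopo$predictions$patient_id == pid, ]
  expect_equal(pr$coefficient, got$coefficient)
  expect_equal(pr$call, got$call)
})

test_that("transfer evaluation has its identity limits", {
  cfg <- small_config()
  co <- generate_cohort(cfg, seed = 57)

  # zero-bias zero-noise pairing: identical predictions both ways
  cfg0 <- cfg
  cfg0$protocol_bias <- c(tetraspanin = 1, antigen = 1)
  cfg0$protocol_noise_cv <- 0
  msp0 <- derive_msp_protocol(co, cfg0, seed = 58)
  fwd <- transfer_evaluate(msp0, co, rf_config(), seed = 6)
  rev <- transfer_evaluate(co, msp0, rf_config(), seed = 6,
                           train_protocol = "IMMUNO", test_protocol = "MSP")
  expect_equal(fwd$predictions$coefficient, rev$predictions$coefficient)
  expect_equal(fwd$confusion$accuracy, rev$confusion$accuracy)
})

test_that("learning curve bins and overfit gap behave", {
  co <- generate_cohort(small_config(), seed = 59)
  lopo <- lopo_validate(co, rf_config(), seed = 8)
  curve <- learning_curve(lopo)
  expect_equal(curve$bin, c("2-5 G0", "6-9 G0", "10-14 G0"))
  expect_equal(sum(curve$n), nrow(lopo$predictions))
  in_bin <- lopo$predictions$n_g0_prior >= 2 & lopo$predictions$n_g0_prior <= 5
  expect_equal(curve$accuracy[1],
               mean(lopo$predictions$call[in_bin] ==
                      lopo$predictions$label[in_bin]))

  # all-correct predictions: every non-empty bin at 100%
  perfect <- lopo
  perfect$predictions$call <- perfect$predictions$label
  pc <- learning_curve(perfect)
  expect_true(all(pc$accuracy[pc$n > 0] == 1))

  # gap is zero when evaluated on the training set itself
  ft <- build_features(co, mode = "retrospective")
  m <- fit_rrf(ft$X, ft$y, rf_config(), seed = 1)
  expect_equal(overfit_gap(m, ft$X, ft$y, ft$X, ft$y), 0)

  # a memorizing model (deep trees) on label-noise data shows a positive
  # gap; the default capped model on disjoint replica halves stays small
  withr::with_seed(60, {
    Xn <- matrix(rnorm(120 * 4), ncol = 4)
    yn <- rbinom(120, 1, 0.5)
  })
  deep <- fit_rrf(Xn[1:60, ], yn[1:60], rf_config(max_splits = 60L),
                  seed = 2)
  expect_gt(overfit_gap(deep, Xn[1:60, ], yn[1:60],
                        Xn[61:120, ], yn[61:120]), 0)

  rep24 <- generate_cohort(default_config(), seed = 61)
  pats <- unique(as.data.frame(rep24)$patient_id)
  half_a <- as_ev_cohort(as.data.frame(rep24)[
    rep24$patient_id %in% pats[1:12], ])
  half_b <- as_ev_cohort(as.data.frame(rep24)[
    !rep24$patient_id %in% pats[1:12], ])
  fa <- build_features(half_a, mode = "retrospective")
  fb <- build_features(half_b, mode = "retrospective")
  os <- oversample(fa$X, fa$y, "RO", seed = 3)
  md <- fit_rrf(os$X, os$y, rf_config(), seed = 3)
  expect_lte(overfit_gap(md, fa$X, fa$y, fb$X, fb$y), 10)
})
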