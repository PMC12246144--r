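# The rejection-probability model: feature building on G0-delta
# percentages, class-imbalance oversampling, grid search, the capped
# random-forest regressor, leave-one-patient-out validation, transfer
# evaluation between protocols, the learning curve over baseline depth,
# and the overfitting gap.
#
# Training uses retrospective deltas (a training patient's full grade-0
# baseline is known); prediction on the held-out patient uses causal
# deltas (only that patient's earlier grade-0 visits), which is the
# dynamically adaptive mechanism of the model.

#' Model configuration
#'
#' @param n_trees Trees in the ensemble (default 10).
#' @param max_splits Maximum internal split nodes per tree (default 10).
#' @param oversampler One of `"NONE"`, `"RO"`, `"SMOTE"`, `"SMOTE_NN"`
#'   (default `"RO"`, the configuration retained by the study).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param threshold Coefficient threshold for a positive call
#'   (default 0.5).
#' @param grid Optional named list of candidate values
#'   (`oversampler`, `n_trees`, `max_splits`) for [grid_search()].
#' @param seed Integer seed.
#' @return An `ev_rf_config` list.
#' @export
rf_config <- function(n_trees = 10L, max_splits = 10L,
                      oversampler = c("RO", "NONE", "SMOTE", "SMOTE_NN"),
                      smote_k = 5L, threshold = 0.5, grid = NULL,
                      seed = 1L) {
  oversampler <- match.arg(oversampler)
  stopifnot(n_trees >= 1, max_splits >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_splits = as.integer(max_splits),
                 oversampler = oversampler, smote_k = as.integer(smote_k),
                 threshold = threshold, grid = grid,
                 seed = as.integer(seed)),
            class = "ev_rf_config")
}

#' Build the model feature matrix
#'
#' One row per evaluable visit: the delta percentages of the model
#' markers, the binary grade 2-3A label, and the patient grouping. The
#' first post-transplant sample and visits without an established
#' baseline (fewer than `min_g0` qualifying grade-0 visits) are masked
#' out.
#'
#' @param cohort An `ev_cohort` (exclusions applied).
#' @param markers Ordered marker list (default the 14-antigen panel).
#' @param mode `"causal"` or `"retrospective"` delta computation.
#' @param protocol Protocol rows to use.
#' @param min_g0 Evaluability threshold.
#' @param normalized Optional precomputed [normalize_cohort()] output of
#'   the same mode.
#' @return List: `X` (matrix, columns in `markers` order), `y`, `groups`
#'   (patient ids), `visit_index`, `n_g0_prior`, `grade`, `timepoint`.
#' @export
build_features <- function(cohort, markers = ev_affected_markers(),
                           mode = c("causal", "retrospective"),
                           protocol = "IMMUNO", min_g0 = 2L,
                           normalized = NULL) {
  mode <- match.arg(mode)
  if (!all(markers %in% ev_panel(protocol)))
    stop("marker(s) missing from the ", protocol, " panel: ",
         paste(setdiff(markers, ev_panel(protocol)), collapse = ", "))
  if (is.null(normalized))
    normalized <- normalize_cohort(cohort, mode, min_g0)
  norm <- normalized[normalized$protocol == protocol, , drop = FALSE]
  keep <- norm$visit_index >= 1L & norm$evaluable
  norm <- norm[keep, , drop = FALSE]
  X <- as.matrix(norm[paste0("delta_", markers)])
  colnames(X) <- markers
  ok <- stats::complete.cases(X)
  norm <- norm[ok, , drop = FALSE]
  X <- X[ok, , drop = FALSE]
  list(X = X, y = binary_label(norm$grade), groups = norm$patient_id,
       visit_index = norm$visit_index, n_g0_prior = norm$n_g0_prior,
       grade = norm$grade, timepoint = norm$timepoint)
}

#' Equalize class counts by oversampling
#'
#' `RO` duplicates random minority rows; `SMOTE` synthesizes minority
#' points on segments between a minority point and one of its `k`
#' nearest minority neighbors; `SMOTE_NN` additionally applies
#' edited-nearest-neighbour cleaning (rows misclassified by their 3
#' nearest neighbours are removed, so counts may end slightly unequal);
#' `NONE` is the identity. Applies to training data only.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param method Oversampling method.
#' @param seed Integer seed.
#' @param k SMOTE neighbor count.
#' @return List with oversampled `X` and `y`.
#' @export
oversample <- function(X, y, method = c("RO", "NONE", "SMOTE", "SMOTE_NN"),
                       seed = 1L, k = 5L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (method == "NONE") return(list(X = X, y = y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 == n0) return(list(X = X, y = y))
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(y == minority)
  need <- abs(n0 - n1)

  if (method %in% c("SMOTE", "SMOTE_NN") && length(min_idx) < k + 1) {
    warning("minority class smaller than smote_k + 1; falling back to RO")
    method <- "RO"
  }

  withr::with_seed(as.integer(seed), {
    if (method == "RO") {
      extra <- sample(min_idx, need, replace = TRUE)
      Xo <- rbind(X, X[extra, , drop = FALSE])
      yo <- c(y, y[extra])
    } else {
      Xm <- X[min_idx, , drop = FALSE]
      d <- as.matrix(stats::dist(Xm))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      base <- sample(seq_len(nrow(Xm)), need, replace = TRUE)
      nbr <- vapply(base, function(i) nn[i, sample.int(k, 1)], integer(1))
      u <- stats::runif(need)
      Xs <- Xm[base, , drop = FALSE] +
        u * (Xm[nbr, , drop = FALSE] - Xm[base, , drop = FALSE])
      Xo <- rbind(X, Xs)
      yo <- c(y, rep(minority, need))
      if (method == "SMOTE_NN") {
        dd <- as.matrix(stats::dist(Xo))
        diag(dd) <- Inf
        vote <- vapply(seq_len(nrow(Xo)), function(i) {
          mean(yo[order(dd[i, ])[1:3]])
        }, numeric(1))
        keep <- (yo == 1 & vote >= 0.5) | (yo == 0 & vote < 0.5)
        if (length(unique(yo[keep])) == 2) {
          Xo <- Xo[keep, , drop = FALSE]
          yo <- yo[keep]
        }
      }
    }
    list(X = Xo, y = yo)
  })
}

#' Fit the rejection-probability model
#'
#' Bagged ensemble of `n_trees` capped regression trees on the {0,1}
#' endpoint. Call [oversample()] on the training data first (or use
#' [lopo_validate()], which does both per fold).
#'
#' @param X Training feature matrix (columns = markers, in order).
#' @param y Binary training labels (both classes required).
#' @param config An `ev_rf_config`.
#' @param seed Integer seed.
#' @return An `ev_rrf` model object.
#' @export
fit_rrf <- function(X, y, config = rf_config(), seed = config$seed) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single-class training data")
  forest <- fit_forest(X, y, config$n_trees, config$max_splits, seed)
  structure(list(forest = forest, config = config,
                 markers = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                 class_counts = table(factor(y, levels = 0:1))),
            class = "ev_rrf")
}

#' Predict rejection coefficients
#'
#' @param object An `ev_rrf` model.
#' @param X Feature matrix with columns matching the model's markers.
#' @param ... Unused.
#' @return Data frame: `coefficient` in \[0,1\] and binary `call` at the
#'   configured threshold.
#' @export
predict.ev_rrf <- function(object, X, ...) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !identical(colnames(X), object$markers))
    stop("feature columns do not match the model's marker list")
  if (ncol(X) != length(object$markers))
    stop("feature columns do not match the model's marker list")
  coef <- predict_forest(object$forest, X)
  data.frame(coefficient = coef,
             call = as.integer(coef >= object$config$threshold))
}

#' Grid search over oversampler and tree hyperparameters
#'
#' Evaluates every candidate combination by patient-grouped internal
#' cross-validation (5 folds of whole patients) on the training set only,
#' and returns the accuracy-maximizing configuration; ties break toward
#' fewer trees, then fewer splits.
#'
#' @param X,y,groups Training features, labels, patient grouping.
#' @param grid Named list of candidate vectors: `oversampler`, `n_trees`,
#'   `max_splits` (missing entries default to the base config value).
#' @param config Base `ev_rf_config`.
#' @param seed Integer seed.
#' @param n_folds Internal grouped folds (default 5).
#' @return The selected `ev_rf_config` (internal accuracy in attribute
#'   `"accuracy"`).
#' @export
grid_search <- function(X, y, groups, grid, config = rf_config(),
                        seed = config$seed, n_folds = 5L) {
  if (is.null(grid) || all(lengths(grid) == 0)) stop("empty grid")
  cand <- expand.grid(
    oversampler = grid$oversampler %||% config$oversampler,
    n_trees = grid$n_trees %||% config$n_trees,
    max_splits = grid$max_splits %||% config$max_splits,
    stringsAsFactors = FALSE)
  pats <- unique(groups)
  if (length(pats) < 2) stop("need >= 2 patients for grid search")
  n_folds <- min(n_folds, length(pats))
  fold_of <- withr::with_seed(as.integer(seed), {
    f <- rep(seq_len(n_folds), length.out = length(pats))
    stats::setNames(sample(f), pats)
  })
  acc <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    correct <- 0; total <- 0
    for (fold in seq_len(n_folds)) {
      test <- fold_of[groups] == fold
      if (!any(test) || length(unique(y[!test])) < 2) next
      os <- oversample(X[!test, , drop = FALSE], y[!test],
                       cand$oversampler[ci], seed = seed + fold,
                       k = config$smote_k)
      cfg <- rf_config(cand$n_trees[ci], cand$max_splits[ci],
                       cand$oversampler[ci], config$smote_k,
                       config$threshold, seed = seed)
      model <- fit_rrf(os$X, os$y, cfg, seed = seed + fold)
      pr <- predict(model, X[test, , drop = FALSE])
      correct <- correct + sum(pr$call == y[test])
      total <- total + sum(test)
    }
    acc[ci] <- if (total > 0) correct / total else -Inf
  }
  ord <- order(-acc, cand$n_trees, cand$max_splits)
  best <- ord[1]
  out <- rf_config(cand$n_trees[best], cand$max_splits[best],
                   cand$oversampler[best], config$smote_k,
                   config$threshold, seed = config$seed)
  attr(out, "accuracy") <- acc[best]
  out
}

#' Leave-one-patient-out validation
#'
#' One fold per patient: the model is trained (oversampling, optional
#' grid search) on the retrospective deltas of the other N-1 patients and
#' predicts the held-out patient's visits from their causal deltas.
#' Mean accuracy is the mean of per-fold accuracies; pooled confusion
#' counts and coefficients are also returned.
#'
#' @param cohort An `ev_cohort` (exclusions applied).
#' @param config Base `ev_rf_config`; if `config$grid` is non-NULL, grid
#'   search runs inside every training fold.
#' @param seed Integer seed.
#' @param markers Model marker list.
#' @param protocol Protocol rows to use.
#' @param min_g0 Evaluability threshold.
#' @return An `ev_lopo` list: `predictions` (per-visit data frame),
#'   `fold_accuracy`, `mean_accuracy`, `confusion`, `auc`, `skipped`.
#' @export
lopo_validate <- function(cohort, config = rf_config(), seed = config$seed,
                          markers = ev_affected_markers(),
                          protocol = "IMMUNO", min_g0 = 2L) {
  if (n_patients(cohort) < 3) stop("need at least 3 patients")
  norm_retro <- normalize_cohort(cohort, "retrospective", min_g0)
  norm_causal <- normalize_cohort(cohort, "causal", min_g0)
  train_all <- build_features(cohort, markers, "retrospective", protocol,
                              min_g0, norm_retro)
  test_all <- build_features(cohort, markers, "causal", protocol,
                             min_g0, norm_causal)
  pats <- unique(as.data.frame(cohort)$patient_id)
  preds <- list()
  fold_acc <- stats::setNames(rep(NA_real_, length(pats)), pats)
  skipped <- character(0)
  for (f in seq_along(pats)) {
    p <- pats[f]
    tr <- train_all$groups != p
    te <- test_all$groups == p
    if (!any(te)) {
      skipped <- c(skipped, p)
      next
    }
    fold_seed <- as.integer(seed) + f
    cfg <- config
    if (!is.null(config$grid))
      cfg <- grid_search(train_all$X[tr, , drop = FALSE], train_all$y[tr],
                         train_all$groups[tr], config$grid, config,
                         seed = fold_seed)
    os <- oversample(train_all$X[tr, , drop = FALSE], train_all$y[tr],
                     cfg$oversampler, seed = fold_seed, k = cfg$smote_k)
    model <- fit_rrf(os$X, os$y, cfg, seed = fold_seed)
    pr <- predict(model, test_all$X[te, , drop = FALSE])
    fold_acc[p] <- mean(pr$call == test_all$y[te])
    preds[[p]] <- data.frame(
      patient_id = p, visit_index = test_all$visit_index[te],
      grade = test_all$grade[te], timepoint = test_all$timepoint[te],
      n_g0_prior = test_all$n_g0_prior[te], label = test_all$y[te],
      coefficient = pr$coefficient, call = pr$call, evaluable = TRUE,
      fold = f, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  confusion <- confusion_metrics(predictions$call, predictions$label)
  auc <- auc_rank(predictions$coefficient, predictions$label)
  structure(list(predictions = predictions,
                 fold_accuracy = fold_acc,
                 mean_accuracy = mean(fold_acc, na.rm = TRUE),
                 confusion = confusion, auc = auc, skipped = skipped,
                 n_folds = length(pats)),
            class = "ev_lopo")
}

#' @export
print.ev_lopo <- function(x, ...) {
  cat(sprintf(paste0("ev_lopo: %d folds, mean accuracy %.3f, ",
                     "pooled accuracy %.3f, AUC %.3f\n"),
              x$n_folds, x$mean_accuracy, x$confusion$accuracy, x$auc))
  invisible(x)
}

#' Transfer evaluation between protocols
#'
#' Fits on cohort A's features and evaluates on cohort B's, both in delta
#' space (the patient-specific delta normalization absorbs the
#' multiplicative inter-protocol bias).
#'
#' @param train_cohort,test_cohort `ev_cohort`s sharing the model markers.
#' @param config An `ev_rf_config`.
#' @param seed Integer seed.
#' @param markers Shared marker list.
#' @param train_protocol,test_protocol Protocol rows used on each side.
#' @param mode Delta mode for both sides (default retrospective).
#' @return List: `confusion`, `roc`, `predictions`.
#' @export
transfer_evaluate <- function(train_cohort, test_cohort,
                              config = rf_config(), seed = config$seed,
                              markers = ev_affected_markers(),
                              train_protocol = "MSP",
                              test_protocol = "IMMUNO",
                              mode = "retrospective") {
  shared <- intersect(markers, intersect(ev_panel(train_protocol),
                                         ev_panel(test_protocol)))
  if (length(shared) == 0) stop("no shared markers between protocols")
  tr <- build_features(train_cohort, shared, mode, train_protocol)
  te <- build_features(test_cohort, shared, mode, test_protocol)
  os <- oversample(tr$X, tr$y, config$oversampler, seed = seed,
                   k = config$smote_k)
  model <- fit_rrf(os$X, os$y, config, seed = seed)
  pr <- predict(model, te$X)
  list(confusion = confusion_metrics(pr$call, te$y),
       roc = roc_auc(pr$coefficient, te$y, n_boot = 500, seed = seed),
       predictions = cbind(data.frame(patient_id = te$groups,
                                      visit_index = te$visit_index,
                                      label = te$y), pr))
}

#' Accuracy by grade-0 baseline depth (learning curve)
#'
#' Groups leave-one-patient-out test visits by how many grade-0 episodes
#' backed their causal reference and reports accuracy per bin.
#'
#' @param lopo An `ev_lopo` result (causal test deltas).
#' @param bins List of `c(lo, hi)` bins of `n_g0_prior`
#'   (default 2-5, 6-9, 10-14).
#' @return Data frame: `bin`, `n`, `accuracy` (`NA` for empty bins).
#' @export
learning_curve <- function(lopo,
                           bins = list(c(2, 5), c(6, 9), c(10, 14))) {
  pr <- lopo$predictions
  rows <- lapply(bins, function(b) {
    in_bin <- pr$n_g0_prior >= b[1] & pr$n_g0_prior <= b[2]
    data.frame(bin = sprintf("%d-%d G0", b[1], b[2]), n = sum(in_bin),
               accuracy = if (any(in_bin))
                 mean(pr$call[in_bin] == pr$label[in_bin]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Overfitting gap
#'
#' Training-set accuracy minus held-out accuracy, in percentage points.
#'
#' @param model An `ev_rrf`.
#' @param train_X,train_y Training set.
#' @param test_X,test_y Held-out set.
#' @return Gap in percentage points.
#' @export
overfit_gap <- function(model, train_X, train_y, test_X, test_y) {
  acc_tr <- mean(predict(model, train_X)$call == train_y)
  acc_te <- mean(predict(model, test_X)$call == test_y)
  100 * (acc_tr - acc_te)
}
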