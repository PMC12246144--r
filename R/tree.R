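# Capped-split CART regression trees and a bagged ensemble.
#
# The rejection model is a small random-forest *regressor* on {0,1}
# labels: each tree is grown best-first (the split with the largest
# squared-error reduction anywhere on the frontier is taken next) up to a
# cap on the number of internal split nodes; leaf predictions are mean
# labels, so the ensemble mean is a probability-like coefficient in
# [0,1]. Implemented in-package: the split cap is the model's defining
# constraint and is not expressible in the usual tree libraries.

# Best split of rows `idx` of X on any feature; NULL if no gain.
best_split <- function(X, y, idx, min_leaf = 1L) {
  n <- length(idx)
  if (n < 2 * min_leaf) return(NULL)
  yy <- y[idx]
  sse0 <- sum(yy^2) - sum(yy)^2 / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]; ys <- yy[o]
    distinct <- which(diff(xs) > 0)   # split after position i
    if (length(distinct) == 0) next
    csum <- cumsum(ys); csq <- cumsum(ys^2)
    tot <- csum[n]
    nl <- distinct
    ok <- nl >= min_leaf & (n - nl) >= min_leaf
    if (!any(ok)) next
    nl <- nl[ok]
    # left SSE + right SSE = csq[n] - csum^2/nl - (tot-csum)^2/(n-nl)
    sse_split <- csq[n] - csum[nl]^2 / nl - (tot - csum[nl])^2 / (n - nl)
    gain <- sse0 - sse_split
    b <- which.max(gain)
    if (gain[b] > 1e-12 && (is.null(best) || gain[b] > best$gain)) {
      pos <- nl[b]
      best <- list(gain = gain[b], feature = j,
                   value = (xs[pos] + xs[pos + 1]) / 2,
                   left = idx[o[seq_len(pos)]],
                   right = idx[o[seq(pos + 1, n)]])
    }
  }
  best
}

# Fit one regression tree, best-first, <= max_splits internal nodes.
fit_tree <- function(X, y, max_splits = 10L, min_leaf = 1L) {
  nodes <- list(list(id = 1L, leaf = TRUE, pred = mean(y),
                     idx = seq_along(y), feature = NA, value = NA,
                     left = NA, right = NA))
  cand <- list()
  cand[1] <- list(best_split(X, y, nodes[[1]]$idx, min_leaf))
  n_splits <- 0L
  while (n_splits < max_splits) {
    gains <- vapply(seq_along(nodes), function(i) {
      if (nodes[[i]]$leaf && !is.null(cand[[i]])) cand[[i]]$gain else -Inf
    }, numeric(1))
    if (all(gains == -Inf)) break
    i <- which.max(gains)
    sp <- cand[[i]]
    li <- length(nodes) + 1L
    ri <- length(nodes) + 2L
    nodes[[li]] <- list(id = li, leaf = TRUE, pred = mean(y[sp$left]),
                        idx = sp$left, feature = NA, value = NA,
                        left = NA, right = NA)
    nodes[[ri]] <- list(id = ri, leaf = TRUE, pred = mean(y[sp$right]),
                        idx = sp$right, feature = NA, value = NA,
                        left = NA, right = NA)
    nodes[[i]]$leaf <- FALSE
    nodes[[i]]$feature <- sp$feature
    nodes[[i]]$value <- sp$value
    nodes[[i]]$left <- li
    nodes[[i]]$right <- ri
    cand[li] <- list(best_split(X, y, sp$left, min_leaf))
    cand[ri] <- list(best_split(X, y, sp$right, min_leaf))
    n_splits <- n_splits + 1L
  }
  for (i in seq_along(nodes)) nodes[[i]]$idx <- NULL
  nodes
}

predict_tree <- function(nodes, X) {
  n <- nrow(X)
  out <- numeric(n)
  node_of <- rep(1L, n)
  repeat {
    leaf <- vapply(node_of, function(i) nodes[[i]]$leaf, logical(1))
    if (all(leaf)) break
    for (i in unique(node_of[!leaf])) {
      rows <- which(node_of == i)
      nd <- nodes[[i]]
      go_left <- X[rows, nd$feature] <= nd$value
      node_of[rows[go_left]] <- nd$left
      node_of[rows[!go_left]] <- nd$right
    }
  }
  vapply(node_of, function(i) nodes[[i]]$pred, numeric(1))
}

# Bagged ensemble of capped regression trees.
fit_forest <- function(X, y, n_trees = 10L, max_splits = 10L, seed = 1L,
                       min_leaf = 1L) {
  X <- as.matrix(X)
  withr::with_seed(as.integer(seed), {
    trees <- lapply(seq_len(n_trees), function(t) {
      rows <- sample.int(nrow(X), nrow(X), replace = TRUE)
      fit_tree(X[rows, , drop = FALSE], y[rows], max_splits, min_leaf)
    })
  })
  structure(list(trees = trees, n_features = ncol(X)),
            class = "ev_forest")
}

predict_forest <- function(forest, X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == forest$n_features)
  preds <- vapply(forest$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  pmin(pmax(rowMeans(preds), 0), 1)
}
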