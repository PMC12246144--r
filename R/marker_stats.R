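# Differential-marker selection across rejection grades and single-marker
# diagnostics: trend test, ROC cutoffs, odds ratios, and the
# post-treatment response test.

#' Trend test of delta values across ordered grade groups
#'
#' Kruskal-Wallis rank test across the grade groups (default); a
#' Jonckheere-Terpstra-style ordered alternative (normal approximation
#' over a Mann-Whitney U sum) is available behind `ordered_alternative`.
#'
#' @param values_by_grade Named list, one numeric vector of delta
#'   percentages per grade group, in increasing grade order.
#' @param ordered_alternative Use the ordered (one-sided increasing)
#'   Jonckheere-style statistic instead of Kruskal-Wallis.
#' @return P-value.
#' @export
grade_trend_test <- function(values_by_grade, ordered_alternative = FALSE) {
  values_by_grade <- values_by_grade[lengths(values_by_grade) > 0]
  if (length(values_by_grade) < 2)
    stop("need at least 2 non-empty grade groups")
  x <- unlist(values_by_grade, use.names = FALSE)
  g <- factor(rep(seq_along(values_by_grade), lengths(values_by_grade)))
  if (!ordered_alternative)
    return(stats::kruskal.test(x, g)$p.value)
  # Jonckheere-Terpstra: sum of pairwise Mann-Whitney U statistics for
  # all ordered group pairs, normal approximation (no tie correction)
  k <- length(values_by_grade)
  n_i <- lengths(values_by_grade)
  J <- 0
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    xa <- values_by_grade[[a]]; xb <- values_by_grade[[b]]
    J <- J + sum(outer(xb, xa, ">")) + 0.5 * sum(outer(xb, xa, "=="))
  }
  N <- sum(n_i)
  mu <- (N^2 - sum(n_i^2)) / 4
  sigma2 <- (N^2 * (2 * N + 3) - sum(n_i^2 * (2 * n_i + 3))) / 72
  stats::pnorm((J - mu) / sqrt(sigma2), lower.tail = FALSE)
}

#' Select differentially expressed markers
#'
#' Tests each panel marker's retrospective G0-delta across the four
#' ordered grade groups (0, 1A/B, 2, 3A; the first post-transplant
#' sample excluded) and selects markers whose Bonferroni-adjusted trend
#' p-value is below `alpha`.
#'
#' @param cohort An `ev_cohort` with immuno-capture (37-antigen) rows.
#' @param alpha Family-wise significance level (default 0.05).
#' @param normalized Optional precomputed [normalize_cohort()]
#'   retrospective output, to avoid recomputation.
#' @param protocol Protocol whose panel is screened.
#' @return Character vector of selected marker ids, with the per-marker
#'   p-value table in attribute `"table"`.
#' @export
select_markers <- function(cohort, alpha = 0.05, normalized = NULL,
                           protocol = "IMMUNO") {
  if (is.null(normalized)) normalized <- normalize_cohort(cohort, "retrospective")
  norm <- normalized[normalized$protocol == protocol &
                       normalized$visit_index >= 1L, , drop = FALSE]
  markers <- ev_panel(protocol)
  grp <- ifelse(norm$grade == "0", "G0",
                ifelse(norm$grade %in% c("1A", "1B"), "G1AB", norm$grade))
  grp <- factor(grp, levels = c("G0", "G1AB", "2", "3A"))
  pvals <- vapply(markers, function(m) {
    d <- norm[[paste0("delta_", m)]]
    keep <- !is.na(d)
    grade_trend_test(split(d[keep], grp[keep], drop = TRUE))
  }, numeric(1))
  p_adj <- pmin(pvals * length(markers), 1)
  selected <- markers[p_adj < alpha]
  attr(selected, "table") <- data.frame(
    marker = markers, trend_p = unname(pvals), trend_p_bonferroni =
      unname(p_adj), selected = markers %in% selected,
    stringsAsFactors = FALSE)
  selected
}

# Rank-based AUC with midrank tie handling (Mann-Whitney form).
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-marker ROC analysis
#'
#' AUC by rank concordance, the Youden-optimal cutoff (ties broken toward
#' the higher cutoff, i.e. higher specificity under the ">= cutoff calls
#' positive" rule), and a stratified-bootstrap percentile CI for the AUC.
#'
#' @param deltas Numeric vector of delta percentages.
#' @param labels Binary labels (1 = grade 2-3A).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @return List: `auc`, `auc_ci`, `cutoff`, `sensitivity`, `specificity`.
#' @export
single_marker_roc <- function(deltas, labels, n_boot = 2000, seed = 1L) {
  keep <- !is.na(deltas) & !is.na(labels)
  deltas <- deltas[keep]; labels <- as.integer(labels[keep])
  if (length(unique(labels)) < 2) stop("both classes must be present")
  auc <- auc_rank(deltas, labels)

  cuts <- sort(unique(deltas))
  sens <- vapply(cuts, function(c) mean(deltas[labels == 1] >= c), 0)
  spec <- vapply(cuts, function(c) mean(deltas[labels == 0] < c), 0)
  j <- sens + spec - 1
  best <- max(which(j == max(j)))   # largest cutoff among ties
  pos <- which(labels == 1); neg <- which(labels == 0)
  boot <- withr::with_seed(as.integer(seed), vapply(seq_len(n_boot),
    function(b) {
      i <- c(sample(pos, length(pos), TRUE), sample(neg, length(neg), TRUE))
      auc_rank(deltas[i], labels[i])
    }, numeric(1)))
  list(auc = auc,
       auc_ci = unname(stats::quantile(boot, c(0.025, 0.975))),
       cutoff = cuts[best],
       sensitivity = sens[best],
       specificity = spec[best])
}

# logistic fit with separation detection; returns OR scale estimates
logistic_or <- function(formula, data, term) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- stats::fitted(fit)
  separated <- warned || any(p > 1 - 1e-8) || any(p < 1e-8)
  b <- stats::coef(fit)[term]
  se <- sqrt(diag(stats::vcov(fit)))[term]
  if (separated)
    warning("possible complete separation: odds ratio unreliable")
  list(or = exp(unname(b)),
       ci = if (separated) c(NA_real_, NA_real_)
            else exp(unname(b) + c(-1, 1) * 1.96 * unname(se)),
       separated = separated)
}

#' Univariate odds ratio per 1% delta increase
#'
#' Logistic regression of the grade 2-3A endpoint on a marker's delta
#' percentage; the odds ratio is the increase in rejection odds per one
#' percentage-point increase over the patient's grade-0 baseline.
#'
#' @param deltas Delta percentages.
#' @param labels Binary labels.
#' @return List: `or_per_pct`, `or_ci`, `separated`.
#' @export
univariate_or <- function(deltas, labels) {
  keep <- !is.na(deltas) & !is.na(labels)
  df <- data.frame(y = as.integer(labels[keep]), d = deltas[keep])
  if (length(unique(df$y)) < 2) stop("both classes must be present")
  r <- logistic_or(y ~ d, df, "d")
  list(or_per_pct = r$or, or_ci = r$ci, separated = r$separated)
}

#' Therapy-adjusted odds ratio
#'
#' As [univariate_or()], with the immunosuppressive regimen
#' (cyclosporine- vs tacrolimus-based) as a covariate.
#'
#' @param deltas Delta percentages.
#' @param labels Binary labels.
#' @param therapy Character vector, `"CSA"` or `"TAC"` per visit.
#' @return List: `adjusted_or`, `or_ci`, `separated`.
#' @export
multivariate_or <- function(deltas, labels, therapy) {
  keep <- !is.na(deltas) & !is.na(labels) & !is.na(therapy)
  df <- data.frame(y = as.integer(labels[keep]), d = deltas[keep],
                   tac = as.integer(therapy[keep] == "TAC"))
  if (length(unique(df$y)) < 2) stop("both classes must be present")
  if (length(unique(df$tac)) < 2) stop("both regimens must be present")
  r <- logistic_or(y ~ d + tac, df, "d")
  list(adjusted_or = r$or, or_ci = r$ci, separated = r$separated)
}

#' Post-treatment response test
#'
#' One-sided Wilcoxon signed-rank test that a marker's delta decreases
#' from the grade 2-3A visit to the first visit after the therapy
#' adjustment.
#'
#' @param pre_post_pairs Two-column matrix or data frame
#'   (`delta_before`, `delta_after`), one row per episode.
#' @return One-sided p-value for a decrease.
#' @export
treatment_response_test <- function(pre_post_pairs) {
  pairs <- as.matrix(pre_post_pairs)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3) stop("insufficient data: need >= 3 pairs")
  stats::wilcox.test(pairs[, 1], pairs[, 2], paired = TRUE,
                     alternative = "greater")$p.value
}

# (before, after) delta pairs for one marker: each grade 2-3A visit paired
# with the patient's first subsequent therapy-adjusted visit.
treatment_pairs <- function(cohort, normalized, marker,
                            protocol = unique(normalized$protocol)[1]) {
  norm <- normalized[normalized$protocol == protocol, , drop = FALSE]
  coh <- as.data.frame(cohort)[cohort$protocol == protocol, , drop = FALSE]
  dcol <- paste0("delta_", marker)
  out <- NULL
  for (pid in unique(coh$patient_id)) {
    s <- coh[coh$patient_id == pid, , drop = FALSE]
    s <- s[order(s$visit_index), , drop = FALSE]
    ns <- norm[norm$patient_id == pid, , drop = FALSE]
    ns <- ns[order(ns$visit_index), , drop = FALSE]
    ep <- which(s$grade %in% c("2", "3A"))
    for (i in ep) {
      after <- which(s$visit_index > s$visit_index[i] &
                       s$therapy_adjusted == 1L)
      if (length(after) == 0) next
      out <- rbind(out, c(ns[[dcol]][i], ns[[dcol]][min(after)]))
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("delta_before", "delta_after")
  out
}

#' Per-marker differential and diagnostic summary table
#'
#' Assembles, for each marker of a protocol's panel: the grade trend
#' p-value (raw and Bonferroni-adjusted), selection flag, ROC summary
#' (AUC with bootstrap CI, Youden cutoff, sensitivity/specificity),
#' univariate and therapy-adjusted odds ratios per 1% delta, and the
#' post-treatment decrease p-value.
#'
#' @param cohort An `ev_cohort` (exclusions applied).
#' @param protocol Protocol panel to summarize.
#' @param alpha Selection significance level.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param seed Integer seed.
#' @return Data frame, one row per marker.
#' @export
marker_stat_table <- function(cohort, protocol = "IMMUNO", alpha = 0.05,
                              n_boot = 2000, seed = 1L) {
  normalized <- normalize_cohort(cohort, "retrospective")
  sel <- select_markers(cohort, alpha, normalized, protocol)
  norm <- normalized[normalized$protocol == protocol &
                       normalized$visit_index >= 1L, , drop = FALSE]
  labels <- binary_label(norm$grade)
  coh <- as.data.frame(cohort)
  key <- paste(coh$patient_id, coh$visit_index, coh$protocol)
  therapy <- coh$therapy[match(
    paste(norm$patient_id, norm$visit_index, norm$protocol), key)]
  seltab <- attr(sel, "table")
  rows <- lapply(seq_len(nrow(seltab)), function(i) {
    m <- seltab$marker[i]
    d <- norm[[paste0("delta_", m)]]
    keep <- !is.na(d)
    roc <- single_marker_roc(d[keep], labels[keep], n_boot, seed)
    uni <- suppressWarnings(univariate_or(d[keep], labels[keep]))
    mult <- suppressWarnings(
      multivariate_or(d[keep], labels[keep], therapy[keep]))
    pairs <- treatment_pairs(cohort, normalized, m, protocol)
    tr_p <- if (nrow(pairs) >= 3) treatment_response_test(pairs) else NA_real_
    data.frame(marker = m, trend_p = seltab$trend_p[i],
               trend_p_bonferroni = seltab$trend_p_bonferroni[i],
               selected = seltab$selected[i],
               auc = roc$auc, auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
               cutoff = roc$cutoff, sensitivity = roc$sensitivity,
               specificity = roc$specificity,
               or_per_pct = uni$or_per_pct,
               or_lo = uni$or_ci[1], or_hi = uni$or_ci[2],
               adjusted_or = mult$adjusted_or,
               treatment_p = tr_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
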