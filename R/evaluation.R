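# Confusion metrics, ROC curves, grade-stratified summaries, and
# Bland-Altman inter-protocol agreement.

#' Confusion metrics from binary calls and labels
#'
#' @param calls Binary calls.
#' @param labels Binary reference labels.
#' @return List of class `ev_confusion`: counts `tp`, `fp`, `tn`, `fn`
#'   and proportions `sensitivity`, `specificity`, `accuracy`, `ppv`,
#'   `npv`. Ratios with a zero denominator are `NA` and named in
#'   `undefined` (never silently coerced to 0).
#' @export
confusion_metrics <- function(calls, labels) {
  if (length(calls) == 0 || length(calls) != length(labels))
    stop("calls and labels must be non-empty and of equal length")
  calls <- as.integer(calls); labels <- as.integer(labels)
  stopifnot(all(calls %in% 0:1), all(labels %in% 0:1))
  tp <- sum(calls == 1 & labels == 1)
  fp <- sum(calls == 1 & labels == 0)
  tn <- sum(calls == 0 & labels == 0)
  fn <- sum(calls == 0 & labels == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              accuracy = (tp + tn) / length(calls),
              ppv = ratio(tp, tp + fp),
              npv = ratio(tn, tn + fn))
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  class(out) <- "ev_confusion"
  out
}

#' @export
print.ev_confusion <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sens=%.3f spec=%.3f acc=%.3f ppv=%.3f npv=%.3f\n",
              x$sensitivity, x$specificity, x$accuracy, x$ppv, x$npv))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve with bootstrap AUC interval
#'
#' AUC via the rank (Mann-Whitney) statistic with midrank tie handling;
#' 95% CI by stratified bootstrap (resampling within each class).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @return List of class `ev_roc`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `auc_ci`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  auc <- auc_rank(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  pos <- which(labels == 1); neg <- which(labels == 0)
  boot <- withr::with_seed(as.integer(seed), vapply(seq_len(n_boot),
    function(b) {
      i <- c(sample(pos, n1, TRUE), sample(neg, n0, TRUE))
      auc_rank(scores[i], labels[i])
    }, numeric(1)))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 auc_ci = unname(stats::quantile(boot, c(0.025, 0.975)))),
            class = "ev_roc")
}

#' Grade-stratified marker summary
#'
#' Median and interquartile range of nMFI and delta per time-point class
#' and marker (classes: after surgery, grade 0, 1A/B, pre-1A/B, 2-3A,
#' pre-2-3A).
#'
#' @param cohort An `ev_cohort`.
#' @param normalized Output of [normalize_cohort()] for the same cohort.
#' @param protocol Protocol rows to summarize.
#' @param markers Markers to include (default the protocol panel).
#' @return Long data frame: `timepoint`, `marker`, `n`, `nmfi_median`,
#'   `nmfi_q1`, `nmfi_q3`, `delta_median`, `delta_q1`, `delta_q3`.
#' @export
stratified_summary <- function(cohort, normalized, protocol = "IMMUNO",
                               markers = ev_panel(protocol)) {
  norm <- normalized[normalized$protocol == protocol, , drop = FALSE]
  rows <- list()
  for (cls in TIMEPOINT_CLASSES) {
    sub <- norm[norm$timepoint == cls, , drop = FALSE]
    for (m in markers) {
      nm <- sub[[paste0("nmfi_", m)]]
      dl <- sub[[paste0("delta_", m)]]
      q <- function(x, p) if (all(is.na(x))) NA_real_ else
        unname(stats::quantile(x, p, na.rm = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = cls, marker = m, n = nrow(sub),
        nmfi_median = q(nm, 0.5), nmfi_q1 = q(nm, 0.25),
        nmfi_q3 = q(nm, 0.75),
        delta_median = q(dl, 0.5), delta_q1 = q(dl, 0.25),
        delta_q3 = q(dl, 0.75), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bland-Altman agreement between paired protocols
#'
#' Per-pair percentage difference `100 * (msp - immuno) / mean(pair)`;
#' reports the mean bias with limits of agreement (mean +/- 1.96 sd) and
#' a normal CI for the mean, plus linear and quadratic correlation
#' coefficients between the paired values, and the mean bias
#' back-converted to a ratio overestimation percentage via
#' ratio = (200 + d) / (200 - d).
#'
#' @param immuno,msp Positive paired measurement vectors.
#' @return List of class `ev_bland_altman`: `mean_pct_bias`, `bias_ci`,
#'   `limits_of_agreement`, `overestimation_pct`, `r_linear`,
#'   `r_quadratic`, `n`.
#' @export
bland_altman <- function(immuno, msp) {
  keep <- !is.na(immuno) & !is.na(msp)
  immuno <- immuno[keep]; msp <- msp[keep]
  if (length(immuno) < 3) stop("need >= 3 pairs")
  if (any(immuno <= 0) || any(msp <= 0)) stop("values must be positive")
  d <- 100 * 2 * (msp - immuno) / (msp + immuno)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  r_lin <- stats::cor(immuno, msp)
  # exact-ratio pairs give a perfect quadratic fit; that is fine here
  r_quad <- sqrt(max(suppressWarnings(summary(
    stats::lm(msp ~ immuno + I(immuno^2)))$r.squared), 0))
  structure(list(
    mean_pct_bias = bias,
    bias_ci = bias + c(-1, 1) * 1.96 * sd_d / sqrt(length(d)),
    limits_of_agreement = bias + c(-1.96, 1.96) * sd_d,
    overestimation_pct = 100 * ((200 + bias) / (200 - bias) - 1),
    r_linear = r_lin, r_quadratic = r_quad, n = length(d)),
    class = "ev_bland_altman")
}

#' @export
print.ev_bland_altman <- function(x, ...) {
  cat(sprintf(paste0("Bland-Altman: bias %.2f%% [%.2f, %.2f], ",
                     "LoA [%.2f, %.2f], n=%d\n"),
              x$mean_pct_bias, x$bias_ci[1], x$bias_ci[2],
              x$limits_of_agreement[1], x$limits_of_agreement[2], x$n))
  invisible(x)
}

# Paired antigen nMFI values between a cohort's IMMUNO and MSP rows.
paired_nmfi <- function(cohort, markers = ev_affected_markers()) {
  norm <- normalize_cohort(cohort, "retrospective")
  imm <- norm[norm$protocol == "IMMUNO", , drop = FALSE]
  msp <- norm[norm$protocol == "MSP", , drop = FALSE]
  key_i <- paste(imm$patient_id, imm$visit_index)
  key_m <- paste(msp$patient_id, msp$visit_index)
  common <- intersect(key_i, key_m)
  imm <- imm[match(common, key_i), , drop = FALSE]
  msp <- msp[match(common, key_m), , drop = FALSE]
  data.frame(
    immuno = unlist(imm[paste0("nmfi_", markers)], use.names = FALSE),
    msp = unlist(msp[paste0("nmfi_", markers)], use.names = FALSE))
}
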