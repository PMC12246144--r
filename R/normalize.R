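# Tetraspanin normalization and patient-specific grade-0 delta statistics.
#
# Every marker's MFI is divided by the mean of the three tetraspanin MFIs
# of the same sample (nMFI), removing per-sample capture/instrument scale.
# The G0-delta then expresses a marker's nMFI as a percentage variation
# relative to that patient's median nMFI over their own grade-0 visits —
# retrospectively (all follow-up, used for cohort-level statistics) or
# causally (only visits before the time point of evaluation, the
# dynamically adaptive reference used at prediction time). The first
# post-transplant sample is excluded from reference pools: surgery itself
# perturbs circulating EV subpopulations.

#' Tetraspanin-normalized intensities for one visit
#'
#' @param visit Named numeric vector (or one-row data frame) of MFIs
#'   including CD9, CD63 and CD81.
#' @return Named numeric vector of nMFI values (tetraspanins included,
#'   normalized by the same mean).
#' @export
compute_nmfi <- function(visit) {
  if (is.data.frame(visit)) {
    stopifnot(nrow(visit) == 1)
    cols <- intersect(names(visit), ev_all_marker_columns())
    visit <- unlist(visit[1, cols, drop = FALSE])
  }
  tets <- ev_tetraspanins()
  if (!all(tets %in% names(visit)) || anyNA(visit[tets]))
    stop("tetraspanin MFIs missing")
  denom <- mean(visit[tets])
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate input: tetraspanin mean is not positive")
  visit / denom
}

#' Percentage variation relative to a reference
#'
#' @param nmfi_value nMFI value(s).
#' @param reference Positive reference nMFI (patient G0 median).
#' @return `(nmfi_value / reference - 1) * 100`.
#' @export
delta_percent <- function(nmfi_value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("degenerate input: reference must be > 0")
  (nmfi_value / reference - 1) * 100
}

# nMFI matrix (visits x markers) for one patient's single-protocol rows,
# ordered by visit_index; markers limited to the protocol panel.
patient_nmfi_matrix <- function(series) {
  series <- series[order(series$visit_index), , drop = FALSE]
  cols <- ev_marker_columns(series$protocol[1])
  mfi <- as.matrix(series[cols])
  denom <- rowMeans(mfi[, ev_tetraspanins(), drop = FALSE])
  if (any(denom <= 0)) stop("degenerate input: non-positive tetraspanin mean")
  sweep(mfi, 1, denom, `/`)
}

#' Patient-specific grade-0 reference for one marker
#'
#' Median nMFI over the patient's grade-0 visits in scope, excluding the
#' first post-transplant sample. In causal mode only visits strictly
#' before `upto_index` qualify; in retrospective mode all visits do.
#'
#' @param series One patient's visit rows (single protocol).
#' @param marker Marker id.
#' @param mode `"retrospective"` or `"causal"`.
#' @param upto_index Evaluation visit index (required in causal mode).
#' @return The reference nMFI, or `NA` if no qualifying grade-0 visit.
#' @export
g0_reference <- function(series, marker,
                         mode = c("retrospective", "causal"),
                         upto_index = NULL) {
  mode <- match.arg(mode)
  nmfi <- patient_nmfi_matrix(series)
  idx <- sort(series$visit_index)
  ok <- series$grade[order(series$visit_index)] == "0" & idx >= 1L
  if (mode == "causal") {
    stopifnot(!is.null(upto_index))
    ok <- ok & idx < upto_index
  }
  if (!any(ok)) return(NA_real_)
  stats::median(nmfi[ok, marker])
}

#' Normalize a cohort
#'
#' Computes nMFI and G0-delta percentages for every visit and panel
#' marker, per protocol. A visit is `evaluable` when at least `min_g0`
#' grade-0 visits back its reference (two, by default — the model only
#' predicts once a patient baseline is minimally established).
#'
#' @param cohort An `ev_cohort` (exclusions applied).
#' @param mode `"retrospective"` (reference over the whole follow-up) or
#'   `"causal"` (reference restricted to earlier visits).
#' @param min_g0 Minimum qualifying grade-0 visits for evaluability.
#' @return Data frame with `patient_id`, `visit_index`, `protocol`,
#'   `grade`, `timepoint`, `mode`, `n_g0_prior`, `evaluable`, then
#'   `nmfi_<marker>` and `delta_<marker>` columns (delta is `NA` where no
#'   reference exists).
#' @export
normalize_cohort <- function(cohort, mode = c("retrospective", "causal"),
                             min_g0 = 2L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "ev_cohort"))
  out <- list()
  for (prot in unique(cohort$protocol)) {
    sub <- as.data.frame(cohort)[cohort$protocol == prot, , drop = FALSE]
    markers <- ev_marker_columns(prot)
    for (pid in unique(sub$patient_id)) {
      series <- sub[sub$patient_id == pid, , drop = FALSE]
      series <- series[order(series$visit_index), , drop = FALSE]
      nmfi <- patient_nmfi_matrix(series)
      v <- nrow(series)
      g0_ok <- series$grade == "0" & series$visit_index >= 1L

      delta <- matrix(NA_real_, nrow = v, ncol = length(markers),
                      dimnames = list(NULL, markers))
      n_g0 <- integer(v)
      ref_retro <- if (any(g0_ok))
        apply(nmfi[g0_ok, , drop = FALSE], 2, stats::median)
      for (i in seq_len(v)) {
        if (mode == "causal") {
          scope <- g0_ok & series$visit_index < series$visit_index[i]
          n_g0[i] <- sum(scope)
          if (n_g0[i] > 0) {
            ref <- apply(nmfi[scope, , drop = FALSE], 2, stats::median)
            delta[i, ] <- (nmfi[i, ] / ref - 1) * 100
          }
        } else {
          n_g0[i] <- sum(g0_ok)
          if (n_g0[i] > 0) delta[i, ] <- (nmfi[i, ] / ref_retro - 1) * 100
        }
      }
      res <- data.frame(patient_id = pid,
                        visit_index = series$visit_index,
                        protocol = prot,
                        grade = series$grade,
                        timepoint = as.character(
                          classify_grade_sequence(series$grade)),
                        mode = mode,
                        n_g0_prior = n_g0,
                        evaluable = n_g0 >= min_g0,
                        stringsAsFactors = FALSE, check.names = FALSE)
      colnames(nmfi) <- paste0("nmfi_", markers)
      colnames(delta) <- paste0("delta_", markers)
      out[[length(out) + 1]] <- cbind(res, nmfi, delta)
    }
  }
  res <- rbind_fill(out)
  rownames(res) <- NULL
  res
}

# rbind data frames with differing columns (missing ones filled with NA);
# needed when a cohort mixes protocols with different panel widths
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA_real_
    d[cols]
  }))
}

#' Write normalized output CSV
#'
#' @param normalized Output of [normalize_cohort()].
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_normalized <- function(normalized, path) {
  utils::write.csv(normalized, path, row.names = FALSE, na = "")
  invisible(path)
}
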