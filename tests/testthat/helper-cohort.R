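# Fixtures built in code: tiny hand-made cohorts and small generator
# configurations used across the suite.

# Minimal valid visit row; markers default to the full IMMUNO panel at a
# constant MFI with tetraspanins at 100.
toy_row <- function(patient_id, visit_index, day, grade,
                    amr = 0L, therapy = "CSA", therapy_adjusted = 0L,
                    protocol = "IMMUNO", mfi = NULL) {
  row <- data.frame(patient_id = patient_id, visit_index = visit_index,
                    day = day, grade = grade, amr = amr, therapy = therapy,
                    therapy_adjusted = therapy_adjusted,
                    protocol = protocol, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cols <- ev_marker_columns(protocol)
  vals <- stats::setNames(rep(50, length(cols)), cols)
  vals[ev_tetraspanins()] <- 100
  if (!is.null(mfi)) vals[names(mfi)] <- mfi
  for (m in names(vals)) row[[m]] <- vals[[m]]
  row
}

# Cohort from per-patient grade sequences, e.g. list(P1 = c("0","0","2")).
toy_cohort <- function(grade_seqs, ...) {
  rows <- list()
  for (pid in names(grade_seqs)) {
    g <- grade_seqs[[pid]]
    for (i in seq_along(g))
      rows[[length(rows) + 1]] <-
        toy_row(pid, i - 1L, 7L + 28L * (i - 1L), g[i], ...)
  }
  as_ev_cohort(do.call(rbind, rows))
}

# Small fast generator config: fewer patients, same structure.
small_config <- function(n_patients = 6L) default_config(n_patients)

# Brute-force AUC: fraction of (positive, negative) pairs ranked
# concordantly, ties counted half. Independent of the package's rank
# implementation.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Naive spreadsheet-style recomputation of nMFI and deltas for one
# patient: explicit loops and sorting only.
naive_patient_deltas <- function(series, mode, min_g0 = 2L) {
  series <- series[order(series$visit_index), , drop = FALSE]
  markers <- ev_marker_columns(series$protocol[1])
  nmfi <- matrix(NA_real_, nrow(series), length(markers),
                 dimnames = list(NULL, markers))
  for (i in seq_len(nrow(series))) {
    tet <- (series$CD9[i] + series$CD63[i] + series$CD81[i]) / 3
    for (m in markers) nmfi[i, m] <- series[[m]][i] / tet
  }
  med <- function(x) {   # midpoint-of-central-values median
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  delta <- matrix(NA_real_, nrow(series), length(markers),
                  dimnames = list(NULL, markers))
  n_g0 <- integer(nrow(series))
  for (i in seq_len(nrow(series))) {
    in_scope <- which(series$grade == "0" & series$visit_index >= 1 &
                        (if (mode == "causal")
                           series$visit_index < series$visit_index[i]
                         else TRUE))
    n_g0[i] <- length(in_scope)
    if (length(in_scope) > 0)
      for (m in markers)
        delta[i, m] <- 100 * (nmfi[i, m] / med(nmfi[in_scope, m]) - 1)
  }
  list(nmfi = nmfi, delta = delta, n_g0 = n_g0,
       evaluable = n_g0 >= min_g0)
}
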