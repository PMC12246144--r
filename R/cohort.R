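# Longitudinal cohort container: one row per visit per protocol, with
# per-visit metadata and raw MFI columns. Grades follow the ISHLT scale
# 0 < 1A < 1B < 2 < 3A; grades 1A/1B and 2/3A are grouped for analysis.

GRADE_LEVELS <- c("0", "1A", "1B", "2", "3A")

META_COLUMNS <- c("patient_id", "visit_index", "day", "grade", "amr",
                  "therapy", "therapy_adjusted", "protocol")

TIMEPOINT_CLASSES <- c("AFTER_SURGERY", "G0", "G1AB", "PRE_1AB",
                       "G23A", "PRE_23A")

#' Ordered rejection grade factor
#'
#' @param x Character vector of grades among `"0"`, `"1A"`, `"1B"`, `"2"`,
#'   `"3A"`.
#' @return Ordered factor with the five ISHLT levels.
#' @export
ev_grade <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), GRADE_LEVELS)
  if (length(bad) > 0)
    stop("unknown grade value(s): ", paste(bad, collapse = ", "))
  factor(x, levels = GRADE_LEVELS, ordered = TRUE)
}

#' Collapse grades into analysis groups
#'
#' Grades 1A and 1B are merged ("1A/B"), as are 2 and 3A ("2-3A"),
#' mirroring how rejection episodes are managed clinically.
#'
#' @param grade Character or factor vector of grades.
#' @return Factor with levels `G0`, `G1AB`, `G23A`.
#' @export
grade_group <- function(grade) {
  grade <- as.character(grade)
  out <- ifelse(grade == "0", "G0",
                ifelse(grade %in% c("1A", "1B"), "G1AB", "G23A"))
  factor(out, levels = c("G0", "G1AB", "G23A"))
}

#' Binary rejection endpoint
#'
#' The modelled endpoint is grade 2-3A rejection versus grade 0-1A/B.
#'
#' @param grade Character or factor vector of grades.
#' @return Integer vector: 1 for grades 2/3A, 0 otherwise.
#' @export
binary_label <- function(grade) {
  as.integer(as.character(grade) %in% c("2", "3A"))
}

#' Construct a cohort from a per-visit data frame
#'
#' Validates the schema (metadata columns, known marker columns, grade
#' values, per-patient visit ordering, tetraspanin completeness,
#' non-negative MFI) and returns the rows sorted by
#' (patient_id, day, protocol).
#'
#' @param df Data frame with the metadata columns `patient_id`,
#'   `visit_index`, `day`, `grade`, `amr`, `therapy`, `therapy_adjusted`,
#'   `protocol`, followed by marker MFI columns.
#' @return An `ev_cohort` (a validated, sorted data frame).
#' @export
as_ev_cohort <- function(df) {
  missing_meta <- setdiff(META_COLUMNS, names(df))
  if (length(missing_meta) > 0)
    stop("schema error: missing required column(s): ",
         paste(missing_meta, collapse = ", "))
  marker_cols <- setdiff(names(df), META_COLUMNS)
  unknown <- setdiff(marker_cols, ev_all_marker_columns())
  if (length(unknown) > 0)
    stop("schema error: unknown marker column(s): ",
         paste(unknown, collapse = ", "))
  missing_tet <- setdiff(ev_tetraspanins(), marker_cols)
  if (length(missing_tet) > 0)
    stop("schema error: missing tetraspanin column(s): ",
         paste(missing_tet, collapse = ", "))

  df$patient_id <- as.character(df$patient_id)
  df$visit_index <- as.integer(df$visit_index)
  df$day <- as.integer(df$day)
  df$grade <- as.character(ev_grade(df$grade))
  df$amr <- as.integer(df$amr)
  df$therapy <- as.character(df$therapy)
  df$therapy_adjusted <- as.integer(df$therapy_adjusted)
  df$protocol <- as.character(df$protocol)
  bad_prot <- setdiff(unique(df$protocol), c("IMMUNO", "MSP"))
  if (length(bad_prot) > 0)
    stop("validation error: unknown protocol value(s): ",
         paste(bad_prot, collapse = ", "))
  bad_ther <- setdiff(unique(df$therapy), c("CSA", "TAC"))
  if (length(bad_ther) > 0)
    stop("validation error: unknown therapy value(s): ",
         paste(bad_ther, collapse = ", "))
  for (m in marker_cols) {
    df[[m]] <- as.numeric(df[[m]])
    if (any(df[[m]] < 0, na.rm = TRUE))
      stop("validation error: negative MFI in column ", m)
  }

  df <- df[order(df$patient_id, df$day, df$protocol), , drop = FALSE]
  rownames(df) <- NULL

  key <- paste(df$patient_id, df$day, df$protocol)
  if (anyDuplicated(key))
    stop("validation error: duplicated (patient_id, day, protocol) row")

  for (pp in split(df, paste(df$patient_id, df$protocol))) {
    if (is.unsorted(pp$day, strictly = TRUE))
      stop("validation error: non-monotone days for patient ",
           pp$patient_id[1])
    if (!identical(sort(pp$visit_index), seq_len(nrow(pp)) - 1L))
      stop("validation error: visit_index not consecutive from 0 for patient ",
           pp$patient_id[1])
    panel_cols <- ev_marker_columns(pp$protocol[1])
    for (m in panel_cols) {
      if (!m %in% names(pp) || anyNA(pp[[m]]))
        stop("validation error: protocol ", pp$protocol[1],
             " rows for patient ", pp$patient_id[1],
             " missing MFI for panel marker ", m)
    }
  }

  class(df) <- c("ev_cohort", "data.frame")
  df
}

#' @export
print.ev_cohort <- function(x, ...) {
  cat(sprintf("ev_cohort: %d patients, %d visit rows (%s)\n",
              length(unique(x$patient_id)), nrow(x),
              paste(unique(x$protocol), collapse = "+")))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `ev_cohort`.
#' @return Integer patient count (the N of leave-one-patient-out).
#' @export
n_patients <- function(cohort) length(unique(cohort$patient_id))

#' Read a cohort CSV
#'
#' Expects the canonical schema: metadata columns then marker MFI columns,
#' one row per visit per protocol, empty cells for markers outside a
#' protocol's panel.
#'
#' @param path File path of the CSV.
#' @return An `ev_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(patient_id = "character"),
                        stringsAsFactors = FALSE)
  as_ev_cohort(df)
}

#' Write a cohort CSV
#'
#' Marker values are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort An `ev_cohort`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ev_cohort"))
  out <- as.data.frame(cohort)
  for (m in setdiff(names(out), META_COLUMNS)) {
    v <- out[[m]]
    out[[m]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Remove excluded visits (antibody-mediated rejection)
#'
#' Visits flagged as AMR are removed (AMR is a distinct rejection form,
#' outside the modelled endpoint); remaining visits are re-indexed
#' consecutively per patient and protocol. Patients left without visits
#' are dropped and noted.
#'
#' @param cohort An `ev_cohort`.
#' @return List with elements `cohort` (filtered) and `report`
#'   (data frame `patient_id`, `visit_index`, `reason`).
#' @export
apply_exclusions <- function(cohort) {
  stopifnot(inherits(cohort, "ev_cohort"))
  flagged <- cohort$amr == 1L
  report <- data.frame(patient_id = cohort$patient_id[flagged],
                       visit_index = cohort$visit_index[flagged],
                       reason = rep("AMR", sum(flagged)),
                       stringsAsFactors = FALSE)
  kept <- as.data.frame(cohort)[!flagged, , drop = FALSE]
  dropped <- setdiff(unique(cohort$patient_id), unique(kept$patient_id))
  if (length(dropped) > 0)
    report <- rbind(report, data.frame(
      patient_id = dropped, visit_index = NA_integer_,
      reason = "patient dropped (no remaining visits)",
      stringsAsFactors = FALSE))
  # re-index visits consecutively within each (patient, protocol)
  if (nrow(kept) > 0) {
    kept <- kept[order(kept$patient_id, kept$day, kept$protocol), ,
                 drop = FALSE]
    grp <- paste(kept$patient_id, kept$protocol)
    kept$visit_index <- stats::ave(seq_len(nrow(kept)), grp,
                                   FUN = function(i) seq_along(i) - 1L)
    kept$visit_index <- as.integer(kept$visit_index)
  }
  list(cohort = as_ev_cohort(kept), report = report)
}

# Vectorized time-point classification over a patient's grade sequence
# (single protocol). The first sample after transplant is its own class;
# a visit immediately preceding a grade 2-3A diagnosis is PRE_23A unless
# it is itself grade 2-3A; a grade-0 visit immediately preceding a 1A/B
# diagnosis is PRE_1AB; otherwise the visit's own grade group applies.
classify_grade_sequence <- function(grades) {
  grades <- as.character(grades)
  n <- length(grades)
  if (n == 0) return(character(0))
  own <- as.character(grade_group(grades))
  nxt <- c(grades[-1], NA)
  cls <- own
  pre23 <- !is.na(nxt) & nxt %in% c("2", "3A") & own != "G23A"
  pre1ab <- !pre23 & !is.na(nxt) & nxt %in% c("1A", "1B") & grades == "0"
  cls[pre23] <- "PRE_23A"
  cls[pre1ab] <- "PRE_1AB"
  cls[own == "G23A"] <- "G23A"   # own 2-3A diagnosis outranks pre-status
  cls[1] <- "AFTER_SURGERY"
  factor(cls, levels = TIMEPOINT_CLASSES)
}

#' Classify a visit's time point
#'
#' @param series Data frame of one patient's visits (single protocol),
#'   ordered by `visit_index`.
#' @param index 0-based visit index to classify.
#' @return One of `AFTER_SURGERY`, `G0`, `G1AB`, `PRE_1AB`, `G23A`,
#'   `PRE_23A`.
#' @export
classify_timepoint <- function(series, index) {
  grades <- series$grade[order(series$visit_index)]
  if (index < 0 || index >= length(grades))
    stop("index out of range: ", index)
  as.character(classify_grade_sequence(grades))[index + 1L]
}

# Time-point class for every row of a (single-protocol) cohort, aligned
# with the row order of `cohort`.
classify_cohort <- function(cohort) {
  cls <- rep(NA_character_, nrow(cohort))
  for (pid in unique(cohort$patient_id)) {
    idx <- which(cohort$patient_id == pid)
    ord <- idx[order(cohort$visit_index[idx])]
    cls[ord] <- as.character(classify_grade_sequence(cohort$grade[ord]))
  }
  factor(cls, levels = TIMEPOINT_CLASSES)
}
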