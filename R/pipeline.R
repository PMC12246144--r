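# End-to-end orchestration: simulate -> normalize -> select ->
# validate -> report, with manifests recording config, seeds and row
# counts at every stage so any output can be regenerated.

# One top-level seed expands deterministically into per-stage seeds.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, msp = 23L, normalize = 37L, select = 53L,
               lopo = 71L, transfer = 89L, report = 107L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483647L
}

write_manifest <- function(path, entries) {
  entries$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  entries$package_version <- as.character(utils::packageVersion("evreject"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

log_stage <- function(...) message(sprintf(...))

#' Simulate a cohort to disk
#'
#' Generates the synthetic cohort (and, optionally, the paired
#' MSP-capture rows) and writes cohort CSVs plus a run manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed.
#' @param config_path Optional JSON generator config (defaults used
#'   otherwise).
#' @param n_patients Optional patient-count override.
#' @param msp Also derive and write the paired MSP protocol rows.
#' @return Invisibly, a list of written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, config_path = NULL,
                         n_patients = NULL, msp = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- if (!is.null(config_path))
    read_generator_config(config_path, n_patients)
  else default_config(n_patients %||% 24L)
  cohort <- generate_cohort(config, seed = stage_seed(seed, "simulate"))
  paths <- list(immuno = file.path(out_dir, "cohort_immuno.csv"))
  write_cohort(cohort, paths$immuno)
  log_stage("simulate: wrote %d IMMUNO rows (%d patients) to %s",
            nrow(cohort), n_patients(cohort), paths$immuno)
  if (msp) {
    msp_rows <- derive_msp_protocol(cohort, config,
                                    seed = stage_seed(seed, "msp"))
    paths$msp <- file.path(out_dir, "cohort_msp.csv")
    write_cohort(msp_rows, paths$msp)
    log_stage("simulate: wrote %d paired MSP rows to %s",
              nrow(msp_rows), paths$msp)
  }
  paths$manifest <- file.path(out_dir, "manifest.json")
  write_manifest(paths$manifest, list(
    stage = "simulate", seed = seed,
    stage_seeds = list(simulate = stage_seed(seed, "simulate"),
                       msp = if (msp) stage_seed(seed, "msp")),
    n_patients = config$n_patients, rows_immuno = nrow(cohort),
    outputs = paths[setdiff(names(paths), "manifest")]))
  invisible(paths)
}

#' Run the analysis pipeline on a cohort CSV
#'
#' Exclusions, normalization in both modes, differential-marker selection
#' (skipped unless the 37-antigen panel is present), leave-one-patient-out
#' validation, learning curve, stratified summary, and the report bundle.
#'
#' @param cohort_path Cohort CSV (IMMUNO and/or MSP rows).
#' @param out_dir Output directory.
#' @param seed Top-level seed.
#' @param protocol Protocol used for modelling.
#' @param config Base model configuration.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(cohort_path, out_dir, seed = 1L,
                         protocol = c("IMMUNO", "MSP"),
                         config = rf_config(), n_boot = 2000) {
  protocol <- match.arg(protocol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_path)
  log_stage("load: %d rows, %d patients", nrow(cohort), n_patients(cohort))

  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort
  utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  log_stage("exclusions: removed %d visit rows, %d rows remain",
            nrow(excl$report), nrow(cohort))

  norm_retro <- normalize_cohort(cohort, "retrospective")
  norm_causal <- normalize_cohort(cohort, "causal")
  write_normalized(norm_retro,
                   file.path(out_dir, "normalized_retrospective.csv"))
  write_normalized(norm_causal, file.path(out_dir, "normalized_causal.csv"))
  log_stage("normalize: %d visit rows per mode", nrow(norm_retro))

  selected <- NULL
  if ("IMMUNO" %in% cohort$protocol) {
    selected <- select_markers(cohort, normalized = norm_retro)
    writeLines(selected, file.path(out_dir, "selected_markers.txt"))
    utils::write.csv(attr(selected, "table"),
                     file.path(out_dir, "marker_selection.csv"),
                     row.names = FALSE)
    log_stage("select: %d differentially expressed markers",
              length(selected))
  } else {
    log_stage("select: skipped (no 37-antigen IMMUNO rows)")
  }

  lopo <- lopo_validate(cohort, config, seed = stage_seed(seed, "lopo"),
                        protocol = protocol)
  utils::write.csv(lopo$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  log_stage("lopo: %d folds, mean accuracy %.3f, pooled AUC %.3f",
            lopo$n_folds, lopo$mean_accuracy, lopo$auc)

  curve <- learning_curve(lopo)
  utils::write.csv(curve, file.path(out_dir, "learning_curve.csv"),
                   row.names = FALSE)

  roc <- roc_auc(lopo$predictions$coefficient, lopo$predictions$label,
                 n_boot = n_boot, seed = stage_seed(seed, "report"))
  utils::write.csv(
    data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
    file.path(out_dir, "roc_points.csv"), row.names = FALSE)

  cm <- lopo$confusion
  metrics <- data.frame(
    metric = c("mean_accuracy", "pooled_accuracy", "sensitivity",
               "specificity", "ppv", "npv", "auc", "auc_lo", "auc_hi"),
    value = c(lopo$mean_accuracy, cm$accuracy, cm$sensitivity,
              cm$specificity, cm$ppv, cm$npv, roc$auc, roc$auc_ci))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  strat <- stratified_summary(cohort, norm_retro, protocol)
  utils::write.csv(strat, file.path(out_dir, "stratified_summary.csv"),
                   row.names = FALSE)

  summary_lines <- c(
    sprintf("cohort: %d patients, %d rows", n_patients(cohort),
            nrow(cohort)),
    sprintf("selected markers: %s",
            if (is.null(selected)) "(stage skipped)"
            else paste(selected, collapse = ", ")),
    sprintf("LOPO mean accuracy: %.3f", lopo$mean_accuracy),
    sprintf("LOPO pooled accuracy: %.3f", cm$accuracy),
    sprintf("LOPO AUC: %.3f [%.3f, %.3f]", roc$auc, roc$auc_ci[1],
            roc$auc_ci[2]))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  write_manifest(file.path(out_dir, "manifest.json"), list(
    stage = "pipeline", seed = seed, protocol = protocol,
    stage_seeds = list(lopo = stage_seed(seed, "lopo"),
                       report = stage_seed(seed, "report")),
    input = cohort_path, rows_in = nrow(cohort) + nrow(excl$report),
    rows_after_exclusion = nrow(cohort),
    n_selected = if (is.null(selected)) NA else length(selected),
    config = unclass(config)[c("n_trees", "max_splits", "oversampler",
                               "threshold")]))
  invisible(list(cohort = cohort, selected = selected, lopo = lopo,
                 roc = roc, learning_curve = curve, out_dir = out_dir))
}

#' Transfer evaluation between two cohort files
#'
#' Evaluates both directions (A trained, B tested, and the reverse) and
#' writes a direction-labelled metric table.
#'
#' @param cohort_a_path,cohort_b_path Cohort CSVs (protocols A and B).
#' @param out_dir Output directory.
#' @param seed Top-level seed.
#' @param protocol_a,protocol_b Protocol of each cohort's rows.
#' @param config Model configuration.
#' @return Invisibly, the metric data frame.
#' @export
run_transfer <- function(cohort_a_path, cohort_b_path, out_dir, seed = 1L,
                         protocol_a = "MSP", protocol_b = "IMMUNO",
                         config = rf_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- apply_exclusions(read_cohort(cohort_a_path))$cohort
  b <- apply_exclusions(read_cohort(cohort_b_path))$cohort
  run <- function(tr_coh, te_coh, tr_p, te_p, tag) {
    res <- transfer_evaluate(tr_coh, te_coh, config,
                             seed = stage_seed(seed, "transfer"),
                             train_protocol = tr_p, test_protocol = te_p)
    cm <- res$confusion
    data.frame(direction = tag, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               auc = res$roc$auc)
  }
  out <- rbind(
    run(a, b, protocol_a, protocol_b,
        sprintf("%s->%s", protocol_a, protocol_b)),
    run(b, a, protocol_b, protocol_a,
        sprintf("%s->%s", protocol_b, protocol_a)))
  utils::write.csv(out, file.path(out_dir, "transfer_metrics.csv"),
                   row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"), list(
    stage = "transfer", seed = seed,
    stage_seeds = list(transfer = stage_seed(seed, "transfer")),
    inputs = c(cohort_a_path, cohort_b_path)))
  invisible(out)
}
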