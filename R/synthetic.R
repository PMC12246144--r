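# Synthetic longitudinal cohort generator.
#
# The generator replicates the study design exactly where the design is
# stated (patient count, visit counts, grade quotas, median visit
# interval) and emulates the measurement model: per-patient lognormal
# marker baselines, grade-dependent multiplicative effects on the 14
# rejection-associated antigens, elevation already present at the visit
# preceding a diagnosis, multiplicative lognormal measurement noise, and
# post-treatment decay of the elevation after a grade 2-3A episode.
# Tetraspanins are grade-independent, so the tetraspanin-normalized nMFI
# carries the grade signal.

# lognormal multiplicative noise with mean exactly 1 (cv = 0 -> exactly 1)
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default generator configuration (study replica)
#'
#' Returns the configuration reproducing the study design: 24 patients
#' with 9-17 visits each summing to 285, exact grade quotas 181/80/10/14
#' (G0 / 1A+1B / 2 / 3A), 14 patients with at least one grade 2-3A
#' episode of whom 3 have three episodes, median visit interval 28 days,
#' and per-marker grade effects evenly spaced across the observed
#' G0-delta ranges (grade 1A/B x3.01-4.14, grade 2 x6.76-11.94, grade 3A
#' x18.88-46.77; pre-1A/B x1.043-2.31, pre-2-3A x1.82-6.39).
#'
#' For other cohort sizes all quotas scale proportionally (largest
#' remainder rounding), which is how validation cohorts are generated.
#'
#' @param n_patients Number of patients (default 24, the study replica).
#' @return An `ev_generator_config` list.
#' @export
default_config <- function(n_patients = 24L) {
  affected <- ev_affected_markers()
  k <- length(affected)
  effect_table <- cbind(
    G1AB = seq(3.01, 4.14, length.out = k),
    G2   = seq(6.76, 11.94, length.out = k),
    G3A  = seq(18.88, 46.77, length.out = k))
  rownames(effect_table) <- affected
  pre_effect_table <- cbind(
    PRE_1AB = seq(1.043, 2.31, length.out = k),
    PRE_23A = seq(1.82, 6.39, length.out = k))
  rownames(pre_effect_table) <- affected

  cfg <- list(
    n_patients = as.integer(n_patients),
    visits_per_patient = c(9L, 17L),
    visit_interval_days = list(median = 28L, range = c(14L, 35L)),
    # per-visit grade proportions of the study: 181/80/10/14 out of 285
    grade_plan = list(mode = "quota",
                      proportions = c(G0 = 181, G1AB = 80, G2 = 10,
                                      G3A = 14) / 285,
                      visits_per_patient_mean = 285 / 24),
    affected_markers = affected,
    effect_table = effect_table,
    pre_effect_table = pre_effect_table,
    noise_cv = 0.25,
    baseline_nmfi = 0.5,
    baseline_spread = 0.5,
    tetraspanin_mean_mfi = 5000,
    protocol_bias = c(tetraspanin = 1.03, antigen = 1.062),
    protocol_noise_cv = 0.05,
    treatment_decay = 0.25,
    seed = 1L)
  class(cfg) <- "ev_generator_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  stopifnot(config$n_patients >= 1,
            config$noise_cv >= 0,
            all(config$effect_table > 0),
            all(config$pre_effect_table > 0),
            config$treatment_decay >= 0, config$treatment_decay < 1)
  config
}

# largest-remainder apportionment of `total` into shares `p` (sums exactly)
apportion <- function(total, p) {
  raw <- total * p / sum(p)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic design allocation: visit counts per patient, grade quotas,
# and each patient's grade sequence (leading G0 block, then a rejection
# tail where each 2-3A episode is preceded by a 1A/B visit when one is
# available, leftover 1A/B visits appended last). Returns a list of
# per-patient grade vectors.
allocate_design <- function(config) {
  n <- config$n_patients
  total <- round(n * config$grade_plan$visits_per_patient_mean)
  vmin <- config$visits_per_patient[1]
  vmax <- config$visits_per_patient[2]
  if (total < n * vmin || total > n * vmax)
    stop("config error: visit quota infeasible for visits_per_patient range")
  # spread follow-up lengths across the allowed range (earlier patients
  # are followed longest), deterministically: quadratically decaying
  # shares of the visits above the minimum, capped at the maximum
  extra <- apportion(total - n * vmin, (n:1)^2)
  over <- sum(pmax(extra - (vmax - vmin), 0L))
  extra <- pmin(extra, vmax - vmin)
  i <- 1
  while (over > 0) {
    if (extra[i] < vmax - vmin) {
      extra[i] <- extra[i] + 1L
      over <- over - 1
    }
    i <- if (i == n) 1 else i + 1
  }
  visits <- vmin + extra

  q <- apportion(total, config$grade_plan$proportions)
  names(q) <- names(config$grade_plan$proportions)
  n23 <- q[["G2"]] + q[["G3A"]]

  # patients with rejection episodes: scale the study's 14-of-24 carriers
  # and 3-of-24 triple-episode patients
  n_triple <- round(n * 3 / 24)
  n_carrier <- max(round(n * 14 / 24), ceiling(n23 / 3))
  n_carrier <- min(n_carrier, n)
  eps <- integer(n)
  eps[seq_len(n_triple)] <- 3L
  left <- n23 - 3L * n_triple
  singles <- setdiff(seq_len(n_carrier), seq_len(n_triple))
  if (left < length(singles) || left > 2L * length(singles))
    stop("config error: 2-3A episode quota infeasible for carrier counts")
  eps[singles] <- 1L
  left <- left - length(singles)
  i <- 1
  while (left > 0) {
    eps[singles[i]] <- eps[singles[i]] + 1L
    left <- left - 1
    i <- i + 1
  }

  # 1A/B quota round-robin, capped so every patient keeps >= 3 G0 visits
  cap <- visits - 3L - eps
  n1 <- integer(n)
  left <- q[["G1AB"]]
  if (left > sum(cap)) stop("config error: 1A/B quota infeasible")
  i <- 1
  while (left > 0) {
    if (n1[i] < cap[i]) {
      n1[i] <- n1[i] + 1L
      left <- left - 1
    }
    i <- if (i == n) 1 else i + 1
  }

  # grade identity of the 2-3A episodes: alternate 3A/2 until the G2
  # quota is exhausted, then 3A
  ep_grades <- character(n23)
  g2_left <- q[["G2"]]
  for (j in seq_len(n23)) {
    if (j %% 2 == 0 && g2_left > 0) {
      ep_grades[j] <- "2"
      g2_left <- g2_left - 1
    } else ep_grades[j] <- "3A"
  }
  n3a_short <- sum(ep_grades == "3A") - q[["G3A"]]
  if (n3a_short != 0) {   # fix any leftover G2 quota at the tail
    idx <- rev(which(ep_grades == "3A"))[seq_len(g2_left)]
    ep_grades[idx] <- "2"
  }

  ab_toggle <- TRUE  # alternate 1A / 1B
  ep_ptr <- 0
  seqs <- vector("list", n)
  for (p in seq_len(n)) {
    v <- visits[p]
    tail <- character(0)
    ab_left <- n1[p]
    for (e in seq_len(eps[p])) {
      if (ab_left > 0) {
        tail <- c(tail, if (ab_toggle) "1A" else "1B")
        ab_toggle <- !ab_toggle
        ab_left <- ab_left - 1
      }
      ep_ptr <- ep_ptr + 1
      tail <- c(tail, ep_grades[ep_ptr])
    }
    if (ab_left > 0) {
      abs <- character(ab_left)
      for (j in seq_len(ab_left)) {
        abs[j] <- if (ab_toggle) "1A" else "1B"
        ab_toggle <- !ab_toggle
      }
      tail <- c(tail, abs)
    }
    g0_count <- v - length(tail)
    seqs[[p]] <- c(rep("0", g0_count), tail)
  }
  seqs
}

#' Generate a synthetic cohort
#'
#' Produces one immuno-capture visit row per scheduled visit. Observed
#' antigen MFI is
#' `latent_baseline(patient, marker) * effect * decay * noise * mean(tet)`,
#' where the effect multiplier is the visit grade's (or pre-diagnosis)
#' fold-change for affected markers and 1 otherwise, and decay is the
#' post-treatment relaxation of a previous episode's elevation.
#' Tetraspanin MFIs are drawn around `tetraspanin_mean_mfi` independently
#' of grade. Fully reproducible from `seed`.
#'
#' @param config An `ev_generator_config` (see [default_config()]).
#' @param seed Integer seed controlling all randomness.
#' @return An `ev_cohort` of immuno-capture rows.
#' @export
generate_cohort <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  seqs <- allocate_design(config)
  n <- config$n_patients
  panel <- ev_panel("IMMUNO")
  tets <- ev_tetraspanins()
  affected <- config$affected_markers

  withr::with_seed(as.integer(seed), {
    rows <- vector("list", n)
    for (p in seq_len(n)) {
      grades <- seqs[[p]]
      v <- length(grades)
      cls <- as.character(classify_grade_sequence(grades))

      # visit days: first sample one week post-transplant; alternate
      # intervals fixed at the median so the overall median is exact
      intervals <- integer(v - 1)
      jitter_pool <- setdiff(seq(config$visit_interval_days$range[1],
                                 config$visit_interval_days$range[2]),
                             config$visit_interval_days$median)
      for (j in seq_len(v - 1)) {
        intervals[j] <- if (j %% 2 == 1) config$visit_interval_days$median
                        else sample(jitter_pool, 1)
      }
      days <- as.integer(7 + c(0, cumsum(intervals)))

      # latent per-marker baseline nMFI for this patient
      L <- config$baseline_nmfi *
        rlnorm_cv(length(panel), config$baseline_spread)
      names(L) <- panel

      # effect multiplier per visit x marker
      mult <- matrix(1, nrow = v, ncol = length(panel),
                     dimnames = list(NULL, panel))
      for (i in seq_len(v)) {
        g <- grade_group(grades[i])
        if (g == "G1AB") mult[i, affected] <- config$effect_table[, "G1AB"]
        if (g == "G23A") {
          col <- if (grades[i] == "2") "G2" else "G3A"
          mult[i, affected] <- config$effect_table[, col]
        }
        if (cls[i] == "PRE_1AB")
          mult[i, affected] <- pmax(mult[i, affected],
                                    config$pre_effect_table[, "PRE_1AB"])
        if (cls[i] == "PRE_23A")
          mult[i, affected] <- pmax(mult[i, affected],
                                    config$pre_effect_table[, "PRE_23A"])
      }

      # therapy adjustment after each 2-3A episode: residual elevation
      # relaxes toward 1 geometrically; the visit's own effect dominates
      therapy_adj <- integer(v)
      last_ep <- NA_integer_
      for (i in seq_len(v)) {
        if (i > 1 && grades[i - 1] %in% c("2", "3A")) {
          therapy_adj[i] <- 1L
          last_ep <- i - 1L
        }
        if (!is.na(last_ep) && i > last_ep) {
          k <- i - last_ep
          ep_col <- if (grades[last_ep] == "2") "G2" else "G3A"
          residual <- 1 + (config$effect_table[, ep_col] - 1) *
            config$treatment_decay^k
          mult[i, affected] <- pmax(mult[i, affected], residual)
        }
      }

      tet_mfi <- matrix(config$tetraspanin_mean_mfi *
                          rlnorm_cv(v * length(tets), config$noise_cv),
                        nrow = v, dimnames = list(NULL, tets))
      tet_mean <- rowMeans(tet_mfi)
      noise <- matrix(rlnorm_cv(v * length(panel), config$noise_cv),
                      nrow = v)
      antigen_mfi <- sweep(mult * noise, 2, L, `*`) * tet_mean

      df <- data.frame(
        patient_id = sprintf("P%02d", p),
        visit_index = seq_len(v) - 1L,
        day = days,
        grade = grades,
        amr = 0L,
        therapy = if (p %% 2 == 1) "CSA" else "TAC",
        therapy_adjusted = therapy_adj,
        protocol = "IMMUNO",
        stringsAsFactors = FALSE, check.names = FALSE)
      df[tets] <- as.data.frame(tet_mfi)
      df[panel] <- as.data.frame(antigen_mfi)
      rows[[p]] <- df
    }
    as_ev_cohort(do.call(rbind, rows))
  })
}

#' Derive paired MSP-capture rows from an immuno-capture cohort
#'
#' Emulates the paired second protocol: for the 14-marker MSP panel plus
#' tetraspanins, `MFI_MSP = MFI_IMMUNO * bias * noise`. The tetraspanin
#' bias applies to raw tetraspanin MFI; the antigen bias is defined on
#' the nMFI scale (the scale on which the inter-protocol overestimation
#' is reported), so raw antigen MFI carries `antigen_bias * tet_bias`.
#'
#' @param cohort An `ev_cohort` containing IMMUNO rows.
#' @param config Generator config providing `protocol_bias` and
#'   `protocol_noise_cv`.
#' @param seed Integer seed.
#' @return An `ev_cohort` of the paired MSP rows.
#' @export
derive_msp_protocol <- function(cohort, config = default_config(),
                                seed = config$seed + 1L) {
  stopifnot(inherits(cohort, "ev_cohort"))
  imm <- as.data.frame(cohort)[cohort$protocol == "IMMUNO", , drop = FALSE]
  if (nrow(imm) == 0) stop("cohort has no IMMUNO rows")
  tets <- ev_tetraspanins()
  antigens <- ev_panel("MSP")
  bias_t <- config$protocol_bias[["tetraspanin"]]
  bias_a <- config$protocol_bias[["antigen"]] * bias_t
  msp <- imm[c(META_COLUMNS, tets, antigens)]
  msp$protocol <- "MSP"
  withr::with_seed(as.integer(seed), {
    for (m in tets)
      msp[[m]] <- imm[[m]] * bias_t *
        rlnorm_cv(nrow(msp), config$protocol_noise_cv)
    for (m in antigens)
      msp[[m]] <- imm[[m]] * bias_a *
        rlnorm_cv(nrow(msp), config$protocol_noise_cv)
  })
  for (m in ev_unaffected_markers()) msp[[m]] <- NA_real_
  as_ev_cohort(msp)
}

#' Read a generator configuration file
#'
#' Flat JSON with any subset of the [default_config()] keys; unknown keys
#' are rejected. `effect_table` / `pre_effect_table` may be given as
#' named lists of per-grade numeric vectors (length 1 or one value per
#' affected marker).
#'
#' @param path JSON file path.
#' @param n_patients Optional override of the patient count.
#' @return An `ev_generator_config`.
#' @export
read_generator_config <- function(path, n_patients = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(if (!is.null(n_patients)) n_patients
                        else raw$n_patients %||% 24L)
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown) > 0)
    stop("config error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  for (key in setdiff(names(raw), c("effect_table", "pre_effect_table"))) {
    cfg[[key]] <- raw[[key]]
  }
  for (key in intersect(names(raw), c("effect_table", "pre_effect_table"))) {
    for (g in names(raw[[key]]))
      cfg[[key]][, g] <- raw[[key]][[g]]
  }
  validate_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
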