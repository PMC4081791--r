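# Synthetic cohort generation. Each label has a prototype and a constraint
# table separating defining indicators (fixed so the diagnosis is forced)
# from free indicators (drawn/flipped), which is what makes latent labels
# recoverable by the rule engine at noise = 0.

# Per-label generative constraints:
#   req    - interview flags that must stay TRUE (defining)
#   forbid - interview flags that must stay FALSE (defining by exclusion)
#   min_counts - lower bounds on questionnaire counts (behavior must appear)
#   max_counts - upper bounds (counts that would trip a higher-precedence
#                rule via the weekly fallback are capped at 3, i.e. below
#                the once-weekly threshold)
#   bmi    - truncation range for the BMI draw
label_constraints <- function() {
  all_flags <- interview_items()
  purge_flags <- c("regular_vomiting", "regular_laxatives",
                   "regular_diuretics")
  comp_flags <- c(purge_flags, "regular_fasting", "regular_excess_exercise")
  sub3 <- c(obe_freq = 3)
  list(
    RAN = list(
      req = c("weight_phobia", "body_disturbance", "amenorrhea",
              "regular_fasting"),
      forbid = c("regular_obe", purge_flags),
      min_counts = c(fasting_score = 4),
      max_counts = NULL, bmi = c(12, 18.4)),
    ANBP = list(
      req = c("weight_phobia", "body_disturbance", "amenorrhea",
              "regular_obe", "regular_vomiting"),
      forbid = character(0),
      min_counts = c(obe_freq = 8, vomit_freq = 8),
      max_counts = NULL, bmi = c(12, 18.4)),
    BN = list(
      req = c("regular_obe", "regular_vomiting", "undue_influence"),
      forbid = character(0),
      min_counts = c(obe_freq = 8, vomit_freq = 8),
      max_counts = NULL, bmi = c(18.6, 45)),
    BED = list(
      req = c("regular_obe", "binge_distress"),
      forbid = comp_flags,
      min_counts = c(obe_freq = 8),
      max_counts = c(vomit_freq = 3, laxative_freq = 3, diuretic_freq = 3,
                     exercise_freq = 3, fasting_score = 3),
      bmi = c(18.6, 55)),
    PD = list(
      req = c("regular_vomiting", "undue_influence", "weight_phobia"),
      forbid = "regular_obe",
      min_counts = c(vomit_freq = 8),
      max_counts = c(obe_freq = 3), bmi = c(18.6, 40)),
    AAN = list(
      req = c("weight_phobia", "body_disturbance", "regular_fasting"),
      forbid = c("regular_obe", purge_flags),
      min_counts = c(fasting_score = 4),
      max_counts = c(obe_freq = 3), bmi = c(18.6, 40)),
    SUBBN = list(
      req = "undue_influence",
      forbid = c("regular_obe", comp_flags, "weight_phobia"),
      min_counts = c(obe_freq = 1, vomit_freq = 1),
      max_counts = c(obe_freq = 3, vomit_freq = 3, laxative_freq = 3,
                     diuretic_freq = 3, exercise_freq = 3, fasting_score = 3),
      bmi = c(18.6, 40)),
    SUBBED = list(
      req = "binge_distress",
      forbid = c("regular_obe", comp_flags, "undue_influence",
                 "weight_phobia"),
      min_counts = c(obe_freq = 1),
      max_counts = c(obe_freq = 3, vomit_freq = 3, laxative_freq = 3,
                     diuretic_freq = 3, exercise_freq = 3, fasting_score = 3),
      bmi = c(18.6, 55)),
    UFED = list(
      req = "weight_phobia",
      forbid = c("regular_obe", comp_flags, "body_disturbance",
                 "undue_influence", "denial_of_seriousness",
                 "binge_distress"),
      min_counts = c(vomit_freq = 1),
      max_counts = c(obe_freq = 3, vomit_freq = 3),
      bmi = c(14, 45))
  )
}

# BMI/age moments per label; sub-threshold BN has no reference row and
# borrows the BN moments
label_moments <- function(label) {
  d <- ref_diagnosis_distribution()
  src <- if (label %in% d$label) label else "BN"
  d[d$label == src, ]
}

behavior_columns <- function() {
  c(obe = "obe_freq", sbe = "sbe_freq", vomiting = "vomit_freq",
    laxatives = "laxative_freq", diuretics = "diuretic_freq",
    exercise = "exercise_freq", fasting = "fasting_score")
}

# hard ceiling on generated 28-day counts (about twice daily)
COUNT_CAP <- 56L

#' Deterministic prototype record for a diagnostic label
#'
#' Returns a single noise-free record satisfying exactly the defining
#' criteria of `label` under the generator's constraint table: defining
#' interview flags set, excluded flags cleared, free indicators at their
#' minimal (absent) state, questionnaire counts at the minimal consistent
#' values, BMI and scores at the label's reference means. The purging-
#' disorder prototype deliberately also satisfies the psychological criteria
#' of atypical anorexia, so that PD/AAN membership is decided purely by
#' category precedence.
#'
#' @param label one of `ed_labels()` or `"UFED"`.
#' @param patient_id identifier for the record.
#' @param timepoint `"baseline"` or `"month12"`.
#' @return one-row cohort data.frame.
#' @export
prototype_record <- function(label, patient_id = paste0("proto_", label),
                             timepoint = "baseline") {
  cons <- label_constraints()
  if (!label %in% names(cons)) {
    stop("no prototype for label '", label, "'")
  }
  cn <- cons[[label]]
  drow <- label_moments(label)
  rec <- empty_record(patient_id, timepoint)
  rec$bmi <- drow$bmi_mean
  rec$age <- drow$age_mean
  rec[cn$req] <- TRUE
  for (nm in names(cn$min_counts)) rec[[nm]] <- as.integer(cn$min_counts[nm])
  sp <- default_score_params()
  plab <- if (label %in% sp$label) label else "BN"
  sp <- sp[sp$label == plab, ]
  for (i in seq_len(nrow(sp))) rec[[sp$scale[i]]] <- sp$mean[i]
  rec
}

empty_record <- function(patient_id, timepoint) {
  rec <- data.frame(patient_id = patient_id, timepoint = timepoint,
                    bmi = 21, age = 25, stringsAsFactors = FALSE)
  for (f in interview_items()) rec[[f]] <- FALSE
  for (cl in c("obe_freq", "sbe_freq", "vomit_freq", "laxative_freq",
               "diuretic_freq", "exercise_freq")) {
    rec[[cl]] <- 0L
  }
  rec$fasting_score <- 0L
  for (cl in c("edeq_restraint", "edeq_eating_concern", "edeq_shape_concern",
               "edeq_weight_concern", "edeq_global", "cia", "cprs",
               "sasb_affiliation", "sasb_self_emancipation",
               "sasb_self_control")) {
    rec[[cl]] <- 0
  }
  rec$mood_disorder <- FALSE
  rec$anxiety_disorder <- FALSE
  rec$substance_use_disorder <- FALSE
  rec
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# truncated-Poisson count for a behavior that is present: at least 1,
# capped; lambda centered on the group's mean reporter frequency
rcount <- function(n, mean_freq, cap = COUNT_CAP) {
  lam <- max(mean_freq - 1, 0.1)
  pmin(1L + stats::rpois(n, lam), as.integer(cap))
}

generate_label_block <- function(label, ids, config, timepoint = "baseline") {
  cons <- label_constraints()[[label]]
  n <- length(ids)
  drow <- label_moments(label)
  rec <- empty_record(rep("x", n), timepoint)
  rec$patient_id <- ids
  rec$bmi <- rtruncnorm(n, drow$bmi_mean, drow$bmi_sd,
                        cons$bmi[1], cons$bmi[2])
  rec$age <- rtruncnorm(n, drow$age_mean, drow$age_sd, 18, 70)

  for (f in cons$req) rec[[f]] <- TRUE
  free <- setdiff(interview_items(), c(cons$req, cons$forbid))
  if (config$noise > 0) {
    for (f in free) rec[[f]] <- stats::runif(n) < config$noise
  }

  # questionnaire behaviors: presence from group prevalence, count from a
  # truncated Poisson at the group's mean reporter frequency, then the
  # label's consistency bounds
  bp <- config$behavior_prevalence
  fq <- config$freq_params
  bcols <- behavior_columns()
  for (b in names(bcols)) {
    col <- bcols[b]
    prev <- if (label %in% colnames(bp)) bp[b, label] else 0
    mfreq <- if (label %in% colnames(fq)) fq[b, label] else 1
    cap <- if (b == "fasting") 6L else COUNT_CAP
    present <- stats::runif(n) < prev
    cnt <- ifelse(present, rcount(n, mfreq, cap), 0L)
    lo <- cn_bound(cons$min_counts, col, 0L)
    hi <- cn_bound(cons$max_counts, col, cap)
    # interview-established regular behavior implies at least twice weekly
    reg_flag <- switch(b, obe = rec$regular_obe,
                       sbe = rec$regular_sbe,
                       vomiting = rec$regular_vomiting,
                       laxatives = rec$regular_laxatives,
                       diuretics = rec$regular_diuretics,
                       exercise = rec$regular_excess_exercise,
                       fasting = rec$regular_fasting)
    lo <- pmax(lo, ifelse(reg_flag, if (b == "fasting") 4L else 8L, 0L))
    rec[[col]] <- as.integer(pmin(pmax(cnt, lo), hi))
  }

  sp <- config$score_params
  bounds <- scale_bounds()
  plab <- if (label %in% sp$label) label else "BED"
  for (s in unique(sp$scale)) {
    row <- sp[sp$scale == s & sp$label == plab, ]
    if (nrow(row)) {
      rec[[s]] <- rtruncnorm(n, row$mean[1], row$sd[1],
                             bounds[[s]][1], bounds[[s]][2])
    }
  }

  cm <- config$comorbidity
  if (label %in% colnames(cm)) {
    rec$mood_disorder <- stats::runif(n) < cm["mood", label]
    rec$anxiety_disorder <- stats::runif(n) < cm["anxiety", label]
    rec$substance_use_disorder <- stats::runif(n) < cm["substance", label]
  }
  rec
}

cn_bound <- function(v, col, default) {
  if (!is.null(v) && col %in% names(v)) v[[col]] else default
}

#' Generate a synthetic baseline cohort
#'
#' Draws each patient's latent diagnosis from the configured mixture and
#' builds an item-level record from that label's prototype: defining
#' indicators fixed, free indicators subject to symptom noise, per-group
#' truncated-normal scores, Bernoulli behavior reports with
#' truncated-Poisson counts, and Bernoulli comorbidity flags. Records carry
#' no label; ground truth is returned separately.
#'
#' @param config a [cohort_config()].
#' @return list with `cohort` (data.frame of records) and `truth`
#'   (data.frame `patient_id`, `true_label`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  labels <- sample(names(config$mixture), n, replace = TRUE,
                   prob = config$mixture)
  ids <- sprintf("P%05d", seq_len(n))
  blocks <- lapply(split(ids, labels), function(block_ids) {
    generate_label_block(labels[match(block_ids[1], ids)], block_ids, config)
  })
  cohort <- do.call(rbind, blocks)
  cohort <- cohort[order(cohort$patient_id), ]
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = data.frame(patient_id = ids,
                          true_label = labels,
                          stringsAsFactors = FALSE))
}

#' Generate 12-month follow-up records
#'
#' Each retained patient's follow-up state is drawn from the transition row
#' of their true baseline label. Remission produces a record that fails both
#' the DSM-IV rules and the EDNOS-Other rule (no symptoms, restored weight,
#' low questionnaire scores); any other state produces a record generated
#' from that label's prototype machinery. A `retention` fraction of patients
#' is kept completely at random, emulating follow-up attrition.
#'
#' @param cohort baseline records from [generate_cohort()].
#' @param truth matching truth data.frame.
#' @param config the [cohort_config()] used at baseline.
#' @return list with `followup` (records at `timepoint = "month12"`) and
#'   `truth` (data.frame `patient_id`, `true_label`, `true_followup_state`).
#' @export
generate_followup <- function(cohort, truth, config) {
  stopifnot(identical(sort(cohort$patient_id), sort(truth$patient_id)))
  set.seed(config$seed + 1L)
  tr <- config$transition
  missing_rows <- setdiff(unique(truth$true_label), rownames(tr))
  if (length(missing_rows)) {
    stop("transition row missing for label(s): ",
         paste(missing_rows, collapse = ", "))
  }
  keep <- stats::runif(nrow(truth)) < config$retention
  kept <- truth[keep, , drop = FALSE]
  states <- vapply(kept$true_label, function(lab) {
    sample(colnames(tr), 1L, prob = tr[lab, ])
  }, character(1))

  blocks <- list()
  for (st in unique(states)) {
    ids <- kept$patient_id[states == st]
    if (st == "REMISSION") {
      blk <- remission_block(ids, cohort)
    } else {
      blk <- generate_label_block(st, ids, config, timepoint = "month12")
    }
    blocks[[st]] <- blk
  }
  followup <- do.call(rbind, blocks)
  followup <- followup[order(followup$patient_id), ]
  rownames(followup) <- NULL
  ord <- order(kept$patient_id)
  list(followup = followup,
       truth = data.frame(patient_id = kept$patient_id[ord],
                          true_label = kept$true_label[ord],
                          true_followup_state = states[ord],
                          stringsAsFactors = FALSE))
}

# symptom-free record: weight restored above the anorexic range, all
# indicators absent, questionnaire scores drawn at sub-clinical levels
remission_block <- function(ids, cohort) {
  n <- length(ids)
  rec <- empty_record(ids, "month12")
  base_bmi <- cohort$bmi[match(ids, cohort$patient_id)]
  rec$bmi <- pmax(base_bmi, 19.5) + stats::rnorm(n, 0.5, 0.8)
  rec$bmi <- pmax(rec$bmi, 18.6)
  rec$age <- cohort$age[match(ids, cohort$patient_id)] + 1
  bounds <- scale_bounds()
  low <- list(edeq_global = c(0.8, 0.6), edeq_restraint = c(0.8, 0.6),
              edeq_eating_concern = c(0.8, 0.6),
              edeq_shape_concern = c(1.0, 0.7),
              edeq_weight_concern = c(1.0, 0.7),
              cia = c(7, 5), cprs = c(0.4, 0.3),
              sasb_affiliation = c(25, 30),
              sasb_self_emancipation = c(35, 15),
              sasb_self_control = c(45, 15))
  for (s in names(low)) {
    rec[[s]] <- rtruncnorm(n, low[[s]][1], low[[s]][2],
                           bounds[[s]][1], bounds[[s]][2])
  }
  rec
}
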