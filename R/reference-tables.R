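# Summary statistics of the reference clinical cohort (2233 adult women from
# Swedish specialist eating-disorder services, baseline + 12-month follow-up).
# These printed summaries are the only public face of that database; they are
# both the default generative parameters of the synthetic-cohort module and
# the inputs to the reference-statistics reproduction in analysis/ and
# scripts/acceptance.R.

#' Reference cohort: DSM-5 diagnosis distribution
#'
#' Baseline counts by diagnosis for the reference clinical cohort, with
#' per-group body-mass-index and age moments and the number of patients with
#' complete 12-month follow-up data.
#'
#' @return data.frame with columns `label`, `n`, `bmi_mean`, `bmi_sd`,
#'   `age_mean`, `age_sd`, `n_followup` (NA where no follow-up group exists).
#' @export
ref_diagnosis_distribution <- function() {
  data.frame(
    label      = c("RAN", "ANBP", "BN", "BED", "AAN", "SUBBED", "PD", "UFED"),
    n          = c(364L, 295L, 874L, 124L, 310L, 11L, 184L, 71L),
    bmi_mean   = c(16.1, 16.8, 23.6, 31.4, 22.7, 30.2, 21.9, 19.9),
    bmi_sd     = c(1.6, 1.4, 4.3, 7.7, 4.5, 7.6, 3.5, 6.7),
    age_mean   = c(23.2, 24.3, 26.4, 30.2, 26.0, 34.4, 25.4, 26.1),
    age_sd     = c(6.6, 7.1, 8.0, 10.2, 7.0, 13.2, 7.9, 9.1),
    n_followup = c(102L, 67L, 219L, 22L, 69L, NA, 39L, 12L),
    stringsAsFactors = FALSE
  )
}

#' Reference cohort: continuous psychopathology scores by diagnosis
#'
#' Group means and standard deviations for the global Eating Disorder
#' Examination Questionnaire score (0-6), Clinical Impairment Assessment
#' (0-48), the psychiatric symptom index of the Comprehensive Psychiatric
#' Rating Scale self-rating (0-3), and three self-image dimensions
#' (affiliation vector, self-emancipation, self-control). The sub-threshold
#' BED group is too small to have its own printed row; it inherits the BED
#' parameters.
#'
#' @return data.frame, one row per (scale, label), columns `scale`, `label`,
#'   `mean`, `sd`.
#' @export
ref_score_params <- function() {
  labs <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "UFED")
  tab <- rbind(
    data.frame(scale = "edeq_global", label = labs,
               mean = c(3.38, 4.18, 4.20, 3.67, 3.64, 4.09, 1.72),
               sd   = c(1.36, 1.18, 0.95, 1.08, 1.16, 0.97, 1.22)),
    data.frame(scale = "cia", label = labs,
               mean = c(29.07, 33.61, 30.51, 29.82, 26.39, 28.41, 19.19),
               sd   = c(11.4, 9.9, 9.3, 9.2, 10.5, 9.5, 11.6)),
    data.frame(scale = "cprs", label = labs,
               mean = c(1.14, 1.34, 1.14, 1.14, 1.08, 1.14, 0.76),
               sd   = c(0.51, 0.52, 0.47, 0.39, 0.49, 0.49, 0.50)),
    data.frame(scale = "sasb_affiliation", label = labs,
               mean = c(-10.98, -28.3, -16.9, -21.4, -11.1, -16.0, 17.3),
               sd   = c(37.2, 31.4, 33.0, 33.4, 35.2, 34.5, 41.6)),
    data.frame(scale = "sasb_self_emancipation", label = labs,
               mean = c(30.4, 31.2, 32.0, 35.1, 31.2, 30.6, 38.6),
               sd   = c(15.6, 17.0, 15.4, 17.1, 15.3, 14.2, 18.6)),
    data.frame(scale = "sasb_self_control", label = labs,
               mean = c(62.1, 59.8, 54.8, 49.5, 57.0, 53.7, 52.5),
               sd   = c(18.3, 17.2, 18.5, 20.8, 17.9, 18.9, 19.7))
  )
  sub <- tab[tab$label == "BED", ]
  sub$label <- "SUBBED"
  out <- rbind(tab, sub)
  rownames(out) <- NULL
  out
}

#' Reference cohort: 28-day behavior report counts by diagnosis
#'
#' Number of patients per diagnostic group reporting each eating-disorder
#' behavior at least once over the last 28 days on the questionnaire.
#' Diagnoses for which a behavior is itself criterion-relevant were omitted
#' from the corresponding omnibus test (binge episodes: RAN and PD omitted,
#' and BED for compensatory behaviors); `omit` records that convention so the
#' omnibus chi-square can be recomputed with the correct denominators.
#'
#' @return list with elements `yes` (matrix behavior x label of reporters),
#'   `group_n` (named vector of group sizes) and `omit` (list behavior ->
#'   labels excluded from the omnibus test).
#' @export
ref_behavior_counts <- function() {
  labs <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "UFED")
  yes <- rbind(
    obe       = c(93, 163, 646, 103, 146, 70, 24),
    sbe       = c(216, 205, 524, 44, 179, 122, 16),
    vomiting  = c(27, 230, 621, 8, 67, 150, 21),
    laxatives = c(8, 60, 138, 2, 5, 33, 1),
    diuretics = c(4, 29, 46, 1, 9, 12, 1),
    exercise  = c(155, 150, 473, 13, 153, 102, 13),
    fasting   = c(210, 227, 576, 45, 180, 128, 13)
  )
  colnames(yes) <- labs
  list(
    yes = yes,
    group_n = stats::setNames(c(364, 295, 874, 124, 310, 184, 71), labs),
    omit = list(
      obe       = c("RAN", "PD"),
      sbe       = character(0),
      vomiting  = c("RAN", "BED"),
      laxatives = c("RAN", "BED"),
      diuretics = c("RAN", "BED"),
      exercise  = "BED",
      fasting   = "BED"
    )
  )
}

#' Reference cohort: mean 28-day behavior frequencies by diagnosis
#'
#' Mean behavior frequency over the last 28 days among reporters. Extreme
#' fasting is an ordinal 0-6 intensity score rather than a count. Cells the
#' reference table leaves blank (too few reporters) are filled with small
#' positive values so the generator always has a rate; `SUBBED` inherits BED.
#'
#' @return data.frame, rows = behaviors, columns = labels.
#' @export
ref_freq_params <- function() {
  labs <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "UFED")
  m <- rbind(
    obe       = c(7.8, 14.0, 12.7, 14.6, 8.1, 8.8, 5.3),
    sbe       = c(11.3, 12.0, 10.9, 11.3, 9.8, 9.8, 6.1),
    vomiting  = c(3.0, 23.8, 20.0, 3.3, 15.1, 14.0, 12.2),
    laxatives = c(2.0, 9.6, 11.5, 1.0, 4.8, 8.3, 4.0),
    diuretics = c(2.5, 11.2, 12.7, 2.0, 4.6, 10.4, 2.0),
    exercise  = c(15.9, 15.7, 13.2, 6.7, 15.5, 14.8, 14.3),
    fasting   = c(1.79, 2.69, 1.76, 0.69, 1.68, 2.10, 0.38)
  )
  colnames(m) <- labs
  out <- as.data.frame(m)
  out$SUBBED <- out$BED
  out
}

#' Reference cohort: Axis-I comorbidity counts by diagnosis
#'
#' Patients per group with a comorbid mood, anxiety, or alcohol/substance use
#' disorder on structured clinical interview. Sub-threshold BED (n = 11) is
#' excluded from these tables, hence the 2222 total.
#'
#' @return list with `yes` (matrix disorder x label) and `group_n`.
#' @export
ref_comorbidity_counts <- function() {
  labs <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "UFED")
  yes <- rbind(
    mood      = c(104, 138, 417, 71, 116, 66, 11),
    anxiety   = c(47, 53, 143, 21, 51, 35, 6),
    substance = c(13, 31, 120, 19, 32, 21, 6)
  )
  colnames(yes) <- labs
  list(yes = yes,
       group_n = stats::setNames(c(364, 295, 874, 124, 310, 184, 71), labs))
}

#' Reference cohort: 12-month diagnostic stability/cross-over counts
#'
#' Counts of baseline-diagnosis by follow-up-state (diagnosis or remission)
#' among the 530 patients with complete 12-month data. Remission means
#' meeting neither DSM-IV criteria nor the EDNOS-Other minimal-symptom rule.
#'
#' @return integer matrix, rows = baseline labels, columns = follow-up states
#'   (`REMISSION` last).
#' @export
ref_crossover_counts <- function() {
  labs <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "UFED")
  m <- rbind(
    RAN  = c(29, 2, 2, 0, 17, 0, 18, 34),
    ANBP = c(6, 13, 6, 0, 7, 5, 11, 19),
    BN   = c(1, 3, 42, 2, 20, 5, 54, 92),
    BED  = c(0, 0, 4, 3, 2, 0, 6, 7),
    AAN  = c(0, 1, 6, 0, 13, 4, 14, 31),
    PD   = c(1, 1, 2, 0, 4, 6, 8, 17),
    UFED = c(1, 0, 1, 0, 0, 0, 4, 6)
  )
  colnames(m) <- c(labs, "REMISSION")
  storage.mode(m) <- "integer"
  m
}
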