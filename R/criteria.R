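# Criterion evaluation: maps item-level records (structured-interview flags +
# 28-day questionnaire frequencies + anthropometry) onto the boolean criteria
# the diagnostic rules consume, recording provenance for every frequency
# criterion (interview vs questionnaire fallback).

#' Column dictionary for patient records
#'
#' A cohort is a plain data.frame, one row per patient-timepoint. Interview
#' items are the DSM-IV-anchored flags of a structured eating-disorder
#' interview ("regular" means at least twice weekly for at least three
#' months); questionnaire items are 28-day behavior counts and 0-6 subscale
#' means; comorbidity flags come from a structured Axis-I interview.
#'
#' @return data.frame with columns `column`, `type`, `description`.
#' @export
cohort_schema <- function() {
  rbind(
    data.frame(column = c("patient_id", "timepoint", "bmi", "age"),
               type = c("character", "character", "numeric", "numeric"),
               description = c("unique patient identifier",
                               "baseline or month12",
                               "body mass index, kg/m^2",
                               "age in years (adult cohort, >= 18)")),
    data.frame(column = interview_items(), type = "logical",
               description = c(
                 "objective binge episodes >= 2/week for >= 3 months",
                 "regular subjective binge episodes",
                 "loss of control during eating",
                 "regular self-induced vomiting",
                 "regular laxative misuse",
                 "regular diuretic misuse",
                 "regular fasting / extreme dieting",
                 "regular excessive exercise for weight control",
                 "intense fear of weight gain (weight phobia)",
                 "self-esteem unduly influenced by weight/shape",
                 "disturbed experience of body weight or shape",
                 "denial of the seriousness of low weight",
                 "amenorrhea",
                 "marked distress regarding binge eating")),
    data.frame(column = c("obe_freq", "sbe_freq", "vomit_freq",
                          "laxative_freq", "diuretic_freq", "exercise_freq"),
               type = "integer",
               description = paste("28-day count of",
                                   c("objective binge episodes",
                                     "subjective binge episodes",
                                     "self-induced vomiting",
                                     "laxative misuse", "diuretic misuse",
                                     "excessive exercise"))),
    data.frame(column = "fasting_score", type = "numeric",
               description = "extreme fasting/dieting intensity, ordinal 0-6"),
    data.frame(column = c("edeq_restraint", "edeq_eating_concern",
                          "edeq_shape_concern", "edeq_weight_concern",
                          "edeq_global"),
               type = "numeric",
               description = "eating-disorder questionnaire subscale mean, 0-6"),
    data.frame(column = c("cia", "cprs", "sasb_affiliation",
                          "sasb_self_emancipation", "sasb_self_control"),
               type = "numeric",
               description = c("clinical impairment assessment total, 0-48",
                               "psychiatric symptom index, 0-3",
                               "self-image affiliation vector",
                               "self-image self-emancipation",
                               "self-image self-control")),
    data.frame(column = c("mood_disorder", "anxiety_disorder",
                          "substance_use_disorder"),
               type = "logical",
               description = paste("comorbid", c("mood", "anxiety",
                                                 "alcohol/substance use"),
                                   "disorder (Axis-I interview)"))
  )
}

interview_items <- function() {
  c("regular_obe", "regular_sbe", "loss_of_control", "regular_vomiting",
    "regular_laxatives", "regular_diuretics", "regular_fasting",
    "regular_excess_exercise", "weight_phobia", "undue_influence",
    "body_disturbance", "denial_of_seriousness", "amenorrhea",
    "binge_distress")
}

#' Threshold for the questionnaire frequency fallback
#'
#' The interview only establishes the DSM-IV twice-weekly threshold; the
#' lower DSM-5 once-weekly criterion is granted through the 28-day
#' questionnaire count when the interview flag is absent. Four weeks at once
#' per week gives a count of 4.
#' @keywords internal
EDEQ_WEEKLY_FALLBACK <- 4L

#' Evaluate every diagnostic criterion for each record
#'
#' Produces the boolean criteria layer consumed by [diagnose_dsm5()],
#' [diagnose_dsm4()] and [meets_ednos_other()]. Weekly-frequency criteria
#' (binge eating and each compensatory behavior at least once weekly) are met
#' when the interview "regular" flag is true, or -- as a fallback -- when the
#' 28-day questionnaire count reaches 4; the source of each verdict is
#' recorded (`interview`, `edeq_fallback`, or `none`). The low-weight
#' criterion is bmi < 18.5. Composite criteria (anorexia psychological
#' criteria, regular purging, EDNOS-Other symptom classes) are precomputed
#' here so every rule reads from one auditable table.
#'
#' @param records cohort data.frame (see [cohort_schema()]).
#' @return data.frame, one row per record, logical criterion columns plus
#'   `*_src` provenance columns for the weekly-frequency criteria.
#' @export
evaluate_criteria <- function(records) {
  r <- validate_records(records)

  weekly <- function(flag, count) {
    met <- flag | count >= EDEQ_WEEKLY_FALLBACK
    src <- ifelse(flag, "interview",
                  ifelse(met, "edeq_fallback", "none"))
    list(met = met, src = src)
  }
  obe  <- weekly(r$regular_obe, r$obe_freq)
  vom  <- weekly(r$regular_vomiting, r$vomit_freq)
  lax  <- weekly(r$regular_laxatives, r$laxative_freq)
  diu  <- weekly(r$regular_diuretics, r$diuretic_freq)
  exe  <- weekly(r$regular_excess_exercise, r$exercise_freq)
  fast <- weekly(r$regular_fasting, as.integer(r$fasting_score))

  cr <- data.frame(
    patient_id = r$patient_id,
    weekly_obe = obe$met, weekly_obe_src = obe$src,
    weekly_vomiting = vom$met, weekly_vomiting_src = vom$src,
    weekly_laxatives = lax$met, weekly_laxatives_src = lax$src,
    weekly_diuretics = diu$met, weekly_diuretics_src = diu$src,
    weekly_exercise = exe$met, weekly_exercise_src = exe$src,
    weekly_fasting = fast$met, weekly_fasting_src = fast$src,
    stringsAsFactors = FALSE
  )
  cr$weekly_compensation <- cr$weekly_vomiting | cr$weekly_laxatives |
    cr$weekly_diuretics | cr$weekly_exercise | cr$weekly_fasting
  # interview-established behaviors (the DSM-IV twice-weekly threshold)
  cr$regular_purging <- r$regular_vomiting | r$regular_laxatives |
    r$regular_diuretics
  cr$regular_compensation <- cr$regular_purging | r$regular_fasting |
    r$regular_excess_exercise
  cr$low_weight <- r$bmi < 18.5

  # anorexia psychological criteria: B = fear of weight gain or persistent
  # weight-gain-preventing behavior; C = disturbed body experience, undue
  # influence on self-evaluation, or denial of seriousness of low weight
  cr$an_crit_b <- r$weight_phobia | r$regular_fasting |
    r$regular_excess_exercise
  cr$an_crit_c <- r$body_disturbance | r$undue_influence |
    r$denial_of_seriousness

  # EDNOS-Other symptom classes: >= 1 psychological symptom plus >= 1
  # behavioral or physical symptom (any occurrence counts, not only regular)
  cr$psych_any <- r$weight_phobia | r$undue_influence | r$body_disturbance |
    r$denial_of_seriousness
  cr$behav_any <-
    (r$regular_obe | r$regular_sbe | r$obe_freq > 0 | r$sbe_freq > 0) |
    r$loss_of_control |
    (cr$regular_purging | r$vomit_freq > 0 | r$laxative_freq > 0 |
       r$diuretic_freq > 0) |
    (r$regular_fasting | r$regular_excess_exercise | r$fasting_score > 0 |
       r$exercise_freq > 0)
  cr$phys_any <- cr$low_weight | r$amenorrhea
  cr
}

#' EDNOS-Other minimal-symptom rule
#'
#' TRUE when a record shows at least one psychological symptom (weight
#' phobia, undue influence of weight/shape on self-esteem, disturbed body
#' experience, or denial of seriousness of low weight) together with at least
#' one behavioral symptom (binge eating, loss of control during eating,
#' purging, or fasting/exercise) or physical symptom (anorexic weight or
#' amenorrhea). Occasional behavior counts: the rule marks residual
#' eating-disorder pathology below any formal category.
#'
#' @param records cohort data.frame.
#' @param criteria optional precomputed [evaluate_criteria()] output.
#' @return logical vector.
#' @export
meets_ednos_other <- function(records, criteria = NULL) {
  cr <- if (is.null(criteria)) evaluate_criteria(records) else criteria
  cr$psych_any & (cr$behav_any | cr$phys_any)
}

validate_records <- function(records) {
  needed <- cohort_schema()$column
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("records are missing required columns: ",
         paste(missing, collapse = ", "))
  }
  if (any(records$bmi <= 0)) stop("bmi must be positive")
  if (!all(records$timepoint %in% c("baseline", "month12"))) {
    stop("timepoint must be 'baseline' or 'month12'")
  }
  counts <- c("obe_freq", "sbe_freq", "vomit_freq", "laxative_freq",
              "diuretic_freq", "exercise_freq")
  for (cl in counts) {
    if (any(records[[cl]] < 0)) stop("negative 28-day count in ", cl)
  }
  flags <- c(interview_items(), "mood_disorder", "anxiety_disorder",
             "substance_use_disorder")
  for (cl in flags) {
    v <- records[[cl]]
    if (anyNA(v)) {
      warning("missing values in '", cl, "' imputed as absent")
      records[[cl]][is.na(v)] <- FALSE
    }
  }
  invisible(records)
}
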