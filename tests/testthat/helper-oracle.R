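# Brute-force truth-table oracle for the diagnostic rules, written as direct
# boolean algebra over record fields (no shared code with the engine's
# criteria/precedence machinery). Valid for records whose questionnaire
# counts are all zero, i.e. the flag_grid() domain.
oracle_dsm5 <- function(r,
                        precedence = c("RAN", "ANBP", "BN", "BED", "PD",
                                       "AAN", "SUBBN", "SUBBED")) {
  stopifnot(all(r$obe_freq == 0), all(r$vomit_freq == 0),
            all(r$fasting_score == 0))
  low <- r$bmi < 18.5
  an_b <- r$weight_phobia | r$regular_fasting | r$regular_excess_exercise
  an_c <- r$body_disturbance | r$undue_influence | r$denial_of_seriousness
  purge <- r$regular_vomiting | r$regular_laxatives | r$regular_diuretics
  comp <- purge | r$regular_fasting | r$regular_excess_exercise
  an <- low & an_b & an_c
  pass <- list(
    RAN = an & !(r$regular_obe | purge),
    ANBP = an & (r$regular_obe | purge),
    BN = r$regular_obe & comp & r$undue_influence & !an,
    BED = r$regular_obe & r$binge_distress & !comp,
    PD = purge & r$bmi > 18.5 & (r$undue_influence | r$weight_phobia) &
      !r$regular_obe,
    AAN = an_b & an_c & r$bmi >= 18.5 & comp &
      !(r$regular_obe & comp & r$undue_influence & !an) &
      !(r$regular_obe & r$binge_distress & !comp),
    SUBBN = rep(FALSE, nrow(r)),   # needs sub-weekly counts, zero here
    SUBBED = rep(FALSE, nrow(r))
  )
  out <- rep(NA_character_, nrow(r))
  for (lab in precedence) out[is.na(out) & pass[[lab]]] <- lab
  psych <- r$weight_phobia | r$undue_influence | r$body_disturbance |
    r$denial_of_seriousness
  behav <- r$regular_obe | r$regular_sbe | r$loss_of_control | purge |
    r$regular_fasting | r$regular_excess_exercise
  phys <- low | r$amenorrhea
  out[is.na(out) & psych & (behav | phys)] <- "UFED"
  out[is.na(out)] <- "NONE"
  out
}
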