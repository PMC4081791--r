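test_that("config invariants are enforced", {
  expect_error(cohort_config(n_patients = 0), "positive")
  bad_mix <- default_mixture()
  bad_mix[1] <- bad_mix[1] + 0.1
  expect_error(cohort_config(mixture = bad_mix), "sum to 1")
  expect_error(cohort_config(mixture = c(XYZ = 1)), "unknown label")
  tr <- default_transition()
  tr[1, 1] <- tr[1, 1] + 0.5
  expect_error(cohort_config(transition = tr), "transition row")
  expect_error(cohort_config(noise = 1.5), "noise")
})

test_that("every prototype is recovered by the engine; PD/AAN overlap is ordering-driven", {
  for (lab in c(ed_labels(), "UFED")) {
    p <- prototype_record(lab)
    expect_identical(diagnose_dsm5(p)$label, lab)
  }
  # restrictive anorexia is criteria-forced under every valid ordering
  ran <- prototype_record("RAN")
  orderings <- list(
    default_precedence(),
    c("SUBBED", "SUBBN", "AAN", "PD", "BED", "RAN", "ANBP", "BN"),
    c("BED", "PD", "AAN", "RAN", "ANBP", "BN", "SUBBN", "SUBBED"))
  for (ord in orderings) {
    expect_identical(diagnose_dsm5(ran, precedence = ord)$label, "RAN")
  }
  pd <- prototype_record("PD")
  expect_identical(
    diagnose_dsm5(pd, c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "SUBBN",
                        "SUBBED"))$label, "AAN")
  # the unspecified-category prototype fails all formal rules but meets
  # EDNOS-Other
  uf <- prototype_record("UFED")
  expect_true(meets_ednos_other(uf))
  expect_identical(diagnose_dsm5(uf)$label, "UFED")
  expect_error(prototype_record("NONE"), "prototype")
})

test_that("generation is deterministic and pure-mixture cohorts are criteria-forced", {
  cfg <- cohort_config(n_patients = 200, mixture = c(BN = 1), noise = 0,
                       seed = 42)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  expect_true(all(diagnose_dsm5(g1$cohort)$label == "BN"))
  expect_false("label" %in% names(g1$cohort))
})

test_that("latent labels are fully recoverable at noise zero and under symptom noise", {
  for (noise in c(0, 0.05)) {
    cfg <- cohort_config(n_patients = 1500, noise = noise, seed = 9)
    g <- generate_cohort(cfg)
    lab <- diagnose_dsm5(g$cohort, cfg$precedence)$label
    truth <- g$truth$true_label[match(g$cohort$patient_id,
                                      g$truth$patient_id)]
    expect_identical(lab, truth)
  }
})

test_that("generated counts and scores respect instrument ranges", {
  cfg <- cohort_config(n_patients = 800, seed = 3)
  g <- generate_cohort(cfg)
  for (cl in c("obe_freq", "sbe_freq", "vomit_freq", "laxative_freq",
               "diuretic_freq", "exercise_freq")) {
    v <- g$cohort[[cl]]
    expect_true(all(v >= 0 & v <= 56 & v == round(v)))
  }
  expect_true(all(g$cohort$fasting_score >= 0 & g$cohort$fasting_score <= 6))
  expect_true(all(g$cohort$edeq_global >= 0 & g$cohort$edeq_global <= 6))
  expect_true(all(g$cohort$cia >= 0 & g$cohort$cia <= 48))
  expect_true(all(g$cohort$cprs >= 0 & g$cohort$cprs <= 3))
  expect_true(all(g$cohort$age >= 18))
})

test_that("engine label frequencies recover the configured mixture at n = 5000", {
  cfg <- cohort_config(n_patients = 5000, noise = 0, seed = 101)
  g <- generate_cohort(cfg)
  lab <- diagnose_dsm5(g$cohort, cfg$precedence)$label
  mix <- cfg$mixture
  obs <- table(factor(lab, levels = names(mix)))
  for (l in names(mix)) {
    se <- sqrt(mix[[l]] * (1 - mix[[l]]) / 5000)
    expect_lt(abs(obs[[l]] / 5000 - mix[[l]]), 3 * se + 1e-12,
              label = paste("mixture recovery for", l))
  }
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = mix[names(obs)] / sum(mix)))
  expect_gt(gof$p.value, 0.01)
})

test_that("identity transitions keep labels; full-remission rows remit everyone", {
  cfg <- cohort_config(n_patients = 600, noise = 0, retention = 1, seed = 5)
  labs <- rownames(cfg$transition)
  ident <- diag(length(labs))
  rownames(ident) <- labs
  colnames(ident) <- labs[match(labs, labs)]
  ident_tr <- matrix(0, length(labs), length(followup_states()),
                     dimnames = list(labs, followup_states()))
  for (l in labs) ident_tr[l, l] <- 1
  cfg$transition <- ident_tr
  g <- generate_cohort(cfg)
  f <- generate_followup(g$cohort, g$truth, cfg)
  lab_f <- diagnose_dsm5(f$followup, cfg$precedence)$label
  truth_base <- f$truth$true_label[match(f$followup$patient_id,
                                         f$truth$patient_id)]
  expect_identical(lab_f, truth_base)

  all_rem <- ident_tr * 0
  all_rem[, "REMISSION"] <- 1
  cfg$transition <- all_rem
  f2 <- generate_followup(g$cohort, g$truth, cfg)
  expect_true(all(classify_remission(f2$followup)))
})

test_that("remission proportions per transition row are recovered at n = 5000", {
  cfg <- cohort_config(n_patients = 5000, noise = 0, retention = 1,
                       seed = 2024)
  g <- generate_cohort(cfg)
  f <- generate_followup(g$cohort, g$truth, cfg)
  rem <- classify_remission(f$followup)
  truth <- f$truth
  rem_by_id <- rem[match(truth$patient_id, f$followup$patient_id)]
  for (lab in intersect(unique(truth$true_label),
                        rownames(cfg$transition))) {
    idx <- truth$true_label == lab
    n_lab <- sum(idx)
    if (n_lab < 50) next
    target <- cfg$transition[lab, "REMISSION"]
    se <- sqrt(target * (1 - target) / n_lab)
    expect_lt(abs(mean(rem_by_id[idx]) - target), 3 * se + 1e-12,
              label = paste("remission recovery for", lab))
  }
})

test_that("attrition retains the configured fraction at random", {
  cfg <- cohort_config(n_patients = 3000, retention = 0.4, seed = 77)
  g <- generate_cohort(cfg)
  f <- generate_followup(g$cohort, g$truth, cfg)
  frac <- nrow(f$followup) / 3000
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / 3000))
  expect_error(
    generate_followup(g$cohort,
                      transform(g$truth, true_label = "XYZ"), cfg),
    "transition row missing")
})
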