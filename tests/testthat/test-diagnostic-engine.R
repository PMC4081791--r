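test_that("weekly-frequency criteria use the interview first, questionnaire fallback second", {
  r <- make_record(regular_vomiting = FALSE, vomit_freq = 6L, bmi = 22)
  cr <- evaluate_criteria(r)
  expect_true(cr$weekly_vomiting)
  expect_identical(cr$weekly_vomiting_src, "edeq_fallback")

  r2 <- make_record(regular_obe = TRUE, obe_freq = 0L, bmi = 22)
  cr2 <- evaluate_criteria(r2)
  expect_true(cr2$weekly_obe)
  expect_identical(cr2$weekly_obe_src, "interview")

  r3 <- make_record(bmi = 22)
  cr3 <- evaluate_criteria(r3)
  crit_cols <- setdiff(names(cr3)[vapply(cr3, is.logical, TRUE)], "")
  expect_false(any(unlist(cr3[crit_cols])))
  # a count just below 4 per 28 days does not reach the weekly threshold
  r4 <- make_record(obe_freq = 3L, bmi = 22)
  expect_false(evaluate_criteria(r4)$weekly_obe)
})

test_that("DSM-IV rules: anorexia needs amenorrhea, bulimia the twice-weekly interview threshold", {
  anr <- make_record(bmi = 16, amenorrhea = TRUE, weight_phobia = TRUE,
                     body_disturbance = TRUE)
  expect_identical(diagnose_dsm4(anr), "ANR")

  bnp <- make_record(bmi = 22, regular_obe = TRUE, regular_vomiting = TRUE,
                     undue_influence = TRUE)
  expect_identical(diagnose_dsm4(bnp), "BNP")

  # fails DSM-IV anorexia on amenorrhea alone, but is an ED-level presentation
  sub_an <- make_record(bmi = 16, weight_phobia = TRUE,
                        body_disturbance = TRUE)
  expect_identical(diagnose_dsm4(sub_an), "EDNOS")
  # ... and DSM-5 still gives it a formal anorexia label
  expect_identical(diagnose_dsm5(sub_an)$label, "RAN")
})

test_that("EDNOS-Other needs one psychological plus one behavioral/physical symptom", {
  expect_false(meets_ednos_other(make_record(weight_phobia = TRUE, bmi = 22)))
  expect_true(meets_ednos_other(
    make_record(weight_phobia = TRUE, vomit_freq = 1L, bmi = 22)))
  expect_false(meets_ednos_other(make_record(amenorrhea = TRUE, bmi = 22)))
  # physical symptom route: anorexic weight
  expect_true(meets_ednos_other(make_record(weight_phobia = TRUE, bmi = 17)))
})

test_that("remission = no DSM-IV diagnosis and no EDNOS-Other residue", {
  clean <- make_record(bmi = 21, timepoint = "month12")
  expect_true(classify_remission(clean))

  residual <- make_record(weight_phobia = TRUE, vomit_freq = 2L, bmi = 21,
                          timepoint = "month12")
  expect_false(classify_remission(residual))

  bn <- make_record(regular_obe = TRUE, regular_vomiting = TRUE,
                    undue_influence = TRUE, bmi = 22, timepoint = "month12")
  expect_false(classify_remission(bn))

  expect_error(classify_remission(make_record(bmi = 21)), "month12")
})

test_that("engine matches the brute-force truth-table oracle on the full flag grid", {
  grid <- flag_grid(c(16, 20, 31))
  engine <- diagnose_dsm5(grid)$label
  oracle <- oracle_dsm5(grid)
  expect_identical(engine, oracle)
})

test_that("precedence redistributes overlap labels but preserves who is diagnosed", {
  grid <- flag_grid(c(16, 20, 31))
  default <- diagnose_dsm5(grid)$label
  aan_first <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "SUBBN", "SUBBED")
  shuffled <- c("SUBBED", "SUBBN", "AAN", "PD", "RAN", "ANBP", "BED", "BN")
  for (ord in list(aan_first, shuffled)) {
    alt <- diagnose_dsm5(grid, precedence = ord)$label
    expect_identical(alt %in% ed_labels(), default %in% ed_labels())
    expect_identical(alt == "NONE", default == "NONE")
  }
  # the oracle agrees under the alternative ordering too
  expect_identical(diagnose_dsm5(grid, precedence = aan_first)$label,
                   oracle_dsm5(grid, precedence = aan_first))
})

test_that("PD/AAN overlap prototypes swap with ordering; non-overlap cohorts are stable", {
  overlap <- do.call(rbind, lapply(1:10, function(i) {
    prototype_record("PD", patient_id = paste0("pd", i))
  }))
  pd_first <- default_precedence()
  aan_first <- c("RAN", "ANBP", "BN", "BED", "AAN", "PD", "SUBBN", "SUBBED")
  tab <- precedence_sensitivity(overlap, list(pd_first, aan_first))
  counts <- function(ord, lab) {
    tab$count[tab$ordering == paste(ord, collapse = ">") & tab$label == lab]
  }
  expect_equal(counts(pd_first, "PD"), 10L)
  expect_equal(counts(pd_first, "AAN"), 0L)
  expect_equal(counts(aan_first, "PD"), 0L)
  expect_equal(counts(aan_first, "AAN"), 10L)

  pure <- do.call(rbind, lapply(c("RAN", "BN", "BED"), prototype_record))
  tab2 <- precedence_sensitivity(pure, list(pd_first, aan_first))
  expect_identical(tab2$count[tab2$ordering == tab2$ordering[1]],
                   tab2$count[tab2$ordering != tab2$ordering[1]])
})

test_that("invalid precedence orderings are rejected", {
  expect_error(diagnose_dsm5(make_record(bmi = 22),
                             precedence = c("BN", "RAN", "ANBP", "BED", "PD",
                                            "AAN", "SUBBN", "SUBBED")),
               "precede")
  expect_error(diagnose_dsm5(make_record(bmi = 22),
                             precedence = c("RAN", "ANBP", "BN")),
               "permutation")
})

test_that("every record gets exactly one label and the label set partitions the cohort", {
  grid <- flag_grid(20)
  lab <- diagnose_dsm5(grid)$label
  expect_true(all(lab %in% ed_labels_all()))
  expect_length(lab, nrow(grid))
})

test_that("DSM-5 thresholds subsume every DSM-IV anorexia/bulimia case", {
  grid <- flag_grid(c(16, 20, 31))
  d4 <- diagnose_dsm4(grid)
  d5 <- diagnose_dsm5(grid)$label
  full4 <- d4 %in% c("ANR", "ANBP", "BNP", "BNNP")
  expect_true(all(d5[full4] %in% ed_labels()))
})

test_that("adding a psychological symptom never demotes a formal diagnosis to NONE", {
  grid <- flag_grid(c(16, 20, 31))
  lab <- diagnose_dsm5(grid)$label
  formal <- grid[lab %in% ed_labels(), ]
  for (flag in c("undue_influence", "weight_phobia")) {
    bumped <- formal
    bumped[[flag]] <- TRUE
    expect_false(any(diagnose_dsm5(bumped)$label == "NONE"))
  }
})

test_that("decision traces name the category verdicts in precedence order", {
  tr <- diagnose_dsm5(prototype_record("BN"), trace = TRUE)$trace
  expect_match(tr, "^RAN:fail;ANBP:fail;BN:pass")
  expect_match(tr, "EDNOS-Other:")
})
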