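Package: edclassify
Title: Rule-Based DSM-5 Eating Disorder Classification and Clinical Cohort Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Operationalizes DSM-IV and DSM-5 eating-disorder diagnoses
    (anorexia nervosa subtypes, bulimia nervosa, binge eating disorder,
    purging disorder, atypical anorexia, sub-threshold syndromes, and the
    unspecified residual category) as an auditable rule engine over
    item-level interview and questionnaire records, with configurable
    category precedence, an EDNOS-Other minimal-symptom rule, and remission
    classification at follow-up. Ships a synthetic-cohort generator that
    emulates the diagnosis mixture, symptom-score distributions, behavior
    prevalences, psychiatric comorbidity rates, and 12-month diagnostic
    transition structure of a large Swedish specialist eating-disorder
    cohort, plus the matching inferential battery: outlier capping with
    z-gap deletion, classical and Welch one-way ANOVA with partial eta
    squared, Scheffe and Games-Howell post hocs under a dual p/Cohen's d
    reporting gate, chi-square and Fisher tests with standardized residuals,
    pairwise phi with Rea-Parker magnitude labels, residual gain scores,
    and Cronbach's alpha.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
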