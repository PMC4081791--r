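# Generative configuration for synthetic cohorts. Defaults reproduce the
# reference cohort's diagnosis mixture, per-group score distributions,
# behavior prevalences and mean frequencies, comorbidity rates, and 12-month
# transition structure.

#' Build a cohort generation configuration
#'
#' All distributional parameters default to the reference clinical cohort
#' summaries (see `ref_*` functions). Scores are drawn from per-group
#' truncated normals (instrument ranges enforced), behavior presence from
#' per-group Bernoulli rates with truncated-Poisson 28-day counts, and
#' follow-up states from a row-stochastic transition matrix over
#' diagnoses plus remission.
#'
#' @param n_patients cohort size.
#' @param mixture named probabilities over generatable labels, summing to 1.
#' @param score_params data.frame `scale`, `label`, `mean`, `sd`.
#' @param behavior_prevalence matrix behavior x label of report
#'   probabilities.
#' @param freq_params data.frame behavior x label of mean 28-day counts
#'   (ordinal 0-6 intensity for fasting).
#' @param comorbidity matrix disorder x label of probabilities.
#' @param transition row-stochastic matrix, rows = baseline labels, columns =
#'   follow-up states (`followup_states()` subset incl. `REMISSION`).
#' @param noise probability of flipping each non-defining interview
#'   indicator (defining indicators are never touched, so generated labels
#'   remain recoverable).
#' @param retention fraction of the cohort retained at 12-month follow-up
#'   (attrition is completely at random).
#' @param precedence generation-time category precedence.
#' @param seed integer RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2233,
                          mixture = default_mixture(),
                          score_params = default_score_params(),
                          behavior_prevalence = default_behavior_prevalence(),
                          freq_params = ref_freq_params(),
                          comorbidity = default_comorbidity(),
                          transition = default_transition(),
                          noise = 0.05,
                          retention = 0.237,
                          precedence = default_precedence(),
                          seed = 1L) {
  cfg <- structure(
    list(n_patients = as.integer(n_patients), mixture = mixture,
         score_params = score_params,
         behavior_prevalence = behavior_prevalence,
         freq_params = freq_params, comorbidity = comorbidity,
         transition = transition, noise = noise, retention = retention,
         precedence = precedence, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients <= 0) stop("n_patients must be positive")
  mix <- config$mixture
  known <- c(ed_labels(), "UFED")
  if (!all(names(mix) %in% known)) {
    stop("unknown label in mixture: ",
         paste(setdiff(names(mix), known), collapse = ", "))
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("mixture must be non-negative and sum to 1")
  }
  if (any(config$score_params$sd < 0)) stop("score sds must be >= 0")
  if (any(config$behavior_prevalence < 0 | config$behavior_prevalence > 1)) {
    stop("behavior prevalences must lie in [0, 1]")
  }
  if (any(config$comorbidity < 0 | config$comorbidity > 1)) {
    stop("comorbidity rates must lie in [0, 1]")
  }
  tr <- config$transition
  if (any(tr < 0) || any(abs(rowSums(tr) - 1) > 1e-9)) {
    stop("every transition row must be non-negative and sum to 1")
  }
  if (config$noise < 0 || config$noise > 1) stop("noise must lie in [0, 1]")
  if (config$retention < 0 || config$retention > 1) {
    stop("retention must lie in [0, 1]")
  }
  validate_precedence(config$precedence)
  invisible(config)
}

#' @rdname cohort_config
#' @export
default_mixture <- function() {
  d <- ref_diagnosis_distribution()
  stats::setNames(d$n / sum(d$n), d$label)
}

#' @rdname cohort_config
#' @export
default_score_params <- function() {
  sp <- ref_score_params()
  # per-group subscale moments are not published; subscales inherit the
  # global-score parameters of their group
  subs <- c("edeq_restraint", "edeq_eating_concern", "edeq_shape_concern",
            "edeq_weight_concern")
  extra <- do.call(rbind, lapply(subs, function(s) {
    g <- sp[sp$scale == "edeq_global", ]
    g$scale <- s
    g
  }))
  out <- rbind(sp, extra)
  rownames(out) <- NULL
  out
}

#' @rdname cohort_config
#' @export
default_behavior_prevalence <- function() {
  b <- ref_behavior_counts()
  prev <- sweep(b$yes, 2L, b$group_n, "/")
  prev <- cbind(prev, SUBBED = prev[, "BED"])
  prev
}

#' @rdname cohort_config
#' @export
default_comorbidity <- function() {
  cm <- ref_comorbidity_counts()
  p <- sweep(cm$yes, 2L, cm$group_n, "/")
  cbind(p, SUBBED = p[, "BED"])
}

#' @rdname cohort_config
#' @export
default_transition <- function() {
  counts <- ref_crossover_counts()
  tr <- sweep(counts, 1L, rowSums(counts), "/")
  # the sub-threshold BED group has no published follow-up row; it follows
  # the BED row proportions
  tr <- rbind(tr, SUBBED = tr["BED", ])
  tr
}

# instrument ranges used to truncate score draws
scale_bounds <- function() {
  list(edeq_global = c(0, 6), edeq_restraint = c(0, 6),
       edeq_eating_concern = c(0, 6), edeq_shape_concern = c(0, 6),
       edeq_weight_concern = c(0, 6), cia = c(0, 48), cprs = c(0, 3),
       sasb_affiliation = c(-100, 100), sasb_self_emancipation = c(0, 100),
       sasb_self_control = c(0, 100))
}
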