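# Longitudinal outcomes: diagnosis distribution composition, the 12-month
# stability/cross-over table, remission rates, and migration summaries.

#' Cross-tabulate baseline diagnoses against 12-month outcomes
#'
#' Builds the stability/cross-over table: rows are baseline diagnoses,
#' columns are follow-up diagnoses plus a terminal `REMISSION` column
#' (remission overrides the follow-up label). The diagonal is diagnostic
#' stability; off-diagonal label columns are cross-over.
#'
#' @param baseline data.frame `patient_id`, `label`.
#' @param followup data.frame `patient_id`, `label`, `remitted` (logical).
#' @return list of class `crossover_table`: `counts` (matrix), `row_pct`,
#'   `row_totals`, `n`.
#' @export
crossover_table <- function(baseline, followup) {
  if (!all(followup$patient_id %in% baseline$patient_id)) {
    stop("follow-up contains patient ids absent from baseline")
  }
  base_lab <- baseline$label[match(followup$patient_id, baseline$patient_id)]
  state <- ifelse(followup$remitted, "REMISSION", followup$label)
  rows <- intersect(c(ed_labels_all()), unique(base_lab))
  counts <- table(factor(base_lab, levels = rows),
                  factor(state, levels = followup_states()))
  counts <- unclass(counts)
  row_tot <- rowSums(counts)
  if (any(row_tot == 0)) counts <- counts[row_tot > 0, , drop = FALSE]
  row_tot <- rowSums(counts)
  structure(list(counts = counts,
                 row_pct = sweep(counts, 1L, row_tot, "/") * 100,
                 row_totals = row_tot,
                 n = sum(counts)),
            class = "crossover_table")
}

#' Build a crossover table directly from a count matrix
#'
#' Wraps an already-tabulated baseline x follow-up count matrix (e.g. the
#' reference cohort's) in the same structure [crossover_table()] produces.
#'
#' @param counts matrix, rows = baseline labels, last column `REMISSION`.
#' @return `crossover_table` object.
#' @export
as_crossover_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!"REMISSION" %in% colnames(counts)) {
    stop("counts must contain a REMISSION column")
  }
  row_tot <- rowSums(counts)
  if (any(row_tot == 0)) stop("empty baseline row in counts")
  structure(list(counts = counts,
                 row_pct = sweep(counts, 1L, row_tot, "/") * 100,
                 row_totals = row_tot,
                 n = sum(counts)),
            class = "crossover_table")
}

#' Remission rates per baseline diagnosis
#'
#' Remission count over row total per baseline label, plus the overall rate,
#' as raw percentages and display-rounded (half-up integer) values.
#'
#' @param table a `crossover_table`.
#' @return data.frame `label`, `n`, `remitted`, `pct`, `pct_display`
#'   (final row `OVERALL`).
#' @export
remission_rates <- function(table) {
  stopifnot(inherits(table, "crossover_table"))
  if (!nrow(table$counts)) stop("empty table")
  rem <- table$counts[, "REMISSION"]
  pct <- 100 * rem / table$row_totals
  out <- data.frame(label = rownames(table$counts),
                    n = as.integer(table$row_totals),
                    remitted = as.integer(rem),
                    pct = as.numeric(pct), stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(label = "OVERALL", n = table$n,
                               remitted = sum(rem),
                               pct = 100 * sum(rem) / table$n))
  out$pct_display <- round_half_up(out$pct)
  out
}

#' Diagnostic migration summary
#'
#' Per baseline diagnosis, the percentage of followed patients whose
#' follow-up diagnosis is a different formal diagnosis, excluding remission
#' and any labels in `excluded`. The headline figure is the unweighted mean
#' of the row percentages. The default exclusion set {UFED, AAN} removes the
#' two destinations that largely reflect partial remission rather than true
#' diagnostic change.
#'
#' @param table a `crossover_table`.
#' @param excluded follow-up labels not counted as migration.
#' @return list of class `migration_summary`: `per_label` (data.frame with
#'   raw and display percentages), `mean_pct`, `min_pct`, `max_pct`,
#'   `excluded`.
#' @export
migration_summary <- function(table, excluded = c("UFED", "AAN")) {
  stopifnot(inherits(table, "crossover_table"))
  dest <- setdiff(colnames(table$counts), c("REMISSION", excluded))
  if (!length(dest)) stop("all destination labels excluded")
  pct <- vapply(rownames(table$counts), function(lab) {
    cols <- setdiff(dest, lab)
    100 * sum(table$counts[lab, cols]) / table$row_totals[lab]
  }, 1)
  per_label <- data.frame(label = rownames(table$counts), pct = pct,
                          pct_display = round_half_up(pct),
                          stringsAsFactors = FALSE)
  rownames(per_label) <- NULL
  structure(list(per_label = per_label,
                 mean_pct = mean(pct),
                 min_pct = min(pct), max_pct = max(pct),
                 excluded = excluded),
            class = "migration_summary")
}

#' Composition of the residual (OSFED/UFED) diagnostic space
#'
#' From a baseline diagnosis distribution: purging disorder's share of the
#' whole cohort, its share of the residual group (atypical anorexia,
#' sub-threshold syndromes, purging disorder, and the unspecified
#' remainder), and the combined share of the three named sub-syndromes
#' (PD + AAN + sub-threshold BED) of that group.
#'
#' @param distribution named counts over the label set.
#' @return list: `pd_pct_cohort`, `pd_pct_osfed`, `named_pct_osfed`, plus
#'   `osfed_n` and `cohort_n`.
#' @export
osfed_composition <- function(distribution) {
  get <- function(lab) {
    if (lab %in% names(distribution)) as.numeric(distribution[[lab]]) else 0
  }
  cohort_n <- sum(unlist(distribution))
  osfed <- c("AAN", "SUBBN", "SUBBED", "PD", "UFED")
  osfed_n <- sum(vapply(osfed, get, 1))
  if (osfed_n == 0) stop("empty residual (OSFED) group")
  list(pd_pct_cohort = 100 * get("PD") / cohort_n,
       pd_pct_osfed = 100 * get("PD") / osfed_n,
       named_pct_osfed = 100 * (get("PD") + get("AAN") + get("SUBBED")) /
         osfed_n,
       osfed_n = osfed_n, cohort_n = cohort_n)
}
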