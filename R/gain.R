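# Change analysis and scale reliability.

#' Residual gain scores
#'
#' Change measure uncorrelated with baseline: residuals of the least-squares
#' regression of follow-up score on baseline score, computed on the pooled
#' sample (all groups together) so that between-group differences in change
#' are preserved for a subsequent ANOVA.
#'
#' @param baseline,followup paired numeric vectors, n >= 3.
#' @return numeric residual vector (sums to 0, orthogonal to baseline).
#' @export
residual_gain <- function(baseline, followup) {
  if (length(baseline) != length(followup)) {
    stop("baseline and followup must be paired")
  }
  if (length(baseline) < 3L) stop("need at least 3 pairs")
  if (stats::var(baseline) == 0) {
    stop("zero baseline variance; regression undefined")
  }
  unname(stats::resid(stats::lm(followup ~ baseline)))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' alpha = k/(k-1) * (1 - sum(item variances) / variance of the total).
#'
#' @param item_matrix numeric matrix, respondents x items (>= 2 items,
#'   >= 3 respondents).
#' @return numeric alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2L) stop("need at least 2 items")
  if (nrow(m) < 3L) stop("need at least 3 respondents")
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance; alpha undefined")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / total_var)
}
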