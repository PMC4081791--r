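# Categorical association: Pearson chi-square with standardized residuals,
# Fisher's exact test, pairwise 2x2 post hocs with phi, and the Rea-Parker
# magnitude taxonomy for phi / Cramer's V.

#' Pearson chi-square test of association
#'
#' Chi-square without continuity correction, with expected counts and
#' standardized residuals (O - E) / sqrt(E) for post-hoc inspection, and
#' Cramer's V (phi on 2x2 tables) as the effect size.
#'
#' @param table matrix of non-negative integer counts.
#' @return list of class `omnibus_result`: `method`, `statistic`, `df`,
#'   `N`, `p_value`, `effect` (Cramer's V), `effect_magnitude`, `expected`,
#'   `std_residuals`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has a zero marginal row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  N <- sum(table)
  v <- cramers_v(unname(ct$statistic), N, dim(table))
  structure(list(method = "chi2",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 N = N,
                 p_value = unname(ct$p.value),
                 effect = v,
                 effect_magnitude = association_magnitude(v),
                 expected = ct$expected,
                 std_residuals = ct$residuals),
            class = "omnibus_result")
}

cramers_v <- function(chi2, N, dims) {
  sqrt(chi2 / (N * (min(dims) - 1)))
}

#' Fisher's exact test for a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("Fisher test requires a 2x2 table")
  stats::fisher.test(table)$p.value
}

#' Rea-Parker magnitude label for phi / Cramer's V
#'
#' Half-open bins: < 0.10 negligible, 0.10-<0.20 weak, 0.20-<0.40 moderate,
#' 0.40-<0.60 relatively strong, 0.60-<0.80 strong, >= 0.80 very strong.
#'
#' @param v non-negative association coefficient(s).
#' @return character vector of labels.
#' @export
association_magnitude <- function(v) {
  if (any(v < 0, na.rm = TRUE)) stop("association coefficient must be >= 0")
  labs <- c("negligible", "weak", "moderate", "relatively strong",
            "strong", "very strong")
  as.character(cut(v, breaks = c(-Inf, 0.1, 0.2, 0.4, 0.6, 0.8, Inf),
                   right = FALSE, labels = labs))
}

#' Pairwise 2x2 post hocs for a presence/absence by group table
#'
#' Decomposes a 2 x k presence/absence table into all group pairs. Each pair
#' is tested as a 2x2 Pearson chi-square, substituting Fisher's exact test
#' whenever any expected cell falls below 5; phi = sqrt(chi2 / N) is
#' attached with its Rea-Parker magnitude, and significance is judged at the
#' stricter pairwise alpha (0.001 by convention for these decompositions).
#'
#' @param table 2 x k matrix: row 1 = present, row 2 = absent, one column
#'   per group.
#' @param alpha pairwise significance level.
#' @return data.frame: `group_a`, `group_b`, `test`, `p_value`, `phi`,
#'   `magnitude`, `significant`.
#' @export
pairwise_categorical <- function(table, alpha = 0.001) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 3L) {
    stop("expect a 2-row presence/absence table with >= 3 groups")
  }
  if (is.null(colnames(table))) {
    colnames(table) <- paste0("g", seq_len(ncol(table)))
  }
  combs <- utils::combn(colnames(table), 2L)
  rows <- apply(combs, 2L, function(pr) {
    sub <- table[, pr]
    if (all(sub[1, ] == 0) || all(sub[2, ] == 0)) {
      stop("degenerate pair ", pr[1], "-", pr[2],
           ": a presence/absence row is all zero")
    }
    N <- sum(sub)
    exp_cells <- outer(rowSums(sub), colSums(sub)) / N
    chi2 <- sum((sub - exp_cells)^2 / exp_cells)
    phi <- sqrt(chi2 / N)
    if (any(exp_cells < 5)) {
      p <- fisher_exact_2x2(sub)
      test <- "fisher"
    } else {
      p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
      test <- "chi2"
    }
    data.frame(group_a = pr[1], group_b = pr[2], test = test, p_value = p,
               phi = phi, magnitude = association_magnitude(phi),
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Omnibus chi-square for a behavior across diagnostic groups
#'
#' Builds the presence/absence x group table from per-group reporter counts
#' and group sizes, dropping criterion-confounded groups, and runs
#' [chi_square()]. This is the computation behind the behavior and
#' comorbidity omnibus tables.
#'
#' @param yes named vector of reporter counts per group.
#' @param group_n named vector of group sizes.
#' @param omit labels to exclude (groups for which the behavior is itself a
#'   criterion).
#' @return `omnibus_result` with the 2 x k `table` attached.
#' @export
behavior_chi_square <- function(yes, group_n, omit = character(0)) {
  keep <- setdiff(names(group_n), omit)
  tab <- rbind(present = yes[keep], absent = group_n[keep] - yes[keep])
  colnames(tab) <- keep
  res <- chi_square(tab)
  res$table <- tab
  res
}
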