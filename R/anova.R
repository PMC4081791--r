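# Continuous group comparisons: classical and Welch one-way ANOVA with
# partial eta squared, Scheffe and Games-Howell pairwise contrasts, Cohen's
# d, and the dual p/d reporting gate.

#' Effect-size magnitude labels for partial eta squared
#'
#' Conventional anchors: >= 0.01 small, >= 0.06 medium, >= 0.14 large.
#' @param eta partial eta squared value(s).
#' @return character vector of labels.
#' @export
eta_squared_magnitude <- function(eta) {
  if (any(eta < 0, na.rm = TRUE)) stop("eta squared cannot be negative")
  cut(eta, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large")) |> as.character()
}

groups_as_list <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups[[1]], groups[[2]])
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs n >= 2")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

anova_sums <- function(groups) {
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ns <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  list(ss_b = ss_b, ss_w = ss_w, ns = ns, means = means,
       k = length(groups), N = length(all_x))
}

#' Classical one-way ANOVA with partial eta squared
#'
#' Fixed-effects omnibus F test (pooled error variance) with
#' eta_p^2 = SS_between / (SS_between + SS_within).
#'
#' @param groups named list of numeric vectors (or a two-column data.frame
#'   of value, group).
#' @return list of class `omnibus_result`: `method`, `statistic`, `df`,
#'   `p_value`, `effect` (partial eta squared), `effect_magnitude`, `N`.
#' @export
one_way_anova <- function(groups) {
  groups <- groups_as_list(groups)
  s <- anova_sums(groups)
  ot <- stats::oneway.test(values ~ g, data = stack_groups(groups),
                           var.equal = TRUE)
  eta <- s$ss_b / (s$ss_b + s$ss_w)
  structure(list(method = "anova",
                 statistic = unname(ot$statistic),
                 df = unname(ot$parameter),
                 p_value = unname(ot$p.value),
                 effect = eta,
                 effect_magnitude = eta_squared_magnitude(eta),
                 N = s$N),
            class = "omnibus_result")
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F with Welch-Satterthwaite denominator degrees of freedom, used
#' when group sizes are small/unequal and variances differ. Partial eta
#' squared is still reported from the classical sums of squares.
#'
#' @inheritParams one_way_anova
#' @return list of class `omnibus_result` (method `"welch"`).
#' @export
welch_anova <- function(groups) {
  groups <- groups_as_list(groups)
  if (all(vapply(groups, stats::var, 1) == 0)) {
    stop("Welch ANOVA undefined when every group has zero variance")
  }
  s <- anova_sums(groups)
  ot <- stats::oneway.test(values ~ g, data = stack_groups(groups),
                           var.equal = FALSE)
  eta <- s$ss_b / (s$ss_b + s$ss_w)
  structure(list(method = "welch",
                 statistic = unname(ot$statistic),
                 df = unname(ot$parameter),
                 p_value = unname(ot$p.value),
                 effect = eta,
                 effect_magnitude = eta_squared_magnitude(eta),
                 N = s$N),
            class = "omnibus_result")
}

stack_groups <- function(groups) {
  data.frame(values = unlist(groups, use.names = FALSE),
             g = factor(rep(names(groups), vapply(groups, length, 1L))))
}

#' Cohen's d for two independent samples
#'
#' Pooled-SD standardized mean difference, (n-1)-weighted pooling.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @return numeric d (positive when `mean(a) > mean(b)`).
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("pooled SD is zero; d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Dual significance gate for pairwise contrasts
#'
#' The reporting rule for post-hoc contrasts: a difference counts only when
#' it is both statistically reliable (p below `alpha`) and at least a
#' medium-sized effect (|d| at or above `d_min`). Guards against trivially
#' small but significant differences in large groups.
#'
#' @param p_value,d contrast p-value and Cohen's d.
#' @param alpha,d_min gate thresholds (defaults 0.01 and 0.50).
#' @return logical.
#' @export
passes_dual_gate <- function(p_value, d, alpha = 0.01, d_min = 0.50) {
  p_value < alpha & abs(d) >= d_min
}

contrast_frame <- function(pairs, method, alpha, d_min) {
  pairs$passes_gate <- passes_dual_gate(pairs$p_value, pairs$cohens_d,
                                        alpha, d_min)
  pairs$method <- method
  pairs
}

#' Scheffe all-pairwise contrasts
#'
#' Each pairwise statistic is referenced against the Scheffe distribution:
#' F_s = t^2 / (k - 1) on (k - 1, N - k) degrees of freedom with the pooled
#' error variance, which controls the error rate over every possible
#' contrast and is therefore never more significant than the unadjusted
#' pairwise test. The dual p/d gate is applied to every contrast.
#'
#' @inheritParams one_way_anova
#' @param alpha,d_min dual-gate thresholds.
#' @return data.frame: `group_a`, `group_b`, `mean_diff`, `p_value`,
#'   `cohens_d`, `passes_gate`, `method`.
#' @export
scheffe_contrasts <- function(groups, alpha = 0.01, d_min = 0.50) {
  groups <- groups_as_list(groups)
  s <- anova_sums(groups)
  mse <- s$ss_w / (s$N - s$k)
  combs <- utils::combn(names(groups), 2L)
  rows <- apply(combs, 2L, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    diff <- mean(a) - mean(b)
    se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
    fs <- (diff / se)^2 / (s$k - 1)
    data.frame(group_a = pr[1], group_b = pr[2], mean_diff = diff,
               p_value = stats::pf(fs, s$k - 1, s$N - s$k,
                                   lower.tail = FALSE),
               cohens_d = cohens_d(a, b), stringsAsFactors = FALSE)
  })
  contrast_frame(do.call(rbind, rows), "scheffe", alpha, d_min)
}

#' Games-Howell all-pairwise contrasts
#'
#' Heteroscedastic post hoc companion to Welch's ANOVA: each pair uses its
#' own variances, Welch-Satterthwaite degrees of freedom, and the
#' studentized-range reference distribution. The dual p/d gate is applied.
#'
#' @inheritParams scheffe_contrasts
#' @return data.frame as in [scheffe_contrasts()] (method `"games_howell"`).
#' @export
games_howell_contrasts <- function(groups, alpha = 0.01, d_min = 0.50) {
  groups <- groups_as_list(groups)
  k <- length(groups)
  combs <- utils::combn(names(groups), 2L)
  rows <- apply(combs, 2L, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    na <- length(a); nb <- length(b)
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    if (se == 0) stop("zero variance in pair ", pr[1], "-", pr[2])
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    diff <- mean(a) - mean(b)
    p <- stats::ptukey(sqrt(2) * abs(diff) / se, k, df, lower.tail = FALSE)
    data.frame(group_a = pr[1], group_b = pr[2], mean_diff = diff,
               p_value = p, cohens_d = cohens_d(a, b),
               stringsAsFactors = FALSE)
  })
  contrast_frame(do.call(rbind, rows), "games_howell", alpha, d_min)
}

#' Omnibus + post hoc selection with the Welch trigger
#'
#' Chooses between the classical ANOVA/Scheffe route and the Welch/
#' Games-Howell route. The Welch route is triggered when variances are
#' unequal (Brown-Forsythe Levene test, `car::leveneTest` with median
#' centering, p < `levene_alpha`) and the smallest group is small
#' (min n < `small_n`); `force` overrides the trigger in either direction.
#'
#' @inheritParams scheffe_contrasts
#' @param levene_alpha,small_n Welch trigger parameters.
#' @param force `NA` (auto), `"welch"`, or `"classic"`.
#' @return list: `omnibus` (an `omnibus_result`), `contrasts` (gated
#'   contrast data.frame), `welch_used`, `levene_p`.
#' @export
compare_groups <- function(groups, alpha = 0.01, d_min = 0.50,
                           levene_alpha = 0.05, small_n = 30,
                           force = NA_character_) {
  groups <- groups_as_list(groups)
  dat <- stack_groups(groups)
  lev <- car::leveneTest(values ~ g, data = dat)
  lev_p <- lev[["Pr(>F)"]][1]
  use_welch <- if (!is.na(force)) {
    force == "welch"
  } else {
    lev_p < levene_alpha && min(vapply(groups, length, 1L)) < small_n
  }
  if (use_welch) {
    list(omnibus = welch_anova(groups),
         contrasts = games_howell_contrasts(groups, alpha, d_min),
         welch_used = TRUE, levene_p = lev_p)
  } else {
    list(omnibus = one_way_anova(groups),
         contrasts = scheffe_contrasts(groups, alpha, d_min),
         welch_used = FALSE, levene_p = lev_p)
  }
}
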