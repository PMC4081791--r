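test_that("cap-then-gap-delete reproduces the worked example and identity cases", {
  res <- cap_and_gap_delete(list(g = c(1, 2, 3, 50)), cap = 30)
  expect_equal(res$values$g, c(1, 2, 3))
  expect_identical(res$log$action, c("cap", "delete"))
  expect_equal(res$log$original, c(50, 30))

  # zero SD: nothing to standardize against
  res2 <- cap_and_gap_delete(list(g = c(5, 5, 5, 5)), cap = 30)
  expect_equal(res2$values$g, c(5, 5, 5, 5))

  # max z-gap <= 1: identity transform
  res3 <- cap_and_gap_delete(list(g = c(1, 2, 3, 4, 5)), cap = 30)
  expect_equal(res3$values$g, c(1, 2, 3, 4, 5))
  expect_equal(nrow(res3$log), 0L)

  # tied outlying block is deleted together
  res4 <- cap_and_gap_delete(list(g = c(1, 2, 3, 40, 40)), cap = 100)
  expect_equal(res4$values$g, c(1, 2, 3))

  expect_warning(cap_and_gap_delete(list(g = c(1, 2)), cap = 10),
                 "fewer than 3")
  expect_error(cap_and_gap_delete(list(g = 1:5), cap = -1), "positive")
})

test_that("two-group ANOVA F equals t-squared for both pooled and Welch variants", {
  set.seed(1)
  a <- rnorm(14, 10, 1)
  b <- rnorm(23, 11, 3)
  g <- list(a = a, b = b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(one_way_anova(g)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(one_way_anova(g)$p_value, tt$p.value, tolerance = 1e-9)
  tw <- t.test(a, b)
  expect_equal(welch_anova(g)$statistic, unname(tw$statistic)^2,
               tolerance = 1e-9)
  expect_equal(welch_anova(g)$p_value, tw$p.value, tolerance = 1e-9)
})

test_that("identical groups give F near 0 and eta_p2 near 0; magnitudes follow the anchors", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res <- one_way_anova(g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$effect, 0, tolerance = 1e-12)
  expect_identical(eta_squared_magnitude(c(0.005, 0.03, 0.08, 0.174)),
                   c("negligible", "small", "medium", "large"))
  expect_error(welch_anova(list(a = c(1, 1), b = c(2, 2))), "zero variance")
})

test_that("Cohen's d follows the pooled-SD formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(cohens_d(x, x), 0)
  set.seed(2)
  a <- rnorm(50); a <- (a - mean(a)) / sd(a) * 2 + 3   # mean 3, sd 2
  b <- rnorm(50); b <- (b - mean(b)) / sd(b) * 2 + 2   # mean 2, sd 2
  expect_equal(cohens_d(a, b), 0.5, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("Scheffe contrasts are conservative and dual-gated", {
  set.seed(3)
  g <- list(a = rnorm(20, 0), b = rnorm(25, 0.5), c = rnorm(15, 1.2))
  sc <- scheffe_contrasts(g)
  s <- edclassify:::anova_sums(lapply(g, identity))
  mse <- s$ss_w / (s$N - s$k)
  for (i in seq_len(nrow(sc))) {
    a <- g[[sc$group_a[i]]]; b <- g[[sc$group_b[i]]]
    t_stat <- (mean(a) - mean(b)) /
      sqrt(mse * (1 / length(a) + 1 / length(b)))
    p_unadj <- 2 * pt(-abs(t_stat), df = s$N - s$k)
    expect_gte(sc$p_value[i], p_unadj - 1e-12)
  }
  expect_identical(sc$passes_gate,
                   sc$p_value < 0.01 & abs(sc$cohens_d) >= 0.5)
  # identical groups: p near 1, d = 0, gate fails
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  sc2 <- scheffe_contrasts(same)
  expect_gt(sc2$p_value, 0.99)
  expect_equal(sc2$cohens_d, 0)
  expect_false(sc2$passes_gate)
})

test_that("Games-Howell p-values match an independent reference implementation", {
  a <- c(10.305, 8.96, 10.75, 10.941, 8.049, 8.698, 10.128, 9.684)
  b <- c(11.933, 8.588, 15.518, 15.111, 12.264, 16.509, 13.87, 8.563,
         13.475, 8.164, 15.514, 11.8, 11.261, 9.276, 16.89)
  c_ <- c(10.691, 10.143, 10.296, 12.065, 11.731, 11.825, 11.862, 15.283,
          10.187, 9.976, 9.372)
  gh <- games_howell_contrasts(list(a = a, b = b, c = c_))
  # reference p-values computed with pingouin 0.6.1 pairwise_gameshowell
  expect_equal(gh$p_value, c(0.0083252000, 0.0569880979, 0.3162697116),
               tolerance = 1e-6)
})

test_that("chi-square matches brute force and phi identity holds on random tables", {
  set.seed(4)
  for (i in 1:20) {
    r <- sample(2:4, 1); k <- sample(2:5, 1)
    tab <- matrix(rpois(r * k, 12) + 1, r, k)
    res <- chi_square(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(unname(res$std_residuals), unname((tab - E) / sqrt(E)),
                 tolerance = 1e-10)
    expect_true(res$effect >= 0 && res$effect <= 1 + 1e-12)
    if (r == 2 && k == 2) {
      expect_equal(res$effect, sqrt(res$statistic / res$N),
                   tolerance = 1e-10)
    }
  }
  # identical row proportions: no association
  expect_equal(chi_square(rbind(c(10, 20, 30), c(20, 40, 60)))$statistic, 0,
               tolerance = 1e-12)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("pairwise categorical post hocs report phi with Rea-Parker magnitudes", {
  tab <- rbind(present = c(30, 28, 5), absent = c(10, 12, 35))
  colnames(tab) <- c("A", "B", "C")
  ph <- pairwise_categorical(tab)
  for (i in seq_len(nrow(ph))) {
    sub <- tab[, c(ph$group_a[i], ph$group_b[i])]
    expect_equal(ph$phi[i],
                 sqrt(chi_square(sub)$statistic / sum(sub)),
                 tolerance = 1e-10)
  }
  expect_identical(ph$magnitude, association_magnitude(ph$phi))

  flat <- cbind(A = c(10, 10), B = c(10, 10), C = c(10, 10))
  ph0 <- pairwise_categorical(flat)
  expect_equal(ph0$phi, rep(0, 3))
  expect_identical(ph0$magnitude, rep("negligible", 3))

  expect_identical(association_magnitude(c(0.05, 0.15, 0.26, 0.40, 0.50,
                                           0.65, 1.0)),
                   c("negligible", "weak", "moderate", "relatively strong",
                     "relatively strong", "strong", "very strong"))
  expect_error(association_magnitude(-0.1), ">= 0")
})

test_that("Fisher substitutes for chi-square when expected cells are small", {
  tab <- rbind(present = c(2, 1, 20), absent = c(30, 28, 15))
  colnames(tab) <- c("A", "B", "C")
  ph <- pairwise_categorical(tab)
  ab <- ph[ph$group_a == "A" & ph$group_b == "B", ]
  expect_identical(ab$test, "fisher")
  expect_equal(ab$p_value,
               fisher_exact_2x2(tab[, c("A", "B")]), tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(1, 2, 3)), "2x2")
})

test_that("residual gain scores are centered, baseline-orthogonal change measures", {
  set.seed(5)
  base <- rnorm(40, 10, 2)
  expect_equal(residual_gain(base, 2 * base), rep(0, 40), tolerance = 1e-10)
  fup <- 0.6 * base + rnorm(40)
  rg <- residual_gain(base, fup)
  expect_equal(sum(rg), 0, tolerance = 1e-9)
  expect_equal(sum(rg * base), 0, tolerance = 1e-8)
  expect_error(residual_gain(rep(1, 10), rnorm(10)), "baseline variance")
  expect_error(residual_gain(1:4, 1:3), "paired")
})

test_that("group ANOVA on residual gains holds its nominal type-I error under the null", {
  set.seed(6)
  reps <- 1000
  n_per <- c(30, 25, 20)
  grp <- factor(rep(letters[1:3], n_per))
  rejections <- vapply(seq_len(reps), function(i) {
    base <- rnorm(sum(n_per), 5, 1.5)
    fup <- 0.5 * base + rnorm(sum(n_per))
    rg <- residual_gain(base, fup)
    one_way_anova(split(rg, grp))$p_value < 0.01
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / reps) + 1e-12)
})

test_that("Cronbach's alpha: duplicated, independent, and parallel items", {
  set.seed(7)
  x <- rnorm(200)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  noise <- matrix(rnorm(5 * 4000), ncol = 5)
  expect_lt(abs(cronbach_alpha(noise)), 0.05)

  # parallel items with loading lambda: alpha -> Spearman-Brown value
  lambda <- 0.8; k <- 6; n <- 20000
  f <- rnorm(n)
  items <- sapply(seq_len(k), function(i) lambda * f + rnorm(n))
  rho <- lambda^2 / (lambda^2 + 1)
  sb <- k * rho / (1 + (k - 1) * rho)
  expect_equal(cronbach_alpha(items), sb, tolerance = 0.02)

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "variance")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)), "2 items")
})

test_that("the Welch trigger routes unequal-variance small samples to Games-Howell", {
  set.seed(8)
  g_het <- list(a = rnorm(12, 0, 0.5), b = rnorm(15, 1, 4),
                c = rnorm(10, 0.5, 2))
  res <- compare_groups(g_het)
  expect_true(res$welch_used)
  expect_identical(res$omnibus$method, "welch")
  expect_identical(unique(res$contrasts$method), "games_howell")

  g_big <- list(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  res2 <- compare_groups(g_big)
  expect_false(res2$welch_used)
  expect_identical(unique(res2$contrasts$method), "scheffe")
  res3 <- compare_groups(g_big, force = "welch")
  expect_true(res3$welch_used)
})
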