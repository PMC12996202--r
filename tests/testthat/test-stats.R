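# Rank tests, effect sizes, correlations, multiplicity control, and the
# interval estimators — each checked against an independent oracle or a
# value that is a closed-form function of published inputs.

# Brute-force Mann-Whitney oracle: count pairs won plus half the ties.
mw_oracle_u <- function(a, b) {
  wins_a <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  wins_b <- sum(outer(b, a, ">")) + 0.5 * sum(outer(b, a, "=="))
  min(wins_a, wins_b)
}

# Brute-force BH step-up oracle straight from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(ord)]
}

test_that("Mann-Whitney U matches the exhaustive pairwise oracle", {
  set.seed(301)
  for (i in 1:8) {
    a <- sample(round(rnorm(20, 50, 10)))  # rounding forces ties
    b <- sample(round(rnorm(31, 55, 10)))
    mw <- mann_whitney(a, b)
    expect_equal(mw$U, mw_oracle_u(a, b))
    # tie-corrected normal p agrees with the base-R test without
    # continuity correction
    wt <- suppressWarnings(wilcox.test(a, b, correct = FALSE, exact = FALSE))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney degenerate cases behave as symmetry dictates", {
  a <- c(1, 2, 3, 4)
  mw <- mann_whitney(a, a)
  expect_equal(mw$U, length(a)^2 / 2)
  expect_equal(mw$Z, 0)
  expect_equal(mw$p, 1)
  sep <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$U, 0)
  expect_identical(sep$direction, "a>b")
  expect_error(mann_whitney(numeric(0), a), "nonempty")
})

test_that("published effect sizes follow from published U values", {
  # r = |Z|/sqrt(N) with the no-tie normal approximation, N = 51
  head_row <- u_to_z_r(182, 20, 31)
  expect_equal(round(head_row$r, 3), 0.346)
  expect_equal(round(head_row$p, 3), 0.014)
  hand_row <- u_to_z_r(160, 20, 31)
  expect_equal(round(hand_row$r, 3), 0.405)
  expect_equal(effect_size_r(0, 51), 0)
})

test_that("U is recovered from published mean ranks", {
  expect_equal(u_from_mean_ranks(33.75, 20, 21.00, 31), 155)
  # no separation: both mean ranks (N+1)/2 -> U = n1 n2 / 2
  expect_equal(u_from_mean_ranks(26, 20, 26, 31), 20 * 31 / 2)
  expect_error(u_from_mean_ranks(30, 20, 21, 31), "inconsistent")
})

test_that("Spearman rho matches rank-then-Pearson and bounds its CI", {
  set.seed(302)
  for (i in 1:5) {
    x <- round(rnorm(25), 1); y <- round(x + rnorm(25), 1)  # ties included
    ct <- spearman_ci(x, y)
    expect_equal(ct$rho, cor(rank(x), rank(y)))
    expect_true(ct$ci_low <= ct$rho && ct$rho <= ct$ci_high)
  }
  expect_equal(spearman_ci(1:10, (1:10)^3)$rho, 1)
  expect_error(spearman_ci(rep(1, 10), 1:10), "zero variance")
})

test_that("Fisher-z interval covers the null at about the nominal rate", {
  set.seed(303)
  covered <- vapply(1:300, function(i) {
    x <- rnorm(30); y <- rnorm(30)
    ct <- spearman_ci(x, y)
    ct$ci_low <= 0 && 0 <= ct$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.995)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(304)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12 & adj <= 1))
    # monotone nondecreasing in sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # the rejection set at level q is a fixed point of re-adjustment
    expect_identical(bh_adjust(adj) <= 0.05, adj <= 0.05)
  }
})

test_that("domain Bonferroni uses 0.05/m with a strict threshold", {
  res <- domain_bonferroni(list(
    head = c(head = 0.014),
    left_lower_limb = c(left_hip = 0.2, left_knee = 0.015,
                        left_ankle = 0.0009, left_foot = 0.0125)))
  expect_equal(res$alpha_adj[res$domain == "head"], 0.05)
  expect_equal(unique(res$alpha_adj[res$domain == "left_lower_limb"]), 0.0125)
  expect_true(res$significant[res$outcome == "head"])
  expect_true(res$significant[res$outcome == "left_ankle"])
  expect_false(res$significant[res$outcome == "left_foot"])  # p == alpha_adj
  expect_error(domain_bonferroni(list(torso = c(a = 0.5))), "unknown domain")
})

test_that("summary-statistic t test reproduces the demographics row", {
  # control 52.58 (3.40), n=31 vs risk 52.75 (3.95), n=20
  tt <- pooled_t_from_summary(52.58, 3.40, 31, 52.75, 3.95, 20)
  expect_equal(round(tt$t, 2), -0.16)
  expect_identical(tt$df, 49)
  expect_equal(round(tt$p, 2), 0.87)
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
})

test_that("summary t equals the long-form t test on matching vectors", {
  make_vec <- function(n, m, s) {
    v <- scale(rnorm(n))  # exact mean 0, sd 1
    as.vector(v * s + m)
  }
  set.seed(305)
  a <- make_vec(31, 52.58, 3.40); b <- make_vec(20, 52.75, 3.95)
  tt <- pooled_t_from_summary(52.58, 3.40, 31, 52.75, 3.95, 20)
  long <- t.test(a, b, var.equal = TRUE)
  expect_equal(tt$t, unname(long$statistic), tolerance = 1e-10)
  expect_equal(tt$p, long$p.value, tolerance = 1e-10)
})

test_that("2x2 chi-square reproduces the sex table and the direct formula", {
  counts <- matrix(c(15, 14, 16, 6), 2)  # rows: control/risk; cols: boys/girls
  ct <- chi2_2x2(counts)
  expect_equal(round(ct$chi2, 2), 2.32)
  expect_identical(ct$df, 1L)
  expect_equal(round(ct$p, 2), 0.13)
  # direct sum((O-E)^2/E) oracle
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(ct$chi2, sum((counts - e)^2 / e))
  same <- matrix(c(10, 20, 5, 10), 2)    # identical column proportions
  expect_equal(chi2_2x2(same)$chi2, 0)
  expect_equal(chi2_2x2(same)$p, 1)
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "zero marginal")
})

test_that("Wilson intervals match published bounds and the score test", {
  w36 <- wilson_interval(36, 51)
  expect_equal(round(100 * w36, 1), c(low = 57.0, high = 81.3))
  w30 <- wilson_interval(30, 51)
  expect_equal(round(100 * w30[["low"]], 1), 45.2)
  expect_equal(round(100 * w30[["high"]], 1), 71.2)
  expect_equal(wilson_interval(0, 20)[["low"]], 0)
  # prop.test without continuity correction inverts the same score test
  for (k in c(1, 10, 25, 50)) {
    pt <- prop.test(k, 51, correct = FALSE)$conf.int
    expect_equal(unname(wilson_interval(k, 51)), as.vector(pt),
                 tolerance = 1e-10)
  }
})

test_that("Hanley-McNeil intervals match the published AUC rows", {
  expect_equal(round(hanley_mcneil_ci(0.76, 20, 31), 2),
               c(low = 0.62, high = 0.90))
  expect_equal(round(hanley_mcneil_ci(0.42, 20, 31), 2),
               c(low = 0.26, high = 0.58))
  sym <- hanley_mcneil_ci(0.5, 15, 15)
  expect_equal(unname(sym[1] + sym[2]), 1, tolerance = 1e-12)
  ci <- hanley_mcneil_ci(0.97, 10, 10)
  expect_true(all(ci >= 0 & ci <= 1))
})

test_that("Shapiro gate picks the nonparametric branch under skew", {
  set.seed(306)
  gauss <- list(a = rnorm(40), b = rnorm(40))
  expect_identical(shapiro_gate(gauss), "parametric")
  skewed <- list(a = rnorm(40), b = rlnorm(40, sdlog = 1.5))
  expect_identical(shapiro_gate(skewed), "nonparametric")
  expect_identical(shapiro_gate(skewed), shapiro_gate(skewed))  # deterministic
  expect_error(shapiro_gate(list(a = 1:2, b = rnorm(10))), "at least 3")
})

test_that("inter-regional Spearman matrix is symmetric with unit diagonal", {
  set.seed(307)
  n <- 40
  ft <- as.data.frame(matrix(rnorm(n * 15), n))
  names(ft) <- regions_analysis
  m <- spearman_matrix(ft)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 15))
  ft$right_ankle <- ft$left_ankle   # duplicated column
  expect_equal(spearman_matrix(ft)["left_ankle", "right_ankle"], 1)
  # independent columns, larger n: off-diagonals near zero
  ft2 <- as.data.frame(matrix(rnorm(600 * 15), 600))
  names(ft2) <- regions_analysis
  m2 <- spearman_matrix(ft2)
  expect_lt(max(abs(m2[upper.tri(m2)])), 0.2)
  ft$head <- 1
  expect_error(spearman_matrix(ft), "zero-variance")
})

test_that("group test table assembles U, r, FDR and direction coherently", {
  co <- generate_cohort(small_spec(n_risk = 10L, n_control = 12L,
                                   duration_s = 5, seed = 51L))
  ft <- features_of(co)
  tab <- group_test_table(ft)
  expect_identical(tab$region, regions_analysis)
  expect_true(all(tab$U >= 0 & tab$U <= 10 * 12 / 2))
  expect_true(all(tab$r >= 0 & tab$r <= 1))
  expect_equal(tab$p_fdr, bh_oracle(tab$p_raw))
  expect_true(all(tab$direction %in% c("risk>control", "control>risk", "n.s.")))
})
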