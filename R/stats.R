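# Univariate statistics: normality gating, Mann-Whitney U with rank
# effect size r, Spearman correlations with Fisher-z intervals,
# Benjamini-Hochberg FDR, domain-wise Bonferroni, summary-statistic t
# and chi-square tests, and the interval estimators used for
# classification metrics (Wilson, Hanley-McNeil).

#' Shapiro-Wilk gate for test selection
#'
#' Returns `"nonparametric"` if the Shapiro-Wilk test rejects normality
#' (p < alpha) in at least one group, else `"parametric"`.
#'
#' @param values_by_group List of numeric vectors (>= 3 values each).
#' @param alpha Rejection level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
shapiro_gate <- function(values_by_group, alpha = 0.05) {
  if (any(vapply(values_by_group, length, 1L) < 3L))
    stop("each group needs at least 3 values for the Shapiro-Wilk test")
  p <- vapply(values_by_group, function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (any(p < alpha)) "nonparametric" else "parametric"
}

#' Mann-Whitney U test with standardized statistic
#'
#' Joint midranks; `U_i = R_i - n_i(n_i+1)/2` per group; the reported U
#' is `min(U_1, U_2)`. Z uses the tie-corrected normal approximation
#' `Z = (U - n1 n2 / 2) / sigma`, the two-sided p comes from the normal
#' distribution, and direction is read off the mean ranks.
#'
#' @param a,b Numeric vectors (group a = risk convention downstream).
#' @return List: `U`, `U_a`, `U_b`, `Z`, `p`, `mean_rank_a`,
#'   `mean_rank_b`, `direction` (`"a>b"`, `"b>a"` or `"n.s."` when the
#'   ranks are tied on average).
#' @export
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  r1 <- sum(r[seq_len(n1)]); r2 <- sum(r[n1 + seq_len(n2)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  u2 <- r2 - n2 * (n2 + 1) / 2
  u <- min(u1, u2)
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
  mr1 <- r1 / n1; mr2 <- r2 / n2
  direction <- if (mr1 > mr2) "a>b" else if (mr2 > mr1) "b>a" else "n.s."
  list(U = u, U_a = u1, U_b = u2, Z = z, p = p,
       mean_rank_a = mr1, mean_rank_b = mr2, direction = direction)
}

#' Rank-test effect size r
#'
#' `r = |Z| / sqrt(N)` from the standardized test statistic and total
#' sample size.
#'
#' @param z Standardized statistic.
#' @param n_total Total sample size (>= 2).
#' @return r in \[0, 1\].
#' @export
effect_size_r <- function(z, n_total) {
  stopifnot(n_total >= 2)
  abs(z) / sqrt(n_total)
}

#' Z and effect size r for a U statistic under the no-tie approximation
#'
#' `Z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)`; used to
#' recover printed effect sizes from printed U values.
#'
#' @param u Reported U (either group's).
#' @param n1,n2 Group sizes.
#' @return List: `Z`, `r`, `p` (two-sided normal).
#' @export
u_to_z_r <- function(u, n1, n2) {
  z <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  list(Z = z, r = effect_size_r(z, n1 + n2),
       p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Recover U from printed mean ranks
#'
#' `U_i = n_i * mean_rank_i - n_i(n_i+1)/2`; returns `min(U_1, U_2)`.
#' The rank sums must be consistent: `n1*mr1 + n2*mr2 = N(N+1)/2`.
#'
#' @param mean_rank1,mean_rank2 Group mean ranks.
#' @param n1,n2 Group sizes.
#' @return U (scalar).
#' @export
u_from_mean_ranks <- function(mean_rank1, n1, mean_rank2, n2) {
  n <- n1 + n2
  if (abs(n1 * mean_rank1 + n2 * mean_rank2 - n * (n + 1) / 2) > 1e-6)
    stop("inconsistent mean ranks: rank sums do not total N(N+1)/2")
  u1 <- n1 * mean_rank1 - n1 * (n1 + 1) / 2
  u2 <- n2 * mean_rank2 - n2 * (n2 + 1) / 2
  min(u1, u2)
}

#' Spearman correlation with Fisher-z confidence interval
#'
#' Midrank-based Spearman rho; the CI uses the Fisher z transform with
#' `SE = 1/sqrt(n-3)`; the two-sided p uses the t approximation with
#' `n - 2` df.
#'
#' @param x,y Paired numeric vectors (n >= 4).
#' @param conf Confidence level (default 0.95).
#' @return List: `rho`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  zr <- atanh(rho)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(zr + c(-1, 1) * zq * se)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p values (monotone, capped at 1),
#' order-preserving with the input.
#'
#' @param p Vector of raw p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Domain-wise Bonferroni correction
#'
#' Movement outcomes are grouped a priori into five anatomical domains
#' (head; right/left upper limb; right/left lower limb). Each domain's
#' threshold is `alpha / m` with `m` the number of outcomes the domain
#' comprises, so each four-outcome limb domain tests at 0.0125 while the
#' single-outcome head domain stays at 0.05. Significance is strict
#' (`p < alpha_adj`).
#'
#' @param p_by_domain Named list: domain -> named numeric vector of raw
#'   p values for the outcomes tested in that domain.
#' @param domain_sizes Named integer vector giving `m` per domain;
#'   defaults to the sizes of the a priori [region_domains] map.
#' @param alpha Family alpha (default 0.05).
#' @return Data frame: `domain`, `outcome`, `m`, `alpha_adj`, `p`,
#'   `significant`.
#' @export
domain_bonferroni <- function(p_by_domain,
                              domain_sizes = lengths(region_domains),
                              alpha = 0.05) {
  unknown <- setdiff(names(p_by_domain), names(domain_sizes))
  if (length(unknown))
    stop("outcome assigned to unknown domain: ", paste(unknown, collapse = ", "))
  out <- lapply(names(p_by_domain), function(d) {
    p <- p_by_domain[[d]]
    m <- domain_sizes[[d]]
    data.frame(domain = d,
               outcome = if (is.null(names(p))) rep(NA_character_, length(p))
                         else names(p),
               m = m, alpha_adj = alpha / m, p = unname(p),
               significant = unname(p) < alpha / m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled two-sample t test from summary statistics
#'
#' Pooled-variance independent-samples t with `df = n1 + n2 - 2` and a
#' two-sided p, computed from group means, SDs and sizes.
#'
#' @param m1,sd1,n1 First group mean, SD, size.
#' @param m2,sd2,n2 Second group mean, SD, size.
#' @return List: `t`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' No continuity correction by default, matching the group-comparison
#' convention used for the sex table.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return List: `chi2`, `df`, `p`.
#' @export
chi2_2x2 <- function(counts, yates = FALSE) {
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero marginal")
  ht <- stats::chisq.test(counts, correct = yates)
  list(chi2 = unname(ht$statistic), df = as.integer(unname(ht$parameter)),
       p = ht$p.value)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Normal-approximation interval with
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)`,
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; bounds clipped to \[0, 1\].
#'
#' @param auc Point estimate A in \[0, 1\].
#' @param n1 Number of positives.
#' @param n2 Number of negatives.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hanley_mcneil_ci <- function(auc, n1, n2, conf = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n1 >= 1, n2 >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(low = max(0, auc - z * se), high = min(1, auc + z * se))
}

#' Group comparison table over movement regions
#'
#' Mann-Whitney U test per analysis region (risk vs control) with effect
#' size `r = |Z|/sqrt(N)` and BH-FDR adjustment across the listed
#' regions; the group-comparison table of the pipeline.
#'
#' @param features Feature table from [build_feature_table()].
#' @param regions Regions to test (default the 15 analysis regions).
#' @param alpha Significance level applied to the FDR-adjusted p.
#' @return Data frame: `region`, `U`, `Z`, `r`, `p_raw`, `p_fdr`,
#'   `direction` (`"risk>control"`, `"control>risk"` or `"n.s."`;
#'   `"n.s."` when `p_fdr >= alpha`).
#' @export
group_test_table <- function(features, regions = regions_analysis,
                             alpha = 0.05) {
  risk <- features[features$group == "risk", , drop = FALSE]
  ctrl <- features[features$group == "control", , drop = FALSE]
  n <- nrow(risk) + nrow(ctrl)
  rows <- lapply(regions, function(rg) {
    mw <- mann_whitney(risk[[rg]], ctrl[[rg]])
    data.frame(region = rg, U = mw$U, Z = mw$Z,
               r = effect_size_r(mw$Z, n), p_raw = mw$p,
               direction = switch(mw$direction, "a>b" = "risk>control",
                                  "b>a" = "control>risk", "n.s."),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p_raw)
  out$direction[out$p_fdr >= alpha] <- "n.s."
  out[, c("region", "U", "Z", "r", "p_raw", "p_fdr", "direction")]
}

#' Correlation table between movement indices and teacher ratings
#'
#' Spearman correlations (with Fisher-z CIs) between each region's
#' activity index and the teacher hyperactivity score; uncorrected for
#' multiplicity by design (exploratory).
#'
#' @param features Feature table.
#' @param regions Regions to correlate (default the 15 analysis regions).
#' @param conf Confidence level.
#' @return Data frame: `region`, `rho`, `ci_low`, `ci_high`, `p`.
#' @export
correlation_table <- function(features, regions = regions_analysis,
                              conf = 0.95) {
  rows <- lapply(regions, function(rg) {
    ct <- spearman_ci(features[[rg]], features$conners_score, conf)
    data.frame(region = rg, rho = ct$rho, ci_low = ct$ci_low,
               ci_high = ct$ci_high, p = ct$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inter-regional Spearman correlation matrix
#'
#' Pairwise Spearman correlations between regional movement indices
#' (symmetric, unit diagonal); the heatmap-figure analog.
#'
#' @param features Feature table.
#' @param regions Regions to include (default the 15 analysis regions).
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(features, regions = regions_analysis) {
  m <- as.matrix(features[, regions, drop = FALSE])
  if (any(apply(m, 2, stats::sd) == 0))
    stop("zero-variance column in feature matrix")
  stats::cor(m, method = "spearman")
}
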