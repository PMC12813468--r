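test_that("descriptives report per-group mean and sample SD", {
  tab <- generate_cohort(make_default_profiles(), seed = 3)
  d <- group_descriptives(tab, "csf_ml")
  expect_equal(nrow(d), 5L)
  expect_equal(d$group, c("AD", "CN", "MCI", "EMCI", "LMCI"))
  v <- tab$csf_ml[tab$group_code == 0]
  expect_equal(d$mean[1], mean(v))
  expect_equal(d$sd[1], sd(v))   # n - 1 denominator

  const <- data.frame(group_code = c(0, 0, 1, 1), x = c(5, 5, 1, 2))
  expect_equal(group_descriptives(const, "x")$sd[1], 0)
  expect_error(group_descriptives(tab, "nope"), "unknown measure")
})

test_that("Kruskal-Wallis reproduces the hand-computed example", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2)   # (12/90) * (3*9 + 0 + 3*9)
  expect_equal(r$df, 2)
  expect_equal(kruskal_wallis(rep(list(rnorm(5)), 4))$df, 3)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(14)
  for (i in 1:20) {
    g <- list(rnorm(8), rnorm(10, 1), rexp(7))
    h0 <- kruskal_wallis(g)$statistic
    expect_equal(kruskal_wallis(lapply(g, exp))$statistic, h0)
    expect_equal(kruskal_wallis(lapply(g, function(x) 3 * x - 10))$statistic,
                 h0)
    # in particular log1p on non-negative data cannot change the result
    gp <- lapply(g, abs)
    expect_equal(kruskal_wallis(lapply(gp, log1p))$statistic,
                 kruskal_wallis(gp)$statistic)
  }
})

test_that("Shapiro-Wilk screening behaves as a normality test should", {
  set.seed(15)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  # skewed data at n = 100 is flagged nearly always
  rej <- mean(replicate(200, shapiro_wilk(rlnorm(100, 0, 1)) < 0.05))
  expect_gt(rej, 0.95)
})

test_that("log1p transform round-trips and preserves order", {
  x <- c(0, 0.5, 3, 120)
  expect_equal(log1p_wmh(0), 0)
  expect_equal(inv_log1p_wmh(log1p_wmh(x)), x, tolerance = 1e-12)
  expect_true(all(diff(log1p_wmh(sort(runif(50, 0, 100)))) >= 0))
  expect_error(log1p_wmh(-1), ">= 0")
})

test_that("BH adjustment matches the hand-worked step-up example", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(16)
  p <- runif(30)
  expect_true(all(fdr_adjust(p) >= p))
  expect_true(all(fdr_adjust(p) <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Dunn post-hoc contrasts follow the rank structure", {
  set.seed(17)
  v <- c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 6))
  g <- rep(c("a", "b", "c"), each = 20)
  d <- dunn_posthoc(v, g)
  expect_equal(nrow(d), 3L)          # k(k-1)/2 pairs
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
  expect_true(all(d$p_adjusted >= d$p_value))
  # group a has the lowest mean rank, c the highest: z(a,c) most extreme
  expect_lt(d$z[d$group1 == "a" & d$group2 == "c"], 0)
  expect_equal(which.max(abs(d$z)), which(d$group1 == "a" & d$group2 == "c"))
  # two-group Dunn z agrees with the normal approximation used at k = 2:
  # z^2 equals the (tie-corrected) Kruskal-Wallis H statistic
  v2 <- c(rnorm(15), rnorm(15, 1)); g2 <- rep(c("a", "b"), each = 15)
  expect_equal(dunn_posthoc(v2, g2)$z^2,
               kruskal_wallis(split(v2, g2))$statistic, tolerance = 1e-9)
})

test_that("the full report reproduces the significance pattern", {
  tab <- generate_cohort(make_default_profiles(), seed = 5)
  rep <- group_stats_report(tab)
  expect_equal(rep$kruskal$df, rep(4, 5))
  expect_true(all(rep$kruskal$p_adjusted >= rep$kruskal$p_value))
  # group structure exists for CSF, GM, CT, WMH by construction
  sig <- rep$kruskal$p_value[rep$kruskal$measure %in%
                               c("csf", "gm", "ct", "wmh")]
  expect_true(all(sig < 0.05))
  # WMH tested on the log scale equals WMH tested raw (rank invariance)
  expect_equal(rep$kruskal$H[rep$kruskal$measure == "wmh"],
               kruskal_wallis_table(tab, "wmh_ml")$statistic)
  # subject-level sensitivity mode runs and keeps df
  rep2 <- group_stats_report(tab, by_subject = TRUE)
  expect_equal(rep2$kruskal$df, rep(4, 5))
  # descriptives recover the generating baseline parameters loosely
  d <- rep$descriptives$ct
  expect_equal(d$mean[d$group == "AD"], 2.22, tolerance = 0.1)
})
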