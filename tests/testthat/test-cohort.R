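test_that("default profiles carry the published group parameters", {
  p <- make_default_profiles()
  expect_length(p, 5)
  expect_equal(vapply(p, function(x) x$group_code, integer(1)),
               c(AD = 0L, CN = 1L, MCI = 2L, EMCI = 3L, LMCI = 4L))
  expect_equal(p$AD$features$csf$annual_change_median, 14.61)
  expect_equal(p$AD$features$csf$annual_change_iqr, c(9.57, 16.42))
  expect_equal(p$AD$features$csf$frac_increasing, 14 / 15)
  expect_equal(p$CN$features$wmh$annual_change_median, 0.122)
  expect_equal(p$CN$features$wmh$annual_change_iqr, c(0.050, 0.266))
  expect_equal(p$AD$features$ct$baseline_mean, 2.22)
  expect_equal(p$AD$features$ct$baseline_sd, 0.150)
  expect_equal(sum(vapply(p, function(x) x$n_subjects, integer(1))), 114L)
  for (prof in p) {
    for (f in prof$features) {
      expect_gte(f$baseline_sd, 0)
      expect_true(f$frac_increasing >= 0 && f$frac_increasing <= 1)
      expect_true(f$plausible_range[1] <= f$baseline_mean &&
                    f$baseline_mean <= f$plausible_range[2])
    }
    expect_gte(prof$sessions_range[1], 2L)
  }
})

test_that("slope distribution honours median, IQR and sign fraction", {
  # evaluate the quantile function on a dense probability grid: the
  # constructed distribution must hit all four published constraints
  for (fp in list(make_default_profiles()$AD$features$csf,
                  make_default_profiles()$CN$features$wmh,
                  make_default_profiles()$EMCI$features$wm)) {
    q <- function(p) longiheat:::slope_quantile(
      p, fp$annual_change_median, fp$annual_change_iqr, fp$frac_increasing)
    expect_equal(q(0.5), fp$annual_change_median, tolerance = 1e-12)
    expect_equal(q(0.25), fp$annual_change_iqr[1], tolerance = 1e-12)
    expect_equal(q(0.75), fp$annual_change_iqr[2], tolerance = 1e-12)
    grid <- seq(0.0005, 0.9995, by = 0.001)
    expect_equal(mean(q(grid) > 0), fp$frac_increasing, tolerance = 0.002)
    expect_true(all(diff(q(grid)) >= -1e-12))  # valid quantile function
  }
  # all-increasing groups never produce a negative slope
  fp <- make_default_profiles()$EMCI$features$wmh
  expect_true(all(longiheat:::slope_quantile(
    seq(0.001, 0.999, by = 0.001), fp$annual_change_median,
    fp$annual_change_iqr, fp$frac_increasing) > 0))
})

test_that("noiseless degenerate subjects follow exact linear trajectories", {
  prof <- deterministic_profile(s = 6)
  traj <- sample_subject(prof, 1, seed = 9, noise_scale = 0)
  expect_equal(traj$visit_months[1], 0)
  expect_true(all(diff(traj$visit_months) > 0))
  expect_equal(traj$features$csf,
               450 + 6 * traj$visit_months / 12, tolerance = 1e-12)
  expect_equal(traj$features$ct,
               2.2 + 6 * traj$visit_months / 12, tolerance = 1e-12)
})

test_that("subject sampling is deterministic and respects the schedule", {
  prof <- make_default_profiles()$MCI
  a <- sample_subject(prof, 3, seed = 42)
  b <- sample_subject(prof, 3, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_subject(prof, 4, seed = 42)))
  expect_true(length(a$visit_months) >= prof$sessions_range[1] &&
                length(a$visit_months) <= prof$sessions_range[2])
  expect_true(all(diff(a$visit_months) >= 3))
  expect_gt(a$tiv_ml, 0)
  for (f in names(a$features)) {
    rng <- prof$features[[f]]$plausible_range
    expect_true(all(a$features[[f]] >= rng[1] & a$features[[f]] <= rng[2]))
  }
})

test_that("infeasible session/follow-up combinations are rejected", {
  prof <- make_default_profiles()$AD
  prof$followup_months_range <- c(0, 5)  # cannot fit 3 visits 3 months apart
  expect_error(sample_subject(prof, 1, seed = 1), "infeasible")
})

test_that("the default cohort reproduces the published structure", {
  tab <- generate_cohort(make_default_profiles(), seed = 1)
  subj <- unique(as.data.frame(tab)[, c("group_code", "subject_num")])
  expect_equal(nrow(subj), 114L)
  expect_equal(as.integer(table(subj$group_code)), c(22L, 22L, 25L, 20L, 25L))
  # baseline convention: every subject's first scan at month 0
  base <- tab[tab$scan_num == 1, ]
  expect_true(all(base$delta_t_months == 0))
  expect_equal(nrow(base), 114L)
  # byte-identical reproduction under the same seed
  expect_identical(tab, generate_cohort(make_default_profiles(), seed = 1))
  expect_false(identical(tab, generate_cohort(make_default_profiles(),
                                              seed = 2)))
  expect_error(generate_cohort(make_default_profiles(), seed = 1,
                               n_subjects = 0), "empty group")
})

test_that("AD cohorts of published size show the published CSF sign rate", {
  tab <- generate_cohort(make_default_profiles()["AD"], seed = 4,
                         n_subjects = 15)
  frac <- mean(subject_slopes(tab, "csf_ml")$slope > 0)
  # binomial band around 14/15 at n = 15 (3 sigma)
  expect_gte(frac, 14 / 15 - 3 * sqrt((14 / 15) * (1 / 15) / 15))
})

test_that("generator recovers baseline means and sign fractions at scale", {
  p <- make_default_profiles()
  tab <- generate_cohort(p["LMCI"], seed = 6, n_subjects = 300)
  base <- tab[tab$scan_num == 1, ]
  for (col in c("gm_ml", "csf_ml", "ct_mm")) {
    f <- p$LMCI$features[[sub("_(ml|mm)$", "", col)]]
    se <- sd(base[[col]]) / sqrt(nrow(base))
    expect_lt(abs(mean(base[[col]]) - f$baseline_mean), 3 * se)
  }
  # sign fraction for CSF within binomial error
  frac <- mean(subject_slopes(tab, "csf_ml")$slope > 0)
  f <- p$LMCI$features$csf$frac_increasing
  expect_lt(abs(frac - f), 3 * sqrt(f * (1 - f) / 300) + 0.02)
  # all values respect plausibility and TIV is positive
  expect_true(all(tab$tiv_ml > 0))
  expect_true(all(tab$wmh_ml >= 0))
})

test_that("localized-signal heatmap sets differ only inside the window", {
  ds <- simulate_heatmap_dataset(n_per_group = 10, signal_bins = 1:10,
                                 delta = 25, noise_sd = 0, seed = 2)
  expect_equal(dim(ds$x), c(50L, 28L, 3L))
  expect_setequal(unique(ds$y), 0:4)
  m_ad <- colMeans(ds$x[ds$y == 4, , 1])
  m_cn <- colMeans(ds$x[ds$y == 0, , 1])
  expect_true(all(abs((m_ad - m_cn)[1:10] - 100) < 1e-9))
  expect_true(all(abs((m_ad - m_cn)[11:28]) < 1e-9))
  expect_identical(ds, simulate_heatmap_dataset(n_per_group = 10,
                                                signal_bins = 1:10,
                                                delta = 25, noise_sd = 0,
                                                seed = 2))
})
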