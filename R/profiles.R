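# Per-group generative parameters for the synthetic longitudinal cohort.
#
# Baseline means/SDs come from the published per-group descriptive table;
# CSF and WMH annual-change medians, IQRs and sign fractions from the
# published change table; participant counts, session counts and follow-up
# windows from the published cohort table. GM, WM and CT annual-change
# parameters are not published numerically (only qualitative trends with an
# ambiguous sign convention for GM), so the defaults below encode the
# standard neurodegeneration convention -- tissue loss and cortical thinning
# that accelerate with disease stage -- and are plain list fields a user can
# edit. Plausible ranges are physical-plausibility clip bounds, deliberately
# wide so they almost never bind on default draws.

FEATURE_NAMES <- c("gm", "wm", "csf", "ct", "wmh")

# Physical plausibility bounds shared by all groups (ml; ct in mm).
PLAUSIBLE_RANGES <- list(
  gm  = c(300, 900),
  wm  = c(250, 750),
  csf = c(100, 950),
  ct  = c(1.2, 3.6),
  wmh = c(0, 150)
)

feature_profile <- function(baseline_mean, baseline_sd,
                            annual_change_median, annual_change_iqr,
                            frac_increasing, plausible_range,
                            baseline_family = c("gaussian", "lognormal")) {
  baseline_family <- match.arg(baseline_family)
  stopifnot(baseline_sd >= 0,
            frac_increasing >= 0, frac_increasing <= 1,
            length(annual_change_iqr) == 2L,
            annual_change_iqr[1] <= annual_change_median,
            annual_change_median <= annual_change_iqr[2],
            plausible_range[1] <= baseline_mean,
            baseline_mean <= plausible_range[2])
  list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
       annual_change_median = annual_change_median,
       annual_change_iqr = annual_change_iqr,
       frac_increasing = frac_increasing,
       plausible_range = plausible_range,
       baseline_family = baseline_family)
}

#' Create a group profile
#'
#' A group profile bundles everything the cohort generator needs for one
#' diagnostic stratum: subject count, session-count range, follow-up window,
#' a TIV distribution, and per-feature baseline and annual-change parameters.
#'
#' @param group_code integer 0..4 (see [GROUP_CODES]).
#' @param n_subjects default number of subjects to simulate.
#' @param sessions_range integer `c(min, max)` scans per subject (min >= 2 so
#'   slopes are estimable).
#' @param followup_months_range `c(min, max)` follow-up window in months.
#' @param tiv_mean,tiv_sd TIV distribution (ml), constant within subject.
#' @param features named list (gm, wm, csf, ct, wmh), each a list with
#'   `baseline_mean`, `baseline_sd`, `annual_change_median`,
#'   `annual_change_iqr` (length 2), `frac_increasing`, `plausible_range`
#'   and `baseline_family` ("gaussian" or "lognormal").
#' @return an object of class `group_profile`.
#' @seealso [make_default_profiles()]
#' @export
group_profile <- function(group_code, n_subjects, sessions_range,
                          followup_months_range, tiv_mean, tiv_sd, features) {
  group_code <- as.integer(group_code)
  if (length(group_code) != 1L || is.na(group_code) ||
      group_code < 0L || group_code > 4L) {
    stop("group_code must be a single integer in 0..4", call. = FALSE)
  }
  stopifnot(length(sessions_range) == 2L,
            sessions_range[1] >= 2L,
            sessions_range[1] <= sessions_range[2],
            length(followup_months_range) == 2L,
            followup_months_range[1] <= followup_months_range[2],
            tiv_mean > 0, tiv_sd >= 0, n_subjects >= 0)
  if (!setequal(names(features), FEATURE_NAMES)) {
    stop("features must be a named list with elements ",
         paste(FEATURE_NAMES, collapse = ", "), call. = FALSE)
  }
  structure(
    list(group_code = group_code, group_name = group_name(group_code),
         n_subjects = as.integer(n_subjects),
         sessions_range = as.integer(sessions_range),
         followup_months_range = as.numeric(followup_months_range),
         tiv_mean = tiv_mean, tiv_sd = tiv_sd,
         features = features[FEATURE_NAMES]),
    class = "group_profile"
  )
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf("<group_profile> %s (code %d): %d subjects, %d-%d sessions\n",
              x$group_name, x$group_code, x$n_subjects,
              x$sessions_range[1], x$sessions_range[2]))
  invisible(x)
}

#' Default generative profiles for the five diagnostic groups
#'
#' Returns one [group_profile] per stratum (AD, CN, MCI, EMCI, LMCI),
#' parameterized from the published per-group statistics: baseline mean (SD)
#' of each feature; CSF and WMH annual-change median, IQR and fraction of
#' subjects increasing; participant counts (22/22/25/20/25, 114 in total),
#' session-count ranges and follow-up windows. WMH baselines use a
#' moment-matched lognormal (WMH volumes are strongly right-skewed and
#' non-negative); all other baselines are Gaussian. GM/WM/CT annual-change
#' parameters are package defaults (see the methods vignette) and can be
#' edited on the returned objects.
#'
#' @return named list of five `group_profile` objects (AD, CN, MCI, EMCI,
#'   LMCI), ordered by group code.
#' @examples
#' p <- make_default_profiles()
#' p$AD$features$csf$annual_change_median  # 14.61 ml/yr
#' @export
make_default_profiles <- function() {
  f <- function(mean, sd, med, iqr, frac, feature,
                family = "gaussian") {
    feature_profile(mean, sd, med, iqr, frac,
                    PLAUSIBLE_RANGES[[feature]], family)
  }
  list(
    AD = group_profile(
      0L, n_subjects = 22L, sessions_range = c(3L, 4L),
      followup_months_range = c(12.3, 95.8), tiv_mean = 1500, tiv_sd = 120,
      features = list(
        gm  = f(558.0, 50.1,  -8.0,   c(-12.0, -4.0),    0.10, "gm"),
        wm  = f(461.0, 66.5,  -5.0,   c(-8.0, -2.0),     0.15, "wm"),
        csf = f(455.0, 79.6,  14.61,  c(9.57, 16.42),    14 / 15, "csf"),
        ct  = f(2.22,  0.150, -0.040, c(-0.055, -0.020), 0.08, "ct"),
        wmh = f(8.22,  12.8,  0.725,  c(0.104, 3.204),   14 / 15, "wmh",
                family = "lognormal"))),
    CN = group_profile(
      1L, n_subjects = 22L, sessions_range = c(4L, 5L),
      followup_months_range = c(25.3, 138.7), tiv_mean = 1500, tiv_sd = 120,
      features = list(
        gm  = f(593.0, 58.1,  -1.5,   c(-3.0, -0.3),     0.20, "gm"),
        wm  = f(464.0, 80.7,  -0.5,   c(-2.0, 1.0),      0.40, "wm"),
        csf = f(443.0, 83.8,  7.16,   c(4.87, 8.29),     21 / 22, "csf"),
        ct  = f(2.33,  0.177, -0.005, c(-0.012, 0.002),  0.30, "ct"),
        wmh = f(3.55,  3.69,  0.122,  c(0.050, 0.266),   19 / 22, "wmh",
                family = "lognormal"))),
    MCI = group_profile(
      2L, n_subjects = 25L, sessions_range = c(3L, 9L),
      followup_months_range = c(11.3, 171.0), tiv_mean = 1500, tiv_sd = 120,
      features = list(
        gm  = f(573.0, 94.4,  -5.0,   c(-8.0, -2.0),     0.12, "gm"),
        wm  = f(465.0, 96.6,  -2.5,   c(-4.5, -1.0),     0.20, "wm"),
        csf = f(397.0, 111.0, 6.39,   c(4.21, 10.93),    22 / 25, "csf"),
        ct  = f(2.28,  0.404, -0.020, c(-0.035, -0.008), 0.16, "ct"),
        wmh = f(4.68,  14.0,  0.189,  c(0.071, 0.484),   23 / 25, "wmh",
                family = "lognormal"))),
    EMCI = group_profile(
      3L, n_subjects = 20L, sessions_range = c(3L, 7L),
      followup_months_range = c(3.0, 141.7), tiv_mean = 1500, tiv_sd = 120,
      features = list(
        gm  = f(615.0, 51.2,  -4.0,   c(-7.0, -1.5),     0.15, "gm"),
        wm  = f(481.0, 65.2,  -1.0,   c(-3.0, 1.0),      0.35, "wm"),
        csf = f(392.0, 63.8,  5.98,   c(4.05, 7.84),     19 / 20, "csf"),
        ct  = f(2.40,  0.101, -0.015, c(-0.028, -0.005), 0.15, "ct"),
        wmh = f(4.48,  6.53,  0.361,  c(0.122, 0.724),   1.0, "wmh",
                family = "lognormal"))),
    LMCI = group_profile(
      4L, n_subjects = 25L, sessions_range = c(6L, 9L),
      followup_months_range = c(12.2, 132.9), tiv_mean = 1500, tiv_sd = 120,
      features = list(
        gm  = f(575.0, 86.6,  -6.0,   c(-9.0, -3.0),     0.12, "gm"),
        wm  = f(479.0, 76.8,  -3.0,   c(-5.0, -1.5),     0.18, "wm"),
        csf = f(400.0, 82.8,  7.98,   c(4.62, 15.43),    23 / 25, "csf"),
        ct  = f(2.30,  0.249, -0.030, c(-0.045, -0.015), 0.12, "ct"),
        wmh = f(3.13,  3.38,  0.118,  c(0.059, 0.256),   21 / 25, "wmh",
                family = "lognormal")))
  )
}

#' Well-separated profiles for sanity experiments
#'
#' A variant of [make_default_profiles()] in which one feature's baseline
#' means are pushed `separation` within-group SDs apart across neighbouring
#' groups (with tightened SDs and TIV spread), while slopes keep the default
#' structure. Used to verify that the classifiers can recover an easy,
#' genuinely separable group structure end to end; not a model of real data.
#'
#' @param feature which feature carries the separation (default "csf").
#' @param separation distance between neighbouring group means in units of
#'   the common within-group SD (default 5).
#' @param baseline_sd common within-group baseline SD for `feature`.
#' @return named list of five `group_profile` objects.
#' @export
make_separable_profiles <- function(feature = "csf", separation = 5,
                                    baseline_sd = NULL) {
  profiles <- make_default_profiles()
  mid <- switch(feature, ct = 2.3, gm = 580, wm = 470, csf = 420, wmh = 10)
  if (is.null(baseline_sd)) {
    baseline_sd <- if (feature == "ct") 0.05 else 20
  }
  step <- separation * baseline_sd
  for (p in names(profiles)) {
    g <- profiles[[p]]$group_code
    fp <- profiles[[p]]$features[[feature]]
    fp$baseline_mean <- mid + (g - 2) * step
    fp$baseline_sd <- baseline_sd
    fp$baseline_family <- "gaussian"
    rng <- range(mid + (0:4 - 2) * step)
    fp$plausible_range <- c(rng[1] - 10 * baseline_sd,
                            rng[2] + 10 * baseline_sd)
    profiles[[p]]$features[[feature]] <- fp
    profiles[[p]]$tiv_sd <- 20
  }
  profiles
}
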