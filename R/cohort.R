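# Longitudinal cohort simulation.
#
# Each subject follows, per feature, a linear trajectory
#   value(t) = baseline + slope * t / 12 + noise,
# with t in months. Slopes are drawn from a distribution constructed to
# match three published summaries exactly: the annual-change median, the
# annual-change IQR, and the fraction of subjects whose feature increases.
# The construction is a piecewise-linear quantile function anchored at
# (0.25, q25), (0.5, median), (0.75, q75) and (1 - frac_increasing, 0), with
# Tukey-whisker tail anchors (q25 - 1.5 IQR at p = 0.01, q75 + 1.5 IQR at
# p = 0.99); uniform draws are clamped to [0.01, 0.99] so the support is
# bounded. See the methods vignette for the rationale.

# Quantile function for the annual-change (slope) distribution.
# Returns slope values at probabilities `p`.
slope_quantile <- function(p, median, iqr, frac_increasing) {
  q25 <- iqr[1]; q75 <- iqr[2]
  width <- q75 - q25
  x_lo <- q25 - 1.5 * width
  x_hi <- q75 + 1.5 * width
  anchors_p <- c(0.01, 0.25, 0.50, 0.75, 0.99)
  anchors_x <- c(x_lo, q25, median, q75, x_hi)
  p0 <- 1 - frac_increasing  # P(slope <= 0)
  if (frac_increasing >= 1) {
    # all subjects increase: truncate the support just above zero
    anchors_x <- pmax(anchors_x, 1e-9 * max(abs(anchors_x), 1))
  } else if (frac_increasing <= 0) {
    anchors_x <- pmin(anchors_x, -1e-9 * max(abs(anchors_x), 1))
  } else if (p0 > 0.01 && p0 < 0.99) {
    keep <- abs(anchors_p - p0) > 1e-9
    anchors_p <- c(anchors_p[keep], p0)
    anchors_x <- c(anchors_x[keep], 0)
    ord <- order(anchors_p)
    anchors_p <- anchors_p[ord]
    anchors_x <- anchors_x[ord]
  }
  if (any(diff(anchors_x) < -1e-12)) {
    stop("inconsistent slope parameters: median/IQR and frac_increasing ",
         "imply a non-monotone quantile function", call. = FALSE)
  }
  anchors_x <- cummax(anchors_x)  # absorb exact ties from degenerate IQRs
  p <- pmin(pmax(p, 0.01), 0.99)
  stats::approx(anchors_p, anchors_x, xout = p, ties = "ordered")$y
}

draw_baseline <- function(fp, n = 1L) {
  if (fp$baseline_sd == 0) return(rep(fp$baseline_mean, n))
  if (fp$baseline_family == "lognormal") {
    cv2 <- (fp$baseline_sd / fp$baseline_mean)^2
    sdlog <- sqrt(log(1 + cv2))
    meanlog <- log(fp$baseline_mean) - sdlog^2 / 2
    stats::rlnorm(n, meanlog, sdlog)
  } else {
    stats::rnorm(n, fp$baseline_mean, fp$baseline_sd)
  }
}

#' Simulate one subject's longitudinal trajectory
#'
#' Draws a visit schedule (session count uniform over the profile's
#' `sessions_range`; inter-visit gaps uniform over `gap_range` months,
#' truncated so visits stay inside the profile's follow-up window) and, for
#' each feature, a baseline, an annual-change slope and per-visit Gaussian
#' noise. Values are clipped to the feature's plausible range. Identical
#' `(profile, subject_num, seed)` yields identical output; the caller's RNG
#' stream is left untouched.
#'
#' @param profile a [group_profile].
#' @param subject_num 1-based subject index within the group.
#' @param seed master integer seed; combined with the group code and
#'   `subject_num` to give every subject an independent substream.
#' @param noise_scale per-visit residual SD as a fraction of the feature's
#'   baseline SD (default 0.05).
#' @param gap_range `c(min, max)` inter-visit gap in months (min >= 3).
#' @return object of class `subject_trajectory`: list with `group_code`,
#'   `subject_num`, `visit_months` (first element 0), `tiv_ml`, and a
#'   `features` data.frame (columns gm, wm, csf, ct, wmh), plus the drawn
#'   `slopes`.
#' @export
sample_subject <- function(profile, subject_num, seed, noise_scale = 0.05,
                           gap_range = c(3, 12)) {
  if (!inherits(profile, "group_profile")) {
    stop("profile must be a group_profile", call. = FALSE)
  }
  if (gap_range[1] < 3) stop("minimum visit gap is 3 months", call. = FALSE)
  fmax <- profile$followup_months_range[2]
  if ((profile$sessions_range[1] - 1L) * gap_range[1] > fmax) {
    stop("sessions_range infeasible for the follow-up window", call. = FALSE)
  }
  with_seed(derive_seed(seed, profile$group_code, subject_num), {
    counts <- seq(profile$sessions_range[1], profile$sessions_range[2])
    n_visits <- if (length(counts) == 1L) counts else sample(counts, 1L)
    gaps <- stats::runif(n_visits - 1L, gap_range[1], gap_range[2])
    visit_months <- c(0, cumsum(gaps))
    # truncate at the follow-up ceiling, keeping at least two visits
    keep <- visit_months <= fmax
    keep[1:2] <- TRUE
    visit_months <- visit_months[keep]
    n_visits <- length(visit_months)

    tiv <- max(stats::rnorm(1L, profile$tiv_mean, profile$tiv_sd), 500)
    values <- list()
    slopes <- numeric(length(FEATURE_NAMES))
    names(slopes) <- FEATURE_NAMES
    for (f in FEATURE_NAMES) {
      fp <- profile$features[[f]]
      baseline <- draw_baseline(fp)
      slope <- slope_quantile(stats::runif(1L), fp$annual_change_median,
                              fp$annual_change_iqr, fp$frac_increasing)
      noise <- if (noise_scale > 0 && fp$baseline_sd > 0) {
        stats::rnorm(n_visits, 0, noise_scale * fp$baseline_sd)
      } else {
        numeric(n_visits)
      }
      v <- baseline + slope * visit_months / 12 + noise
      v <- pmin(pmax(v, fp$plausible_range[1]), fp$plausible_range[2])
      values[[f]] <- v
      slopes[[f]] <- slope
    }
    structure(
      list(group_code = profile$group_code, subject_num = subject_num,
           visit_months = visit_months, tiv_ml = tiv,
           features = as.data.frame(values), slopes = slopes),
      class = "subject_trajectory"
    )
  })
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates every subject of every group and flattens the trajectories into
#' a session-level [feature_table]. With the default profiles this emulates
#' the published cohort structure: 114 subjects (22 AD, 22 CN, 25 MCI,
#' 20 EMCI, 25 LMCI) with irregular visit schedules.
#'
#' @param profiles named list of [group_profile]s, e.g.
#'   [make_default_profiles()].
#' @param seed master integer seed; the same `(profiles, seed)` pair
#'   reproduces the table byte for byte.
#' @param n_subjects optional integer vector (recycled over profiles)
#'   overriding each profile's subject count; all entries must be >= 1.
#' @param noise_scale,gap_range passed to [sample_subject()].
#' @return a validated [feature_table].
#' @examples
#' tab <- generate_cohort(make_default_profiles(), seed = 1)
#' nrow(unique(tab[, c("group_code", "subject_num")]))  # 114 subjects
#' @export
generate_cohort <- function(profiles = make_default_profiles(), seed,
                            n_subjects = NULL, noise_scale = 0.05,
                            gap_range = c(3, 12)) {
  if (length(profiles) == 0L) stop("no profiles supplied", call. = FALSE)
  n <- if (is.null(n_subjects)) {
    vapply(profiles, function(p) p$n_subjects, integer(1L))
  } else {
    as.integer(rep_len(n_subjects, length(profiles)))
  }
  if (any(n < 1L)) stop("empty group request: n_subjects must be >= 1",
                        call. = FALSE)
  rows <- vector("list", sum(n))
  k <- 0L
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    for (s in seq_len(n[i])) {
      traj <- sample_subject(prof, s, seed, noise_scale, gap_range)
      m <- length(traj$visit_months)
      k <- k + 1L
      rows[[k]] <- data.frame(
        label = make_label(prof$group_code, s, seq_len(m)),
        group_code = prof$group_code, subject_num = s, scan_num = seq_len(m),
        delta_t_months = traj$visit_months, tiv_ml = traj$tiv_ml,
        gm_ml = traj$features$gm, wm_ml = traj$features$wm,
        csf_ml = traj$features$csf, ct_mm = traj$features$ct,
        wmh_ml = traj$features$wmh
      )
    }
  }
  df <- do.call(rbind, rows)
  for (v in VOLUME_FEATURES) {
    df[[paste0(v, "_pct")]] <- pct_of_tiv(df[[paste0(v, "_ml")]], df$tiv_ml)
  }
  feature_table(df)
}

#' Per-subject least-squares annual slopes
#'
#' Ordinary least-squares slope of a feature against time in years, fitted
#' separately for every subject with at least two sessions. This is the
#' estimator used to check that the generator reproduces the published
#' annual-change medians and sign fractions.
#'
#' @param table a [feature_table].
#' @param column which column to regress (e.g. `"csf_ml"`).
#' @return data.frame with `group_code`, `subject_num`, `slope` (units of
#'   `column` per year).
#' @export
subject_slopes <- function(table, column) {
  if (!column %in% names(table)) {
    stop("unknown column: ", column, call. = FALSE)
  }
  subj <- interaction(table$group_code, table$subject_num, drop = TRUE)
  out <- lapply(split(seq_len(nrow(table)), subj), function(idx) {
    t_yr <- table$delta_t_months[idx] / 12
    y <- table[[column]][idx]
    if (length(idx) < 2L || stats::var(t_yr) == 0) return(NULL)
    data.frame(group_code = table$group_code[idx][1L],
               subject_num = table$subject_num[idx][1L],
               slope = stats::cov(t_yr, y) / stats::var(t_yr))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Simulate a heatmap dataset with a localized group signal
#'
#' Builds ready-made heatmap tensors (value, rate, mask channels) in which
#' the group difference lives only in a chosen window of time bins: inside
#' `signal_bins` the value channel is offset by `group_code * delta` around a
#' common base level, outside it all groups share the base level. Used to
#' test that temporal attribution methods localize the discriminative bins.
#'
#' @param n_per_group subjects per group (5 groups).
#' @param signal_bins integer vector of 1-based bin indices carrying the
#'   group difference (default 1:10, i.e. months 0-30).
#' @param delta per-group offset of the value channel inside the window.
#' @param base base level of the value channel (0-255 scale).
#' @param noise_sd per-bin Gaussian noise SD.
#' @param n_bins number of time bins (default 28).
#' @param seed integer seed.
#' @return list with `x` (array `n x n_bins x 3`), `y` (group codes 0..4)
#'   and `subject` (labels).
#' @export
simulate_heatmap_dataset <- function(n_per_group = 20L, signal_bins = 1:10,
                                     delta = 25, base = 60, noise_sd = 5,
                                     n_bins = 28L, seed = 1L) {
  stopifnot(all(signal_bins >= 1L), all(signal_bins <= n_bins))
  n <- 5L * n_per_group
  with_seed(derive_seed(seed, 77L), {
    y <- rep(0:4, each = n_per_group)
    x <- array(0, dim = c(n, n_bins, 3L))
    x[, , 1L] <- base + matrix(stats::rnorm(n * n_bins, 0, noise_sd),
                               n, n_bins)
    x[, signal_bins, 1L] <- x[, signal_bins, 1L] + y * delta
    x[, , 1L] <- pmin(pmax(x[, , 1L], 0), 255)
    x[, , 3L] <- 1
    list(x = x, y = y,
         subject = paste(y, rep(seq_len(n_per_group), 5L), sep = "."))
  })
}
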