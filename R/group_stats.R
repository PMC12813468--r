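# Nonparametric group-comparison protocol: per-group descriptives,
# Shapiro-Wilk normality screening within each group, Kruskal-Wallis
# omnibus tests across the five groups, a log(1 + WMH) transform for the
# right-skewed lesion volumes, Benjamini-Hochberg FDR adjustment, and Dunn
# pairwise post-hoc contrasts.

STAT_MEASURES <- c(csf = "csf_ml", gm = "gm_ml", wm = "wm_ml",
                   ct = "ct_mm", wmh = "wmh_ml")

#' Per-group descriptive statistics
#'
#' @param table a [feature_table] (or any data.frame with `group_code`).
#' @param measure column to summarize, e.g. `"csf_ml"`.
#' @return data.frame with `group`, `group_code`, `n`, `mean`, `sd`
#'   (sample SD, n - 1 denominator).
#' @export
group_descriptives <- function(table, measure) {
  if (!measure %in% names(table)) {
    stop("unknown measure: ", measure, call. = FALSE)
  }
  g <- sort(unique(table$group_code))
  out <- do.call(rbind, lapply(g, function(gc) {
    v <- table[[measure]][table$group_code == gc]
    if (length(v) == 0L) stop("empty group ", gc, call. = FALSE)
    data.frame(group = group_name(gc), group_code = gc, n = length(v),
               mean = mean(v), sd = stats::sd(v))
  }))
  rownames(out) <- NULL
  out
}

#' Shapiro-Wilk normality screen within each group
#'
#' Wraps [stats::shapiro.test()] (Royston's approximation) per group;
#' samples are subsampled to 5000 observations if necessary (the test's
#' implementation limit).
#'
#' @param table a [feature_table].
#' @param measure column to test.
#' @return data.frame with `group`, `group_code`, `n`, `p_value`.
#' @export
shapiro_by_group <- function(table, measure) {
  g <- sort(unique(table$group_code))
  out <- do.call(rbind, lapply(g, function(gc) {
    v <- table[[measure]][table$group_code == gc]
    data.frame(group = group_name(gc), group_code = gc, n = length(v),
               p_value = shapiro_wilk(v))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname shapiro_by_group
#' @param x numeric sample, 3 <= n; constant samples are an error.
#' @return `shapiro_wilk()`: the p-value.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant sample", call. = FALSE)
  if (length(x) > 5000L) x <- x[seq(1L, length(x), length.out = 5000L)]
  stats::shapiro.test(x)$p.value
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-group comparison with tie correction; the statistic H is
#' referred to a chi-squared distribution with k - 1 degrees of freedom.
#' Accepts either a list of per-group numeric vectors or a table plus
#' measure name.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return list with `statistic` (H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L) {
    stop("all observations identical; H undefined under tie correction",
         call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' @rdname kruskal_wallis
#' @param table a [feature_table].
#' @param measure column to test across `group_code`.
#' @export
kruskal_wallis_table <- function(table, measure) {
  kruskal_wallis(split(table[[measure]], table$group_code))
}

#' log(1 + x) transform for WMH volumes
#'
#' WMH volumes are non-negative and right-skewed; hypothesis tests run on
#' `log(1 + WMH)`. Strictly monotone, so rank-based tests are unchanged;
#' `inv_log1p_wmh()` back-transforms.
#'
#' @param values non-negative numeric vector.
#' @export
log1p_wmh <- function(values) {
  if (any(values < 0)) stop("WMH volumes must be >= 0", call. = FALSE)
  log1p(values)
}

#' @rdname log1p_wmh
#' @export
inv_log1p_wmh <- function(values) expm1(values)

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with input
#' validation; adjusted values are monotone, >= raw, and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Dunn pairwise post-hoc contrasts
#'
#' Rank-based pairwise z tests on the pooled ranks underlying the
#' Kruskal-Wallis statistic, with the usual tie correction
#' `sum(t^3 - t) / (12 (N - 1))` in the variance, and BH-adjusted p-values.
#' The choice of Dunn (rather than pairwise rank-sum) as the post-hoc is a
#' package assumption; see the methods vignette.
#'
#' @param values numeric vector of observations.
#' @param groups group identifier per observation.
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  }))
  out$p_adjusted <- fdr_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Full group-comparison report
#'
#' Runs the whole protocol over the five scalar measures: descriptives,
#' per-group Shapiro-Wilk screening, Kruskal-Wallis omnibus tests (WMH on
#' the log(1 + x) scale) and Dunn post-hoc contrasts with FDR adjustment.
#' Observations are session rows by default; `by_subject = TRUE` collapses
#' to subject means first, a sensitivity mode that removes the repeated-
#' measures inflation of the session-level analysis.
#'
#' @param table a [feature_table].
#' @param measures named character vector mapping short measure names to
#'   columns (default: csf, gm, wm, ct, wmh absolute volumes/thickness).
#' @param by_subject collapse to one mean value per subject first?
#' @return object of class `group_stats_report`: lists `descriptives`,
#'   `shapiro`, `kruskal` (data.frame with H, df, p), `posthoc`.
#' @export
group_stats_report <- function(table, measures = STAT_MEASURES,
                               by_subject = FALSE) {
  tab <- as.data.frame(table)
  if (by_subject) {
    key <- paste(tab$group_code, tab$subject_num, sep = ".")
    agg <- stats::aggregate(tab[, unname(measures), drop = FALSE],
                            by = list(key = key,
                                      group_code = tab$group_code), mean)
    tab <- agg
  }
  kw <- do.call(rbind, lapply(names(measures), function(m) {
    col <- measures[[m]]
    v <- if (m == "wmh") log1p_wmh(tab[[col]]) else tab[[col]]
    res <- kruskal_wallis(split(v, tab$group_code))
    data.frame(measure = m, H = res$statistic, df = res$df,
               p_value = res$p_value)
  }))
  kw$p_adjusted <- fdr_adjust(kw$p_value)
  desc <- lapply(measures, function(col) group_descriptives(tab, col))
  sw <- lapply(measures, function(col) shapiro_by_group(tab, col))
  ph <- lapply(names(measures), function(m) {
    col <- measures[[m]]
    v <- if (m == "wmh") log1p_wmh(tab[[col]]) else tab[[col]]
    dunn_posthoc(v, group_name(tab$group_code))
  })
  names(ph) <- names(measures)
  structure(list(descriptives = desc, shapiro = sw, kruskal = kw,
                 posthoc = ph, by_subject = by_subject),
            class = "group_stats_report")
}

#' @export
print.group_stats_report <- function(x, ...) {
  cat("<group_stats_report>",
      if (x$by_subject) "(subject-level means)" else "(session rows)", "\n")
  cat("Kruskal-Wallis omnibus tests:\n")
  print(x$kruskal, digits = 4)
  invisible(x)
}
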