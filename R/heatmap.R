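# Heatmap encoding: one subject's longitudinal feature series becomes a
# 28-bin x 3-channel tensor. Channel 1 holds the min-max scaled, bit-depth
# quantized feature values; channel 2 the min-max scaled rate of change
# between consecutive occupied bins; channel 3 a binary availability mask
# distinguishing "no scan in this bin" from "no change".

#' Time grid for heatmap encoding
#'
#' The study window is 0-84 months discretized into half-open 3-month bins
#' `[3k, 3k + 3)`; the right edge (84) joins the last bin, giving 28 bins.
#'
#' @param bin_width_months bin width (default 3).
#' @param t_min,t_max window in months (defaults 0 and 84).
#' @return object of class `time_grid` with `n_bins` and per-bin centers.
#' @export
time_grid <- function(bin_width_months = 3, t_min = 0, t_max = 84) {
  stopifnot(bin_width_months > 0, t_max > t_min)
  n_bins <- (t_max - t_min) / bin_width_months
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("window is not a whole number of bins", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  structure(
    list(bin_width_months = bin_width_months, t_min = t_min, t_max = t_max,
         n_bins = n_bins,
         bin_centers = t_min + (seq_len(n_bins) - 0.5) * bin_width_months),
    class = "time_grid"
  )
}

#' Quantization specification
#'
#' Supported bit depths are 2, 3, 4, 8 and 16, corresponding to 4, 8, 16,
#' 256 and 65,536 intensity levels.
#'
#' @param bit_depth one of 2, 3, 4, 8, 16.
#' @return object of class `quantization_spec` with `n_levels = 2^bit_depth`.
#' @export
quantization_spec <- function(bit_depth) {
  if (!bit_depth %in% c(2L, 3L, 4L, 8L, 16L)) {
    stop("unsupported bit depth; use 2, 3, 4, 8 or 16", call. = FALSE)
  }
  structure(list(bit_depth = as.integer(bit_depth),
                 n_levels = 2^as.integer(bit_depth)),
            class = "quantization_spec")
}

#' Map a time in months to its 0-based bin index
#'
#' Bins are half-open `[3k, 3k + 3)`; the right window edge is clamped into
#' the last bin so a scan at exactly 84 months is retained.
#'
#' @param t_months numeric vector of times within the window.
#' @param grid a [time_grid].
#' @return integer vector of 0-based bin indices.
#' @examples
#' g <- time_grid()
#' bin_index(c(0, 10.5, 84), g)  # 0 3 27
#' @export
bin_index <- function(t_months, grid = time_grid()) {
  if (any(t_months < grid$t_min | t_months > grid$t_max)) {
    stop(sprintf("time outside the [%g, %g] month window",
                 grid$t_min, grid$t_max), call. = FALSE)
  }
  idx <- floor((t_months - grid$t_min) / grid$bin_width_months)
  as.integer(pmin(idx, grid$n_bins - 1L))
}

#' Aggregate sessions into per-bin values and an availability mask
#'
#' Bins containing at least one session get mask 1 and the mean of the
#' session values falling in them; empty bins get mask 0 and value 0.
#'
#' @param delta_t_months session times (months from baseline).
#' @param values feature values aligned with `delta_t_months`.
#' @param grid a [time_grid].
#' @return list with numeric `values` and integer `mask`, both of length
#'   `grid$n_bins`.
#' @export
aggregate_bins <- function(delta_t_months, values, grid = time_grid()) {
  if (length(delta_t_months) != length(values)) {
    stop("delta_t_months and values must be aligned", call. = FALSE)
  }
  out_v <- numeric(grid$n_bins)
  out_m <- integer(grid$n_bins)
  if (length(values) > 0L) {
    b <- bin_index(delta_t_months, grid) + 1L
    sums <- tapply(values, b, mean)
    idx <- as.integer(names(sums))
    out_v[idx] <- as.numeric(sums)
    out_m[idx] <- 1L
  }
  list(values = out_v, mask = out_m)
}

#' Raw rate-of-change channel
#'
#' For each occupied bin after the first occupied one, the slope of the
#' binned value between it and the previous occupied bin, using bin-center
#' times: `(S(t2) - S(t1)) / (t2 - t1)` in units per month. The first
#' occupied bin and all empty bins carry 0. When `total_T_months` is given
#' the slope is additionally divided by it (study-duration normalization
#' mode; see the methods vignette for why this is off by default).
#'
#' @param binned_values,binned_mask output of [aggregate_bins()].
#' @param grid a [time_grid].
#' @param total_T_months optional duration normalizer (e.g. 180).
#' @return numeric vector of length `grid$n_bins`.
#' @export
rate_channel <- function(binned_values, binned_mask, grid = time_grid(),
                         total_T_months = NULL) {
  occ <- which(binned_mask == 1L)
  out <- numeric(grid$n_bins)
  if (length(occ) >= 2L) {
    t <- grid$bin_centers[occ]
    s <- binned_values[occ]
    out[occ[-1L]] <- diff(s) / diff(t)
    if (!is.null(total_T_months)) out <- out / total_T_months
  }
  out
}

#' Min-max scale to the [0, 255] intensity range
#'
#' `(f - f_min) / (f_max - f_min) * 255`, with out-of-range inputs clipped
#' to the ends. A degenerate range (`f_max == f_min`) maps everything to 0.
#'
#' @param values numeric vector.
#' @param f_min,f_max normalization range (from the training split).
#' @return numeric vector in `[0, 255]`.
#' @export
minmax_scale <- function(values, f_min, f_max) {
  stopifnot_scalar_number(f_min, "f_min")
  stopifnot_scalar_number(f_max, "f_max")
  if (f_max < f_min) stop("f_max must be >= f_min", call. = FALSE)
  if (f_max == f_min) return(numeric(length(values)))
  pmin(pmax((values - f_min) / (f_max - f_min) * 255, 0), 255)
}

#' Quantize intensities to a bit depth
#'
#' Snaps values on the `[0, 255]` scale to the nearest of `2^bit_depth`
#' evenly spaced levels: `round(x / 255 * (L - 1)) * 255 / (L - 1)`.
#' Idempotent; the per-entry error is at most `255 / (2 (L - 1))`.
#'
#' @param values numeric vector in `[0, 255]`.
#' @param spec a [quantization_spec].
#' @return numeric vector taking at most `spec$n_levels` distinct values.
#' @examples
#' quantize(100, quantization_spec(2))  # 85: level 1 of {0, 85, 170, 255}
#' @export
quantize <- function(values, spec) {
  if (!inherits(spec, "quantization_spec")) {
    stop("spec must be a quantization_spec", call. = FALSE)
  }
  if (any(values < -1e-9 | values > 255 + 1e-9)) {
    stop("values must be in [0, 255]", call. = FALSE)
  }
  L1 <- spec$n_levels - 1L
  round(values / 255 * L1) * 255 / L1
}

#' Normalization statistics for heatmap encoding
#'
#' Computes the (f_min, f_max) ranges used by [minmax_scale()] for the value
#' channel (over session values of `feature`) and the rate channel (over all
#' subjects' raw per-bin rates). Compute these on the training split only
#' and reuse them when encoding test subjects, so no test information leaks
#' into the representation.
#'
#' @param table a [feature_table] (typically the training rows).
#' @param feature feature column, e.g. `"gm_pct"` or `"ct_mm"`.
#' @param grid a [time_grid].
#' @param rate_total_T optional duration normalizer forwarded to
#'   [rate_channel()].
#' @return list with `value = c(min, max)` and `rate = c(min, max)`.
#' @export
compute_norm_stats <- function(table, feature, grid = time_grid(),
                               rate_total_T = NULL) {
  if (!feature %in% names(table)) {
    stop("unknown feature column: ", feature, call. = FALSE)
  }
  keep <- table$delta_t_months >= grid$t_min &
    table$delta_t_months <= grid$t_max
  tab <- table[keep, , drop = FALSE]
  subj <- interaction(tab$group_code, tab$subject_num, drop = TRUE)
  rates <- unlist(lapply(split(seq_len(nrow(tab)), subj), function(idx) {
    agg <- aggregate_bins(tab$delta_t_months[idx], tab[[feature]][idx], grid)
    r <- rate_channel(agg$values, agg$mask, grid, rate_total_T)
    r[agg$mask == 1L][-1L]
  }))
  list(value = range(tab[[feature]]),
       rate = if (length(rates)) range(rates) else c(0, 0))
}

#' Encode one subject's feature series as a heatmap
#'
#' Produces the `n_bins x 3` tensor consumed by the classifiers: C1 is the
#' quantized, min-max scaled binned value; C2 the min-max scaled raw rate of
#' change; C3 the binary availability mask. C1 and C2 are forced to 0
#' wherever C3 is 0. Sessions outside the grid window are dropped (with a
#' warning); encoding fails only if none remain.
#'
#' @param delta_t_months,values the subject's session times and feature
#'   values.
#' @param norm_stats list from [compute_norm_stats()].
#' @param spec a [quantization_spec].
#' @param grid a [time_grid].
#' @param rate_total_T optional duration normalizer (see [rate_channel()]).
#' @param label optional session/subject label stored on the result.
#' @param feature optional feature name stored on the result.
#' @return a `heatmap`: numeric matrix `n_bins x 3` with columns C1, C2, C3
#'   and attributes `grid`, `spec`, `feature`, `label`, `norm_stats`.
#' @export
encode_heatmap <- function(delta_t_months, values, norm_stats, spec,
                           grid = time_grid(), rate_total_T = NULL,
                           label = NULL, feature = NULL) {
  inside <- delta_t_months >= grid$t_min & delta_t_months <= grid$t_max
  if (!any(inside)) {
    stop("all sessions fall outside the encoding window", call. = FALSE)
  }
  if (!all(inside)) {
    warning(sprintf("dropping %d session(s) outside the window",
                    sum(!inside)))
    values <- values[inside]
    delta_t_months <- delta_t_months[inside]
  }
  agg <- aggregate_bins(delta_t_months, values, grid)
  rate <- rate_channel(agg$values, agg$mask, grid, rate_total_T)
  c1 <- quantize(minmax_scale(agg$values, norm_stats$value[1],
                              norm_stats$value[2]), spec)
  c2 <- minmax_scale(rate, norm_stats$rate[1], norm_stats$rate[2])
  c1[agg$mask == 0L] <- 0
  c2[agg$mask == 0L] <- 0
  hm <- cbind(C1 = c1, C2 = c2, C3 = as.numeric(agg$mask))
  structure(hm, class = c("heatmap", class(hm)), grid = grid, spec = spec,
            feature = feature, label = label, norm_stats = norm_stats)
}

#' Encode a cohort into a per-subject heatmap dataset
#'
#' One heatmap per subject for a chosen feature. Normalization statistics
#' are taken from `norm_subjects` (typically the training subjects) and
#' frozen for everyone else; by default they come from the whole table.
#'
#' @param table a [feature_table].
#' @param feature feature column, e.g. `"csf_pct"`.
#' @param spec a [quantization_spec].
#' @param grid a [time_grid].
#' @param norm_subjects optional character vector of `"group.subject"` keys
#'   whose rows define the normalization statistics.
#' @param rate_total_T optional duration normalizer.
#' @return list with `x` (array `n_subjects x n_bins x 3`), `y` (group
#'   codes), `subject` (keys), `norm_stats`.
#' @export
encode_cohort <- function(table, feature, spec = quantization_spec(8),
                          grid = time_grid(), norm_subjects = NULL,
                          rate_total_T = NULL) {
  subj_key <- paste(table$group_code, table$subject_num, sep = ".")
  norm_tab <- if (is.null(norm_subjects)) {
    table
  } else {
    table[subj_key %in% norm_subjects, , drop = FALSE]
  }
  ns <- compute_norm_stats(norm_tab, feature, grid, rate_total_T)
  keys <- unique(subj_key)
  x <- array(0, dim = c(length(keys), grid$n_bins, 3L))
  y <- integer(length(keys))
  for (i in seq_along(keys)) {
    idx <- which(subj_key == keys[i])
    hm <- suppressWarnings(
      encode_heatmap(table$delta_t_months[idx], table[[feature]][idx],
                     ns, spec, grid, rate_total_T,
                     label = keys[i], feature = feature))
    x[i, , ] <- unclass(hm)
    y[i] <- table$group_code[idx[1L]]
  }
  list(x = x, y = y, subject = keys, norm_stats = ns)
}

#' @export
print.heatmap <- function(x, ...) {
  g <- attr(x, "grid"); s <- attr(x, "spec")
  cat(sprintf("<heatmap> %d bins x 3 channels, %d-bit, feature %s\n",
              g$n_bins, s$bit_depth,
              if (is.null(attr(x, "feature"))) "?" else attr(x, "feature")))
  invisible(x)
}
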