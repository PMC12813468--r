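test_that("the study window discretizes into 28 three-month bins", {
  g <- time_grid()
  expect_equal(g$n_bins, 28L)
  expect_equal(g$bin_width_months, 3)
  expect_equal(g$t_max, 84)
  expect_equal(g$bin_centers[1], 1.5)
  expect_error(time_grid(bin_width_months = 5), "whole number")
})

test_that("bin_index uses half-open bins with a clamped right edge", {
  g <- time_grid()
  expect_equal(bin_index(0, g), 0L)
  expect_equal(bin_index(10.5, g), 3L)
  expect_equal(bin_index(84, g), 27L)
  expect_equal(bin_index(c(2.999, 3), g), c(0L, 1L))
  expect_error(bin_index(-1, g), "window")
  expect_error(bin_index(84.5, g), "window")
})

test_that("bin aggregation averages co-binned sessions and masks gaps", {
  g <- time_grid()
  agg <- aggregate_bins(c(0, 6), c(10, 20), g)
  expect_equal(which(agg$mask == 1L), c(1L, 3L))
  expect_equal(sum(agg$mask), 2L)

  agg2 <- aggregate_bins(c(0, 1), c(10, 14), g)   # same bin
  expect_equal(agg2$values[1], 12)
  expect_equal(sum(agg2$mask), 1L)

  empty <- aggregate_bins(numeric(0), numeric(0), g)
  expect_true(all(empty$mask == 0L) && all(empty$values == 0))
})

test_that("rate channel matches hand-computed slopes", {
  g <- time_grid()
  agg <- aggregate_bins(c(0, 12), c(10, 16), g)
  r <- rate_channel(agg$values, agg$mask, g)
  expect_equal(r[bin_index(12, g) + 1L], 0.5)   # (16-10)/(13.5-1.5)
  expect_equal(sum(r != 0), 1L)                 # first occupied bin is 0

  # study-duration normalization mode
  rT <- rate_channel(agg$values, agg$mask, g, total_T_months = 180)
  expect_equal(rT[bin_index(12, g) + 1L], 0.5 / 180)

  # constant series has zero rate everywhere
  aggc <- aggregate_bins(c(0, 10, 20), c(7, 7, 7), g)
  expect_true(all(rate_channel(aggc$values, aggc$mask, g) == 0))

  # single occupied bin: no slope estimable
  agg1 <- aggregate_bins(5, 11, g)
  expect_true(all(rate_channel(agg1$values, agg1$mask, g) == 0))
})

test_that("rate channel equals an independent finite-difference oracle", {
  g <- time_grid()
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:9, 1)
    dt <- sort(runif(n, 0, 84))
    v <- rnorm(n, 100, 20)
    agg <- aggregate_bins(dt, v, g)
    expect_equal(rate_channel(agg$values, agg$mask, g),
                 oracle_rates(dt, v, g), tolerance = 1e-12)
  }
})

test_that("min-max scaling maps the range onto [0, 255]", {
  expect_equal(minmax_scale(10, 0, 10), 255)
  expect_equal(minmax_scale(0, 0, 10), 0)
  expect_equal(minmax_scale(5, 0, 10), 127.5)
  expect_equal(minmax_scale(c(-5, 20), 0, 10), c(0, 255))  # clipping
  expect_equal(minmax_scale(c(3, 7), 5, 5), c(0, 0))       # degenerate range
  expect_error(minmax_scale(1, 10, 0), "f_max")
})

test_that("quantization snaps to 2^bit levels and is idempotent", {
  expect_equal(quantization_spec(16)$n_levels, 65536)
  expect_equal(vapply(c(2, 3, 4, 8, 16),
                      function(b) quantization_spec(b)$n_levels, numeric(1)),
               c(4, 8, 16, 256, 65536))
  expect_error(quantization_spec(5), "unsupported")

  s2 <- quantization_spec(2)
  expect_equal(quantize(100, s2), 85)   # level round(100/255*3) = 1
  x <- seq(0, 255, length.out = 1000)
  q <- quantize(x, s2)
  expect_lte(length(unique(q)), 4L)
  expect_equal(quantize(q, s2), q)      # idempotent
  # error bound: half a level step
  expect_lte(max(abs(q - x)), 255 / (2 * (s2$n_levels - 1)) + 1e-12)
  # monotone order preservation
  for (b in c(2, 3, 8)) {
    q <- quantize(x, quantization_spec(b))
    expect_true(all(diff(q) >= 0))
  }
  expect_error(quantize(300, s2), "0, 255")
})

test_that("encoded heatmaps satisfy the channel contracts", {
  g <- time_grid()
  ns <- list(value = c(400, 500), rate = c(-2, 2))
  hm <- encode_heatmap(c(0, 7, 30), c(420, 450, 480), ns,
                       quantization_spec(8), g)
  expect_equal(dim(hm), c(28L, 3L))
  expect_true(all(hm[, "C3"] %in% c(0, 1)))
  expect_true(all(hm[, "C1"] >= 0 & hm[, "C1"] <= 255))
  expect_true(all(hm[, "C2"] >= 0 & hm[, "C2"] <= 255))
  expect_true(all(hm[hm[, "C3"] == 0, c("C1", "C2")] == 0))
  expect_equal(sum(hm[, "C3"]), 3)   # mask sum = occupied bins <= sessions

  # 2-bit C1 takes at most 4 distinct values
  hm2 <- encode_heatmap(c(0, 7, 30, 60), c(420, 450, 480, 412), ns,
                        quantization_spec(2), g)
  expect_lte(length(unique(hm2[, "C1"])), 4L)

  # sessions beyond the window are dropped with a warning
  expect_warning(
    hmw <- encode_heatmap(c(0, 12, 90), c(420, 450, 480), ns,
                          quantization_spec(8), g),
    "outside")
  expect_equal(sum(hmw[, "C3"]), 2)
  expect_error(
    suppressWarnings(encode_heatmap(c(90, 100), c(1, 2), ns,
                                    quantization_spec(8), g)),
    "outside")
})

test_that("cohort encoding yields one 28 x 3 heatmap per subject", {
  tab <- generate_cohort(make_default_profiles(), seed = 2)
  ds <- encode_cohort(tab, "csf_pct", quantization_spec(8))
  expect_equal(dim(ds$x), c(114L, 28L, 3L))
  expect_setequal(unique(ds$y), 0:4)
  # mask sums never exceed each subject's in-window session count
  subj_key <- paste(tab$group_code, tab$subject_num, sep = ".")
  for (i in sample(114, 10)) {
    n_sess <- sum(subj_key == ds$subject[i] & tab$delta_t_months <= 84)
    expect_lte(sum(ds$x[i, , 3]), n_sess)
  }
})

test_that("normalization statistics can be frozen on a training subset", {
  tab <- generate_cohort(make_default_profiles(), seed = 2)
  subj_key <- unique(paste(tab$group_code, tab$subject_num, sep = "."))
  train_subj <- subj_key[seq(1, length(subj_key), by = 2)]
  ds <- encode_cohort(tab, "gm_pct", quantization_spec(8),
                      norm_subjects = train_subj)
  in_train <- paste(tab$group_code, tab$subject_num, sep = ".") %in%
    train_subj & tab$delta_t_months <= 84
  expect_equal(ds$norm_stats$value, range(tab$gm_pct[in_train]))
})
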