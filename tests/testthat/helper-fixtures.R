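# Shared fixtures and independent oracles for the test suite.

# A tiny hand-built feature table: 2 subjects x 2-3 scans.
tiny_table <- function() {
  df <- data.frame(
    label = c("0.1.1", "0.1.2", "0.1.3", "1.1.1", "1.1.2"),
    group_code = c(0L, 0L, 0L, 1L, 1L),
    subject_num = 1L,
    scan_num = c(1L, 2L, 3L, 1L, 2L),
    delta_t_months = c(0, 6, 12, 0, 9),
    tiv_ml = c(1500, 1500, 1500, 1400, 1400),
    gm_ml = c(560, 555, 550, 600, 598),
    wm_ml = c(460, 458, 455, 470, 469),
    csf_ml = c(450, 458, 466, 440, 445),
    ct_mm = c(2.2, 2.19, 2.18, 2.35, 2.34),
    wmh_ml = c(8, 8.4, 8.8, 3, 3.1)
  )
  for (v in c("gm", "wm", "csf", "wmh")) {
    df[[paste0(v, "_pct")]] <- 100 * df[[paste0(v, "_ml")]] / df$tiv_ml
  }
  feature_table(df)
}

# A degenerate profile whose draws are fully deterministic: zero SDs, fixed
# slope s for every feature (frac_increasing consistent with sign(s)).
deterministic_profile <- function(s = 6) {
  feats <- lapply(list(gm = 560, wm = 460, csf = 450, ct = 2.2, wmh = 8),
                  function(m) {
                    list(baseline_mean = m, baseline_sd = 0,
                         annual_change_median = s,
                         annual_change_iqr = c(s, s),
                         frac_increasing = as.numeric(s > 0),
                         plausible_range = c(-1e6, 1e6),
                         baseline_family = "gaussian")
                  })
  group_profile(0L, n_subjects = 2L, sessions_range = c(3L, 3L),
                followup_months_range = c(0, 120), tiv_mean = 1500,
                tiv_sd = 0, features = feats)
}

# Independent oracle for the rate channel: finite differences computed
# directly over the session list, bypassing rate_channel().
oracle_rates <- function(delta_t, values, grid) {
  b <- floor((delta_t - grid$t_min) / grid$bin_width_months)
  b <- pmin(b, grid$n_bins - 1L)
  means <- tapply(values, b, mean)
  occ <- sort(as.integer(names(means)))
  out <- numeric(grid$n_bins)
  if (length(occ) >= 2L) {
    for (j in 2:length(occ)) {
      t2 <- grid$t_min + (occ[j] + 0.5) * grid$bin_width_months
      t1 <- grid$t_min + (occ[j - 1L] + 0.5) * grid$bin_width_months
      out[occ[j] + 1L] <-
        (means[[as.character(occ[j])]] - means[[as.character(occ[j - 1L])]]) /
        (t2 - t1)
    }
  }
  out
}

# Finite-difference gradient check over a sample of weights in every
# parameter layer; returns the worst relative error among gradients of
# non-negligible size.
grad_check_model <- function(model, x, y, n_per_layer = 6L, eps = 1e-6) {
  ml <- longiheat:::model_loss(model, x, y)
  bk <- longiheat:::nn_backward(model, ml$fwd, ml$ce$dlogits)
  worst <- 0
  for (li in seq_along(model$layers)) {
    if (is.null(model$layers[[li]]$W)) next
    W <- model$layers[[li]]$W
    ks <- sample(length(W), min(n_per_layer, length(W)))
    for (k in ks) {
      m2 <- model
      m2$layers[[li]]$W[k] <- W[k] + eps
      lp <- longiheat:::model_loss(m2, x, y)$ce$loss
      m2$layers[[li]]$W[k] <- W[k] - eps
      lm <- longiheat:::model_loss(m2, x, y)$ce$loss
      num <- (lp - lm) / (2 * eps)
      ana <- bk$grads[[li]]$dW[k]
      denom <- abs(num) + abs(ana)
      if (denom > 1e-7) {
        worst <- max(worst, abs(num - ana) / denom)
      }
    }
  }
  worst
}
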