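# Gradient-weighted class activation mapping over the time axis.
#
# For a target class, the gradient of its pre-softmax score with respect to
# the last convolutional layer's activations is averaged over time positions
# to weight each filter; the ReLU of the weighted activation sum, min-max
# normalized to [0, 1] and linearly upsampled back to the input width, shows
# which time bins drove the decision.

#' Grad-CAM temporal attribution map
#'
#' @param model a `longiheat_model` with at least one convolutional layer.
#' @param x a single heatmap (`n_bins x n_channels`) or a batch array.
#' @param target_class integer code 0..4, a vector (one per sample), or
#'   `NULL` to explain each sample's predicted class.
#' @return matrix `n x n_bins` of attributions in `[0, 1]` (a batch of one
#'   still returns a 1-row matrix). Rows whose gradient vanished everywhere
#'   are all-zero and flagged in the `zero_gradient` attribute.
#' @export
gradcam_map <- function(model, x, target_class = NULL) {
  x <- as_batch(x, model$spec)
  N <- dim(x)[1L]
  fwd <- nn_forward(model, x)
  probs <- subject_probs(model, fwd, N)
  if (is.null(target_class)) {
    target_class <- max.col(probs) - 1L
  }
  target_class <- as.integer(rep_len(target_class, N))
  if (any(target_class < 0L | target_class >= model$spec$n_classes)) {
    stop("target_class must be in 0..", model$spec$n_classes - 1L,
         call. = FALSE)
  }
  # Seed the backward pass with d(score_c)/d(logits): 1 on the target logit
  # (for the FCN the subject score is the bin-mean logit, so 1/T per bin).
  dout <- matrix(0, nrow(fwd$out), ncol(fwd$out))
  if (inherits(model, "longiheat_cnn")) {
    dout[cbind(seq_len(N), target_class + 1L)] <- 1
  } else {
    T_out <- nrow(fwd$out) %/% N
    rows <- rep(seq_len(N), times = T_out) + rep((seq_len(T_out) - 1L) * N,
                                                 each = N)
    dout[cbind(rows, rep(target_class + 1L, times = T_out))] <- 1 / T_out
  }
  bk <- nn_backward(model, fwd, dout, stop_at = model$gradcam_layer)
  acts <- layer_output(model, fwd, model$gradcam_layer)
  T_conv <- nrow(acts) %/% N
  grads <- bk$dx
  n_filt <- ncol(acts)
  maps <- matrix(0, N, T_conv)
  zero_grad <- logical(N)
  for (i in seq_len(N)) {
    rows <- i + (seq_len(T_conv) - 1L) * N
    A <- acts[rows, , drop = FALSE]       # T_conv x filters
    G <- grads[rows, , drop = FALSE]
    alpha <- colMeans(G)                  # spatially averaged gradients
    m <- pmax(A %*% alpha, 0)
    if (max(m) <= 0) {
      zero_grad[i] <- all(abs(G) < 1e-12)
      maps[i, ] <- 0
    } else {
      maps[i, ] <- (m - min(m)) / (max(m) - min(m))
    }
  }
  out <- t(apply(maps, 1L, upsample_linear, n_out = model$spec$n_bins))
  if (N == 1L) out <- matrix(out, 1L, model$spec$n_bins)
  attr(out, "target_class") <- target_class
  attr(out, "zero_gradient") <- zero_grad
  out
}

# Forward pass value at the output of layer `j` (re-derived from caches).
layer_output <- function(model, fwd, j) {
  l <- model$layers[[j]]
  if (l$type != "conv") stop("gradcam layer must be convolutional")
  Z <- sweep(fwd$caches[[j]]$Xcol %*% l$W, 2L, l$b, "+")
  if (l$relu) pmax(Z, 0) else Z
}

upsample_linear <- function(v, n_out) {
  n_in <- length(v)
  if (n_in == n_out) return(v)
  # align bin centers of the coarse and fine grids
  x_in <- (seq_len(n_in) - 0.5) / n_in
  x_out <- (seq_len(n_out) - 0.5) / n_out
  stats::approx(x_in, v, xout = x_out, rule = 2L)$y
}

#' Group-averaged attribution profile
#'
#' Element-wise mean of a set of attribution maps, re-normalized to
#' `[0, 1]`; averaging over members of one diagnostic group yields the
#' smooth group-level temporal profile.
#'
#' @param maps matrix `n x n_bins` (rows are per-subject maps).
#' @return numeric vector of length `n_bins` in `[0, 1]`.
#' @export
group_average_map <- function(maps) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) stop("at least one map is required", call. = FALSE)
  m <- colMeans(maps)
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Randomized-weights sanity check for Grad-CAM
#'
#' If attributions reflect learned structure, maps from the trained model
#' should decorrelate from maps produced by the same architecture with
#' freshly randomized weights. Computes the mean per-sample Spearman
#' correlation between trained-model and random-model maps and a permutation
#' p-value for the null that the mean correlation is 0 (sign-flip
#' permutation over samples).
#'
#' @param model trained `longiheat_model`.
#' @param x batch of heatmaps (>= 2 samples, ideally >= 20).
#' @param seed integer seed for the re-initialization and permutations.
#' @param n_perm number of sign-flip permutations.
#' @param target_class forwarded to [gradcam_map()] (default: each model's
#'   own predicted class per sample).
#' @return list with `mean_correlation`, `p_value`, per-sample
#'   `correlations`, and `n_degenerate` (samples whose map was constant and
#'   was skipped).
#' @export
gradcam_sanity_check <- function(model, x, seed = 1L, n_perm = 999L,
                                 target_class = NULL) {
  x <- as_batch(x, model$spec)
  if (dim(x)[1L] < 2L) stop("need at least 2 inputs", call. = FALSE)
  random_model <- if (inherits(model, "longiheat_cnn")) {
    build_cnn(model$spec, seed = derive_seed(seed, 101L))
  } else {
    build_fcn(model$spec, seed = derive_seed(seed, 101L))
  }
  m_trained <- gradcam_map(model, x, target_class)
  m_random <- gradcam_map(random_model, x, target_class)
  cors <- vapply(seq_len(nrow(m_trained)), function(i) {
    a <- m_trained[i, ]; b <- m_random[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }, numeric(1L))
  ok <- !is.na(cors)
  if (!any(ok)) {
    return(list(mean_correlation = NA_real_, p_value = NA_real_,
                correlations = cors, n_degenerate = sum(!ok)))
  }
  obs <- mean(cors[ok])
  perm <- with_seed(derive_seed(seed, 102L), {
    vapply(seq_len(n_perm), function(k) {
      mean(cors[ok] * sample(c(-1, 1), sum(ok), replace = TRUE))
    }, numeric(1L))
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(mean_correlation = obs, p_value = p, correlations = cors,
       n_degenerate = sum(!ok))
}
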