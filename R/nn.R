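# Minimal 1-D convolutional network engine.
#
# The heatmap inputs are height-1 images (1 x T bins x C channels), so every
# "2-D" operation of the reference architectures reduces to a 1-D operation
# along the time axis: 3x3 convolutions become width-3 convolutions, 2x2 max
# pooling becomes 1x2 pooling. Activations for a batch of N samples are kept
# as a matrix A[N*T, C] whose row index is n + (t - 1) * N; this makes
# convolution an im2col matrix product and lets flatten/unflatten be pure
# dim changes (the memory layout equals array(N, T, C)).
#
# Everything is written against base R matrix ops with manual backprop and
# Adam updates. Backprop is verified against finite differences in the test
# suite.

nn_glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

nn_layer_conv <- function(cin, cout, k = 3L, relu = TRUE) {
  W <- nn_glorot(k * cin, k * cout, c(k * cin, cout))
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       relu = relu, W = W, b = numeric(cout))
}

nn_layer_pool <- function() list(type = "pool")
nn_layer_upsample <- function() list(type = "upsample")
nn_layer_flatten <- function() list(type = "flatten")

nn_layer_dense <- function(fin, fout, relu = TRUE) {
  list(type = "dense", fin = fin, fout = fout, relu = relu,
       W = nn_glorot(fin, fout, c(fin, fout)), b = numeric(fout))
}

# -- shifting helpers (time axis), layout row = n + (t-1)N ------------------

shift_time <- function(Xm, N, T, offset) {
  C <- ncol(Xm)
  if (offset == -1L) {
    rbind(matrix(0, N, C), Xm[seq_len(N * (T - 1L)), , drop = FALSE])
  } else if (offset == 1L) {
    rbind(Xm[(N + 1L):(N * T), , drop = FALSE], matrix(0, N, C))
  } else {
    Xm
  }
}

odd_rows <- function(N, T) {
  rep((seq(1L, T, 2L) - 1L) * N, each = N) + seq_len(N)
}

# -- forward / backward per layer -------------------------------------------

nn_forward_layer <- function(layer, Xm, N, T) {
  switch(layer$type,
    conv = {
      Xcol <- if (layer$k == 1L) {
        Xm
      } else {
        cbind(shift_time(Xm, N, T, -1L), Xm, shift_time(Xm, N, T, 1L))
      }
      Z <- sweep(Xcol %*% layer$W, 2L, layer$b, "+")
      A <- if (layer$relu) pmax(Z, 0) else Z
      list(X = A, N = N, T = T, cache = list(Xcol = Xcol, pos = Z > 0))
    },
    pool = {
      if (T %% 2L != 0L) stop("pooling needs an even time dimension")
      io <- odd_rows(N, T)
      ie <- io + N
      A <- Xm[io, , drop = FALSE]
      B <- Xm[ie, , drop = FALSE]
      takeA <- A >= B
      list(X = pmax(A, B), N = N, T = T %/% 2L,
           cache = list(io = io, ie = ie, takeA = takeA, T_in = T))
    },
    upsample = {
      in_t <- rep(seq_len(T), each = 2L)
      rows <- rep((in_t - 1L) * N, each = N) + seq_len(N)
      list(X = Xm[rows, , drop = FALSE], N = N, T = 2L * T,
           cache = list(T_in = T))
    },
    flatten = {
      list(X = matrix(Xm, N, T * ncol(Xm)), N = N, T = 1L,
           cache = list(T_in = T, C_in = ncol(Xm)))
    },
    dense = {
      Z <- sweep(Xm %*% layer$W, 2L, layer$b, "+")
      A <- if (layer$relu) pmax(Z, 0) else Z
      list(X = A, N = N, T = T, cache = list(Xin = Xm, pos = Z > 0))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward_layer <- function(layer, dA, cache, N) {
  switch(layer$type,
    conv = {
      dZ <- if (layer$relu) dA * cache$pos else dA
      dW <- crossprod(cache$Xcol, dZ)
      db <- colSums(dZ)
      dXcol <- dZ %*% t(layer$W)
      C <- layer$cin
      T <- nrow(dZ) %/% N
      if (layer$k == 1L) {
        dX <- dXcol
      } else {
        dX <- dXcol[, C + seq_len(C), drop = FALSE]
        dprev <- dXcol[, seq_len(C), drop = FALSE]
        dnxt <- dXcol[, 2L * C + seq_len(C), drop = FALSE]
        lower <- seq_len(N * (T - 1L))
        dX[lower, ] <- dX[lower, ] + dprev[N + lower, , drop = FALSE]
        dX[N + lower, ] <- dX[N + lower, ] + dnxt[lower, , drop = FALSE]
      }
      list(dX = dX, dW = dW, db = db)
    },
    pool = {
      C <- ncol(dA)
      dX <- matrix(0, N * cache$T_in, C)
      dX[cache$io, ] <- dA * cache$takeA
      dX[cache$ie, ] <- dA * (!cache$takeA)
      list(dX = dX)
    },
    upsample = {
      io <- odd_rows(N, 2L * cache$T_in)
      list(dX = dA[io, , drop = FALSE] + dA[io + N, , drop = FALSE])
    },
    flatten = {
      list(dX = matrix(dA, N * cache$T_in, cache$C_in))
    },
    dense = {
      dZ <- if (layer$relu) dA * cache$pos else dA
      list(dX = dZ %*% t(layer$W), dW = crossprod(cache$Xin, dZ),
           db = colSums(dZ))
    }
  )
}

# Full forward pass. `x` is an array [N, T, C].
nn_forward <- function(model, x) {
  N <- dim(x)[1L]
  T <- dim(x)[2L]
  Xm <- matrix(x, N * T, dim(x)[3L])
  caches <- vector("list", length(model$layers))
  dims <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    step <- nn_forward_layer(model$layers[[i]], Xm, N, T)
    Xm <- step$X
    T <- step$T
    caches[[i]] <- step$cache
    dims[[i]] <- c(N = N, T = T)
  }
  list(out = Xm, caches = caches, dims = dims, N = N)
}

# Backward pass from a gradient on the network output. Returns per-layer
# parameter gradients and, if `stop_at > 0`, the gradient with respect to
# the *output* of layer `stop_at` (used by Grad-CAM).
nn_backward <- function(model, fwd, dout, stop_at = 0L) {
  grads <- vector("list", length(model$layers))
  dA <- dout
  for (i in rev(seq_along(model$layers))) {
    if (i == stop_at) {
      return(list(grads = grads, dx = dA))
    }
    g <- nn_backward_layer(model$layers[[i]], dA, fwd$caches[[i]], fwd$N)
    grads[[i]] <- g[c("dW", "db")]
    dA <- g$dX
  }
  list(grads = grads, dx = dA)
}

# Softmax over rows plus sparse categorical cross-entropy.
nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# labels: integer 1..K per row of `logits`; weights: optional per-row.
nn_softmax_ce <- function(logits, labels, weights = NULL) {
  P <- nn_softmax(logits)
  M <- nrow(P)
  if (is.null(weights)) weights <- rep(1, M)
  wsum <- sum(weights)
  if (wsum <= 0) stop("degenerate loss weights")
  picked <- P[cbind(seq_len(M), labels)]
  loss <- -sum(weights * log(pmax(picked, 1e-12))) / wsum
  dlogits <- P
  dlogits[cbind(seq_len(M), labels)] <-
    dlogits[cbind(seq_len(M), labels)] - 1
  dlogits <- dlogits * (weights / wsum)
  if (!all(is.finite(loss))) stop("NaN loss encountered; aborting training")
  list(loss = loss, dlogits = dlogits, probs = P)
}

# -- Adam -------------------------------------------------------------------

nn_adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else {
      NULL
    }
  })
}

nn_adam_step <- function(model, grads, state, t, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}
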