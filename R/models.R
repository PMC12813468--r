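# Classifier construction and training: a small CNN (two conv blocks, dense
# head) and an FCN (conv encoder, 128-filter bottleneck, upsampling decoder,
# 1x1 conv classifier) over the 1 x 28 x 3 heatmap inputs, trained with Adam
# on sparse categorical cross-entropy under a stratified 80:20 split.

#' Architecture specifications
#'
#' `cnn_spec()` describes the convolutional classifier: two convolution
#' blocks (32 then 64 filters, width-3 kernels, ReLU, same padding, each
#' followed by 1x2 max pooling along time), a flatten, a 128-unit ReLU dense
#' layer and a 5-way softmax. `fcn_spec()` describes the fully convolutional
#' variant: the same 32/64 encoder, a 128-filter bottleneck, two upsample +
#' convolution decoder steps (64 then 32 filters) restoring the input width,
#' and a 1x1 convolution + softmax giving per-bin class probabilities.
#'
#' On height-1 inputs a nominal 2x2 pooling window is ill-defined; pooling
#' is applied as 1x2 along the time axis, preserving the spatial-reduction
#' intent.
#'
#' @param n_bins input width in time bins (default 28; must be divisible
#'   by 4 so two pooling stages fit).
#' @param n_channels input channels (default 3: value, rate, mask).
#' @param n_classes output classes (default 5).
#' @param filters encoder filter counts (default `c(32, 64)`).
#' @param dense_units CNN dense-layer width (default 128).
#' @param bottleneck FCN bottleneck filters (default 128).
#' @return a spec list consumed by [build_cnn()] / [build_fcn()].
#' @export
cnn_spec <- function(n_bins = 28L, n_channels = 3L, n_classes = 5L,
                     filters = c(32L, 64L), dense_units = 128L) {
  stopifnot(n_bins %% 4L == 0L, length(filters) == 2L)
  list(kind = "cnn", n_bins = as.integer(n_bins),
       n_channels = as.integer(n_channels),
       n_classes = as.integer(n_classes),
       filters = as.integer(filters), dense_units = as.integer(dense_units))
}

#' @rdname cnn_spec
#' @export
fcn_spec <- function(n_bins = 28L, n_channels = 3L, n_classes = 5L,
                     filters = c(32L, 64L), bottleneck = 128L) {
  stopifnot(n_bins %% 4L == 0L, length(filters) == 2L)
  list(kind = "fcn", n_bins = as.integer(n_bins),
       n_channels = as.integer(n_channels),
       n_classes = as.integer(n_classes),
       filters = as.integer(filters), bottleneck = as.integer(bottleneck))
}

#' Build an untrained model
#'
#' Instantiates the layer stack of a [cnn_spec()] or [fcn_spec()] with
#' seeded Glorot-uniform weights.
#'
#' @param spec architecture specification.
#' @param seed integer seed for weight initialization.
#' @return object of class `longiheat_model` (and `longiheat_cnn` or
#'   `longiheat_fcn`).
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(identical(spec$kind, "cnn"))
  with_seed(derive_seed(seed, 11L), {
    flat <- (spec$n_bins %/% 4L) * spec$filters[2L]
    layers <- list(
      nn_layer_conv(spec$n_channels, spec$filters[1L]),
      nn_layer_pool(),
      nn_layer_conv(spec$filters[1L], spec$filters[2L]),
      nn_layer_pool(),
      nn_layer_flatten(),
      nn_layer_dense(flat, spec$dense_units),
      nn_layer_dense(spec$dense_units, spec$n_classes, relu = FALSE)
    )
    structure(list(spec = spec, layers = layers, gradcam_layer = 3L,
                   trained = FALSE, history = NULL, seed = seed),
              class = c("longiheat_cnn", "longiheat_model"))
  })
}

#' @rdname build_cnn
#' @export
build_fcn <- function(spec = fcn_spec(), seed = 1L) {
  stopifnot(identical(spec$kind, "fcn"))
  with_seed(derive_seed(seed, 12L), {
    layers <- list(
      nn_layer_conv(spec$n_channels, spec$filters[1L]),
      nn_layer_pool(),
      nn_layer_conv(spec$filters[1L], spec$filters[2L]),
      nn_layer_pool(),
      nn_layer_conv(spec$filters[2L], spec$bottleneck),
      nn_layer_upsample(),
      nn_layer_conv(spec$bottleneck, spec$filters[2L]),
      nn_layer_upsample(),
      nn_layer_conv(spec$filters[2L], spec$filters[1L]),
      nn_layer_conv(spec$filters[1L], spec$n_classes, k = 1L, relu = FALSE)
    )
    structure(list(spec = spec, layers = layers, gradcam_layer = 9L,
                   trained = FALSE, history = NULL, seed = seed),
              class = c("longiheat_fcn", "longiheat_model"))
  })
}

#' Parameter-bearing layer audit
#'
#' @param model a `longiheat_model`.
#' @return data.frame listing each parameter-bearing layer with its type,
#'   kernel width and input/output sizes; used to assert the architecture
#'   matches its printed description.
#' @export
model_architecture <- function(model) {
  rows <- lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    if (l$type == "conv") {
      data.frame(type = "conv", kernel = l$k, n_in = l$cin, n_out = l$cout)
    } else {
      data.frame(type = "dense", kernel = NA_integer_,
                 n_in = l$fin, n_out = l$fout)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Subject-level stratified train/test split
#'
#' Splits sample indices so each class keeps (within rounding) the requested
#' train fraction, with at least one sample of every class on each side.
#' Because every subject contributes exactly one heatmap per feature,
#' splitting samples is splitting subjects, so no subject's scans straddle
#' the split.
#'
#' @param labels class label per sample (any atomic type).
#' @param ratio train fraction (default 0.8).
#' @param seed integer seed.
#' @return list with integer `train` and `test` index vectors.
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 samples to split", call. = FALSE)
  }
  with_seed(derive_seed(seed, 21L), {
    train <- integer(0)
    for (cl in names(counts)) {
      idx <- which(as.character(labels) == cl)
      n_tr <- min(max(round(ratio * length(idx)), 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.001,
#' batch size 32, sparse categorical cross-entropy. Epoch counts are 70 for
#' the CNN and 50 for the FCN (set by the caller).
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed integer seed controlling shuffling.
#' @param mask_loss FCN only: weight each time position's loss by the
#'   availability mask so empty bins do not contribute (default FALSE).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 70L, batch_size = 32L, lr = 0.001,
                         seed = 1L, mask_loss = FALSE) {
  stopifnot(epochs > 0L, batch_size > 0L, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), mask_loss = isTRUE(mask_loss)),
            class = "train_config")
}

# Internal: per-batch loss/gradient for either architecture.
model_loss <- function(model, xb, yb, mask_loss = FALSE) {
  fwd <- nn_forward(model, xb)
  N <- dim(xb)[1L]
  if (inherits(model, "longiheat_cnn")) {
    ce <- nn_softmax_ce(fwd$out, yb + 1L)
  } else {
    T <- nrow(fwd$out) %/% N
    labels <- rep(yb + 1L, times = T)
    w <- if (mask_loss) as.vector(matrix(xb[, , 3L], N, T)) else NULL
    ce <- nn_softmax_ce(fwd$out, labels, weights = w)
  }
  list(fwd = fwd, ce = ce)
}

#' Train a model
#'
#' Minibatch Adam training on sparse categorical cross-entropy. For the FCN
#' the subject label is broadcast to every time position. Training is fully
#' deterministic for a fixed `config$seed`; if `sample_ids` is supplied the
#' samples are first sorted by it, making the result invariant to the input
#' ordering as well.
#'
#' @param model an untrained (or previously trained) `longiheat_model`.
#' @param x array `n x n_bins x n_channels` of heatmaps.
#' @param y integer group codes 0..4, length `n`.
#' @param config a [train_config()].
#' @param sample_ids optional vector of unique per-sample keys used to
#'   canonicalize sample order before training.
#' @return the trained model, with a `history` data.frame (epoch, loss,
#'   accuracy).
#' @export
train_model <- function(model, x, y, config = train_config(),
                        sample_ids = NULL) {
  stopifnot(inherits(model, "longiheat_model"),
            length(dim(x)) == 3L, dim(x)[1L] == length(y))
  if (any(y < 0L | y >= model$spec$n_classes)) {
    stop("labels must be integers in 0..", model$spec$n_classes - 1L,
         call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
    ord <- order(sample_ids)
    x <- x[ord, , , drop = FALSE]
    y <- y[ord]
  }
  n <- dim(x)[1L]
  state <- nn_adam_init(model)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  step <- 0L
  with_seed(derive_seed(config$seed, 31L), {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      losses <- c()
      correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        batch <- idx[start:min(start + config$batch_size - 1L, n)]
        xb <- x[batch, , , drop = FALSE]
        yb <- y[batch]
        ml <- model_loss(model, xb, yb, config$mask_loss)
        step <- step + 1L
        bk <- nn_backward(model, ml$fwd, ml$ce$dlogits)
        upd <- nn_adam_step(model, bk$grads, state, step, config$lr)
        model <- upd$model
        state <- upd$state
        losses <- c(losses, ml$ce$loss)
        pred <- subject_probs(model, ml$fwd, length(batch))
        correct <- correct + sum(max.col(pred) - 1L == yb)
      }
      history$loss[epoch] <- mean(losses)
      history$accuracy[epoch] <- correct / n
    }
  })
  model$trained <- TRUE
  model$history <- history
  model$train_config <- config
  model
}

# Internal: subject-level class probabilities from a forward pass.
subject_probs <- function(model, fwd, N) {
  P <- nn_softmax(fwd$out)
  if (inherits(model, "longiheat_cnn")) return(P)
  T <- nrow(P) %/% N
  out <- matrix(0, N, ncol(P))
  for (k in seq_len(ncol(P))) {
    out[, k] <- rowMeans(matrix(P[, k], N, T))
  }
  out
}

#' Predict class probabilities
#'
#' For the CNN, one probability vector per sample. For the FCN, per-bin
#' probability distributions are averaged over bins to give the
#' subject-level prediction; set `type = "bin"` to get the per-bin maps.
#'
#' @param object a trained `longiheat_model`.
#' @param x array `n x n_bins x n_channels` (a single `n_bins x n_channels`
#'   matrix is promoted to a batch of one).
#' @param type `"subject"` (default) or, for the FCN, `"bin"`.
#' @param ... unused.
#' @return `"subject"`: matrix `n x n_classes` of probabilities (rows sum
#'   to 1). `"bin"`: array `n x n_bins x n_classes`.
#' @export
predict.longiheat_model <- function(object, x, type = c("subject", "bin"),
                                    ...) {
  type <- match.arg(type)
  x <- as_batch(x, object$spec)
  fwd <- nn_forward(object, x)
  N <- dim(x)[1L]
  if (type == "bin") {
    if (!inherits(object, "longiheat_fcn")) {
      stop("per-bin predictions only exist for the FCN", call. = FALSE)
    }
    P <- nn_softmax(fwd$out)
    return(array(P, dim = c(N, nrow(P) %/% N, ncol(P))))
  }
  subject_probs(object, fwd, N)
}

#' @rdname predict.longiheat_model
#' @param model a trained `longiheat_model`.
#' @return `predict_class()`: integer group codes 0..4.
#' @export
predict_class <- function(model, x) {
  max.col(predict(model, x)) - 1L
}

as_batch <- function(x, spec) {
  if (length(dim(x)) == 2L) {
    x <- array(x, dim = c(1L, dim(x)))
  }
  if (length(dim(x)) != 3L || dim(x)[2L] != spec$n_bins ||
      dim(x)[3L] != spec$n_channels) {
    stop(sprintf("input must be [n x %d x %d]", spec$n_bins,
                 spec$n_channels), call. = FALSE)
  }
  x
}

#' @export
print.longiheat_model <- function(x, ...) {
  arch <- model_architecture(x)
  cat(sprintf("<%s> %s, %d parameter layers, %strained\n",
              class(x)[1L], toupper(x$spec$kind), nrow(arch),
              if (x$trained) "" else "un"))
  print(arch)
  invisible(x)
}
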