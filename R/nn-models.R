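# The four architectures: instance-based CNN, sequence-based LSTM, the
# sequential CNN-LSTM baseline, and the parallel multi-frame network.
#
# Instance branch: three blocks of [conv 3x3 same -> batch norm -> ReLU],
# 2x2 max pooling after blocks 1 and 2 only, applied to the (2, N, N)
# segment tensor treated as a 2-channel image; the final map is flattened.
# Sequence branch: a single LSTM over the segment's M time columns (each an
# N-vector); the feature is the final hidden state. Both are followed by a
# fully connected head 128 -> 64 -> 2 with ReLU + dropout on the first two
# layers and softmax on the last.

#' Describe a model architecture
#'
#' @param kind One of `"cnn"`, `"lstm"`, `"cnn_lstm"`, `"multiframe"`.
#' @param n_channels Number of EEG channels N (the tensor is 2 x N x N).
#' @param seq_len Samples per segment M (equals the sampling rate for 1-s
#'   segments).
#' @param conv_filters Integer vector of length 3: filters per conv block.
#' @param conv_kernel Odd kernel size (default 3).
#' @param lstm_units LSTM hidden size (default 256).
#' @param fc_sizes Fully connected head sizes; must end in 2
#'   (default `c(128, 64, 2)`).
#' @param dropout Dropout rate on the first two head layers, in `[0, 1)`
#'   (default 0.5); active in training only.
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = c("multiframe", "cnn", "lstm", "cnn_lstm"),
                       n_channels, seq_len,
                       conv_filters = c(32L, 64L, 128L), conv_kernel = 3L,
                       lstm_units = 256L, fc_sizes = c(128L, 64L, 2L),
                       dropout = 0.5) {
  kind <- match.arg(kind)
  stopifnot_scalar_num(n_channels, "n_channels", lower = 1)
  stopifnot_scalar_num(seq_len, "seq_len", lower = 1)
  stopifnot_scalar_num(lstm_units, "lstm_units", lower = 1)
  stopifnot_scalar_num(dropout, "dropout", lower = 0, upper = 1, strict_upper = TRUE)
  if (length(conv_filters) != 3L) stop("`conv_filters` must have length 3", call. = FALSE)
  if (conv_kernel %% 2 != 1) stop("`conv_kernel` must be odd", call. = FALSE)
  if (utils::tail(fc_sizes, 1) != 2L) stop("`fc_sizes` must end in 2 (binary softmax)", call. = FALSE)
  if (length(fc_sizes) != 3L) stop("`fc_sizes` must have length 3", call. = FALSE)
  spec <- structure(
    list(kind = kind, n_channels = as.integer(n_channels),
         seq_len = as.integer(seq_len),
         conv_filters = as.integer(conv_filters),
         conv_kernel = as.integer(conv_kernel),
         lstm_units = as.integer(lstm_units),
         fc_sizes = as.integer(fc_sizes), dropout = dropout),
    class = "model_spec"
  )
  if (kind != "lstm") .conv_shapes(spec)  # validates N against the pooling schedule
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec '%s': N = %d channels, M = %d samples\n",
              x$kind, x$n_channels, x$seq_len))
  if (x$kind != "lstm") {
    cat(sprintf("  conv blocks: %s filters, %dx%d kernels, pool after blocks 1-2\n",
                paste(x$conv_filters, collapse = "/"), x$conv_kernel, x$conv_kernel))
  }
  if (x$kind != "cnn") cat(sprintf("  LSTM units: %d\n", x$lstm_units))
  cat(sprintf("  FC head: %s, dropout %.2f\n",
              paste(x$fc_sizes, collapse = "/"), x$dropout))
  invisible(x)
}

# Spatial extents through the conv stack: N -> pool -> pool (floor), pooling
# after blocks 1 and 2 only.
.conv_shapes <- function(spec) {
  h1 <- spec$n_channels
  h2 <- h1 %/% 2L
  h3 <- h2 %/% 2L
  if (h3 < 1L) {
    stop(sprintf("n_channels = %d is too small for two 2x2 poolings; need at least 4",
                 spec$n_channels), call. = FALSE)
  }
  list(h = c(h1, h2, h3), flat = spec$conv_filters[3] * h3 * h3)
}

# Input dimensionality of the LSTM for each wiring.
.lstm_input_dim <- function(spec) {
  if (spec$kind == "cnn_lstm") {
    sh <- .conv_shapes(spec)
    sh$h[3] * spec$conv_filters[3]
  } else {
    spec$n_channels
  }
}

.head_input_dim <- function(spec) {
  switch(spec$kind,
    cnn = .conv_shapes(spec)$flat,
    lstm = spec$lstm_units,
    cnn_lstm = spec$lstm_units,
    multiframe = .conv_shapes(spec)$flat + spec$lstm_units
  )
}

# --- parameter initialisation ---------------------------------------------

.init_conv_stack <- function(spec) {
  k2 <- spec$conv_kernel^2
  chans <- c(2L, spec$conv_filters)
  p <- list()
  for (l in 1:3) {
    ci <- chans[l]; co <- chans[l + 1]
    p[[paste0("cnn.W", l)]] <- glorot(ci * k2, co * k2, c(k2, ci, co))
    p[[paste0("cnn.b", l)]] <- numeric(co)
    p[[paste0("cnn.g", l)]] <- rep(1, co)
    p[[paste0("cnn.beta", l)]] <- numeric(co)
  }
  p
}

.init_lstm <- function(spec) {
  d <- .lstm_input_dim(spec)
  H <- spec$lstm_units
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  list(
    "lstm.Wx" = glorot(d, H, c(d, 4L * H)),
    "lstm.Wh" = glorot(H, H, c(H, 4L * H)),
    "lstm.b" = b
  )
}

.init_head <- function(spec) {
  dims <- c(.head_input_dim(spec), spec$fc_sizes)
  p <- list()
  for (l in 1:3) {
    p[[paste0("fc.W", l)]] <- glorot(dims[l], dims[l + 1], c(dims[l], dims[l + 1]))
    p[[paste0("fc.b", l)]] <- numeric(dims[l + 1])
  }
  p
}

.init_bn_state <- function(spec) {
  lapply(spec$conv_filters, function(f) list(mean = numeric(f), var = rep(1, f)))
}

.layer_listing <- function(spec) {
  conv <- c("conv1", "batchnorm1", "relu1", "maxpool1",
            "conv2", "batchnorm2", "relu2", "maxpool2",
            "conv3", "batchnorm3", "relu3", "flatten")
  lstm <- "lstm"
  head <- c("fc1", "relu", "dropout", "fc2", "relu", "dropout", "fc3", "softmax")
  switch(spec$kind,
    cnn = c(conv, head),
    lstm = c(lstm, head),
    cnn_lstm = c(conv[-length(conv)], "unroll", lstm, head),
    multiframe = c(conv, lstm, "concatenate", head)
  )
}

#' Build an untrained model from a spec
#'
#' Weight initialisation is Glorot-uniform and fully determined by `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the initialisation.
#' @return An `mfnet_model`: spec, parameter list, batch-norm state and a
#'   layer listing. Feature and head dimensions are in `$feature_dim` and
#'   `$spec$fc_sizes`.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    params <- list()
    if (spec$kind %in% c("cnn", "cnn_lstm", "multiframe")) {
      params <- c(params, .init_conv_stack(spec))
    }
    if (spec$kind %in% c("lstm", "cnn_lstm", "multiframe")) {
      params <- c(params, .init_lstm(spec))
    }
    params <- c(params, .init_head(spec))
    structure(
      list(spec = spec, params = params,
           bn_state = if (spec$kind == "lstm") NULL else .init_bn_state(spec),
           layers = .layer_listing(spec),
           feature_dim = .head_input_dim(spec)),
      class = "mfnet_model"
    )
  })
}

#' @rdname build_model
#' @details `build_cnn_branch()`, `build_lstm_branch()`, `build_multiframe()`
#'   and `build_cnn_lstm()` are convenience constructors fixing the model
#'   kind; the two branch builders return the single-frame classifier whose
#'   pre-head features are the branch output (see [model_features()]).
#' @export
build_cnn_branch <- function(spec, seed = 1) {
  spec$kind <- "cnn"; build_model(spec, seed)
}

#' @rdname build_model
#' @export
build_lstm_branch <- function(spec, seed = 1) {
  spec$kind <- "lstm"; build_model(spec, seed)
}

#' @rdname build_model
#' @export
build_multiframe <- function(spec, seed = 1) {
  spec$kind <- "multiframe"; build_model(spec, seed)
}

#' @rdname build_model
#' @export
build_cnn_lstm <- function(spec, seed = 1) {
  spec$kind <- "cnn_lstm"; build_model(spec, seed)
}

#' @export
print.mfnet_model <- function(x, ...) {
  cat(sprintf("mfnet model (%s), %d parameters, feature dim %d\n",
              x$spec$kind, sum(lengths(x$params)), x$feature_dim))
  cat("  layers:", paste(x$layers, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
coef.mfnet_model <- function(object, ...) object$params

# --- forward / backward ---------------------------------------------------

# Conv stack forward. A: (B, 2, N, N) array. Returns the pre-flatten map
# (rows (b, i, j) x F3), its dims, the flattened feature, caches and the
# updated batch-norm state.
.conv_stack_fwd <- function(params, state, A, spec, training) {
  B <- dim(A)[1]
  X <- aperm(A, c(1, 3, 4, 2))
  dim(X) <- c(B * dim(A)[3] * dim(A)[4], 2L)
  dims <- c(B, dim(A)[3], dim(A)[4])
  caches <- list()
  for (l in 1:3) {
    cv <- conv_fwd(X, dims, params[[paste0("cnn.W", l)]], params[[paste0("cnn.b", l)]])
    bn <- bn_fwd(cv$out, params[[paste0("cnn.g", l)]], params[[paste0("cnn.beta", l)]],
                 state[[l]], training)
    state[[l]] <- bn$state
    rl <- relu_fwd(bn$out)
    caches[[l]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache, pool = NULL)
    X <- rl$out
    if (l < 3) {
      pl <- pool_fwd(X, dims)
      caches[[l]]$pool <- pl$cache
      X <- pl$out
      dims <- pl$dims_out
    }
  }
  feat <- X
  dim(feat) <- NULL
  feat <- matrix(feat, B, dims[2] * dims[3] * ncol(X))
  list(map = X, map_dims = dims, feat = feat, caches = caches, state = state)
}

.conv_stack_bwd <- function(dmap, caches, params) {
  grads <- list()
  dX <- dmap
  for (l in 3:1) {
    cc <- caches[[l]]
    if (!is.null(cc$pool)) dX <- pool_bwd(dX, cc$pool)
    dX <- relu_bwd(dX, cc$relu)
    bn <- bn_bwd(dX, cc$bn)
    grads[[paste0("cnn.g", l)]] <- bn$dgamma
    grads[[paste0("cnn.beta", l)]] <- bn$dbeta
    cv <- conv_bwd(bn$dX, cc$conv)
    grads[[paste0("cnn.W", l)]] <- cv$dW
    grads[[paste0("cnn.b", l)]] <- cv$db
    dX <- cv$dX
  }
  grads
}

# FC head forward: feat (B x D) -> logits (B x 2).
.head_fwd <- function(params, feat, spec, training) {
  caches <- list()
  X <- feat
  for (l in 1:3) {
    dn <- dense_fwd(X, params[[paste0("fc.W", l)]], params[[paste0("fc.b", l)]])
    X <- dn$out
    caches[[l]] <- list(dense = dn$cache, relu = NULL, drop = NULL)
    if (l < 3) {
      rl <- relu_fwd(X)
      dr <- dropout_fwd(rl$out, spec$dropout, training)
      caches[[l]]$relu <- rl$cache
      caches[[l]]$drop <- dr$cache
      X <- dr$out
    }
  }
  list(logits = X, caches = caches)
}

.head_bwd <- function(dlogits, caches, params) {
  grads <- list()
  dX <- dlogits
  for (l in 3:1) {
    cc <- caches[[l]]
    if (l < 3) {
      dX <- dropout_bwd(dX, cc$drop)
      dX <- relu_bwd(dX, cc$relu)
    }
    dn <- dense_bwd(dX, cc$dense, params[[paste0("fc.W", l)]])
    grads[[paste0("fc.W", l)]] <- dn$dW
    grads[[paste0("fc.b", l)]] <- dn$db
    dX <- dn$dX
  }
  grads$dfeat <- dX
  grads
}

# Re-wire the pre-flatten conv map into the CNN-LSTM sequence: length =
# final spatial width, element dim = final height x filters.
.map_to_sequence <- function(map, dims) {
  B <- dims[1]; H <- dims[2]; W <- dims[3]
  Fc <- ncol(map)
  A <- array(as.vector(map), c(B, H, W, Fc))
  A <- aperm(A, c(1, 2, 4, 3))
  dim(A) <- c(B, H * Fc, W)
  A
}

.sequence_to_map <- function(dA, dims, Fc) {
  B <- dims[1]; H <- dims[2]; W <- dims[3]
  dim(dA) <- c(B, H, Fc, W)
  dA <- aperm(dA, c(1, 2, 4, 3))
  matrix(as.vector(dA), B * H * W, Fc)
}

# Full model forward. batch: list(tensor = (B,2,N,N) array or NULL,
# raw = (B,N,M) array or NULL). Returns logits, caches, updated bn state.
.model_fwd <- function(params, state, spec, batch, training) {
  caches <- list(kind = spec$kind)
  feat <- NULL
  if (spec$kind %in% c("cnn", "multiframe")) {
    cs <- .conv_stack_fwd(params, state, batch$tensor, spec, training)
    state <- cs$state
    caches$conv <- cs$caches
    feat <- cs$feat
  }
  if (spec$kind %in% c("lstm", "multiframe")) {
    lf <- lstm_fwd(batch$raw, params[["lstm.Wx"]], params[["lstm.Wh"]],
                   params[["lstm.b"]], keep_cache = training)
    caches$lstm <- lf$cache
    feat <- if (is.null(feat)) lf$out else cbind(feat, lf$out)
  }
  if (spec$kind == "cnn_lstm") {
    cs <- .conv_stack_fwd(params, state, batch$tensor, spec, training)
    state <- cs$state
    caches$conv <- cs$caches
    caches$map_dims <- cs$map_dims
    caches$map_nf <- ncol(cs$map)
    seqA <- .map_to_sequence(cs$map, cs$map_dims)
    lf <- lstm_fwd(seqA, params[["lstm.Wx"]], params[["lstm.Wh"]],
                   params[["lstm.b"]], keep_cache = training)
    caches$lstm <- lf$cache
    feat <- lf$out
  }
  hd <- .head_fwd(params, feat, spec, training)
  caches$head <- hd$caches
  list(logits = hd$logits, caches = caches, state = state)
}

.model_bwd <- function(dlogits, caches, params, spec) {
  grads <- .head_bwd(dlogits, caches$head, params)
  dfeat <- grads$dfeat
  grads$dfeat <- NULL
  if (spec$kind == "cnn") {
    B <- nrow(dfeat)
    dmap <- matrix(as.vector(dfeat), length(dfeat) / utils::tail(spec$conv_filters, 1),
                   utils::tail(spec$conv_filters, 1))
    grads <- c(grads, .conv_stack_bwd(dmap, caches$conv, params))
  } else if (spec$kind == "lstm") {
    lb <- lstm_bwd(dfeat, caches$lstm, need_dx = FALSE)
    grads[["lstm.Wx"]] <- lb$dWx
    grads[["lstm.Wh"]] <- lb$dWh
    grads[["lstm.b"]] <- lb$db
  } else if (spec$kind == "multiframe") {
    flat <- .conv_shapes(spec)$flat
    dcnn <- dfeat[, seq_len(flat), drop = FALSE]
    dlstm <- dfeat[, flat + seq_len(spec$lstm_units), drop = FALSE]
    lb <- lstm_bwd(dlstm, caches$lstm, need_dx = FALSE)
    grads[["lstm.Wx"]] <- lb$dWx
    grads[["lstm.Wh"]] <- lb$dWh
    grads[["lstm.b"]] <- lb$db
    Fc <- utils::tail(spec$conv_filters, 1)
    dmap <- matrix(as.vector(dcnn), length(dcnn) / Fc, Fc)
    grads <- c(grads, .conv_stack_bwd(dmap, caches$conv, params))
  } else if (spec$kind == "cnn_lstm") {
    lb <- lstm_bwd(dfeat, caches$lstm, need_dx = TRUE)
    grads[["lstm.Wx"]] <- lb$dWx
    grads[["lstm.Wh"]] <- lb$dWh
    grads[["lstm.b"]] <- lb$db
    dmap <- .sequence_to_map(lb$dX, caches$map_dims, caches$map_nf)
    grads <- c(grads, .conv_stack_bwd(dmap, caches$conv, params))
  }
  grads
}

# Assemble the batch views a model kind needs from an eeg_segments object.
.model_batch <- function(segs, idx, spec) {
  need_tensor <- spec$kind %in% c("cnn", "cnn_lstm", "multiframe")
  if (need_tensor && is.null(segs$tensor)) {
    stop("segments must be tensorized first (see tensorize_segments())", call. = FALSE)
  }
  list(
    tensor = if (need_tensor) segs$tensor[idx, , , , drop = FALSE] else NULL,
    raw = if (spec$kind %in% c("lstm", "multiframe")) segs$x[idx, , , drop = FALSE] else NULL
  )
}

#' Pre-head feature matrix of a model on a set of segments
#'
#' For the single-frame models this is the branch output (the flattened
#' instance-based feature for `"cnn"`, the final LSTM hidden state for
#' `"lstm"`); for the multi-frame network it is their concatenation.
#' Computed in inference mode.
#'
#' @param model An `mfnet_model` (trained or untrained).
#' @param segs An `eeg_segments` object (tensorized when the model needs
#'   the instance view).
#' @return Numeric matrix, one row per segment, `model$feature_dim`
#'   columns.
#' @export
model_features <- function(model, segs) {
  stopifnot(inherits(model, "mfnet_model"))
  spec <- model$spec
  idx <- seq_len(if (inherits(segs, "eeg_segments")) dim(segs$x)[1] else dim(segs$raw)[1])
  batch <- if (inherits(segs, "eeg_segments")) .model_batch(segs, idx, spec) else segs
  feat <- NULL
  if (spec$kind %in% c("cnn", "multiframe")) {
    cs <- .conv_stack_fwd(model$params, model$bn_state, batch$tensor, spec, FALSE)
    feat <- cs$feat
  }
  if (spec$kind %in% c("lstm", "multiframe")) {
    lf <- lstm_fwd(batch$raw, model$params[["lstm.Wx"]], model$params[["lstm.Wh"]],
                   model$params[["lstm.b"]], keep_cache = FALSE)
    feat <- if (is.null(feat)) lf$out else cbind(feat, lf$out)
  }
  if (spec$kind == "cnn_lstm") {
    cs <- .conv_stack_fwd(model$params, model$bn_state, batch$tensor, spec, FALSE)
    seqA <- .map_to_sequence(cs$map, cs$map_dims)
    lf <- lstm_fwd(seqA, model$params[["lstm.Wx"]], model$params[["lstm.Wh"]],
                   model$params[["lstm.b"]], keep_cache = FALSE)
    feat <- lf$out
  }
  feat
}

#' Class probabilities from a (possibly untrained) model
#'
#' @param object An `mfnet_model`.
#' @param newdata An `eeg_segments` object.
#' @param batch_size Forward-pass batch size (memory control only).
#' @param ... Ignored.
#' @return Matrix with columns `interictal`, `preictal`; rows sum to 1.
#' @export
predict.mfnet_model <- function(object, newdata, batch_size = 256L, ...) {
  spec <- object$spec
  n <- dim(newdata$x)[1]
  out <- matrix(0, n, 2, dimnames = list(NULL, c("interictal", "preictal")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- .model_batch(newdata, idx, spec)
    fw <- .model_fwd(object$params, object$bn_state, spec, batch, training = FALSE)
    out[idx, ] <- softmax_rows(fw$logits)
  }
  out
}
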