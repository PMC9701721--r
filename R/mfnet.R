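# Model fitting: Adam on softmax cross-entropy with early stopping on
# validation loss and best-checkpoint restore. `mfnet()` is the single
# fitting entry point; the returned object carries print/summary/predict/
# plot/coef methods.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, batch size 512,
#' learning rate 3e-4. The batch size is capped at the training-set size
#' for small runs. Epoch budget and patience are configurable since the
#' stopping rule is not part of the recipe.
#'
#' @param batch_size Minibatch size (default 512).
#' @param learning_rate Adam step size (default 0.0003).
#' @param optimizer Only `"adam"` is available.
#' @param max_epochs Maximum number of epochs (default 50).
#' @param patience Early-stopping patience on validation loss, in epochs
#'   (default 5).
#' @param weight_decay Decoupled weight decay applied to weight matrices at
#'   each Adam step (default 0, i.e. plain Adam).
#' @param seed Integer seed covering initialisation, shuffling and dropout.
#' @return A `train_cfg` object.
#' @export
train_cfg <- function(batch_size = 512L, learning_rate = 3e-4,
                      optimizer = "adam", max_epochs = 50L, patience = 5L,
                      weight_decay = 0, seed = 1L) {
  stopifnot_scalar_num(batch_size, "batch_size", lower = 1)
  stopifnot_scalar_num(learning_rate, "learning_rate", lower = 0)
  optimizer <- match.arg(optimizer, "adam")
  stopifnot_scalar_num(max_epochs, "max_epochs", lower = 1)
  stopifnot_scalar_num(patience, "patience", lower = 1)
  stopifnot_scalar_num(weight_decay, "weight_decay", lower = 0)
  structure(
    list(batch_size = as.integer(batch_size), learning_rate = learning_rate,
         optimizer = optimizer, max_epochs = as.integer(max_epochs),
         patience = as.integer(patience), weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "train_cfg"
  )
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_step <- function(params, grads, opt, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  decay_ok <- weight_decay > 0
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    # decay acts on weight matrices only, not biases/gains
    if (decay_ok && grepl("\\.W", nm)) {
      params[[nm]] <- params[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(params = params, opt = opt)
}

#' Fit a seizure-prediction network
#'
#' Trains one of the four architectures on labelled 1-second segments by
#' minimising mean binary cross-entropy with Adam. An 80/20
#' stratified train/validation split is made internally when no validation
#' set is given. The parameters achieving the best validation loss are
#' restored at the end. The whole fit — initialisation, shuffling, dropout —
#' is a deterministic function of the data, spec and `cfg$seed`.
#'
#' @param train_segments An `eeg_segments` object with both classes
#'   (tensorized when the model uses the instance view).
#' @param spec A [model_spec()].
#' @param cfg A [train_cfg()].
#' @param val_segments Optional `eeg_segments` held-out validation set;
#'   when `NULL`, 20% of `train_segments` is split off, stratified by
#'   class.
#' @return An object of class `mfnet`: the trained `mfnet_model` plus a
#'   per-epoch `history` data.frame (train loss, validation loss and
#'   accuracy) and the fit configuration.
#' @export
#' @examples
#' \donttest{
#' spec <- synth_spec(n_channels = 4, fs = 32, n_seizures = 3,
#'                    interictal_minutes = 1, preictal_minutes = 1, seed = 2)
#' rec <- generate_subject(spec)
#' iv <- label_intervals(rec, preictal_min = 1, postictal_buffer_min = 0.25)
#' segs <- tensorize_segments(segment_recording(rec, iv))
#' ms <- model_spec("multiframe", n_channels = 4, seq_len = 32,
#'                  conv_filters = c(4, 8, 8), lstm_units = 8)
#' fit <- mfnet(segs, ms, train_cfg(batch_size = 64, max_epochs = 3, seed = 1))
#' fit
#' }
mfnet <- function(train_segments, spec, cfg = train_cfg(),
                  val_segments = NULL) {
  stopifnot(inherits(train_segments, "eeg_segments"),
            inherits(spec, "model_spec"), inherits(cfg, "train_cfg"))
  if (spec$seq_len != dim(train_segments$x)[3]) {
    stop("spec$seq_len does not match the segment length", call. = FALSE)
  }

  with_seed(cfg$seed, {
    if (is.null(val_segments)) {
      sp <- .stratified_split(train_segments$label, val_fraction = 0.2)
      val_segments <- train_segments[sp$val]
      train_segments <- train_segments[sp$train]
    }
    y <- train_segments$label
    if (length(unique(y)) < 2L) {
      stop("training set must contain both classes", call. = FALSE)
    }
    n <- length(y)
    bs <- min(cfg$batch_size, n)

    model <- build_model(spec, seed = sample.int(.Machine$integer.max, 1))
    opt <- .adam_init(model$params)

    best <- list(loss = Inf, params = model$params, bn = model$bn_state,
                 epoch = 0L)
    hist <- NULL
    wait <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tr_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        batch <- .model_batch(train_segments, idx, spec)
        fw <- .model_fwd(model$params, model$bn_state, spec, batch,
                         training = TRUE)
        model$bn_state <- fw$state
        sc <- softmax_ce(fw$logits, y[idx])
        tr_loss <- tr_loss + sc$loss
        n_batches <- n_batches + 1L
        grads <- .model_bwd(sc$dlogits, fw$caches, model$params, spec)
        st <- .adam_step(model$params, grads, opt, cfg$learning_rate,
                         weight_decay = cfg$weight_decay %||% 0)
        model$params <- st$params
        opt <- st$opt
      }
      val_p <- predict(model, val_segments)
      val_loss <- cross_entropy(val_segments$label, val_p[, "preictal"])
      val_acc <- mean((val_p[, "preictal"] >= 0.5) == (val_segments$label == 1L))
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = tr_loss / n_batches,
        val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = model$params,
                     bn = model$bn_state, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model$params <- best$params
    model$bn_state <- best$bn
    structure(
      list(model = model, spec = spec, cfg = cfg, history = hist,
           best_epoch = best$epoch, n_train = n,
           n_val = length(val_segments$label)),
      class = "mfnet"
    )
  })
}

# Stratified train/val split: within each class, a seeded permutation with
# round(fraction * n_class) indices going to validation.
.stratified_split <- function(y, val_fraction = 0.2) {
  val <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_val <- round(val_fraction * length(idx))
    val <- c(val, sample(idx)[seq_len(n_val)])
  }
  list(train = sort(setdiff(seq_along(y), val)), val = sort(val))
}

#' @export
print.mfnet <- function(x, ...) {
  cat(sprintf("Fitted mfnet (%s): %d train / %d val segments, best epoch %d\n",
              x$spec$kind, x$n_train, x$n_val, x$best_epoch))
  cat(sprintf("  final val loss %.4f, val acc %.3f\n",
              min(x$history$val_loss), x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.mfnet <- function(object, ...) {
  cat(sprintf("mfnet fit, kind '%s'\n", object$spec$kind))
  print(object$spec)
  cat(sprintf("parameters: %d\n", sum(lengths(object$model$params))))
  cat(sprintf("epochs run: %d (best %d)\n",
              nrow(object$history), object$best_epoch))
  print(utils::tail(object$history, 3), row.names = FALSE)
  invisible(object)
}

#' @export
coef.mfnet <- function(object, ...) object$model$params

#' Predict pre-ictal probabilities from a fitted network
#'
#' @param object An `mfnet` fit.
#' @param newdata An `eeg_segments` object.
#' @param type `"prob"` for the two-column probability matrix, `"score"`
#'   for the pre-ictal probability vector, `"class"` for 0/1 labels at
#'   threshold 0.5 (ties count as pre-ictal).
#' @param ... Ignored.
#' @return See `type`.
#' @export
predict.mfnet <- function(object, newdata, type = c("prob", "score", "class"),
                          ...) {
  type <- match.arg(type)
  p <- predict(object$model, newdata)
  switch(type,
    prob = p,
    score = p[, "preictal"],
    class = as.integer(p[, "preictal"] >= 0.5)
  )
}

#' Plot the training history of a fit
#'
#' @param x An `mfnet` fit.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.mfnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
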