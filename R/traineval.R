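# Evaluation: binary cross-entropy, confusion metrics and AUC,
# leave-one-seizure-out folds, per-subject evaluation and the four-model
# ablation.

#' Binary cross-entropy
#'
#' `-[y log(p) + (1 - y) log(1 - p)]`, averaged over samples, with
#' predictions clipped to `[eps, 1 - eps]` so the loss stays finite.
#'
#' @param y_true 0/1 labels.
#' @param p_hat Predicted probabilities of class 1, same length.
#' @param eps Clipping constant (default 1e-7).
#' @return Mean loss (non-negative scalar).
#' @export
cross_entropy <- function(y_true, p_hat, eps = 1e-7) {
  if (length(y_true) != length(p_hat)) {
    stop("`y_true` and `p_hat` must have the same length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) stop("`y_true` must be 0/1", call. = FALSE)
  p <- pmin(pmax(p_hat, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

#' Empirical ROC AUC by trapezoidal integration
#'
#' Sweeps every distinct score as a threshold, builds the empirical ROC
#' curve (ties grouped), and integrates with the trapezoid rule.
#'
#' @param labels 0/1 labels (1 = positive).
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
roc_auc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # group tied scores
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Confusion metrics and AUC for one evaluation
#'
#' Thresholds the pre-ictal scores (ties at the threshold count as
#' positive), tabulates TP/TN/FP/FN with pre-ictal as the positive class,
#' and derives accuracy, sensitivity (recall), specificity, precision and
#' F1; AUC comes from [roc_auc()]. A metric whose denominator is zero is
#' reported as 0 and the report's `degenerate` flag is set.
#'
#' @param labels 0/1 labels (1 = pre-ictal).
#' @param scores Predicted pre-ictal probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @param fold_id Optional fold identifier carried into the report.
#' @return A `fold_report`: one-row data.frame with counts and metrics.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5, fold_id = NA) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have the same length", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)

  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else {
      num / den
    }
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  f1 <- if (prec + sen == 0) {
    degenerate <- TRUE
    0
  } else {
    2 * prec * sen / (prec + sen)
  }
  auc <- roc_auc(labels, scores)
  if (is.na(auc)) {
    degenerate <- TRUE
    auc <- 0
  }
  if (degenerate) warning("degenerate confusion table: some metrics reported as 0")
  structure(
    data.frame(fold_id = fold_id, TP = tp, TN = tn, FP = fp, FN = fn,
               acc = acc, sen = sen, spe = spe, precision = prec, f1 = f1,
               auc = auc, degenerate = degenerate),
    class = c("fold_report", "data.frame")
  )
}

#' Leave-one-seizure-out folds
#'
#' One fold per pre-ictal block. Fold k's test set is every segment of
#' pre-ictal block k plus the inter-ictal block paired with it; the
#' remaining segments are split 80/20 into train/validation at the segment
#' level, stratified by class. Inter-ictal segments are paired with
#' pre-ictal blocks by partitioning them, in time order, into K
#' equally-sized contiguous runs.
#'
#' @param segs A balanced `eeg_segments` object with at least 3 pre-ictal
#'   blocks.
#' @param val_fraction Validation share of the non-test segments
#'   (default 0.2).
#' @param seed Seed for the stratified split.
#' @return List of folds, each `list(train, val, test)` of segment indices;
#'   the three sets are pairwise disjoint and cover all segments.
#' @export
make_loo_folds <- function(segs, val_fraction = 0.2, seed = 1) {
  stopifnot(inherits(segs, "eeg_segments"))
  pre_blocks <- sort(unique(segs$block_id[segs$label == 1L]))
  K <- length(pre_blocks)
  if (K < 3L) {
    stop(sprintf(paste0(
      "only %d pre-ictal block(s): subjects need at least three seizures ",
      "for leave-one-seizure-out evaluation"), K), call. = FALSE)
  }
  inter_idx <- which(segs$label == 0L)
  inter_idx <- inter_idx[order(segs$t0_s[inter_idx])]
  inter_chunk <- split(inter_idx, cut(seq_along(inter_idx), K, labels = FALSE))

  folds <- vector("list", K)
  for (k in seq_len(K)) {
    test <- sort(c(which(segs$label == 1L & segs$block_id == pre_blocks[k]),
                   inter_chunk[[k]]))
    rest <- setdiff(seq_along(segs$label), test)
    sp <- with_seed(derive_seed(seed, k), {
      .stratified_split(segs$label[rest], val_fraction = val_fraction)
    })
    folds[[k]] <- list(train = rest[sp$train], val = rest[sp$val], test = test)
  }
  folds
}

#' Leave-one-seizure-out evaluation of one architecture
#'
#' Trains a fresh model per fold (seeded per fold from `cfg$seed`),
#' evaluates it on the held-out pre-ictal/inter-ictal blocks, and averages
#' the fold metrics.
#'
#' @param segs A balanced, tensorized `eeg_segments` object.
#' @param spec A [model_spec()].
#' @param cfg A [train_cfg()].
#' @param val_fraction Validation share within each fold's non-test data.
#' @return A `subject_report`: list with `folds` (one [compute_metrics()]
#'   row per fold) and `means` (arithmetic mean of every metric).
#' @export
loo_evaluate <- function(segs, spec, cfg = train_cfg(), val_fraction = 0.2) {
  folds <- make_loo_folds(segs, val_fraction = val_fraction, seed = cfg$seed)
  reports <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, 1000L + k)
    fit <- mfnet(segs[f$train], spec, cfg_k, val_segments = segs[f$val])
    scores <- predict(fit, segs[f$test], type = "score")
    reports[[k]] <- compute_metrics(segs$label[f$test], scores, fold_id = k)
  }
  folds_df <- do.call(rbind, reports)
  metric_cols <- c("acc", "sen", "spe", "precision", "f1", "auc")
  structure(
    list(folds = folds_df, means = colMeans(folds_df[, metric_cols]),
         kind = spec$kind, n_folds = length(folds)),
    class = "subject_report"
  )
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("Leave-one-seizure-out report (%s), %d folds\n", x$kind, x$n_folds))
  print(x$folds[, c("fold_id", "TP", "TN", "FP", "FN", "acc", "sen", "spe",
                    "f1", "auc")], row.names = FALSE, digits = 3)
  cat("means:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Four-model ablation
#'
#' Runs [loo_evaluate()] for each architecture over one or more seeds and
#' tabulates per-model mean and standard deviation of every metric, plus
#' the pairwise AUC deltas of the multi-frame network against each
#' baseline.
#'
#' @param segs A balanced, tensorized `eeg_segments` object.
#' @param spec_template A [model_spec()] whose sizes are shared by all
#'   models; its `kind` is overridden.
#' @param cfg A [train_cfg()]; `cfg$seed` seeds the first replicate.
#' @param kinds Architectures to compare.
#' @param n_seeds Number of replicate seeds (default 1).
#' @return An `ablation_table`: `runs` (one row per model x seed with mean
#'   fold metrics), `summary` (mean and sd per model and metric) and
#'   `auc_delta` (multi-frame AUC minus each baseline's, when present).
#' @export
run_ablation <- function(segs, spec_template, cfg = train_cfg(),
                         kinds = c("cnn", "lstm", "cnn_lstm", "multiframe"),
                         n_seeds = 1L) {
  stopifnot(n_seeds >= 1L)
  runs <- NULL
  for (kind in kinds) {
    spec <- spec_template
    spec$kind <- kind
    for (s in seq_len(n_seeds)) {
      cfg_s <- cfg
      cfg_s$seed <- derive_seed(cfg$seed, 100L * s)
      rep <- loo_evaluate(segs, spec, cfg_s)
      runs <- rbind(runs, cbind(
        data.frame(model = kind, seed = cfg_s$seed),
        as.data.frame(as.list(rep$means))))
    }
  }
  metric_cols <- c("acc", "sen", "spe", "precision", "f1", "auc")
  summ <- do.call(rbind, lapply(split(runs, runs$model), function(d) {
    data.frame(model = d$model[1],
               metric = metric_cols,
               mean = vapply(metric_cols, function(m) mean(d[[m]]), 0),
               sd = vapply(metric_cols, function(m) stats::sd(d[[m]]), 0))
  }))
  rownames(summ) <- NULL
  auc_means <- vapply(split(runs, runs$model), function(d) mean(d$auc), 0)
  auc_delta <- if ("multiframe" %in% names(auc_means)) {
    auc_means[["multiframe"]] - auc_means[setdiff(names(auc_means), "multiframe")]
  } else {
    NULL
  }
  structure(list(runs = runs, summary = summ, auc_delta = auc_delta),
            class = "ablation_table")
}

#' @export
print.ablation_table <- function(x, ...) {
  cat("Ablation over", length(unique(x$runs$seed)), "seed(s):\n")
  wide <- x$summary[x$summary$metric %in% c("acc", "auc"), ]
  print(wide, row.names = FALSE, digits = 3)
  if (!is.null(x$auc_delta)) {
    cat("multi-frame AUC minus baseline:\n")
    print(round(x$auc_delta, 4))
  }
  invisible(x)
}
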