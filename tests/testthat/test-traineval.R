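# Metrics, folds, subject-level evaluation and the ablation table.

test_that("cross_entropy matches direct evaluation and clips", {
  expect_equal(cross_entropy(1, 1), 0, tolerance = 1e-6)
  expect_equal(cross_entropy(0, 0.5), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy(1, 0), -log(1e-7), tolerance = 1e-9)
  set.seed(2)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50, 0.01, 0.99)
  oracle <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(cross_entropy(y, p), oracle, tolerance = 1e-12)
  expect_error(cross_entropy(c(0, 2), c(0.5, 0.5)), "0/1")
})

test_that("compute_metrics reproduces the defining formulas", {
  # worked confusion table: TP=3, FP=1, FN=1, TN=5
  labels <- c(rep(1, 4), rep(0, 6))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.3, 0.2, 0.1, 0.05, 0.3)
  r <- compute_metrics(labels, scores)
  expect_equal(c(r$TP, r$FP, r$FN, r$TN), c(3, 1, 1, 5))
  expect_equal(r$acc, 0.8)
  expect_equal(r$sen, 0.75)
  expect_equal(r$spe, 5 / 6)
  expect_equal(r$precision, 0.75)
  expect_equal(r$f1, 0.75)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(6:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    r <- suppressWarnings(compute_metrics(labels, scores))
    expect_equal(r$TP + r$TN + r$FP + r$FN, n)
    expect_equal(r$acc, (r$TP + r$TN) / n)
    if (r$TP + r$FN > 0) expect_equal(r$sen, r$TP / (r$TP + r$FN))
    if (r$TN + r$FP > 0) expect_equal(r$spe, r$TN / (r$TN + r$FP))
    if (r$precision + r$sen > 0) {
      expect_equal(r$f1, 2 * r$precision * r$sen / (r$precision + r$sen))
    }
    expect_true(all(unlist(r[c("acc", "sen", "spe", "precision", "f1", "auc")]) >= 0))
    expect_true(all(unlist(r[c("acc", "sen", "spe", "precision", "f1", "auc")]) <= 1))
  }
})

test_that("ties at the threshold count as positive", {
  r <- compute_metrics(c(1, 0), c(0.5, 0.5))
  expect_equal(r$TP, 1)
  expect_equal(r$FP, 1)
  expect_equal(r$TN, 0)
})

test_that("AUC: perfect separation, chance, tie handling, rank invariance", {
  labels <- c(rep(0, 50), rep(1, 50))
  scores <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  r <- compute_metrics(labels, scores)
  expect_equal(r$auc, 1)
  expect_equal(r$acc, 1)
  expect_equal(r$sen, 1)
  expect_equal(r$spe, 1)

  set.seed(12)
  y <- rbinom(4000, 1, 0.5)
  s <- runif(4000)
  expect_lt(abs(roc_auc(y, s) - 0.5), 0.05)
  # invariant under strictly increasing transforms
  expect_equal(roc_auc(y, s), roc_auc(y, qlogis(s)))
  # tied scores handled by the grouped ROC
  expect_equal(roc_auc(c(0, 1), c(0.3, 0.3)), 0.5)
})

test_that("trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:20) {
    y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(60), 2)  # force ties
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(y, s, quiet = TRUE, levels = c(0, 1), direction = "<"))))
    expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are flagged, empty input errors", {
  expect_warning(r <- compute_metrics(c(1, 1), c(0.9, 0.8)), "degenerate")
  expect_equal(r$spe, 0)
  expect_true(r$degenerate)
  expect_error(compute_metrics(numeric(), numeric()), "empty")
})

test_that("leave-one-seizure-out folds cover each pre-ictal block once, no leakage", {
  set.seed(20)
  # 4 pre-ictal blocks of 30 segments; 120 balanced inter-ictal in 1 block id
  # sequence ordered by time
  n <- 240
  x <- array(rnorm(n * 2 * 8), c(n, 2, 8))
  label <- c(rep(1, 120), rep(0, 120))
  block <- c(rep(1:4, each = 30), rep(1:6, each = 20))
  segs <- toy_segments(x, label, block)
  folds <- make_loo_folds(segs, seed = 3)
  expect_length(folds, 4)
  tested_pre <- sort(unique(unlist(lapply(folds, function(f) {
    unique(segs$block_id[f$test][segs$label[f$test] == 1])
  }))))
  expect_equal(tested_pre, 1:4)
  for (f in folds) {
    expect_length(intersect(f$test, c(f$train, f$val)), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val, f$test), seq_len(n))
    # validation share of the non-test data: 0.20 within one segment's worth
    frac <- length(f$val) / (length(f$val) + length(f$train))
    expect_lt(abs(frac - 0.2), 1 / (length(f$val) + length(f$train)) + 1e-9)
    # each fold tests exactly one pre-ictal block
    expect_length(unique(segs$block_id[f$test][segs$label[f$test] == 1]), 1)
  }
  # pre-ictal segments of the tested block never leak into training
  for (k in seq_along(folds)) {
    blk <- unique(segs$block_id[folds[[k]]$test][segs$label[folds[[k]]$test] == 1])
    train_blocks <- segs$block_id[folds[[k]]$train][segs$label[folds[[k]]$train] == 1]
    expect_false(blk %in% train_blocks)
  }
})

test_that("fewer than three pre-ictal blocks is an eligibility error", {
  x <- array(rnorm(40 * 2 * 8), c(40, 2, 8))
  segs <- toy_segments(x, label = rep(0:1, 20), block_id = rep(1:2, 20))
  expect_error(make_loo_folds(segs), "three seizures")
})

test_that("loo_evaluate aggregates fold metrics arithmetically", {
  segs <- blob_segments(n_per_class = 45, n_blocks = 3, seed = 21)
  spec <- model_spec("multiframe", n_channels = 4, seq_len = 16,
                     conv_filters = c(2, 3, 4), lstm_units = 8,
                     fc_sizes = c(8, 4, 2))
  cfg <- train_cfg(batch_size = 16, max_epochs = 8, patience = 8,
                   learning_rate = 3e-3, seed = 22)
  rep <- loo_evaluate(segs, spec, cfg)
  expect_s3_class(rep, "subject_report")
  expect_equal(rep$n_folds, 3)
  for (m in c("acc", "sen", "spe", "precision", "f1", "auc")) {
    expect_equal(unname(rep$means[m]), mean(rep$folds[[m]]))
  }
  # blobs are separable: the evaluation should be near-perfect
  expect_gt(rep$means["auc"], 0.95)
  expect_output(print(rep), "Leave-one-seizure-out")
})

test_that("loo_evaluate is reproducible from its seed", {
  segs <- blob_segments(n_per_class = 30, n_blocks = 3, seed = 23)
  spec <- model_spec("lstm", n_channels = 4, seq_len = 16, lstm_units = 4,
                     fc_sizes = c(8, 4, 2))
  cfg <- train_cfg(batch_size = 16, max_epochs = 2, patience = 2, seed = 24)
  r1 <- suppressWarnings(loo_evaluate(segs, spec, cfg))
  r2 <- suppressWarnings(loo_evaluate(segs, spec, cfg))
  expect_identical(r1$folds, r2$folds)
})

test_that("run_ablation tabulates every model and the AUC deltas", {
  segs <- blob_segments(n_per_class = 45, n_blocks = 3, seed = 25)
  spec <- model_spec("multiframe", n_channels = 4, seq_len = 16,
                     conv_filters = c(2, 3, 4), lstm_units = 4,
                     fc_sizes = c(8, 4, 2))
  cfg <- train_cfg(batch_size = 16, max_epochs = 3, patience = 3,
                   learning_rate = 3e-3, seed = 26)
  ab <- suppressWarnings(run_ablation(segs, spec, cfg, kinds = c("cnn", "multiframe"),
                     n_seeds = 2))
  expect_equal(nrow(ab$runs), 4)
  expect_setequal(unique(ab$runs$model), c("cnn", "multiframe"))
  expect_equal(nrow(ab$summary), 12)  # 2 models x 6 metrics
  expect_named(ab$auc_delta, "cnn")
  agg <- aggregate(auc ~ model, ab$runs, mean)
  expect_equal(unname(ab$auc_delta["cnn"]),
               agg$auc[agg$model == "multiframe"] - agg$auc[agg$model == "cnn"])
})
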