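small_data <- function(n = 48, seed = 17, mutation = 0) {
  generate_motif_dataset(synth_config(n_records = n, length = 40,
                                      mutation_prob = mutation, seed = seed))
}

fast_fit_cfg <- function(epochs = 3, seed = 1) {
  finetune_config(batch_size = 16, max_epochs = epochs, seed = seed)
}

small_enc_cfg <- encoder_config(kernel_size = 8, num_kernels = 12)
small_cls_cfg <- classifier_config(hidden_units = 6)

test_that("confusion metrics reproduce the crafted table", {
  # TP=3, FP=1, FN=1, TN=5
  labels <- c(rep(1L, 4), rep(0L, 6))
  y_pred <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.2)
  cc <- confusion_counts(labels, y_pred)
  expect_equal(unlist(cc), c(TP = 3L, FP = 1L, FN = 1L, TN = 5L))
  m <- metrics_from_confusion(cc)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
})

test_that("degenerate confusion tables warn and report 0", {
  cc <- confusion_counts(c(1L, 0L), c(0.1, 0.2))
  expect_warning(m <- metrics_from_confusion(cc), "Precision")
  expect_equal(m$precision, 0)
})

test_that("F1 equals the harmonic mean form whenever both are defined", {
  set.seed(60)
  for (rep in 1:50) {
    labels <- sample(0:1, 40, replace = TRUE)
    y_pred <- runif(40)
    cc <- confusion_counts(labels, y_pred)
    if (cc$TP == 0) next
    m <- metrics_from_confusion(cc)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-12)
  }
})

test_that("AUC equals the Mann-Whitney statistic and external pROC", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    labels <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # force ties sometimes
    expect_equal(auc_score(labels, scores), auc_rank_oracle(labels, scores),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(62)
  labels <- sample(0:1, 100, replace = TRUE)
  scores <- runif(100)
  expect_equal(auc_score(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and single-class inputs warn NA", {
  expect_equal(auc_score(c(0L, 0L, 1L, 1L), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_warning(a <- auc_score(rep(1L, 5), runif(5)), "single-class")
  expect_true(is.na(a))
})

test_that("pretrain runs per-mode, logs finite non-negative losses", {
  d <- small_data()
  for (mode in c("editclr", "supclr", "simclr")) {
    pt <- pretrain(d, mode = mode,
                   cfg = pretrain_config(batch_size = 12, max_epochs = 2,
                                         seed = 3),
                   encoder_cfg = small_enc_cfg)
    expect_s3_class(pt, "clr_pretrain")
    expect_equal(max(pt$log$epoch), 2L)
    expect_true(all(is.finite(pt$log$loss)))
    expect_true(all(pt$log$loss >= 0))
    expect_equal(dim(pt$encoder$W), c(4L * 8L, 12L))
  }
})

test_that("pretraining is bit-identical under a fixed seed", {
  d <- small_data()
  cfg <- pretrain_config(batch_size = 12, max_epochs = 2, seed = 5)
  p1 <- pretrain(d, "supclr", cfg = cfg, encoder_cfg = small_enc_cfg)
  p2 <- pretrain(d, "supclr", cfg = cfg, encoder_cfg = small_enc_cfg)
  expect_identical(p1$encoder$W, p2$encoder$W)
  expect_identical(p1$log, p2$log)
})

test_that("supclr pre-training requires labels", {
  d <- small_data()[, c("id", "sequence")]
  expect_error(pretrain(d, "supclr",
                        cfg = pretrain_config(batch_size = 12, seed = 1),
                        encoder_cfg = small_enc_cfg), "label")
  # self-supervised modes run fine without labels
  pt <- pretrain(d, "simclr",
                 cfg = pretrain_config(batch_size = 12, max_epochs = 1,
                                       seed = 1),
                 encoder_cfg = small_enc_cfg)
  expect_s3_class(pt, "clr_pretrain")
})

test_that("finetune selects the best validation epoch, not the last", {
  d <- small_data(n = 64)
  m <- finetune(new_encoder(small_enc_cfg), d, cfg = fast_fit_cfg(epochs = 5),
                classifier_cfg = small_cls_cfg)
  expect_s3_class(m, "clr_model")
  expect_equal(nrow(m$history), 5L)
  expect_equal(m$best_epoch,
               which.max(m$history$validation_accuracy))
  expect_equal(m$validation_accuracy,
               max(m$history$validation_accuracy))
})

test_that("fine-tuning is deterministic and accepts clr_pretrain input", {
  d <- small_data(n = 40)
  pt <- pretrain(d, "supclr",
                 cfg = pretrain_config(batch_size = 10, max_epochs = 1,
                                       seed = 2),
                 encoder_cfg = small_enc_cfg)
  m1 <- finetune(pt, d, cfg = fast_fit_cfg(), classifier_cfg = small_cls_cfg)
  m2 <- finetune(pt, d, cfg = fast_fit_cfg(), classifier_cfg = small_cls_cfg)
  expect_identical(m1$encoder$W, m2$encoder$W)
  expect_identical(m1$classifier$W1, m2$classifier$W1)
  expect_identical(m1$history, m2$history)
})

test_that("transfer: an encoder pre-trained on one dataset fine-tunes on another", {
  dA <- small_data(seed = 100)
  dB <- small_data(seed = 200)
  pt <- pretrain(dA, "editclr",
                 cfg = pretrain_config(batch_size = 12, max_epochs = 1,
                                       seed = 2),
                 encoder_cfg = small_enc_cfg)
  m <- finetune(pt, dB, cfg = fast_fit_cfg(), classifier_cfg = small_cls_cfg)
  expect_s3_class(m, "clr_model")
})

test_that("the baseline shares the contrastive models' architecture", {
  d <- small_data(n = 40)
  base <- train_baseline(d, cfg = fast_fit_cfg(epochs = 2),
                         encoder_cfg = small_enc_cfg,
                         classifier_cfg = small_cls_cfg)
  pt <- pretrain(d, "supclr",
                 cfg = pretrain_config(batch_size = 10, max_epochs = 1,
                                       seed = 2),
                 encoder_cfg = small_enc_cfg)
  ft <- finetune(pt, d, cfg = fast_fit_cfg(epochs = 2),
                 classifier_cfg = small_cls_cfg)
  expect_identical(base$architecture, ft$architecture)
})

test_that("evaluate produces coherent metrics and prediction tables", {
  d <- small_data(n = 60)
  te <- small_data(n = 30, seed = 18)
  m <- train_baseline(d, cfg = fast_fit_cfg(epochs = 2),
                      encoder_cfg = small_enc_cfg,
                      classifier_cfg = small_cls_cfg)
  # the barely-trained model may predict a single class; that pathway warns
  ev <- suppressWarnings(evaluate(m, te))
  expect_s3_class(ev, "clr_metrics")
  expect_equal(sum(unlist(ev$confusion)), nrow(te))
  expect_true(all(unlist(ev$metrics) >= 0 & unlist(ev$metrics) <= 1))
  expect_equal(nrow(ev$predictions), nrow(te))
  expect_true(all(ev$predictions$y_pred >= 0 & ev$predictions$y_pred <= 1))
})

test_that("grid search enumerates every combination and picks the best", {
  d <- small_data(n = 40)
  g <- grid_search(
    d, mode = "supclr",
    dropout_grid = c(0.1, 0.5), temperature_grid = 0.1,
    lr_scale_grid = 0.001, weight_decay_grid = c(1e-4, 1e-3),
    pre_cfg = pretrain_config(batch_size = 10, max_epochs = 1, seed = 2),
    fit_cfg = fast_fit_cfg(epochs = 2),
    encoder_cfg = small_enc_cfg
  )
  expect_equal(nrow(g$report), 4L)
  expect_equal(g$best$validation_accuracy, max(g$report$validation_accuracy))
  expect_s3_class(g$best_model, "clr_model")
  expect_error(grid_search(d, "supclr", dropout_grid = numeric(0)),
               "non-empty")
})

test_that("default grids multiply to the documented cardinality", {
  f <- formals(grid_search)
  expect_equal(length(eval(f$dropout_grid)) * length(eval(f$temperature_grid)) *
                 length(eval(f$lr_scale_grid)) *
                 length(eval(f$weight_decay_grid)), 3 * 3 * 6 * 4)
  expect_equal(eval(f$temperature_grid), c(1.0, 0.1, 0.01))
})

test_that("shrinking the training set degrades validation accuracy on average", {
  accs <- sapply(c(1.0, 0.15), function(frac) {
    mean(sapply(c(301, 302), function(seed) {
      d <- generate_motif_dataset(synth_config(n_records = round(800 * frac),
                                               mutation_prob = 0, seed = seed))
      m <- train_baseline(d, cfg = finetune_config(max_epochs = 6, seed = 1))
      m$validation_accuracy
    }))
  })
  expect_gte(accs[1], accs[2] - 0.05)
})

test_that("model and metric objects expose tidy/glance/autoplot", {
  d <- small_data(n = 40)
  te <- small_data(n = 24, seed = 19)
  pt <- pretrain(d, "supclr",
                 cfg = pretrain_config(batch_size = 10, max_epochs = 1,
                                       seed = 2),
                 encoder_cfg = small_enc_cfg)
  expect_s3_class(tidy(pt), "tbl_df")
  expect_equal(glance(pt)$mode, "supclr")
  expect_s3_class(autoplot(pt), "ggplot")
  m <- finetune(pt, d, cfg = fast_fit_cfg(epochs = 2),
                classifier_cfg = small_cls_cfg)
  expect_s3_class(tidy(m), "tbl_df")
  expect_s3_class(autoplot(m), "ggplot")
  ev <- evaluate(m, te)
  expect_equal(nrow(tidy(ev)), 5L)
  expect_s3_class(autoplot(ev), "ggplot")
})
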