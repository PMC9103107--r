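#' Pre-training configuration
#'
#' Contrastive pre-training settings. The learning rate follows the
#' square-root batch scaling `alpha * sqrt(n)` (SimCLR-style), with
#' `alpha` searchable logarithmically over `{0.001, ..., 0.5}`; an
#' explicit `learning_rate` overrides the formula.
#'
#' @param batch_size Mini-batch size `n`; default 1024 (reduce for
#'   CPU-scale runs).
#' @param max_epochs Pre-training epoch cap; default 5.
#' @param lr_scale `alpha` in the `alpha * sqrt(n)` learning-rate rule;
#'   default 0.001.
#' @param learning_rate Optional explicit learning rate overriding the
#'   scaling rule.
#' @param weight_decay Adam L2 weight decay; default `1e-4` (searchable
#'   over `[1e-5, 1e-2]`).
#' @param seed Integer seed for shuffling, augmentation and
#'   initialization.
#' @return A list of class `pretrain_config`.
#' @export
pretrain_config <- function(batch_size = 1024L, max_epochs = 5L,
                            lr_scale = 0.001, learning_rate = NULL,
                            weight_decay = 1e-4, seed = 1L) {
  stopifnot(batch_size >= 2, max_epochs >= 1, lr_scale > 0, weight_decay >= 0)
  lr <- if (is.null(learning_rate)) lr_scale * sqrt(batch_size) else learning_rate
  if (lr <= 0) abort("`learning_rate` must be positive.")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_scale = lr_scale, learning_rate = lr,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Fine-tuning configuration
#'
#' @param batch_size Default 128.
#' @param max_epochs Default 20; the returned model is the epoch with the
#'   highest validation accuracy, not the last.
#' @param learning_rate,weight_decay Adam settings; both default 0.001.
#' @param validation_fraction Hold-out fraction for model selection;
#'   default 1/8.
#' @param seed Integer seed.
#' @return A list of class `finetune_config`.
#' @export
finetune_config <- function(batch_size = 128L, max_epochs = 20L,
                            learning_rate = 0.001, weight_decay = 0.001,
                            validation_fraction = 1 / 8, seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, learning_rate > 0,
            weight_decay >= 0, validation_fraction > 0,
            validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)), class = "finetune_config")
}

#' Contrastively pre-train a sequence encoder
#'
#' Per epoch: shuffles the data, forms mini-batches of `n` records,
#' augments each batch into `2n` views, builds the mode's pair-label
#' matrix, encodes the views, computes the contrastive loss and steps
#' Adam. Runs at most `max_epochs` epochs and returns the final-epoch
#' encoder plus a per-step training log. Trailing batches with fewer than
#' 2 records are dropped (no contrastive pairs exist).
#'
#' @param train_data A labeled dataset tibble (labels are only required
#'   in `"supclr"` mode, but length consistency is always enforced).
#' @param mode `"editclr"`, `"supclr"` or `"simclr"`.
#' @param cfg A [pretrain_config()].
#' @param ccfg A [contrastive_config()]; its `mode` is overridden by
#'   `mode`.
#' @param encoder_cfg An [encoder_config()].
#' @param aug_cfg An [augment_config()].
#' @return An object of class `clr_pretrain`: list with `encoder`,
#'   `mode`, `log` (tibble of per-step losses), and the configs.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
pretrain <- function(train_data, mode = c("editclr", "supclr", "simclr"),
                     cfg = pretrain_config(), ccfg = contrastive_config(),
                     encoder_cfg = encoder_config(),
                     aug_cfg = augment_config()) {
  mode <- match.arg(mode)
  labeled <- mode == "supclr"
  d <- check_dataset(train_data, labeled = labeled)
  if (!"label" %in% names(d)) d$label <- 0L
  if (anyNA(d$label)) {
    if (labeled) abort("supclr pre-training requires labels.")
    d$label[is.na(d$label)] <- 0L
  }
  ccfg$mode <- mode
  enc_cfg <- encoder_cfg
  enc_cfg$seed <- cfg$seed
  encoder <- new_encoder(enc_cfg)
  params <- list(W = encoder$W, b = encoder$b)
  opt <- adam_init(params, lr = cfg$learning_rate,
                   weight_decay = cfg$weight_decay)
  log <- list()
  step <- 0L
  withr_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(d))
      starts <- seq(1L, nrow(d), by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, nrow(d))]
        if (length(idx) < 2L) next
        batch <- d[idx, , drop = FALSE]
        views <- make_batch_views(batch, config = aug_cfg)
        M <- if (mode == "supclr") NULL else build_pair_labels(views, ccfg)
        encoder$W <- params$W; encoder$b <- params$b
        fwd <- encoder_forward(encoder, encode_batch(views$sequence),
                               want_cache = TRUE)
        lg <- if (mode == "supclr") {
          sup_loss_grad(fwd$Z, views$origin_label, ccfg$temperature)
        } else {
          self_loss_grad(fwd$Z, M, ccfg$temperature)
        }
        grads <- encoder_backward(encoder, fwd, lg$grad)
        upd <- adam_step(opt, params, grads)
        opt <- upd$state; params <- upd$params
        step <- step + 1L
        log[[step]] <- tibble(epoch = epoch, step = step,
                              batch_n = length(idx), loss = lg$loss)
      }
    }
  })
  encoder$W <- params$W; encoder$b <- params$b
  log <- dplyr::bind_rows(log)
  structure(list(encoder = encoder, mode = mode, log = log,
                 pretrain_config = cfg, contrastive_config = ccfg,
                 augment_config = aug_cfg), class = "clr_pretrain")
}

# One pass of supervised training shared by finetune() and
# train_baseline(). Selection is by validation accuracy (first epoch
# attaining the maximum wins); test data never enters selection.
supervised_train <- function(encoder, train_data, cfg, classifier_cfg) {
  d <- check_dataset(train_data)
  L <- nchar(d$sequence[1])
  if (L < encoder$config$kernel_size) {
    abort("Encoder kernel size exceeds the data's sequence length.")
  }
  sp <- split_train_validation(d, fraction = cfg$validation_fraction,
                               seed = cfg$seed)
  tr <- sp$train; val <- sp$validation
  cls_cfg <- classifier_cfg
  cls_cfg$seed <- cfg$seed
  classifier <- new_classifier(cls_cfg, input_dim = encoder$config$num_kernels)
  params <- list(W = encoder$W, b = encoder$b,
                 W1 = classifier$W1, b1 = classifier$b1,
                 W2 = classifier$W2, b2 = classifier$b2)
  opt <- adam_init(params, lr = cfg$learning_rate,
                   weight_decay = cfg$weight_decay)
  X_val <- encode_batch(val$sequence)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- list()
  step <- 0L
  withr_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(tr))
      starts <- seq(1L, nrow(tr), by = cfg$batch_size)
      epoch_losses <- numeric(0)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, nrow(tr))]
        batch <- tr[idx, , drop = FALSE]
        encoder$W <- params$W; encoder$b <- params$b
        classifier$W1 <- params$W1; classifier$b1 <- params$b1
        classifier$W2 <- params$W2; classifier$b2 <- params$b2
        efwd <- encoder_forward(encoder, encode_batch(batch$sequence),
                                want_cache = TRUE)
        cfwd <- classifier_forward(classifier, efwd$Z, training = TRUE,
                                   want_cache = TRUE)
        eps_p <- 1e-12
        loss <- -mean(log(cfwd$probs[cbind(seq_len(nrow(batch)),
                                           batch$label + 1L)] + eps_p))
        cgrad <- classifier_backward(classifier, cfwd, batch$label)
        egrad <- encoder_backward(encoder, efwd, cgrad$dZ)
        grads <- list(W = egrad$W, b = egrad$b,
                      W1 = cgrad$W1, b1 = cgrad$b1,
                      W2 = cgrad$W2, b2 = cgrad$b2)
        upd <- adam_step(opt, params, grads)
        opt <- upd$state; params <- upd$params
        step <- step + 1L
        epoch_losses <- c(epoch_losses, loss)
      }
      encoder$W <- params$W; encoder$b <- params$b
      classifier$W1 <- params$W1; classifier$b1 <- params$b1
      classifier$W2 <- params$W2; classifier$b2 <- params$b2
      val_probs <- classifier_forward(
        classifier, encoder_forward(encoder, X_val)$Z)$probs
      val_acc <- mean(as.integer(val_probs[, 2] > 0.5) == val$label)
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = mean(epoch_losses),
                                 validation_accuracy = val_acc)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = params, epoch = epoch)
      }
    }
  })
  encoder$W <- best$params$W; encoder$b <- best$params$b
  classifier$W1 <- best$params$W1; classifier$b1 <- best$params$b1
  classifier$W2 <- best$params$W2; classifier$b2 <- best$params$b2
  structure(list(encoder = encoder, classifier = classifier,
                 best_epoch = best$epoch,
                 validation_accuracy = best$acc,
                 history = dplyr::bind_rows(history),
                 finetune_config = cfg,
                 architecture = architecture_hash(encoder, classifier)),
            class = "clr_model")
}

#' Fine-tune a pre-trained encoder with a classifier head
#'
#' Splits off a validation fraction (default 1/8), jointly trains the
#' encoder and the DNN classifier with 2-class cross-entropy and Adam,
#' evaluates validation accuracy after every epoch, and returns the
#' weights of the best epoch. The encoder may have been pre-trained on a
#' different dataset of the same sequence length (transfer learning).
#'
#' @param encoder A `clr_encoder` or a `clr_pretrain` result.
#' @param train_data A labeled dataset tibble.
#' @param cfg A [finetune_config()].
#' @param classifier_cfg A [classifier_config()].
#' @return An object of class `clr_model` with elements `encoder`,
#'   `classifier`, `best_epoch`, `validation_accuracy`, `history`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
finetune <- function(encoder, train_data, cfg = finetune_config(),
                     classifier_cfg = classifier_config()) {
  if (inherits(encoder, "clr_pretrain")) encoder <- encoder$encoder
  if (!inherits(encoder, "clr_encoder")) {
    abort("`encoder` must be a clr_encoder or clr_pretrain object.")
  }
  supervised_train(encoder, train_data, cfg, classifier_cfg)
}

#' Train the end-to-end CNN baseline
#'
#' Identical to [finetune()] but starting from a freshly initialized
#' encoder: the direct-training comparator sharing every architectural
#' hyper-parameter with the contrastive pipelines.
#'
#' @inheritParams finetune
#' @param encoder_cfg An [encoder_config()].
#' @return A `clr_model`.
#' @export
train_baseline <- function(train_data, cfg = finetune_config(),
                           encoder_cfg = encoder_config(),
                           classifier_cfg = classifier_config()) {
  enc_cfg <- encoder_cfg
  enc_cfg$seed <- cfg$seed
  supervised_train(new_encoder(enc_cfg), train_data, cfg, classifier_cfg)
}

#' Evaluate a fitted model on labeled test data
#'
#' Computes the predicted binding probability `y_pred` (second softmax
#' digit) per record, thresholds at 0.5 for the confusion counts, and
#' reports accuracy, precision, recall, F1 and ROC-AUC.
#'
#' @param model A `clr_model`.
#' @param test_data A labeled dataset tibble.
#' @return An object of class `clr_metrics`: list with `metrics` (one-row
#'   tibble), `confusion`, `predictions` and `roc` tibbles. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
evaluate <- function(model, test_data) {
  d <- check_dataset(test_data)
  Z <- encode(model$encoder, d$sequence)
  y_pred <- classify(model$classifier, Z)[, 2]
  cc <- confusion_counts(d$label, y_pred)
  mets <- metrics_from_confusion(cc)
  single_class <- length(unique(d$label)) < 2L
  mets$auc <- auc_score(d$label, y_pred)
  structure(list(
    metrics = mets, confusion = cc,
    predictions = tibble(id = d$id, label = d$label, y_pred = y_pred),
    roc = if (single_class) NULL else roc_points(d$label, y_pred)
  ), class = "clr_metrics")
}

#' Exhaustive hyper-parameter grid search
#'
#' Enumerates every combination of the supplied grids (defaults: dropout
#' `{0.1, 0.25, 0.5}`, temperature `{1.0, 0.1, 0.01}`, learning-rate
#' scale `{0.001, 0.005, 0.01, 0.05, 0.1, 0.5}`, pre-training weight
#' decay `{1e-5, 1e-4, 1e-3, 1e-2}`), runs the mode's
#' pre-train + fine-tune pipeline (or the baseline, which ignores the
#' contrastive grids) for each, and selects by validation accuracy. The
#' report lists every combination and its score.
#'
#' @param train_data A labeled dataset tibble.
#' @param mode One of `"editclr"`, `"supclr"`, `"simclr"`, `"baseline"`.
#' @param dropout_grid,temperature_grid,lr_scale_grid,weight_decay_grid
#'   Numeric grids; set to a single value to freeze an axis.
#' @param pre_cfg,fit_cfg,encoder_cfg Base configurations whose
#'   non-gridded fields are held fixed.
#' @return A list of class `clr_grid`: `report` (one row per
#'   combination, with `validation_accuracy`), `best` (one-row tibble)
#'   and `best_model`.
#' @export
grid_search <- function(train_data, mode = c("editclr", "supclr", "simclr",
                                             "baseline"),
                        dropout_grid = c(0.1, 0.25, 0.5),
                        temperature_grid = c(1.0, 0.1, 0.01),
                        lr_scale_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.5),
                        weight_decay_grid = c(1e-5, 1e-4, 1e-3, 1e-2),
                        pre_cfg = pretrain_config(),
                        fit_cfg = finetune_config(),
                        encoder_cfg = encoder_config()) {
  mode <- match.arg(mode)
  if (any(lengths(list(dropout_grid, temperature_grid, lr_scale_grid,
                       weight_decay_grid)) == 0L)) {
    abort("Grids must be non-empty.")
  }
  if (mode == "baseline") {
    grid <- tidyr::expand_grid(dropout = dropout_grid)
  } else {
    grid <- tidyr::expand_grid(dropout = dropout_grid,
                               temperature = temperature_grid,
                               lr_scale = lr_scale_grid,
                               weight_decay = weight_decay_grid)
  }
  results <- purrr::pmap(grid, function(dropout, temperature = NULL,
                                        lr_scale = NULL, weight_decay = NULL) {
    cls_cfg <- classifier_config(dropout_rate = dropout, seed = fit_cfg$seed)
    if (mode == "baseline") {
      model <- train_baseline(train_data, cfg = fit_cfg,
                              encoder_cfg = encoder_cfg,
                              classifier_cfg = cls_cfg)
    } else {
      pc <- pre_cfg
      pc$lr_scale <- lr_scale
      pc$learning_rate <- lr_scale * sqrt(pc$batch_size)
      pc$weight_decay <- weight_decay
      pt <- pretrain(train_data, mode = mode, cfg = pc,
                     ccfg = contrastive_config(mode = mode,
                                               temperature = temperature),
                     encoder_cfg = encoder_cfg)
      model <- finetune(pt, train_data, cfg = fit_cfg,
                        classifier_cfg = cls_cfg)
    }
    list(acc = model$validation_accuracy, model = model)
  })
  grid$validation_accuracy <- purrr::map_dbl(results, "acc")
  best_i <- which.max(grid$validation_accuracy)
  structure(list(report = grid, best = grid[best_i, , drop = FALSE],
                 best_model = results[[best_i]]$model, mode = mode),
            class = "clr_grid")
}
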