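#' @export
print.clr_pretrain <- function(x, ...) {
  cat(sprintf("Contrastively pre-trained encoder (%s)\n", x$mode))
  cat(sprintf("  kernels: %d x %d, steps: %d, final loss: %.4f\n",
              x$encoder$config$num_kernels, x$encoder$config$kernel_size,
              nrow(x$log), utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' @rdname pretrain
#' @param x,object A `clr_pretrain` object.
#' @param ... Unused.
#' @export
tidy.clr_pretrain <- function(x, ...) x$log

#' @rdname pretrain
#' @export
glance.clr_pretrain <- function(x, ...) {
  tibble(mode = x$mode, steps = nrow(x$log),
         epochs = max(x$log$epoch),
         final_loss = utils::tail(x$log$loss, 1),
         mean_loss_last_epoch = mean(x$log$loss[x$log$epoch == max(x$log$epoch)]))
}

#' @rdname pretrain
#' @export
autoplot.clr_pretrain <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "pre-training step", y = "contrastive loss",
                  title = sprintf("%s pre-training", object$mode)) +
    ggplot2::theme_minimal()
}

#' @export
print.clr_model <- function(x, ...) {
  cat("Fine-tuned motif occupancy model\n")
  cat(sprintf("  architecture: %s, best epoch: %d, validation accuracy: %.4f\n",
              x$architecture, x$best_epoch, x$validation_accuracy))
  invisible(x)
}

#' @rdname finetune
#' @param x,object A `clr_model` object.
#' @param ... Unused.
#' @export
tidy.clr_model <- function(x, ...) x$history

#' @rdname finetune
#' @export
glance.clr_model <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         validation_accuracy = x$validation_accuracy,
         architecture = x$architecture)
}

#' @rdname finetune
#' @export
autoplot.clr_model <- function(object, ...) {
  if (is.null(object$history)) abort("This model carries no training history.")
  long <- tidyr::pivot_longer(object$history, -"epoch")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "fine-tuning epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.clr_metrics <- function(x, ...) {
  cat("Test-set evaluation\n")
  print(x$metrics)
  print(x$confusion)
  invisible(x)
}

#' @rdname evaluate
#' @param x,object A `clr_metrics` object.
#' @param ... Unused.
#' @export
tidy.clr_metrics <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname evaluate
#' @export
glance.clr_metrics <- function(x, ...) dplyr::bind_cols(x$metrics, x$confusion)

#' @rdname evaluate
#' @export
autoplot.clr_metrics <- function(object, ...) {
  if (is.null(object$roc)) abort("No ROC curve for a single-class test set.")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @export
print.clr_grid <- function(x, ...) {
  cat(sprintf("Grid search (%s): %d combinations\n", x$mode, nrow(x$report)))
  print(x$best)
  invisible(x)
}

#' @rdname grid_search
#' @param x A `clr_grid` object.
#' @param ... Unused.
#' @export
tidy.clr_grid <- function(x, ...) x$report

#' @rdname grid_search
#' @export
glance.clr_grid <- function(x, ...) x$best
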