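#' Plot group-mean risk trajectories
#'
#' Mean predicted risk per day offset for the discharge success and failure
#' groups with 95% bands; optionally a dashed horizontal line at an
#' operating threshold (see [optimal_threshold()]).
#'
#' @param object A `trajectory_summary`.
#' @param threshold Optional numeric threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory_summary
#' @export
autoplot.trajectory_summary <- function(object, threshold = NULL, ...) {
  anchor <- if (attr(object, "align") == "discharge") "days before discharge"
            else "days since admission"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean,
                                            colour = .data$group,
                                            fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = anchor, y = "mean predicted risk",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a training loss log
#'
#' @param object A `grud_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch with the selected
#'   epoch marked.
#' @method autoplot grud_fit
#' @export
autoplot.grud_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fine-tuning learning curve
#'
#' @param object A `finetune_curve`.
#' @param ... Unused.
#' @return A ggplot of test AUROC/AUPR against the training fraction.
#' @method autoplot finetune_curve
#' @export
autoplot.finetune_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("auroc", "aupr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction of new-site data", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Beeswarm-style Shapley importance plot
#'
#' Per-stay Shapley values per channel, ordered by global importance,
#' coloured by the percentile of the stay's own channel level (red high,
#' blue low in the conventional rendering).
#'
#' @param result An `attribution_result`.
#' @param tensors The attributed `stay_tensors` (for channel levels).
#' @param top_n Show only the `top_n` most important players.
#' @return A ggplot.
#' @export
plot_importance <- function(result, tensors = NULL, top_n = 20) {
  summ <- importance_summary(result, tensors)
  keep <- utils::head(summ$ranking$player, top_n)
  dat <- summ$export[summ$export$player %in% keep, ]
  dat$player <- factor(dat$player, levels = rev(keep))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value, y = .data$player,
                                    colour = .data$feature_percentile)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1, alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "#3b6fb6", high = "#d7342a",
                                   na.value = "grey60",
                                   name = "feature level") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Shapley value (log-odds)", y = NULL) +
    ggplot2::theme_minimal()
}
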