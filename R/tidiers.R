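#' Tidy per-fold metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble with one row per fold.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(model = attr(x, "model"), mode = attr(x, "mode"),
                  .before = 1)
}

#' One-row summary of an evaluation report (mean +/- sd across folds)
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble: model, mode, folds, AUROC and AUPR mean/sd.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"), mode = attr(x, "mode"), folds = nrow(x),
    auroc_mean = mean(x$auroc), auroc_sd = stats::sd(x$auroc),
    aupr_mean = mean(x$aupr), aupr_sd = stats::sd(x$aupr)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  g <- glance.eval_report(x)
  cat(sprintf("<eval_report> %s [%s], %d fold(s)\n", g$model, g$mode, g$folds))
  cat(sprintf("  AUROC %.3f (+/- %.3f)   AUPR %.3f (+/- %.3f)\n",
              g$auroc_mean, g$auroc_sd %||% NA, g$aupr_mean, g$aupr_sd %||% NA))
  invisible(x)
}

#' Tidy a paired DeLong comparison
#'
#' @param x A `delong_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy delong_test
#' @export
tidy.delong_test <- function(x, ...) {
  tibble::tibble(auroc_a = x$auroc_a, auroc_b = x$auroc_b, delta = x$delta,
                 statistic = x$z, p_value = x$p_value,
                 degenerate = x$degenerate)
}

#' @rdname tidy.delong_test
#' @method glance delong_test
#' @export
glance.delong_test <- tidy.delong_test

#' Per-epoch training log of a fitted recurrent model
#'
#' @param x A `grud_fit`.
#' @param ... Unused.
#' @return The per-epoch loss log as a tibble.
#' @method tidy grud_fit
#' @export
tidy.grud_fit <- function(x, ...) x$log

#' One-row summary of a fitted recurrent model
#'
#' @param x A `grud_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variant, sizes, epochs, best validation loss.
#' @method glance grud_fit
#' @export
glance.grud_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, hidden = x$hidden,
    n_channels = length(x$channels),
    n_params = length(flatten_params(x$params)),
    epochs_run = x$stopped_epoch, best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' @export
print.grud_fit <- function(x, ...) {
  g <- glance.grud_fit(x)
  cat(sprintf(
    "<grud_fit> %s: %d channels, %d hidden units, %d parameters\n  stopped after epoch %d (best validation loss %.4f at epoch %d)\n",
    g$variant, g$n_channels, g$hidden, g$n_params, g$epochs_run,
    g$best_val_loss, g$best_epoch))
  invisible(x)
}

#' Tidy per-stay Shapley values
#'
#' @param x An `attribution_result`.
#' @param ... Unused.
#' @return The long value table.
#' @method tidy attribution_result
#' @export
tidy.attribution_result <- function(x, ...) x$values

#' One-row summary of an attribution run
#'
#' @param x An `attribution_result`.
#' @param ... Unused.
#' @return A one-row tibble with sampling parameters and the worst per-stay
#'   efficiency gap.
#' @method glance attribution_result
#' @export
glance.attribution_result <- function(x, ...) {
  tibble::tibble(
    n_stays = nrow(x$efficiency), n_players = length(x$players),
    n_samples = x$n_samples, seed = x$seed,
    max_abs_efficiency_gap = max(abs(x$efficiency$gap)),
    reference = x$reference
  )
}
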