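#' Training configuration for the recurrent classifiers
#'
#' Binary cross-entropy loss, Adam updates, early stopping when the
#' validation loss has not decreased for `patience` consecutive epochs, with
#' 10% of the training data reserved for model selection.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap; early stopping usually halts far sooner.
#' @param patience Epochs without a new validation-loss minimum before
#'   stopping (default 20).
#' @param val_frac Fraction of the training stays held out for model
#'   selection (default 0.10).
#' @param weight_decay L2 penalty on the dense gate and readout weights
#'   (default 0.03; biases and decay/no-history parameters are exempt), the
#'   regularizer that keeps a 32-unit recurrent net from overfitting
#'   cohorts of a few thousand stays within a handful of epochs.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         max_epochs = 500, patience = 20, val_frac = 0.10,
                         weight_decay = 1e-4) {
  if (patience < 1) stop_posticu("`patience` must be >= 1.", "config")
  if (!(val_frac > 0 && val_frac < 1)) {
    stop_posticu("`val_frac` must lie in (0, 1).", "config")
  }
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 val_frac = val_frac, weight_decay = weight_decay),
            class = "train_config")
}

# Convert a stay_tensors table to the flat lists the compiled core consumes.
tensors_to_lists <- function(tensors) {
  if (!isTRUE(attr(tensors, "normalized"))) {
    stop_posticu("tensors must be normalized before modeling.", "input")
  }
  stats <- attr(tensors, "norm_stats")
  channels <- tensor_channels(tensors)
  xbar <- stats$channels$xbar[match(channels, stats$channels$channel)]
  list(
    Xs = tensors$X, Ms = tensors$M, Ds = tensors$Delta,
    statics = cbind(age = tensors$age_z, sex = tensors$sex),
    y = as.numeric(tensors$label),
    xbar = xbar, channels = channels
  )
}

grud_batch_eval <- function(params, dat, idx, vcode, want_grad) {
  cpp_grud_batch(params, dat$Xs[idx], dat$Ms[idx], dat$Ds[idx],
                 dat$statics[idx, , drop = FALSE], dat$y[idx], dat$xbar,
                 vcode, want_grad)
}

# stratified index split: returns held-out indices
stratified_holdout <- function(labels, frac) {
  pick <- function(idx) {
    k <- max(1L, round(length(idx) * frac))
    sample(idx, k)
  }
  sort(c(pick(which(labels == 1)), pick(which(labels == 0))))
}

#' Train a recurrent deterioration classifier
#'
#' Fits a plain GRU (`"gru"`, for filled tensors), GRU-D (`"grud"`), or
#' GRU-D++ (`"grudpp"`) with a 32-unit tanh hidden layer, binary
#' cross-entropy loss, Adam, and patience-based early stopping on a
#' stratified model-selection split. Deterministic given `seed` (fixed
#' initialization, fixed batch order); the parameters returned are those of
#' the epoch with minimal validation loss.
#'
#' @param tensors Normalized training `stay_tensors` (filled, for `"gru"`).
#' @param variant One of `"grudpp"`, `"grud"`, `"gru"`.
#' @param config A [train_config()].
#' @param seed Integer seed for initialization, splits and batch order.
#' @param hidden Hidden units (default 32).
#' @param validation Optional `stay_tensors` used as the model-selection
#'   split; when `NULL`, `val_frac` of `tensors` is split off (stratified).
#' @param init Optional `grud_params` to warm-start from (fine-tuning).
#' @return A `grud_fit`: best parameters, variant, per-epoch loss log,
#'   stopping/best epochs, and the channel list + normalization stats the
#'   model is bound to (predictions on mismatched preprocessing are refused).
#' @export
grud_train <- function(tensors, variant = c("grudpp", "grud", "gru"),
                       config = train_config(), seed = 1, hidden = 32,
                       validation = NULL, init = NULL) {
  variant <- match.arg(variant)
  vcode <- variant_code(variant)
  if (variant == "gru" && !isTRUE(attr(tensors, "filled"))) {
    stop_posticu("the plain GRU consumes filled tensors; run forward_mean_fill().",
                 "input")
  }
  if (length(unique(tensors$label)) < 2) {
    stop_posticu("training data must contain both classes.", "degenerate")
  }
  local_seed(derive_seed(seed, 1L), {
    dat <- tensors_to_lists(tensors)
    n <- length(dat$y)
    if (is.null(validation)) {
      val_idx <- stratified_holdout(dat$y, config$val_frac)
      train_idx <- setdiff(seq_len(n), val_idx)
      dat_val <- dat
    } else {
      if (!identical(tensor_channels(validation), dat$channels)) {
        stop_posticu("validation tensors have a different channel list.", "input")
      }
      dat_val <- tensors_to_lists(validation)
      val_idx <- seq_along(dat_val$y)
      train_idx <- seq_len(n)
    }

    params <- init
    if (is.null(params)) {
      params <- grud_init_params(length(dat$channels),
                                 n_static = ncol(dat$statics),
                                 hidden = hidden,
                                 seed = derive_seed(seed, 2L))
      # start the output bias at the log-odds of the training prevalence so
      # early epochs learn ranking, not calibration
      params$b_out <- qlogis(max(1e-4, min(1 - 1e-4, mean(dat$y[train_idx]))))
    }
    template <- params
    # L2 applies to dense gate/readout weights only: biases, the decay-gate
    # parameters and the no-history default x0 are exempt (shrinking those
    # would pin the decay gates open and erase the imputation mechanism)
    decayable <- c("Wz", "Uz", "Vz", "Wr", "Ur", "Vr", "Wc", "Uc", "Vc",
                   "w_out")
    wd_mask <- unlist(lapply(names(template), function(nm) {
      rep(as.numeric(nm %in% decayable), length(template[[nm]]))
    }), use.names = FALSE)
    theta <- flatten_params(params)
    mom <- numeric(length(theta)); vel <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learning_rate
    step <- 0L

    # the starting state is a selection candidate too: fine-tuning an
    # already-good warm start must never return something worse than it
    best_loss <- grud_batch_eval(params, dat_val, val_idx, vcode, FALSE)$loss
    best_theta <- theta; best_epoch <- 0L
    since_best <- 0L
    log_rows <- vector("list", config$max_epochs)
    stopped <- config$max_epochs

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      tr_loss <- 0
      for (bidx in batches) {
        res <- grud_batch_eval(params, dat, bidx, vcode, TRUE)
        tr_loss <- tr_loss + res$loss * length(bidx)
        g <- unlist(lapply(names(template),
                           function(nm) as.numeric(res$grads[[nm]])),
                    use.names = FALSE)
        if ((config$weight_decay %||% 0) > 0) {
          g <- g + config$weight_decay * wd_mask * theta
        }
        step <- step + 1L
        mom <- b1 * mom + (1 - b1) * g
        vel <- b2 * vel + (1 - b2) * g^2
        mhat <- mom / (1 - b1^step)
        vhat <- vel / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        params <- unflatten_params(theta, template)
      }
      val <- grud_batch_eval(params, dat_val, val_idx, vcode, FALSE)$loss
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr_loss / length(train_idx),
        val_loss = val)
      if (val < best_loss) {
        best_loss <- val; best_theta <- theta; best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        # halve the step size when the validation loss plateaus so late
        # epochs refine rather than oscillate
        if (since_best %% 5L == 0L && lr > 1e-4) lr <- lr / 2
      }
      if (since_best >= config$patience) { stopped <- epoch; break }
    }

    structure(
      list(params = unflatten_params(best_theta, template),
           variant = variant,
           log = dplyr::bind_rows(log_rows),
           best_epoch = best_epoch, stopped_epoch = stopped,
           best_val_loss = best_loss,
           channels = dat$channels,
           norm_stats = attr(tensors, "norm_stats"),
           filled = isTRUE(attr(tensors, "filled")),
           config = config, seed = seed, hidden = hidden),
      class = "grud_fit")
  })
}

check_fit_tensors <- function(object, tensors, allow_refit_stats = FALSE) {
  if (!identical(tensor_channels(tensors), object$channels)) {
    stop_posticu(
      "tensor channel list does not match the checkpoint; refusing to predict.",
      "mismatch")
  }
  if (!isTRUE(attr(tensors, "normalized"))) {
    stop_posticu("tensors must be normalized with the training-fold stats.",
                 "input")
  }
  if (object$variant == "gru" && !isTRUE(attr(tensors, "filled"))) {
    stop_posticu("this checkpoint consumes filled tensors.", "input")
  }
  ts <- attr(tensors, "norm_stats")
  if (!allow_refit_stats && !is.null(ts) && !is.null(object$norm_stats) &&
      !isTRUE(all.equal(ts$channels$mean, object$norm_stats$channels$mean,
                        tolerance = 1e-12))) {
    stop_posticu(
      "tensors were normalized with different statistics than the checkpoint's; refusing to predict.",
      "mismatch")
  }
  invisible(TRUE)
}

#' Predict deterioration risk at discharge
#'
#' @param object A `grud_fit`.
#' @param tensors `stay_tensors` preprocessed with the fold's statistics.
#' @param type `"prob"` (default) or `"logit"`.
#' @param allow_refit_stats Allow tensors normalized with statistics other
#'   than the checkpoint's (the cross-site transfer flow, where the new
#'   site's normalization is refitted); the channel list must still match.
#' @param ... Unused.
#' @return A numeric vector aligned with `tensors` rows.
#' @export
predict.grud_fit <- function(object, tensors, type = c("prob", "logit"),
                             allow_refit_stats = FALSE, ...) {
  type <- match.arg(type)
  check_fit_tensors(object, tensors, allow_refit_stats)
  dat <- tensors_to_lists(tensors)
  res <- cpp_grud_batch(object$params, dat$Xs, dat$Ms, dat$Ds, dat$statics,
                        dat$y, dat$xbar, variant_code(object$variant), FALSE)
  if (type == "prob") as.numeric(res$probs) else as.numeric(res$logits)
}

#' Per-day risk trajectories
#'
#' Applies the readout to every prefix hidden state, so the day-`t` risk uses
#' only bins up to `t`: the discharge-day risk equals the final trajectory
#' point, and earlier points are the predictions the model would have issued
#' on those days.
#'
#' @param object A `grud_fit`.
#' @param tensors Preprocessed `stay_tensors`.
#' @return A tibble: `stay_id`, `label`, `day`, `n_days`, `risk`.
#' @export
risk_trajectory <- function(object, tensors) {
  check_fit_tensors(object, tensors)
  dat <- tensors_to_lists(tensors)
  vcode <- variant_code(object$variant)
  rows <- lapply(seq_len(nrow(tensors)), function(i) {
    fw <- cpp_grud_forward(object$params, dat$Xs[[i]], dat$Ms[[i]],
                           dat$Ds[[i]], dat$statics[i, ], dat$xbar, vcode)
    tibble::tibble(stay_id = tensors$stay_id[i], label = tensors$label[i],
                   day = seq_along(fw$traj_logit),
                   n_days = tensors$n_days[i],
                   risk = plogis(as.numeric(fw$traj_logit)))
  })
  dplyr::bind_rows(rows)
}

#' Fine-tune a pretrained model on a new site with nested data fractions
#'
#' Splits the new-site stays into a fixed test set, a fixed model-selection
#' set, and a training pool; training subsets at increasing fractions are
#' nested (the 10% set is a prefix of the 20% set, and so on) so the learning
#' curve reflects data volume, not split noise. All weights are warm-started
#' from the pretrained parameters; fraction 0 reports the zero-shot transfer
#' performance of the pretrained model.
#'
#' @param pretrained A `grud_fit` trained on the source cohort.
#' @param tensors New-site `stay_tensors`, preprocessed with the same channel
#'   list (normalization refitted on the new site is allowed and typical).
#' @param fractions Fractions of the full new-site data used for training.
#' @param test_frac,selection_frac Fractions held out for testing and model
#'   selection.
#' @param config A [train_config()]; defaults to the pretrained fit's.
#' @param seed Integer seed for the split and training.
#' @return A `finetune_curve` tibble: `fraction`, `n_train`, `auroc`, `aupr`.
#' @export
fine_tune <- function(pretrained, tensors,
                      fractions = seq(0.1, 0.5, by = 0.1),
                      test_frac = 0.4, selection_frac = 0.1,
                      config = NULL, seed = 1) {
  config <- config %||% pretrained$config
  if (max(fractions) + test_frac + selection_frac > 1 + 1e-9) {
    stop_posticu("fractions + test + selection exceed the available data.",
                 "config")
  }
  check_fit_tensors(pretrained, tensors, allow_refit_stats = TRUE)
  n <- nrow(tensors)
  local_seed(derive_seed(seed, 3L), {
    test_idx <- stratified_holdout(tensors$label, test_frac)
    rest <- setdiff(seq_len(n), test_idx)
    sel_local <- stratified_holdout(tensors$label[rest],
                                    selection_frac * n / length(rest))
    sel_idx <- rest[sel_local]
    pool <- sample(setdiff(rest, sel_idx))

    test_t <- tensors[test_idx, ]
    sel_t <- tensors[sel_idx, ]
    rows <- lapply(fractions, function(fr) {
      k <- round(fr * n)
      # the stratified holdouts round per class, so the pool can fall a
      # stay or two short of round(fr * n) at the largest feasible fraction
      if (k > length(pool) + ceiling(0.005 * n)) {
        stop_posticu("training fraction exceeds the available pool.", "config")
      }
      k <- min(k, length(pool))
      if (k == 0) {
        sc <- predict(pretrained, test_t, allow_refit_stats = TRUE)
        return(tibble::tibble(fraction = fr, n_train = 0L,
                              auroc = auroc(sc, test_t$label),
                              aupr = aupr(sc, test_t$label)))
      }
      tr <- tensors[pool[seq_len(k)], ]
      fit <- grud_train(tr, variant = pretrained$variant, config = config,
                        seed = derive_seed(seed, 17L), hidden = pretrained$hidden,
                        validation = sel_t, init = pretrained$params)
      sc <- predict(fit, test_t)
      tibble::tibble(fraction = fr, n_train = k,
                     auroc = auroc(sc, test_t$label),
                     aupr = aupr(sc, test_t$label))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("finetune_curve", class(out))
    attr(out, "split") <- list(test = tensors$stay_id[test_idx],
                               selection = tensors$stay_id[sel_idx],
                               pool = tensors$stay_id[pool])
    attr(out, "train_ids") <- stats::setNames(
      lapply(fractions, function(fr) {
        tensors$stay_id[pool[seq_len(min(round(fr * n), length(pool)))]]
      }),
      as.character(fractions))
    out
  })
}
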