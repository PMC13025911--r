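#' Permutation-sampling Shapley values of an arbitrary set function
#'
#' Estimates the Shapley value of each player by averaging marginal
#' contributions along uniformly random player orderings, with antithetic
#' pairs (each sampled ordering is also traversed reversed) to cut variance.
#' Because marginal contributions telescope along an ordering, the estimated
#' values sum exactly to `v(full) - v(empty)` (efficiency holds by
#' construction, not only in expectation).
#'
#' @param value_fn Function taking a logical inclusion vector of length
#'   `n_players` and returning a scalar.
#' @param n_players Number of players.
#' @param n_samples Total number of orderings (>= 2; rounded up to even).
#' @param seed Integer seed; the estimate is deterministic given it.
#' @return Numeric Shapley values, length `n_players`.
#' @export
shapley_sample <- function(value_fn, n_players, n_samples = 200, seed = 1) {
  if (n_samples < 2) stop_posticu("`n_samples` must be at least 2.", "config")
  n_pairs <- ceiling(n_samples / 2)
  local_seed(derive_seed(seed, 23L), {
    acc <- numeric(n_players)
    for (k in seq_len(n_pairs)) {
      perm <- sample(n_players)
      for (p in list(perm, rev(perm))) {
        inc <- rep(FALSE, n_players)
        v_prev <- value_fn(inc)
        for (j in p) {
          inc[j] <- TRUE
          v_new <- value_fn(inc)
          acc[j] <- acc[j] + (v_new - v_prev)
          v_prev <- v_new
        }
      }
    }
    acc / (2 * n_pairs)
  })
}

#' Exact Shapley values by subset enumeration
#'
#' Evaluates all `2^n` coalitions; the independent oracle for the sampling
#' estimator at small dimension.
#'
#' @inheritParams shapley_sample
#' @return Numeric Shapley values, length `n_players`.
#' @export
shapley_exact <- function(value_fn, n_players) {
  if (n_players > 20) {
    stop_posticu("exact enumeration is limited to 20 players.", "config")
  }
  vals <- numeric(2^n_players)
  masks <- lapply(seq_len(2^n_players) - 1L, function(b) {
    as.logical(bitwAnd(bitwShiftR(b, seq_len(n_players) - 1L), 1L))
  })
  for (i in seq_along(masks)) vals[i] <- value_fn(masks[[i]])
  lf <- lgamma(seq_len(n_players + 1))  # lgamma(k+1) = log(k!)
  out <- numeric(n_players)
  for (j in seq_len(n_players)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (i in seq_along(masks)) {
      b <- i - 1L
      if (bitwAnd(b, bit) == 0L) {
        s <- sum(masks[[i]])
        w <- exp(lf[s + 1] + lf[n_players - s] - lf[n_players + 1])
        out[j] <- out[j] + w * (vals[i + bit] - vals[i])
      }
    }
  }
  out
}

# Build the coalition value function for one stay: players not in the
# coalition are replaced by the reference stay's series (observed-at-
# reference semantics); value is the model logit.
stay_value_fn <- function(object, X, M, Delta, static, dat, players,
                          channel_idx, static_idx, ref) {
  vcode <- variant_code(object$variant)
  grid_delta <- function(T_) c(0, rep(1, T_ - 1))
  T_ <- nrow(X)
  function(inc) {
    Xm <- X; Mm <- M; Dm <- Delta; sm <- static
    for (p in which(!inc)) {
      d <- channel_idx[p]
      if (!is.na(d)) {
        if (ref$kind == "global-mean") {
          Xm[, d] <- ref$xbar[d]
          Mm[, d] <- 1
          Dm[, d] <- grid_delta(T_)
        } else { # all-missing
          Xm[, d] <- NaN
          Mm[, d] <- 0
          Dm[, d] <- seq_len(T_) - 1
        }
      } else {
        sm[static_idx[p]] <- ref$static[static_idx[p]]
      }
    }
    fw <- cpp_grud_forward(object$params, Xm, Mm, Dm, sm, dat$xbar, vcode)
    fw$traj_logit[T_]
  }
}

#' Shapley attribution of discharge risk to input channels
#'
#' Channel-level Shapley values of the model logit: masking a player
#' replaces its whole series (or its static value) with the reference
#' stay's, so a value is the average marginal effect of revealing that
#' channel's actual trajectory. The default reference is the all-global-mean
#' stay (every channel observed at its global mean every day); the
#' `"all-missing"` reference instead withholds the channel entirely,
#' probing the model's own imputation path. Estimated by antithetic
#' permutation sampling on the logit scale; deterministic given `seed`.
#'
#' @param object A `grud_fit`.
#' @param tensors Preprocessed `stay_tensors` (the stays to attribute).
#' @param reference `"global-mean"` (default) or `"all-missing"`.
#' @param n_samples Orderings per stay (default 200).
#' @param seed Integer seed.
#' @param include_static Attribute the static covariates too (default TRUE).
#' @return An `attribution_result`: `values` (tibble `stay_id`, `player`,
#'   `value` in log-odds units), `players`, `efficiency` (per-stay sum vs
#'   full-minus-reference gap), sampling parameters, and a reference
#'   description.
#' @export
shapley_attribution <- function(object, tensors,
                                reference = c("global-mean", "all-missing"),
                                n_samples = 200, seed = 1,
                                include_static = TRUE) {
  reference <- match.arg(reference)
  if (n_samples < 2) stop_posticu("`n_samples` must be at least 2.", "config")
  check_fit_tensors(object, tensors, allow_refit_stats = TRUE)
  dat <- tensors_to_lists(tensors)
  channels <- dat$channels
  statics <- if (include_static) colnames(dat$statics) else character()
  players <- c(channels, statics)
  channel_idx <- c(seq_along(channels), rep(NA_integer_, length(statics)))
  static_idx <- c(rep(NA_integer_, length(channels)), seq_along(statics))
  ref <- list(kind = reference, xbar = dat$xbar,
              static = colMeans(dat$statics))

  rows <- vector("list", nrow(tensors))
  eff <- numeric(nrow(tensors))
  for (i in seq_len(nrow(tensors))) {
    vf <- stay_value_fn(object, dat$Xs[[i]], dat$Ms[[i]], dat$Ds[[i]],
                        dat$statics[i, ], dat, players, channel_idx,
                        static_idx, ref)
    vals <- shapley_sample(vf, length(players), n_samples,
                           seed = derive_seed(seed, 31L + i))
    full <- vf(rep(TRUE, length(players)))
    empty <- vf(rep(FALSE, length(players)))
    eff[i] <- sum(vals) - (full - empty)
    rows[[i]] <- tibble::tibble(stay_id = tensors$stay_id[i],
                                player = players, value = vals)
  }
  structure(
    list(values = dplyr::bind_rows(rows), players = players,
         efficiency = tibble::tibble(stay_id = tensors$stay_id, gap = eff),
         n_samples = n_samples, seed = seed,
         reference = sprintf(
           "%s stay (statics at cohort means), logit scale", reference)),
    class = "attribution_result")
}

#' Rank channels by global Shapley importance
#'
#' Global importance is the mean absolute Shapley value per player across
#' stays. The export pairs each per-stay value with the percentile of that
#' stay's observed channel level in the cohort, the layout of a
#' beeswarm-style importance display (high-vs-low coloring).
#'
#' @param result An `attribution_result`.
#' @param tensors The `stay_tensors` that were attributed (for channel
#'   levels); optional.
#' @return A list: `ranking` (tibble `player`, `importance`, ordered
#'   decreasing, ties in stable player order) and `export` (per-stay values
#'   with `feature_percentile`, `NA` where a level is undefined).
#' @export
importance_summary <- function(result, tensors = NULL) {
  vals <- result$values
  ranking <- vals |>
    dplyr::summarise(importance = mean(abs(.data$value)), .by = "player") |>
    dplyr::arrange(dplyr::desc(.data$importance),
                   match(.data$player, result$players))
  export <- vals
  export$feature_level <- NA_real_
  if (!is.null(tensors)) {
    channels <- tensor_channels(tensors)
    lev <- lapply(seq_len(nrow(tensors)), function(i) {
      X <- tensors$X[[i]]; M <- tensors$M[[i]]
      means <- vapply(seq_len(ncol(X)), function(d) {
        if (any(M[, d] == 1)) mean(X[M[, d] == 1, d]) else NA_real_
      }, numeric(1))
      nm <- c(channels, "age", "sex")
      stats::setNames(c(means,
                        if ("age_z" %in% names(tensors)) tensors$age_z[i] else tensors$age[i],
                        tensors$sex[i]), nm)
    })
    lev_tab <- do.call(rbind, lev)
    rownames(lev_tab) <- tensors$stay_id
    export$feature_level <- lev_tab[cbind(export$stay_id, export$player)]
    export <- export |>
      dplyr::mutate(feature_percentile = stats::ave(
        .data$feature_level, .data$player,
        FUN = function(x) {
          if (all(is.na(x))) return(x)
          r <- rank(x, na.last = "keep", ties.method = "average")
          (r - 0.5) / sum(!is.na(x))
        }))
  } else {
    export$feature_percentile <- NA_real_
  }
  list(ranking = ranking, export = tibble::as_tibble(export))
}
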