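#' Aggregate a cohort's event stream onto the daily grid
#'
#' Day bins are 24 h windows anchored at ICU admission: bin `t` covers
#' `[icu_in + (t-1) days, icu_in + t days)` and the number of bins is the
#' ceiling of the length of stay in days. Numeric channels take the
#' arithmetic mean of their in-bin measurements; treatment channels are 1 if
#' any event fell in the bin and are never missing. A bin with no measurement
#' is missing: its mask entry is 0 and its value is the `NaN` sentinel, which
#' no downstream consumer may read as data. The per-channel days-since-last-
#' observation matrix follows the recursion `Delta[1, ] = 0`;
#' `Delta[t, d] = 1` if the channel was observed on day `t - 1`, else
#' `Delta[t-1, d] + 1`.
#'
#' @param cohort An `icu_cohort`, already merged ([merge_planned_readmissions()])
#'   and filtered ([select_cohort()]).
#' @param channels Channel names in column order; defaults to the cohort
#'   config's channel list, falling back to sorted names seen in the events.
#' @param treatment_channels Names of binary treatment channels; defaults to
#'   the cohort config's treatment channels.
#' @param window_days Outcome window passed to [label_outcome()].
#' @return A `stay_tensors` tibble: `stay_id`, `n_days`, list-columns `X`,
#'   `M`, `Delta` (T x D matrices with channel column names), `age`, `sex`,
#'   `los_days`, `label`.
#' @export
daily_aggregate <- function(cohort, channels = NULL, treatment_channels = NULL,
                            window_days = 7) {
  stays <- cohort$stays
  events <- cohort$events
  if (is.null(channels)) {
    channels <- if (!is.null(cohort$config)) {
      cohort$config$channels$name
    } else {
      sort(unique(events$channel))
    }
  }
  if (is.null(treatment_channels)) {
    treatment_channels <- if (!is.null(cohort$config)) {
      cohort$config$channels$name[cohort$config$channels$kind == "treatment"]
    } else {
      character()
    }
  }
  unknown <- setdiff(unique(events$channel), channels)
  if (length(unknown) > 0) {
    stop_posticu(paste("events carry channels not in the channel list:",
                       paste(unknown, collapse = ", ")), "input")
  }
  labs <- label_outcome(cohort, window_days = window_days)

  los_days <- as.numeric(difftime(stays$icu_out, stays$icu_in, units = "days"))
  n_days <- as.integer(ceiling(los_days - 1e-9))
  key <- stats::setNames(seq_len(nrow(stays)), stays$stay_id)

  ev <- events
  si <- key[ev$stay_id]
  rel <- as.numeric(difftime(ev$time, stays$icu_in[si], units = "days"))
  if (any(rel < -1e-9 | rel > los_days[si] + 1e-9)) {
    stop_posticu("event timestamp outside its stay's ICU interval.", "input")
  }
  ev$day <- pmin(pmax(floor(rel) + 1L, 1L), n_days[si])
  is_treat <- ev$channel %in% treatment_channels

  agg <- dplyr::bind_rows(
    ev[!is_treat, ] |>
      dplyr::summarise(value = mean(.data$value),
                       .by = c("stay_id", "channel", "day")),
    ev[is_treat, ] |>
      dplyr::summarise(value = 1, .by = c("stay_id", "channel", "day"))
  )
  agg_split <- split(agg[c("channel", "day", "value")], agg$stay_id)

  D <- length(channels)
  treat_col <- channels %in% treatment_channels
  build <- function(i) {
    t_i <- n_days[i]
    X <- matrix(NaN, t_i, D, dimnames = list(NULL, channels))
    M <- matrix(0, t_i, D, dimnames = list(NULL, channels))
    X[, treat_col] <- 0
    M[, treat_col] <- 1
    a <- agg_split[[stays$stay_id[i]]]
    if (!is.null(a)) {
      idx <- cbind(a$day, match(a$channel, channels))
      X[idx] <- a$value
      M[idx] <- 1
      M[, treat_col] <- 1
    }
    list(X = X, M = M, Delta = compute_delta(M))
  }
  mats <- lapply(seq_len(nrow(stays)), build)

  out <- tibble::tibble(
    stay_id = stays$stay_id,
    n_days = n_days,
    X = lapply(mats, `[[`, "X"),
    M = lapply(mats, `[[`, "M"),
    Delta = lapply(mats, `[[`, "Delta"),
    age = stays$age,
    sex = stays$sex,
    los_days = los_days,
    label = labs$label[match(stays$stay_id, labs$stay_id)]
  )
  new_stay_tensors(out, channels = channels,
                   treatment_channels = treatment_channels)
}

new_stay_tensors <- function(df, channels, treatment_channels,
                             normalized = FALSE, filled = FALSE,
                             norm_stats = NULL) {
  structure(df,
            class = c("stay_tensors", class(tibble::tibble()))) |>
    `attr<-`("channels", channels) |>
    `attr<-`("treatment_channels", treatment_channels) |>
    `attr<-`("normalized", normalized) |>
    `attr<-`("filled", filled) |>
    `attr<-`("norm_stats", norm_stats)
}

tensor_channels <- function(tensors) {
  attr(tensors, "channels") %||% colnames(tensors$X[[1]])
}

#' Days-since-last-observation matrix from an observation mask
#'
#' @param M A T x D binary mask (1 = observed) on the daily grid.
#' @return A T x D matrix: row 1 is 0; thereafter 1 if the channel was
#'   observed the previous day, else the previous entry plus one.
#' @export
compute_delta <- function(M) {
  T_ <- nrow(M)
  Delta <- matrix(0, T_, ncol(M), dimnames = dimnames(M))
  if (T_ >= 2) {
    for (t in 2:T_) {
      Delta[t, ] <- ifelse(M[t - 1, ] == 1, 1, Delta[t - 1, ] + 1)
    }
  }
  Delta
}

#' Drop channels with too much missingness
#'
#' A channel is retained iff its pooled missing rate over all stay-days is
#' strictly below `max_missing`. Fit this on training folds only and restrict
#' validation/test tensors to the kept channel list.
#'
#' @param tensors A `stay_tensors` table.
#' @param max_missing Strict upper bound on the pooled missing rate
#'   (default 0.5).
#' @return A list: `tensors` (restricted to kept channels), `kept` (channel
#'   names), `rates` (named pooled missing rates for all input channels).
#' @export
filter_variables <- function(tensors, max_missing = 0.5) {
  channels <- tensor_channels(tensors)
  obs <- Reduce(`+`, lapply(tensors$M, colSums))
  days <- sum(tensors$n_days)
  rates <- 1 - obs / days
  names(rates) <- channels
  kept <- channels[rates < max_missing]
  if (length(kept) == 0) {
    stop_posticu("no channel survives the missing-rate filter.", "degenerate")
  }
  list(tensors = restrict_channels(tensors, kept), kept = kept, rates = rates)
}

#' Restrict tensors to a kept channel list
#'
#' @param tensors A `stay_tensors` table.
#' @param kept Channel names to keep, in order.
#' @return The restricted tensors.
#' @export
restrict_channels <- function(tensors, kept) {
  channels <- tensor_channels(tensors)
  idx <- match(kept, channels)
  if (anyNA(idx)) stop_posticu("unknown channel in `kept`.", "input")
  out <- tensors
  out$X <- lapply(tensors$X, function(m) m[, idx, drop = FALSE])
  out$M <- lapply(tensors$M, function(m) m[, idx, drop = FALSE])
  out$Delta <- lapply(tensors$Delta, function(m) m[, idx, drop = FALSE])
  new_stay_tensors(out, channels = kept,
                   treatment_channels = intersect(attr(tensors, "treatment_channels"), kept),
                   normalized = attr(tensors, "normalized") %||% FALSE,
                   filled = attr(tensors, "filled") %||% FALSE,
                   norm_stats = attr(tensors, "norm_stats"))
}

#' Fit per-channel normalization statistics on a training split
#'
#' Means and standard deviations (population convention, divide by n) are
#' computed over the observed entries of each numeric channel, pooled across
#' stay-days of the training tensors only; binary treatment channels are not
#' normalized. Age is standardized with the same convention. The per-channel
#' global mean in model space (`xbar`) — the decay-imputation target and the
#' mean-fill value — is 0 for standardized numeric channels and the observed
#' mean for treatment channels.
#'
#' @param tensors Training-split `stay_tensors`.
#' @return A `norm_stats` object.
#' @export
fit_normalization <- function(tensors) {
  channels <- tensor_channels(tensors)
  treat <- channels %in% attr(tensors, "treatment_channels")
  stats_tab <- lapply(seq_along(channels), function(d) {
    vals <- unlist(lapply(seq_len(nrow(tensors)), function(i) {
      x <- tensors$X[[i]][, d]
      x[tensors$M[[i]][, d] == 1]
    }), use.names = FALSE)
    if (treat[d]) {
      return(tibble::tibble(channel = channels[d], kind = "treatment",
                            mean = NA_real_, sd = NA_real_,
                            xbar = mean(vals)))
    }
    if (length(vals) == 0) {
      stop_posticu(sprintf("channel '%s' has no observed values.", channels[d]),
                   "degenerate")
    }
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    if (s <= 0) {
      stop_posticu(sprintf("channel '%s' has zero variance.", channels[d]),
                   "degenerate")
    }
    tibble::tibble(channel = channels[d], kind = "numeric",
                   mean = m, sd = s, xbar = 0)
  })
  age_m <- mean(tensors$age)
  age_s <- sqrt(mean((tensors$age - age_m)^2))
  if (age_s <= 0) age_s <- 1
  structure(
    list(channels = dplyr::bind_rows(stats_tab),
         age_mean = age_m, age_sd = age_s),
    class = "norm_stats"
  )
}

#' Standardize tensors with previously fitted statistics
#'
#' Observed entries of numeric channels become z-scores under `stats`;
#' treatment channels, masks and Delta are unchanged; a standardized `age_z`
#' column is added. Re-application is an error (tensors carry a normalized
#' flag) so a split can never be standardized twice.
#'
#' @param tensors A `stay_tensors` table.
#' @param stats A `norm_stats` from [fit_normalization()] (training split only).
#' @return The standardized tensors, flagged `normalized`.
#' @export
apply_normalization <- function(tensors, stats) {
  if (isTRUE(attr(tensors, "normalized"))) {
    stop_posticu("tensors are already normalized.", "renormalize")
  }
  channels <- tensor_channels(tensors)
  st <- stats$channels
  idx <- match(channels, st$channel)
  if (anyNA(idx)) {
    stop_posticu("normalization stats lack some tensor channels.", "input")
  }
  mu <- st$mean[idx]
  sdv <- st$sd[idx]
  numeric_col <- st$kind[idx] == "numeric"
  out <- tensors
  out$X <- lapply(tensors$X, function(m) {
    for (d in which(numeric_col)) m[, d] <- (m[, d] - mu[d]) / sdv[d]
    m
  })
  out$age_z <- (tensors$age - stats$age_mean) / stats$age_sd
  new_stay_tensors(out, channels = channels,
                   treatment_channels = attr(tensors, "treatment_channels"),
                   normalized = TRUE, filled = attr(tensors, "filled") %||% FALSE,
                   norm_stats = stats)
}

#' Forward-fill then mean-fill tensors for fill-based models
#'
#' Every missing entry takes the most recent prior observation of its
#' channel; entries with no prior observation take the channel's global mean
#' (`xbar` from the fitted statistics). The result carries no sentinels: `X`
#' is dense, the mask is all ones and Delta all zeros, which is exactly what
#' the fill-based recurrent baseline consumes (it sees filled values only).
#'
#' @param tensors A `stay_tensors` table (normalized).
#' @param stats A `norm_stats`; defaults to the stats attached at
#'   normalization time.
#' @return Dense tensors flagged `filled`.
#' @export
forward_mean_fill <- function(tensors, stats = NULL) {
  stats <- stats %||% attr(tensors, "norm_stats")
  if (is.null(stats)) {
    stop_posticu("no normalization stats available for mean fill.", "input")
  }
  channels <- tensor_channels(tensors)
  xbar <- stats$channels$xbar[match(channels, stats$channels$channel)]
  out <- tensors
  filled <- lapply(seq_len(nrow(tensors)), function(i) {
    X <- tensors$X[[i]]
    M <- tensors$M[[i]]
    for (d in seq_len(ncol(X))) {
      last <- xbar[d]
      for (t in seq_len(nrow(X))) {
        if (M[t, d] == 1) last <- X[t, d] else X[t, d] <- last
      }
    }
    X
  })
  out$X <- filled
  out$M <- lapply(tensors$M, function(m) {
    matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  })
  out$Delta <- lapply(tensors$Delta, function(m) {
    matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  })
  new_stay_tensors(out, channels = channels,
                   treatment_channels = attr(tensors, "treatment_channels"),
                   normalized = attr(tensors, "normalized") %||% FALSE,
                   filled = TRUE, norm_stats = stats)
}

#' Per-stay snapshot features for non-temporal models
#'
#' Concatenates the static covariates (standardized age, sex), the filled
#' final-day value of every channel, and the cumulative length of stay: a
#' fixed-length vector of D + 3 features per stay, the input contract of the
#' logistic/tree/forest/boosting baselines that cannot consume time series.
#'
#' @param tensors Filled `stay_tensors` (see [forward_mean_fill()]).
#' @return A tibble: `stay_id`, `label`, then one column per feature.
#' @export
last_day_snapshot <- function(tensors) {
  if (!isTRUE(attr(tensors, "filled"))) {
    stop_posticu("snapshot requires filled tensors (forward_mean_fill()).",
                 "input")
  }
  channels <- tensor_channels(tensors)
  lastvals <- t(vapply(tensors$X, function(m) m[nrow(m), ],
                       numeric(length(channels))))
  colnames(lastvals) <- channels
  age_feat <- if ("age_z" %in% names(tensors)) tensors$age_z else tensors$age
  tibble::tibble(stay_id = tensors$stay_id, label = tensors$label,
                 age = age_feat, sex = tensors$sex) |>
    dplyr::bind_cols(tibble::as_tibble(lastvals)) |>
    dplyr::mutate(los = tensors$los_days)
}

#' @export
`[.stay_tensors` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("X", "M", "Delta") %in% names(out))) {
    out <- new_stay_tensors(
      out, channels = attr(x, "channels"),
      treatment_channels = attr(x, "treatment_channels"),
      normalized = attr(x, "normalized") %||% FALSE,
      filled = attr(x, "filled") %||% FALSE,
      norm_stats = attr(x, "norm_stats"))
  }
  out
}

#' @export
print.stay_tensors <- function(x, ...) {
  cat("<stay_tensors> ", nrow(x), " stays, ",
      length(tensor_channels(x)), " channels",
      if (isTRUE(attr(x, "normalized"))) ", normalized",
      if (isTRUE(attr(x, "filled"))) ", filled",
      "\n", sep = "")
  NextMethod()
}
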