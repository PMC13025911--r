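#' Trainable exponential input decay
#'
#' `gamma = exp(-max(0, w * delta + b))`, elementwise per channel. The gate
#' is 1 when `w * delta + b <= 0` and strictly decreasing in `delta` when
#' `w > 0`, so a freshly observed channel keeps its last value while a stale
#' one relaxes toward the global mean.
#'
#' @param delta Nonnegative per-channel days since last observation.
#' @param w,b Per-channel decay weight and bias (diagonal parameterization).
#' @return Decay factors in (0, 1], same length as `delta`.
#' @export
input_decay <- function(delta, w, b) {
  if (any(delta < 0)) stop_posticu("`delta` must be nonnegative.", "input")
  exp(-pmax(0, w * delta + b))
}

#' Decay-blended imputation of one day's inputs
#'
#' Observed channels pass through unchanged. A missing channel with history
#' takes `gamma * x_last + (1 - gamma) * xbar`. A missing channel with no
#' prior observation in the stay depends on the variant: the GRU-D++ rule
#' substitutes the trainable per-channel default `x0` for `x_last`; the
#' GRU-D rule substitutes `xbar`, collapsing the blend to the global mean
#' (this is the fully-observed-first-step assumption it inherits); a variant
#' without a no-history rule errors.
#'
#' @param x Day values (missing entries may be NaN; never read).
#' @param m Observation mask for the day.
#' @param gamma Input decay factors, see [input_decay()].
#' @param x_last Last observed value per channel; `NA` where no history.
#' @param xbar Per-channel global mean in model space.
#' @param x0 Trainable no-history default (GRU-D++).
#' @param variant `"grudpp"`, `"grud"`, or `"strict"`.
#' @return The imputed input vector.
#' @export
impute_input <- function(x, m, gamma, x_last, xbar, x0 = NULL,
                         variant = c("grudpp", "grud", "strict")) {
  variant <- match.arg(variant)
  no_hist <- is.na(x_last)
  if (any(no_hist & m == 0)) {
    if (variant == "strict") {
      stop_posticu(
        "channel missing with no history: this variant assumes fully observed first steps.",
        "no_history")
    }
    if (variant == "grudpp" && is.null(x0)) {
      stop_posticu("GRU-D++ imputation requires the trainable default `x0`.",
                   "input")
    }
  }
  fallback <- if (variant == "grudpp") x0 else xbar
  xl <- ifelse(no_hist, fallback, x_last)
  ifelse(m == 1, x, gamma * xl + (1 - gamma) * xbar)
}

#' One recurrent step of the decay cell
#'
#' The hidden state is pre-decayed (`hh = gamma_h * h_prev`), then update and
#' reset gates and the tanh candidate are computed from the imputed input,
#' the decayed state, and the observation mask:
#' `h = (1 - z) * hh + z * c`. With every channel observed and both decay
#' gates at 1 this is exactly a plain GRU step with the mask as a constant
#' extra input.
#'
#' @param params A `grud_params` list (see [grud_init_params()]).
#' @param xhat Imputed input for the day.
#' @param m Observation mask for the day.
#' @param gamma_h Hidden-state decay vector (length H).
#' @param h_prev Previous hidden state.
#' @return The new hidden state (values in (-1, 1) by tanh saturation).
#' @export
cell_step <- function(params, xhat, m, gamma_h, h_prev) {
  if (any(!is.finite(xhat)) || any(!is.finite(h_prev))) {
    stop_posticu("non-finite inputs to cell_step().", "input")
  }
  hh <- gamma_h * h_prev
  z <- plogis(drop(t(params$Wz) %*% xhat + t(params$Uz) %*% hh +
                     t(params$Vz) %*% m) + params$bz)
  r <- plogis(drop(t(params$Wr) %*% xhat + t(params$Ur) %*% hh +
                     t(params$Vr) %*% m) + params$br)
  cc <- tanh(drop(t(params$Wc) %*% xhat + t(params$Uc) %*% (r * hh) +
                    t(params$Vc) %*% m) + params$bc)
  (1 - z) * hh + z * cc
}

#' Pure-R forward pass of the decay cell over one stay
#'
#' Step-by-step composition of [input_decay()], [impute_input()] and
#' [cell_step()]. This is the reference implementation the compiled forward
#' pass is tested against; it is not used for training.
#'
#' @param params A `grud_params` list.
#' @param X,M,Delta T x D matrices of values, mask, and staleness.
#' @param static Static covariate vector appended to the readout.
#' @param xbar Per-channel global mean in model space.
#' @param variant `"gru"`, `"grud"`, or `"grudpp"`.
#' @return A list: `traj_logit` (per-day readout logits), `hidden`
#'   (T x H hidden trajectory).
#' @export
grud_forward_r <- function(params, X, M, Delta, static, xbar,
                           variant = c("grudpp", "grud", "gru")) {
  variant <- match.arg(variant)
  T_ <- nrow(X); H <- length(params$bz)
  h <- numeric(H)
  x_last <- rep(NA_real_, ncol(X))
  hidden <- matrix(0, T_, H)
  traj <- numeric(T_)
  for (t in seq_len(T_)) {
    x <- ifelse(M[t, ] == 1, X[t, ], 0)
    if (variant == "gru") {
      gx <- rep(1, ncol(X)); gh <- rep(1, H)
    } else {
      gx <- input_decay(Delta[t, ], params$w_gx, params$b_gx)
      gh <- exp(-pmax(0, drop(t(params$W_gh) %*% Delta[t, ]) + params$b_gh))
    }
    imp_variant <- if (variant == "grudpp") "grudpp" else "grud"
    xhat <- impute_input(x, M[t, ], gx, x_last, xbar, params$x0, imp_variant)
    h <- cell_step(params, xhat, M[t, ], gh, h)
    hidden[t, ] <- h
    traj[t] <- sum(params$w_out * c(h, static)) + params$b_out
    x_last <- ifelse(M[t, ] == 1, X[t, ], x_last)
  }
  list(traj_logit = traj, hidden = hidden)
}

#' Initialize decay-cell parameters
#'
#' Fan-in-scaled uniform weights, zero biases, `x0` at 0 (the standardized
#' global mean). Input-decay weights start positive and of order one, so a
#' day-old missing value already relaxes about halfway to the channel mean
#' and staleness is informative from the first gradient step; the hidden-
#' decay map starts near zero with a small positive bias so its rectifier
#' is active.
#'
#' @param n_channels Number of input channels D.
#' @param n_static Number of static covariates appended to the readout.
#' @param hidden Hidden size H (default 32).
#' @param seed Integer seed making initialization deterministic.
#' @return A `grud_params` list of weight matrices and vectors.
#' @export
grud_init_params <- function(n_channels, n_static = 2, hidden = 32, seed = 1) {
  local_seed(seed, {
    D <- n_channels; H <- hidden
    u <- function(nr, nc, fan) {
      matrix(runif(nr * nc, -1 / sqrt(fan), 1 / sqrt(fan)), nr, nc)
    }
    p <- list(
      Wz = u(D, H, D), Uz = u(H, H, H), Vz = u(D, H, D), bz = numeric(H),
      Wr = u(D, H, D), Ur = u(H, H, H), Vr = u(D, H, D), br = numeric(H),
      Wc = u(D, H, D), Uc = u(H, H, H), Vc = u(D, H, D), bc = numeric(H),
      w_gx = runif(D, 0.5, 1.0), b_gx = numeric(D),
      W_gh = u(D, H, D) * 0.1, b_gh = rep(0.01, H),
      x0 = numeric(D),
      w_out = runif(H + n_static, -1 / sqrt(H + n_static), 1 / sqrt(H + n_static)),
      b_out = 0
    )
    structure(p, class = "grud_params", hidden = H, n_static = n_static)
  })
}

variant_code <- function(variant) {
  switch(variant, gru = 0L, grud = 1L, grudpp = 2L,
         stop_posticu(sprintf("unknown variant '%s'.", variant), "input"))
}

# flatten/unflatten for optimizers and finite differencing
flatten_params <- function(p) {
  unlist(lapply(p, as.numeric), use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[pos:(pos + n - 1L)]
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(v, nrow(template[[nm]]), ncol(template[[nm]]))
    } else if (n == 1L) v else v
    pos <- pos + n
  }
  out
}
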