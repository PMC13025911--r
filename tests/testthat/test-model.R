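tiny_params <- function(D = 3, H = 4, seed = 5) {
  p <- grud_init_params(D, n_static = 2, hidden = H, seed = seed)
  p$b_gx <- runif(D, 0.2, 0.5)   # keep the rectifiers away from their kinks
  p$b_gh <- runif(H, 0.05, 0.3)
  p
}

random_stay <- function(D = 3, T_ = 4, obs = 0.6) {
  M <- matrix(rbinom(T_ * D, 1, obs), T_, D)
  X <- matrix(rnorm(T_ * D), T_, D)
  X[M == 0] <- NaN
  list(X = X, M = M, Delta = compute_delta(M))
}

test_that("the input decay gate has its closed forms and matches scalar evaluation", {
  expect_equal(input_decay(0, w = 2, b = 0), 1)
  expect_equal(input_decay(log(2), w = 1, b = 0), 0.5)
  expect_equal(input_decay(5, w = -1, b = 0), 1)   # negative pre-activation
  withr::with_seed(31, {
    for (rep in 1:50) {
      w <- rnorm(1); b <- rnorm(1); d <- rexp(1)
      expect_equal(input_decay(d, w, b), exp(-max(0, w * d + b)),
                   tolerance = 1e-12)
    }
  })
  expect_error(input_decay(-1, 1, 0), class = "posticu_input")
})

test_that("decay-blended imputation follows the observed/history/no-history rules", {
  expect_equal(impute_input(x = 7, m = 1, gamma = 0.1, x_last = 2, xbar = 0,
                            x0 = 5, variant = "grudpp"), 7)
  expect_equal(impute_input(x = NaN, m = 0, gamma = 1, x_last = 2, xbar = 0,
                            x0 = 5, variant = "grudpp"), 2)
  expect_equal(impute_input(x = NaN, m = 0, gamma = 0.3, x_last = 2, xbar = 0,
                            x0 = 5, variant = "grudpp"), 0.6)
  # no history: trainable default vs global-mean collapse vs error
  expect_equal(impute_input(x = NaN, m = 0, gamma = 0.5, x_last = NA, xbar = 1,
                            x0 = 3, variant = "grudpp"), 0.5 * 3 + 0.5 * 1)
  expect_equal(impute_input(x = NaN, m = 0, gamma = 0.5, x_last = NA, xbar = 1,
                            variant = "grud"), 1)
  expect_error(impute_input(x = NaN, m = 0, gamma = 0.5, x_last = NA, xbar = 1,
                            variant = "strict"), class = "posticu_no_history")
})

test_that("a single cell step matches a pencil-and-paper recurrence at hidden size 1", {
  p <- list(Wz = matrix(c(0.5, -0.2), 2, 1), Uz = matrix(0.3, 1, 1),
            Vz = matrix(c(0.1, 0), 2, 1), bz = 0.05,
            Wr = matrix(c(0.2, 0.4), 2, 1), Ur = matrix(-0.1, 1, 1),
            Vr = matrix(c(0, 0.2), 2, 1), br = -0.1,
            Wc = matrix(c(0.7, 0.1), 2, 1), Uc = matrix(0.6, 1, 1),
            Vc = matrix(c(0.05, 0.05), 2, 1), bc = 0)
  xhat <- c(1.2, -0.4); m <- c(1, 0); gh <- 0.8; h_prev <- 0.5
  hh <- gh * h_prev
  z <- plogis(0.5 * 1.2 + (-0.2) * (-0.4) + 0.3 * hh + 0.1 * 1 + 0 * 0 + 0.05)
  r <- plogis(0.2 * 1.2 + 0.4 * (-0.4) + (-0.1) * hh + 0 * 1 + 0.2 * 0 - 0.1)
  cc <- tanh(0.7 * 1.2 + 0.1 * (-0.4) + 0.6 * (r * hh) + 0.05 * 1 + 0.05 * 0)
  expect_equal(cell_step(p, xhat, m, gh, h_prev), (1 - z) * hh + z * cc,
               tolerance = 1e-12)
  expect_error(cell_step(p, c(NaN, 1), m, gh, h_prev), class = "posticu_input")
})

test_that("hidden-state decay of a zero state stays zero and full observation with unit decay reduces to a plain GRU", {
  withr::with_seed(32, {
    p <- tiny_params()
    x <- rnorm(3); m <- c(1, 1, 1)
    # decaying a zero hidden state is a no-op whatever the gate says
    expect_equal(cell_step(p, x, m, rnorm(4), numeric(4)),
                 cell_step(p, x, m, rep(1, 4), numeric(4)),
                 tolerance = 1e-14)
    # reduction: fully observed, decay weights zeroed -> plain GRU oracle
    p$w_gx[] <- 0; p$b_gx[] <- 0; p$W_gh[] <- 0; p$b_gh[] <- 0
    T_ <- 5; D <- 3
    X <- matrix(rnorm(T_ * D), T_, D)
    M <- matrix(1, T_, D)
    Dl <- compute_delta(M)
    st <- rnorm(2); xbar <- rep(0, D)
    for (v in c("grud", "grudpp")) {
      got <- grud_forward_r(p, X, M, Dl, st, xbar, v)$traj_logit
      # independent plain-GRU oracle, written out longhand
      h <- numeric(4)
      want <- numeric(T_)
      for (t in seq_len(T_)) {
        x <- X[t, ]; m <- M[t, ]
        z <- plogis(drop(t(p$Wz) %*% x + t(p$Uz) %*% h + t(p$Vz) %*% m) + p$bz)
        r <- plogis(drop(t(p$Wr) %*% x + t(p$Ur) %*% h + t(p$Vr) %*% m) + p$br)
        cc <- tanh(drop(t(p$Wc) %*% x + t(p$Uc) %*% (r * h) + t(p$Vc) %*% m) + p$bc)
        h <- (1 - z) * h + z * cc
        want[t] <- sum(p$w_out * c(h, st)) + p$b_out
      }
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("the compiled forward pass equals the step-by-step composition of audited cell operations", {
  withr::with_seed(33, {
    for (v in c("gru", "grud", "grudpp")) {
      p <- tiny_params(D = 4, H = 3, seed = 7)
      s <- random_stay(D = 4, T_ = 5)
      if (v == "gru") {
        s$X[is.nan(s$X)] <- 0; s$M[, ] <- 1; s$Delta[, ] <- 0
      }
      st <- rnorm(2); xbar <- rnorm(4) * 0.1
      ours <- grud_forward_r(p, s$X, s$M, s$Delta, st, xbar, v)
      cpp <- posticu:::cpp_grud_forward(p, s$X, s$M, s$Delta, st, xbar,
                                       posticu:::variant_code(v))
      expect_equal(ours$traj_logit, as.numeric(cpp$traj_logit),
                   tolerance = 1e-12)
    }
  })
})

test_that("with zero weights the risk is the sigmoid of the output bias and the trajectory ends at the risk", {
  tens <- make_tensors(n = 6, seed = 41, normalized = TRUE)
  fit <- grud_train(tens, "grudpp",
                    config = train_config(max_epochs = 1, batch_size = 4),
                    seed = 1)
  for (nm in names(fit$params)) fit$params[[nm]][] <- 0
  fit$params$b_out <- 0.7
  risk <- predict(fit, tens)
  expect_equal(risk, rep(plogis(0.7), nrow(tens)), tolerance = 1e-12)
  tr <- risk_trajectory(fit, tens)
  last <- tr |> dplyr::slice_tail(n = 1, by = stay_id)
  expect_equal(last$risk, risk, tolerance = 1e-12)
})

test_that("the day-t prediction uses only bins up to t", {
  withr::with_seed(34, {
    fit <- grud_train(make_tensors(n = 30, seed = 43, normalized = TRUE),
                      "grudpp", config = train_config(max_epochs = 3),
                      seed = 1)
    seed2 <- 52
    repeat {
      tens2 <- make_tensors(n = 1, seed = seed2, t_max = 6, obs_prob = 0.9)
      if (tens2$n_days[1] >= 3) break
      seed2 <- seed2 + 1
    }
    tens2 <- apply_normalization(tens2, fit$norm_stats)
    base <- risk_trajectory(fit, tens2)
    # perturb the final bin: all earlier predictions must be bitwise identical
    pert <- tens2
    T_ <- pert$n_days[1]
    if (T_ >= 2) {
      pert$X[[1]][T_, ] <- 5
      pert$M[[1]][T_, ] <- 1
      got <- risk_trajectory(fit, pert)
      expect_identical(base$risk[seq_len(T_ - 1)], got$risk[seq_len(T_ - 1)])
      expect_false(isTRUE(all.equal(base$risk[T_], got$risk[T_])))
    }
  })
})

test_that("training separates a linearly separable toy problem", {
  withr::with_seed(35, {
    n <- 200
    rows <- lapply(seq_len(n), function(i) {
      y <- rbinom(1, 1, 0.5)
      X <- matrix(rnorm(2, mean = c(2 * y - 1, 1 - 2 * y), sd = 0.3), 1, 2,
                  dimnames = list(NULL, c("u", "v")))
      M <- matrix(1, 1, 2, dimnames = list(NULL, c("u", "v")))
      Dl <- compute_delta(M)
      tibble::tibble(stay_id = sprintf("x%03d", i), n_days = 1L,
                     X = list(X), M = list(M), Delta = list(Dl),
                     age = 50, sex = 0, los_days = 1, label = y)
    })
    tens <- posticu:::new_stay_tensors(dplyr::bind_rows(rows),
                                       channels = c("u", "v"),
                                       treatment_channels = character())
    tens <- apply_normalization(tens, fit_normalization(tens))
    fit <- grud_train(tens, "grudpp",
                      config = train_config(max_epochs = 200, weight_decay = 0),
                      seed = 2)
    expect_gte(auroc(predict(fit, tens), tens$label), 0.99)
  })
})

test_that("label shuffling leaves held-out discrimination at chance", {
  withr::with_seed(36, {
    tens <- make_tensors(n = 300, seed = 61, normalized = TRUE)
    tens$label <- sample(rep(c(0L, 1L), c(150, 150)))
    tr <- tens[1:150, ]; te <- tens[151:300, ]
    fit <- grud_train(tr, "grudpp", seed = 3)
    a <- auroc(predict(fit, te), te$label)
    expect_gt(a, 0.4)
    expect_lt(a, 0.6)
  })
})

test_that("early stopping runs to the epoch cap while the validation loss still improves", {
  withr::with_seed(37, {
    tens <- make_tensors(n = 80, seed = 62, normalized = TRUE)
    tens$label <- as.integer(vapply(seq_len(nrow(tens)), function(i) {
      obs <- tens$X[[i]][tens$M[[i]] == 1]
      length(obs) > 0 && mean(obs) > 0
    }, logical(1)))
    if (length(unique(tens$label)) < 2) tens$label[1] <- 1L - tens$label[1]
    fit <- grud_train(tens, "grudpp",
                      config = train_config(max_epochs = 5, weight_decay = 0),
                      seed = 4)
    expect_equal(fit$stopped_epoch, 5L)  # improvement phase: no early stop
    expect_equal(nrow(fit$log), 5L)
    # patience fires on a stagnant problem
    tens2 <- make_tensors(n = 60, seed = 63, normalized = TRUE)
    fit2 <- grud_train(tens2, "grudpp",
                       config = train_config(max_epochs = 400, patience = 5),
                       seed = 4)
    expect_lt(fit2$stopped_epoch, 400L)
    expect_equal(fit2$stopped_epoch - fit2$best_epoch, 5L)
  })
})

test_that("training is deterministic given the seed and rejects single-class data", {
  tens <- make_tensors(n = 40, seed = 64, normalized = TRUE)
  cfg <- train_config(max_epochs = 4)
  f1 <- grud_train(tens, "grud", config = cfg, seed = 9)
  f2 <- grud_train(tens, "grud", config = cfg, seed = 9)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log, f2$log)
  bad <- tens; bad$label <- 0L
  expect_error(grud_train(bad, "grud", config = cfg, seed = 1),
               class = "posticu_degenerate")
  expect_error(grud_train(tens, "gru", config = cfg, seed = 1),
               class = "posticu_input")  # gru needs filled tensors
})

test_that("checkpoints round-trip through JSON and refuse mismatched preprocessing", {
  tens <- make_tensors(n = 30, seed = 65, normalized = TRUE)
  fit <- grud_train(tens, "grudpp", config = train_config(max_epochs = 3),
                    seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  expect_equal(predict(back, tens), predict(fit, tens), tolerance = 1e-12)
  other <- make_tensors(n = 5, channels = c("a", "b"), seed = 66,
                        normalized = TRUE)
  expect_error(predict(back, other), class = "posticu_mismatch")
  refit <- apply_normalization(make_tensors(n = 30, seed = 67),
                               fit_normalization(make_tensors(n = 30, seed = 67)))
  expect_error(predict(fit, refit), class = "posticu_mismatch")
  expect_silent(predict(fit, refit, allow_refit_stats = TRUE))
})

test_that("fine-tuning uses nested training subsets and fraction zero is the zero-shot model", {
  tens <- make_tensors(n = 120, seed = 68, normalized = TRUE)
  fit <- grud_train(tens[1:60, ], "grudpp",
                    config = train_config(max_epochs = 4), seed = 6)
  ftc <- fine_tune(fit, tens, fractions = c(0, 0.1, 0.3),
                   config = train_config(max_epochs = 3), seed = 7)
  ids <- attr(ftc, "train_ids")
  expect_true(all(ids[["0.1"]] %in% ids[["0.3"]]))
  expect_equal(length(ids[["0"]]), 0L)
  split <- attr(ftc, "split")
  expect_length(intersect(split$test, unlist(ids)), 0)
  # fraction 0 reproduces the pretrained model's scores on the test split
  te <- tens[match(split$test, tens$stay_id), ]
  expect_equal(ftc$auroc[1], auroc(predict(fit, te), te$label),
               tolerance = 1e-12)
  expect_error(fine_tune(fit, tens, fractions = 0.8, seed = 1),
               class = "posticu_config")
})
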