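#' Model adapters for cross-validated evaluation
#'
#' A `risk_model` bundles a `fit(tensors, seed)` closure and a
#' `predict(fitted, tensors)` closure operating on raw (unnormalized,
#' unfiltered) `stay_tensors`, so that every preprocessing statistic — the
#' variable filter, normalization means/sds, global means — is fitted inside
#' each training fold and never sees test stays.
#'
#' @param name Display name.
#' @param fit,predict Closures as described.
#' @return A `risk_model`.
#' @export
risk_model <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "risk_model")
}

#' Recurrent model adapter (GRU / GRU-D / GRU-D++)
#'
#' @param variant `"grudpp"`, `"grud"`, or `"gru"` (the fill-based baseline:
#'   tensors are forward/mean-filled and the mask carries no information).
#' @param config A [train_config()].
#' @param hidden Hidden units.
#' @param max_missing Variable-filter threshold (default 0.5).
#' @return A `risk_model`.
#' @export
model_grud <- function(variant = "grudpp", config = train_config(),
                       hidden = 32, max_missing = 0.5) {
  prep <- function(tensors, flt, stats) {
    tt <- restrict_channels(tensors, flt)
    tt <- apply_normalization(tt, stats)
    if (variant == "gru") tt <- forward_mean_fill(tt) else tt
  }
  risk_model(
    name = switch(variant, grudpp = "GRU-D++", grud = "GRU-D", gru = "GRU"),
    fit = function(tensors, seed) {
      flt <- filter_variables(tensors, max_missing)
      stats <- fit_normalization(flt$tensors)
      tr <- apply_normalization(flt$tensors, stats)
      if (variant == "gru") tr <- forward_mean_fill(tr)
      fit <- grud_train(tr, variant = variant, config = config, seed = seed,
                        hidden = hidden)
      list(fit = fit, kept = flt$kept, stats = stats)
    },
    predict = function(fitted, tensors) {
      tt <- prep(tensors, fitted$kept, fitted$stats)
      predict(fitted$fit, tt)
    }
  )
}

#' Snapshot model adapters (logistic, tree, forest, boosting)
#'
#' Thin wrappers over established learners fitted on the per-stay
#' [last_day_snapshot()] features (static covariates, filled final-day
#' values, length of stay). The boosting configuration is 1000 rounds,
#' learning rate 0.01, maximum depth 6; the other engines use their
#' library defaults.
#'
#' @param engine One of `"logistic"`, `"tree"`, `"forest"`, `"xgboost"`.
#' @param max_missing Variable-filter threshold.
#' @return A `risk_model`.
#' @export
model_snapshot <- function(engine = c("logistic", "tree", "forest", "xgboost"),
                           max_missing = 0.5) {
  engine <- match.arg(engine)
  need <- c(tree = "rpart", forest = "ranger", xgboost = "xgboost")
  if (engine %in% names(need) && !requireNamespace(need[[engine]], quietly = TRUE)) {
    stop_posticu(sprintf("engine '%s' needs the %s package.", engine,
                         need[[engine]]), "dependency")
  }
  snap <- function(tensors, flt, stats) {
    tt <- restrict_channels(tensors, flt)
    tt <- apply_normalization(tt, stats)
    last_day_snapshot(forward_mean_fill(tt))
  }
  fit_engine <- function(df, seed) {
    dat <- df[setdiff(names(df), "stay_id")]
    x <- as.matrix(dat[setdiff(names(dat), "label")])
    switch(engine,
      logistic = glm(label ~ ., data = dat, family = binomial()),
      tree = {
        dat$label <- factor(dat$label, levels = c(0, 1))
        rpart::rpart(label ~ ., data = dat, method = "class")
      },
      forest = ranger::ranger(x = x, y = factor(dat$label, levels = c(0, 1)),
                              probability = TRUE, seed = seed,
                              num.threads = 1),
      xgboost = xgboost::xgb.train(
        params = list(eta = 0.01, max_depth = 6,
                      objective = "binary:logistic", nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = dat$label), nrounds = 1000)
    )
  }
  predict_engine <- function(fitobj, df) {
    dat <- df[setdiff(names(df), "stay_id")]
    x <- as.matrix(dat[setdiff(names(dat), "label")])
    switch(engine,
      logistic = as.numeric(predict(fitobj, newdata = dat, type = "response")),
      tree = as.numeric(predict(fitobj, newdata = dat)[, "1"]),
      forest = as.numeric(predict(fitobj, data = x,
                                  num.threads = 1)$predictions[, "1"]),
      xgboost = as.numeric(predict(fitobj, xgboost::xgb.DMatrix(x)))
    )
  }
  risk_model(
    name = c(logistic = "LR", tree = "DT", forest = "RF",
             xgboost = "XGB")[[engine]],
    fit = function(tensors, seed) {
      flt <- filter_variables(tensors, max_missing)
      stats <- fit_normalization(flt$tensors)
      df <- snap(tensors, flt$kept, stats)
      list(fit = fit_engine(df, seed), kept = flt$kept, stats = stats)
    },
    predict = function(fitted, tensors) {
      df <- snap(tensors, fitted$kept, fitted$stats)
      predict_engine(fitted$fit, df)
    }
  )
}

#' Fixed-score model adapter
#'
#' Wraps a precomputed per-stay score table (the latent-severity oracle, the
#' SWIFT score, or any external score) as a model whose training is a no-op.
#' Its cross-validated standard deviation across folds reflects only fold
#' composition, and is zero in expectation-free checks where every fold sees
#' the same deterministic score.
#'
#' @param scores A tibble `stay_id`, `score`.
#' @param name Display name.
#' @return A `risk_model`.
#' @export
model_fixed_score <- function(scores, name = "fixed") {
  risk_model(
    name = name,
    fit = function(tensors, seed) NULL,
    predict = function(fitted, tensors) {
      s <- scores$score[match(tensors$stay_id, scores$stay_id)]
      if (anyNA(s)) stop_posticu("fixed score missing for some stays.", "input")
      s
    }
  )
}

#' Stratified fold assignment
#'
#' @param labels Binary 0/1 outcomes.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return An integer fold id per stay; within each class, fold sizes differ
#'   by at most one.
#' @export
cv_folds <- function(labels, k, seed = 1) {
  if (k < 2 || k > length(labels)) {
    stop_posticu("`k` must lie in [2, n].", "config")
  }
  local_seed(derive_seed(seed, 11L), {
    fold <- integer(length(labels))
    start <- 0L
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' Stay-level stratified folds; each fold's model is fitted on the remaining
#' folds with the model adapter's own inner preprocessing and 10%
#' model-selection split, then scored on the held-out fold. AUROC and AUPR
#' are reported per fold with the across-fold mean and standard deviation.
#'
#' @param tensors Raw `stay_tensors` (the adapter preprocesses per fold).
#' @param model A `risk_model`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @return An `eval_report` tibble (`fold`, `n_test`, `auroc`, `aupr`) with
#'   out-of-fold scores attached as attribute `"scores"`; see
#'   [glance.eval_report()].
#' @export
kfold_cv <- function(tensors, model, k = 10, seed = 1) {
  labels <- tensors$label
  if (min(table(labels)) < k) {
    stop_posticu("fewer positives (or negatives) than folds; a fold would lack a class.",
                 "degenerate")
  }
  fold <- cv_folds(labels, k, seed)
  rows <- vector("list", k)
  scores_l <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- tensors[fold != f, ]
    te <- tensors[fold == f, ]
    fitted <- model$fit(tr, derive_seed(seed, 100L + f))
    sc <- model$predict(fitted, te)
    rows[[f]] <- tibble::tibble(fold = f, n_test = nrow(te),
                                auroc = auroc(sc, te$label),
                                aupr = aupr(sc, te$label))
    scores_l[[f]] <- tibble::tibble(stay_id = te$stay_id, fold = f,
                                    score = sc, label = te$label)
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
            class = c("eval_report", class(out)),
            model = model$name, seed = seed, mode = "internal-cv",
            scores = dplyr::bind_rows(scores_l))
}

#' Zero-shot evaluation of a fitted adapter on an external cohort
#'
#' Scores an external site's stays with a model fitted elsewhere (no
#' retraining, no refitted preprocessing), reporting a single-fold
#' `eval_report` whose mode is named `"zero-shot"` to distinguish it from
#' site-internal cross-validation.
#'
#' @param fitted The object returned by a `risk_model`'s `fit`.
#' @param model The `risk_model` that produced it.
#' @param tensors External-site raw `stay_tensors`.
#' @return An `eval_report`.
#' @export
evaluate_zero_shot <- function(fitted, model, tensors) {
  sc <- model$predict(fitted, tensors)
  out <- tibble::tibble(fold = 1L, n_test = nrow(tensors),
                        auroc = auroc(sc, tensors$label),
                        aupr = aupr(sc, tensors$label))
  structure(out, class = c("eval_report", class(out)),
            model = model$name, seed = NA_integer_, mode = "zero-shot",
            scores = tibble::tibble(stay_id = tensors$stay_id, fold = 1L,
                                    score = sc, label = tensors$label))
}
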