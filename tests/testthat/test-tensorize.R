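test_that("daily bins average repeated measurements and flag empty bins missing", {
  stays <- default_stay("A", icu_out = day_time(2))
  events <- tibble::tibble(
    stay_id = "A", channel = "hr",
    time = c(day_time(0.2), day_time(0.6), day_time(1.5)),
    value = c(80, 90, 70)
  )
  tens <- daily_aggregate(mini_cohort(stays, events),
                          channels = c("hr", "gcs"))
  X <- tens$X[[1]]; M <- tens$M[[1]]
  expect_equal(unname(X[1, "hr"]), 85)  # mean of 80 and 90
  expect_equal(unname(X[2, "hr"]), 70)
  expect_equal(M[, "hr"], c(1, 1))
  expect_equal(M[, "gcs"], c(0, 0))     # never charted
  expect_true(all(is.nan(X[, "gcs"])))  # sentinel, never data
  expect_equal(tens$n_days, 2L)
})

test_that("treatment channels are any-event-in-bin indicators and never missing", {
  stays <- default_stay("A", icu_out = day_time(2))
  events <- tibble::tibble(stay_id = "A", channel = "vasopressor",
                           time = day_time(0.4), value = 1)
  tens <- daily_aggregate(mini_cohort(stays, events),
                          channels = c("hr", "vasopressor"),
                          treatment_channels = "vasopressor")
  expect_equal(tens$X[[1]][, "vasopressor"], c(1, 0))
  expect_equal(tens$M[[1]][, "vasopressor"], c(1, 1))
})

test_that("events outside the stay interval are an error", {
  stays <- default_stay("A", icu_out = day_time(2))
  events <- tibble::tibble(stay_id = "A", channel = "hr",
                           time = day_time(2.5), value = 80)
  expect_error(daily_aggregate(mini_cohort(stays, events), channels = "hr"),
               class = "posticu_input")
})

test_that("staleness follows the recursive definition and matches a brute-force scan", {
  M <- matrix(c(1, 0, 0, 1), 4, 1)
  expect_equal(compute_delta(M)[, 1], c(0, 1, 2, 3))
  withr::with_seed(42, {
    for (rep in 1:300) {
      nr <- sample(1:6, 1); nc <- sample(1:4, 1)
      M <- matrix(rbinom(nr * nc, 1, runif(1)), nr, nc)
      expect_equal(unname(compute_delta(M)), brute_delta(M))
    }
  })
})

test_that("the variable filter keeps channels strictly below the threshold", {
  # plant exact pooled missing rates on a single 100-day stay
  rates <- c(a = 0.20, b = 0.50, c = 0.49, d = 0.70)
  M <- sapply(rates, function(r) rep(c(0, 1), c(100 * r, 100 * (1 - r))))
  X <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, names(rates)))
  X[M == 0] <- NaN
  Dl <- compute_delta(M)
  tens <- posticu:::new_stay_tensors(
    tibble::tibble(stay_id = "S", n_days = 100L, X = list(X), M = list(M),
                   Delta = list(Dl), age = 50, sex = 1,
                   los_days = 100, label = 0L),
    channels = names(rates), treatment_channels = character())
  flt <- filter_variables(tens)
  expect_identical(flt$kept, c("a", "c"))
  expect_equal(unname(flt$rates), unname(rates))
  # rate 0 everywhere: identity
  M1 <- matrix(1, 10, 2, dimnames = list(NULL, c("x", "y")))
  t1 <- posticu:::new_stay_tensors(
    tibble::tibble(stay_id = "S", n_days = 10L,
                   X = list(matrix(rnorm(20), 10, 2,
                                   dimnames = list(NULL, c("x", "y")))),
                   M = list(M1), Delta = list(compute_delta(matrix(1, 10, 2))),
                   age = 50, sex = 1, los_days = 10, label = 0L),
    channels = c("x", "y"), treatment_channels = character())
  expect_identical(filter_variables(t1)$kept, c("x", "y"))
  expect_error(filter_variables(tens, max_missing = 0.1),
               class = "posticu_degenerate")
})

test_that("normalization uses the population-variance convention on observed entries only", {
  M <- matrix(1, 3, 1, dimnames = list(NULL, "a"))
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  Dl <- compute_delta(M)
  tens <- posticu:::new_stay_tensors(
    tibble::tibble(stay_id = "S", n_days = 3L, X = list(X), M = list(M),
                   Delta = list(Dl), age = 50, sex = 1,
                   los_days = 3, label = 0L),
    channels = "a", treatment_channels = character())
  stats <- fit_normalization(tens)
  out <- apply_normalization(tens, stats)
  expect_equal(out$X[[1]][, "a"],
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  expect_error(apply_normalization(out, stats), class = "posticu_renormalize")
})

test_that("observed entries of a normalized training split have mean 0 and unit variance", {
  tens <- make_tensors(n = 40, seed = 3)
  stats <- fit_normalization(tens)
  out <- apply_normalization(tens, stats)
  for (d in seq_along(attr(out, "channels"))) {
    vals <- unlist(lapply(seq_len(nrow(out)), function(i) {
      x <- out$X[[i]][, d]; x[out$M[[i]][, d] == 1]
    }))
    expect_lt(abs(mean(vals)), 1e-9)
    expect_lt(abs(mean(vals^2) - 1), 1e-9)
  }
  # a disjoint split normalized with these stats is generally off-center
  test_tens <- make_tensors(n = 40, seed = 99)
  tout <- apply_normalization(test_tens, stats)
  vals <- unlist(lapply(seq_len(nrow(tout)), function(i) {
    x <- tout$X[[i]][, 1]; x[tout$M[[i]][, 1] == 1]
  }))
  expect_gt(abs(mean(vals)), 1e-6)
})

test_that("a constant channel is rejected by name", {
  M <- matrix(1, 5, 1, dimnames = list(NULL, "flatline"))
  X <- matrix(7, 5, 1, dimnames = list(NULL, "flatline"))
  Dl <- compute_delta(M)
  tens <- posticu:::new_stay_tensors(
    tibble::tibble(stay_id = "S", n_days = 5L, X = list(X), M = list(M),
                   Delta = list(Dl), age = 50, sex = 1,
                   los_days = 5, label = 0L),
    channels = "flatline", treatment_channels = character())
  expect_error(fit_normalization(tens), "flatline",
               class = "posticu_degenerate")
})

test_that("forward fill carries the last observation and mean-fills leading gaps", {
  M <- matrix(c(1, 0, 0,
                0, 1, 0), 3, 2, dimnames = list(NULL, c("p", "q")))
  X <- matrix(c(5, NaN, NaN,
                NaN, 3, NaN), 3, 2, dimnames = list(NULL, c("p", "q")))
  Dl <- compute_delta(M)
  tens <- posticu:::new_stay_tensors(
    tibble::tibble(stay_id = "S", n_days = 3L, X = list(X), M = list(M),
                   Delta = list(Dl), age = 50, sex = 1,
                   los_days = 3, label = 0L),
    channels = c("p", "q"), treatment_channels = character())
  stats <- list(channels = tibble::tibble(
    channel = c("p", "q"), kind = "numeric", mean = 0, sd = 1,
    xbar = c(0, 1)), age_mean = 50, age_sd = 1)
  filled <- forward_mean_fill(tens, stats)
  expect_equal(filled$X[[1]][, "p"], c(5, 5, 5))
  expect_equal(filled$X[[1]][, "q"], c(1, 3, 3))
  expect_true(all(filled$M[[1]] == 1))
  expect_true(all(filled$Delta[[1]] == 0))
})

test_that("the last-day snapshot is a fixed-length static + final-day + LOS vector", {
  tens <- make_tensors(n = 12, seed = 8, normalized = TRUE)
  filled <- forward_mean_fill(tens)
  snap <- last_day_snapshot(filled)
  D <- length(attr(tens, "channels"))
  expect_equal(ncol(snap) - 2, D + 3)  # stay_id + label excluded
  # a single-day stay snapshot equals its only day
  one <- filled[filled$n_days == 1, ]
  if (nrow(one) > 0) {
    s1 <- last_day_snapshot(one)
    expect_equal(unname(unlist(s1[1, attr(tens, "channels")])),
                 unname(one$X[[1]][1, ]))
  }
  # identical final day, different history: identical snapshot features
  X1 <- filled$X[[1]]
  i2 <- which(filled$n_days == nrow(X1))[1]
  expect_error(last_day_snapshot(tens), class = "posticu_input")
})
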