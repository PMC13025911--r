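test_that("identical configuration and seed reproduce the cohort byte for byte", {
  cfg <- sim_config(n_stays = 60, seed = 404)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$stays, b$stays)
  expect_identical(a$readmissions, b$readmissions)
  expect_identical(a$severity, b$severity)
})

test_that("with missingness switched off every daily bin of every channel is observed", {
  ch <- sim_channels_default()
  ch$miss_rate <- 0
  ch$mechanism <- "MCAR"
  ch$day1_missing <- FALSE
  cfg <- suppressWarnings(sim_config(
    n_stays = 30, seed = 2, channels = ch,
    planned_readmit_frac = 0, under24h_frac = 0, icu_death_frac = 0,
    transfer_frac = 0, under18_frac = 0))
  co <- suppressWarnings(generate_cohort(cfg))
  sel <- select_cohort(co)
  tens <- daily_aggregate(sel$cohort)
  expect_true(all(vapply(tens$M, function(m) all(m == 1), logical(1))))
})

test_that("realized per-channel missing rates track the configured rates within 3 points", {
  co <- cached_cohort(1500, 7, planned_readmit_frac = 0)
  sel <- select_cohort(merge_planned_readmissions(co))
  tens <- daily_aggregate(sel$cohort)
  ch <- co$config$channels
  channels <- attr(tens, "channels")
  Mall <- do.call(rbind, tens$M)
  day1 <- unlist(lapply(tens$M, function(m) seq_len(nrow(m)) == 1))
  for (j in which(ch$kind == "numeric")) {
    d <- match(ch$name[j], channels)
    keep_rows <- if (ch$day1_missing[j]) !day1 else rep(TRUE, nrow(Mall))
    realized <- 1 - mean(Mall[keep_rows, d])
    expect_lt(abs(realized - ch$miss_rate[j]), 0.03,
              label = sprintf("channel %s realized %.3f configured %.3f",
                              ch$name[j], realized, ch$miss_rate[j]))
  }
})

test_that("empirical outcome rate matches the logistic-normal closed-form expectation", {
  co <- cached_cohort(2000, 11)
  cfg <- co$config
  expected <- integrate(function(s) {
    plogis(cfg$outcome_intercept + cfg$outcome_coeff * s) * dnorm(s)
  }, -Inf, Inf)$value
  sel <- select_cohort(merge_planned_readmissions(co))
  labs <- label_outcome(sel$cohort)
  expect_lt(abs(mean(labs$label) - expected), 0.02)
})

test_that("value-dependent observation recovers the configured MNAR sign, MCAR shows none", {
  co <- cached_cohort(1500, 7, planned_readmit_frac = 0)
  sel <- select_cohort(merge_planned_readmissions(co))
  tens <- daily_aggregate(sel$cohort)
  sev <- co$severity
  channels <- attr(tens, "channels")
  mask_vs_sev <- function(channel) {
    d <- match(channel, channels)
    rows <- lapply(seq_len(nrow(tens)), function(i) {
      m <- tens$M[[i]][, d]
      s <- sev$severity[sev$stay_id == tens$stay_id[i]][seq_along(m)]
      keep <- seq_along(m) > 1  # skip structural day-1 missingness
      tibble::tibble(obs = m[keep], sev = s[keep])
    })
    df <- dplyr::bind_rows(rows)
    coef(glm(obs ~ sev, data = df, family = binomial()))[["sev"]]
  }
  # wbc: MNAR with positive value coefficient and positive severity loading
  expect_gt(mask_vs_sev("wbc"), 0.1)
  # sodium: MCAR, no severity dependence
  expect_lt(abs(mask_vs_sev("sodium")), 0.1)
})

test_that("planted special-case counts are exact when proportions are integral", {
  co <- cached_cohort(400, 5)
  tab <- table(co$stays$planted_category)
  expect_equal(unname(tab[["under18"]]), 4)
  expect_equal(unname(tab[["under24h"]]), 10)
  expect_equal(unname(tab[["icu_death"]]), 12)
  expect_equal(unname(tab[["transfer"]]), 8)
  expect_equal(unname(tab[["planned_readmit"]]), 16)
})

test_that("the severity oracle matches independent pairwise counting and collapses to chance without signal", {
  co <- cached_cohort(800, 13)
  sel <- select_cohort(merge_planned_readmissions(co))
  labs <- label_outcome(sel$cohort)
  stays <- sel$cohort$stays
  fd <- ceiling(as.numeric(difftime(stays$icu_out, stays$icu_in,
                                    units = "days")) - 1e-9)
  sev <- co$severity
  sT <- sev$severity[match(paste(stays$stay_id, fd),
                           paste(sev$stay_id, sev$day))]
  expect_equal(oracle_auroc(co), brute_auroc(sT, labs$label), tolerance = 1e-12)

  co0 <- cached_cohort(1200, 17, outcome_coeff = 0)
  expect_lt(abs(oracle_auroc(co0) - 0.5), 0.06)

  no_truth <- co
  no_truth$severity <- NULL
  expect_error(oracle_auroc(no_truth), class = "posticu_input")
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_stays = 0), class = "posticu_config")
  expect_error(sim_config(latent_ar_coeff = 1.2), class = "posticu_config")
  expect_error(sim_config(under18_frac = 0.5, icu_death_frac = 0.6),
               class = "posticu_config")
  ch <- sim_channels_default()
  ch$miss_rate[1] <- 1.4
  expect_error(sim_config(channels = ch), class = "posticu_config")
})
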