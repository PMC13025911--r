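swift_inputs_fixture <- function(admission_source = "ward", icu_los = 5,
                                 gcs = 9, pf = 120, sf = NA, paco2 = 50) {
  structure(list(admission_source = admission_source, icu_los = icu_los,
                 gcs = gcs, pf_ratio = pf, sf_ratio = sf, paco2 = paco2,
                 provenance = c(admission_source = "measured",
                                icu_los = "measured", gcs = "measured",
                                oxygenation = "measured",
                                paco2 = "measured")),
            class = "swift_inputs")
}

test_that("the packaged table reproduces hand-summed scores and spans 0 to 64", {
  tab <- swift_table_default()
  expect_equal(tab$version, "gajic-2008-v1")
  # ward (8) + 5-day stay (1) + GCS 9 (14) + P/F 120 (10) + PaCO2 50 (5)
  res <- compute_swift(swift_inputs_fixture(), tab)
  expect_equal(res$score, 38L)
  expect_equal(unname(res$breakdown),
               c(8L, 1L, 14L, 10L, 5L))
  # all lowest-risk bins
  best <- compute_swift(swift_inputs_fixture("emergency", 1, 15, 450, NA, 40),
                        tab)
  expect_equal(best$score, 0L)
  # all worst bins
  worst <- compute_swift(swift_inputs_fixture("ward", 12, 3, 80, NA, 60), tab)
  expect_equal(worst$score, 64L)
})

test_that("each component is monotone: worse physiology never scores fewer points", {
  tab <- swift_table_default()
  pts <- function(...) compute_swift(swift_inputs_fixture(...), tab)$score
  # worsening GCS 15 -> 8 is non-decreasing
  scores <- vapply(c(15, 14, 10, 8, 5), function(g) {
    pts(gcs = g)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  # falling oxygenation ratio
  scores <- vapply(c(450, 300, 140, 90), function(r) pts(pf = r), numeric(1))
  expect_true(all(diff(scores) >= 0))
  # rising PaCO2 and longer stays
  expect_gte(pts(paco2 = 50), pts(paco2 = 40))
  expect_gte(pts(icu_los = 12), pts(icu_los = 5))
  # randomized inputs stay in the table's range
  withr::with_seed(71, {
    for (rep in 1:100) {
      s <- compute_swift(swift_inputs_fixture(
        admission_source = sample(c("emergency", "ward", "other-hospital",
                                    "operating-room"), 1),
        icu_los = rexp(1, 1 / 5), gcs = sample(3:15, 1),
        pf = runif(1, 50, 500), paco2 = runif(1, 25, 80)), tab)$score
      expect_gte(s, 0L); expect_lte(s, 64L)
    }
  })
})

test_that("out-of-domain inputs are rejected naming the component", {
  tab <- swift_table_default()
  expect_error(compute_swift(swift_inputs_fixture(gcs = 20), tab),
               class = "posticu_domain")
  expect_error(compute_swift(swift_inputs_fixture(admission_source = "home"),
                             tab), class = "posticu_domain")
})

test_that("unavailable components take the lowest-risk bin instead of excluding the stay", {
  tab <- swift_table_default()
  res <- compute_swift(swift_inputs_fixture(gcs = NA, pf = NA, paco2 = NA),
                       tab)
  expect_equal(unname(res$breakdown[c("gcs", "oxygenation", "paco2")]),
               c(0L, 0L, 0L))
})

test_that("discharge extraction forward-fills, flags carried values and uses the oximetry proxy", {
  stay <- default_stay("A", icu_out = day_time(5), admission_source = "ward")
  events <- tibble::tibble(
    stay_id = "A",
    channel = c("gcs", "spo2", "fio2", "paco2"),
    time = c(day_time(0.5), day_time(4.5), day_time(4.6), day_time(4.2)),
    value = c(12, 95, 0.4, 48)
  )
  inp <- extract_swift_inputs(stay, events)
  expect_equal(inp$gcs, 12)
  expect_equal(inp$provenance[["gcs"]], "carried-forward")  # day-1 value
  expect_true(is.na(inp$pf_ratio))
  expect_equal(inp$sf_ratio, 95 / 0.4)
  expect_equal(inp$provenance[["oxygenation"]], "proxy")
  expect_equal(inp$paco2, 48)
  expect_equal(inp$provenance[["paco2"]], "measured")
  # arterial gas present: P/F preferred over the proxy
  ev2 <- dplyr::bind_rows(events, tibble::tibble(
    stay_id = "A", channel = "pao2", time = day_time(4.7), value = 80))
  inp2 <- extract_swift_inputs(stay, ev2)
  expect_equal(inp2$pf_ratio, 80 / 0.4)
  expect_true(is.na(inp2$sf_ratio))
  # no inspired-oxygen record: room air assumed
  ev3 <- events[events$channel != "fio2", ]
  inp3 <- extract_swift_inputs(stay, ev3)
  expect_equal(inp3$sf_ratio, 95 / 0.21)
  # nothing at all: unavailable
  inp4 <- extract_swift_inputs(stay, events[0, ])
  expect_equal(inp4$provenance[["oxygenation"]], "unavailable")
})

test_that("proxy substitution changes only the oxygenation component of the breakdown", {
  tab <- swift_table_default()
  with_pf <- compute_swift(swift_inputs_fixture(pf = 120, sf = NA), tab)
  with_sf <- compute_swift(swift_inputs_fixture(pf = NA, sf = 300), tab)
  keep <- setdiff(names(with_pf$breakdown), "oxygenation")
  expect_equal(with_pf$breakdown[keep], with_sf$breakdown[keep])
  expect_false(with_pf$breakdown[["oxygenation"]] ==
                 with_sf$breakdown[["oxygenation"]])
})

test_that("the raw integer score discriminates a severity-linked cohort and ties are half-credited", {
  co <- cached_cohort(800, 13)
  sel <- select_cohort(merge_planned_readmissions(co))
  rep <- swift_auroc(sel$cohort)
  expect_gt(rep$auroc, 0.55)
  sc <- attr(rep, "scores")
  expect_equal(rep$auroc, brute_auroc(sc$score, sc$label), tolerance = 1e-12)
  # permuted labels: chance
  withr::with_seed(72, {
    perm <- replicate(20, auroc(sc$score, sample(sc$label)))
    expect_lt(abs(mean(perm) - 0.5), 0.05)
  })
})
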