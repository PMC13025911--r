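#' Default channel specification for the synthetic ICU-stay generator
#'
#' One row per monitored channel. Binary treatment channels are threshold
#' functions of latent severity and are never missing; numeric channels are
#' linear readouts of severity on a clinically plausible scale (location and
#' spread chosen to resemble routine ICU charting: vitals charted several
#' times a day with modest missingness, daily labs with heavy missingness,
#' plus consciousness (GCS) and sedation (SAS) scores). One lab (lactate) is
#' deliberately configured above the 50% missing-rate selection threshold,
#' and three labs are structurally unavailable on the first stay day
#' (results return the next morning), so both the variable filter and the
#' no-history imputation path are exercised by default.
#'
#' Columns: `name`; `kind` (`"numeric"` or `"treatment"`); `mu`, `scale`
#' (location/spread of the readout); `weight` (loading of the standardized
#' channel signal on latent severity); `noise_sd` (channel noise on the
#' standardized scale); `miss_rate` (target per-day missing probability);
#' `mechanism` (`"MCAR"` or `"MNAR"`); `mnar_coef` (log-odds of observation
#' per standardized unit of the realized value, MNAR only); `day1_missing`
#' (structurally unobserved on day 1); `lo`, `hi` (physiologic clamps);
#' `n_per_day` (measurements emitted per observed day); `treat_rate`
#' (marginal daily rate, treatment channels only).
#'
#' @return A tibble with one row per channel.
#' @export
sim_channels_default <- function() {
  tr <- function(name, rate) {
    tibble::tibble(
      name = name, kind = "treatment", mu = NA_real_, scale = NA_real_,
      weight = NA_real_, noise_sd = NA_real_, miss_rate = 0,
      mechanism = "MCAR", mnar_coef = 0, day1_missing = FALSE,
      lo = 0, hi = 1, n_per_day = 1L, treat_rate = rate
    )
  }
  nm <- function(name, mu, scale, weight, noise_sd, miss_rate,
                 mechanism = "MCAR", mnar_coef = 0, day1_missing = FALSE,
                 lo = -Inf, hi = Inf, n_per_day = 1L) {
    tibble::tibble(
      name = name, kind = "numeric", mu = mu, scale = scale, weight = weight,
      noise_sd = noise_sd, miss_rate = miss_rate, mechanism = mechanism,
      mnar_coef = mnar_coef, day1_missing = day1_missing, lo = lo, hi = hi,
      n_per_day = as.integer(n_per_day), treat_rate = NA_real_
    )
  }
  dplyr::bind_rows(
    tr("hfnc", 0.05), tr("ventilator", 0.04), tr("dialysis", 0.03),
    tr("vasopressor", 0.02), tr("sedation", 0.05), tr("transfusion", 0.04),
    nm("mbp", 85, 12, -0.40, 0.90, 0.25, lo = 40, hi = 140, n_per_day = 2),
    nm("hr", 84, 14, 0.60, 0.80, 0.25, lo = 30, hi = 180, n_per_day = 2),
    nm("rr", 19, 3.5, 0.60, 0.80, 0.25, lo = 8, hi = 45, n_per_day = 2),
    nm("bt", 36.8, 0.45, -0.20, 1.00, 0.25, lo = 34, hi = 41, n_per_day = 2),
    nm("spo2", 96.5, 2.0, -0.50, 0.90, 0.25, lo = 70, hi = 100, n_per_day = 2),
    nm("urine_output", 1500, 650, -0.50, 0.90, 0.25, lo = 0, hi = 6000),
    nm("hco3", 24, 4, -0.25, 1.00, 0.28, day1_missing = TRUE, lo = 5, hi = 45),
    nm("wbc", 9.5, 3.5, 0.60, 0.80, 0.28, mechanism = "MNAR",
       mnar_coef = 0.8, day1_missing = TRUE, lo = 1, hi = 40),
    nm("hemoglobin", 10.2, 1.8, -0.35, 1.00, 0.44, lo = 5, hi = 18),
    nm("platelet", 190, 80, -0.25, 1.00, 0.28, day1_missing = TRUE,
       lo = 10, hi = 600),
    nm("glucose", 125, 35, 0.35, 1.00, 0.42, lo = 40, hi = 400),
    nm("bun", 22, 12, 0.80, 0.70, 0.42, mechanism = "MNAR", mnar_coef = 0.8,
       lo = 3, hi = 120),
    nm("creatinine", 1.0, 0.55, 0.50, 0.90, 0.44, lo = 0.2, hi = 8),
    nm("sodium", 138.5, 4, 0.15, 1.00, 0.44, lo = 120, hi = 160),
    nm("potassium", 3.9, 0.4, 0.15, 1.00, 0.44, lo = 2.5, hi = 6.5),
    nm("gcs", 14.3, 1.6, -1.00, 0.65, 0.30, lo = 3, hi = 15),
    nm("sas", 4, 0.55, -0.45, 0.90, 0.44, lo = 1, hi = 7),
    nm("lactate", 1.8, 1.1, 0.60, 0.90, 0.60, mechanism = "MNAR",
       mnar_coef = 0.6, lo = 0.3, hi = 15)
  )
}

#' Configuration for the synthetic ICU-stay generator
#'
#' Defines the study conditions the generator emulates: a per-day latent
#' severity AR(1) process with unit stationary variance, channel readouts per
#' [sim_channels_default()], a logistic 7-day deterioration outcome on
#' severity at the discharge day (default intercept/slope solve the
#' logistic-normal integral for 7% prevalence), and planted exclusion
#' categories in fixed proportions so downstream cohort filters can be
#' audited exactly.
#'
#' @param n_stays Number of ICU stays to generate.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @param channels Channel specification tibble, see [sim_channels_default()].
#' @param latent_ar_coeff AR(1) coefficient of daily latent severity, in (0,1).
#' @param outcome_coeff Log-odds of deterioration per unit severity at the
#'   discharge day.
#' @param outcome_intercept Log-odds intercept of the outcome model.
#' @param planned_readmit_frac,under24h_frac,icu_death_frac,transfer_frac,under18_frac
#'   Proportions of stays planted in each special category. Planted counts are
#'   `round(frac * n_stays)` and are assigned, not sampled, so they are exact
#'   whenever the product is integral.
#' @param los_meanlog,los_sdlog Log-normal parameters of the continuous ICU
#'   length of stay in days (median `exp(los_meanlog)`).
#' @param site_shift Optional list of distribution shifts used to emulate an
#'   external hospital: `mu_shift` (channel means move by this many channel
#'   scales), `miss_shift` (added to numeric missing rates, capped at 0.49
#'   for retained channels), `intercept_shift` (added to the outcome
#'   intercept), `weight_jitter` (relative re-weighting of the channel
#'   severity loadings — strong loadings shrink, weak ones grow — concept
#'   drift that renormalization cannot remove).
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_stays = 2000, seed = 1,
                       channels = sim_channels_default(),
                       latent_ar_coeff = 0.7,
                       outcome_coeff = 1.5,
                       outcome_intercept = -3.4248,
                       planned_readmit_frac = 0.04,
                       under24h_frac = 0.025,
                       icu_death_frac = 0.03,
                       transfer_frac = 0.02,
                       under18_frac = 0.01,
                       los_meanlog = log(2.6),
                       los_sdlog = 0.75,
                       site_shift = NULL) {
  cfg <- structure(
    list(
      n_stays = as.integer(n_stays), seed = as.integer(seed),
      channels = channels, latent_ar_coeff = latent_ar_coeff,
      outcome_coeff = outcome_coeff, outcome_intercept = outcome_intercept,
      planned_readmit_frac = planned_readmit_frac,
      under24h_frac = under24h_frac, icu_death_frac = icu_death_frac,
      transfer_frac = transfer_frac, under18_frac = under18_frac,
      los_meanlog = los_meanlog, los_sdlog = los_sdlog
    ),
    class = "sim_config"
  )
  if (!is.null(site_shift)) {
    mu_shift <- site_shift$mu_shift %||% 0
    miss_shift <- site_shift$miss_shift %||% 0
    cfg$outcome_intercept <- cfg$outcome_intercept +
      (site_shift$intercept_shift %||% 0)
    num <- cfg$channels$kind == "numeric"
    cfg$channels$mu[num] <- cfg$channels$mu[num] +
      mu_shift * cfg$channels$scale[num]
    keepable <- num & cfg$channels$miss_rate < 0.5
    cfg$channels$miss_rate[keepable] <-
      pmin(cfg$channels$miss_rate[keepable] + miss_shift, 0.49)
    jit <- site_shift$weight_jitter %||% 0
    if (jit > 0) {
      # deterministic re-weighting: the risk signal moves away from the
      # channels that carry it at the source site (strong loadings shrink,
      # weak ones grow) — concept drift that mean/variance renormalization
      # cannot undo, which warm-started fine-tuning must absorb
      k <- which(num)
      strong <- rank(-abs(cfg$channels$weight[k]), ties.method = "first") <=
        length(k) / 2
      fac <- ifelse(strong, 1 - jit, 1 + jit)
      cfg$channels$weight[k] <- cfg$channels$weight[k] * fac
    }
  }
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    stop_posticu(sprintf("invalid `%s`: %s", field, msg), "config")
  }
  ch <- cfg$channels
  req <- c("name", "kind", "mu", "scale", "weight", "noise_sd", "miss_rate",
           "mechanism", "mnar_coef", "day1_missing", "lo", "hi",
           "n_per_day", "treat_rate")
  if (!all(req %in% names(ch))) {
    bad("channels", paste("missing columns:",
                          paste(setdiff(req, names(ch)), collapse = ", ")))
  }
  if (anyDuplicated(ch$name)) bad("channels", "duplicated channel names")
  if (!all(ch$kind %in% c("numeric", "treatment"))) {
    bad("channels", "kind must be 'numeric' or 'treatment'")
  }
  if (any(ch$miss_rate < 0 | ch$miss_rate > 1)) {
    bad("channels", "missing rates must lie in [0, 1]")
  }
  if (!all(ch$mechanism %in% c("MCAR", "MNAR"))) {
    bad("channels", "mechanism must be 'MCAR' or 'MNAR'")
  }
  if (!any(ch$miss_rate >= 0.5)) {
    warning("no channel has missing rate >= 0.5; the variable filter will not be exercised")
  }
  if (!any(ch$day1_missing)) {
    warning("no channel is structurally missing on day 1; the no-history path will not be exercised")
  }
  if (cfg$n_stays < 1) bad("n_stays", "must be positive")
  if (!(cfg$latent_ar_coeff > 0 && cfg$latent_ar_coeff < 1)) {
    bad("latent_ar_coeff", "must lie in (0, 1)")
  }
  props <- c(cfg$planned_readmit_frac, cfg$under24h_frac, cfg$icu_death_frac,
             cfg$transfer_frac, cfg$under18_frac)
  if (any(props < 0 | props > 1)) {
    bad("proportions", "all planted proportions must lie in [0, 1]")
  }
  excl <- cfg$under24h_frac + cfg$icu_death_frac + cfg$transfer_frac +
    cfg$under18_frac + cfg$planned_readmit_frac
  if (excl > 1) bad("proportions", "planted categories must sum to at most 1")
  if (cfg$los_sdlog <= 0) bad("los_sdlog", "must be positive")
  invisible(cfg)
}

# Solve the MNAR observation-model intercept so the marginal missing rate
# matches the configured one: E_z[plogis(a + k z)] = 1 - miss, z ~ N(0, 1).
mnar_intercept <- function(miss_rate, coef) {
  if (coef == 0) return(qlogis(1 - miss_rate))
  f <- function(a) {
    integrate(function(z) plogis(a + coef * z) * stats::dnorm(z),
              -Inf, Inf)$value - (1 - miss_rate)
  }
  uniroot(f, c(-15, 15), tol = 1e-10)$root
}

#' Generate a synthetic ICU cohort
#'
#' Draws `n_stays` seeded synthetic ICU stays: stay-level metadata, a
#' long-format event stream on a daily sampling grid, planned/unplanned
#' readmission events, and the per-day latent severity truth. Special-case
#' stays (age under 18, stay under 24 h, in-ICU death, transfer to a
#' specialized unit or operating room, planned surgical readmission) are
#' planted in the configured proportions with exact counts.
#'
#' @param config A [sim_config()] object.
#' @return An `icu_cohort` list with tibbles `stays`, `events`,
#'   `readmissions`, `severity`, and the generating `config`. Latent severity
#'   is present only for synthetic cohorts.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_stays
  ch <- cfg$channels
  phi <- cfg$latent_ar_coeff
  innov_sd <- sqrt(1 - phi^2)
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  day_s <- 86400

  # observation-model intercepts per channel (solved once so marginal
  # missing rates match the configured ones under either mechanism)
  ch$obs_intercept <- vapply(seq_len(nrow(ch)), function(i) {
    if (ch$kind[i] != "numeric") return(Inf)
    if (ch$mechanism[i] == "MNAR" && ch$mnar_coef[i] != 0) {
      mnar_intercept(ch$miss_rate[i], ch$mnar_coef[i])
    } else {
      qlogis(1 - ch$miss_rate[i])
    }
  }, numeric(1))
  ch$sig_sd <- sqrt(ch$weight^2 + ch$noise_sd^2)
  ch$mnar_k <- ifelse(ch$mechanism == "MNAR", ch$mnar_coef, 0)
  treat_tau <- qnorm(1 - ch$treat_rate) * sqrt(2)

  counts <- c(
    under18 = round(cfg$under18_frac * n),
    under24h = round(cfg$under24h_frac * n),
    icu_death = round(cfg$icu_death_frac * n),
    transfer = round(cfg$transfer_frac * n),
    planned_readmit = round(cfg$planned_readmit_frac * n)
  )
  cats <- sample(c(rep(names(counts), counts),
                   rep("standard", n - sum(counts))))

  ids <- sprintf("S%05d", seq_len(n))
  age <- integer(n); sex <- integer(n); src <- character(n)
  icu_in <- rep(origin, n); icu_out <- rep(origin, n)
  death_time <- rep(as.POSIXct(NA, tz = "UTC"), n)
  dest <- character(n)
  events_l <- vector("list", n)
  readmits_l <- vector("list", n)
  sev_l <- vector("list", n)

  for (i in seq_len(n)) {
    cat_i <- cats[i]
    age[i] <- if (cat_i == "under18") sample(1:17, 1) else {
      min(95L, max(18L, as.integer(round(rnorm(1, 66, 15)))))
    }
    sex[i] <- rbinom(1, 1, 0.56)
    src[i] <- sample(c("emergency", "ward", "other-hospital", "operating-room"),
                     1, prob = c(0.55, 0.25, 0.12, 0.08))
    icu_in[i] <- origin + runif(1, 0, 365) * day_s

    los1 <- switch(cat_i,
      under24h = runif(1, 0.27, 0.97),
      icu_death = runif(1, 2, 10),
      min(30, max(1.05, rlnorm(1, cfg$los_meanlog, cfg$los_sdlog)))
    )
    intervals <- rbind(c(0, los1))
    if (cat_i == "planned_readmit") {
      gap <- runif(1, 0.5, 3)
      dur2 <- runif(1, 1, 4)
      intervals <- rbind(intervals, c(los1 + gap, los1 + gap + dur2))
    }
    horizon <- max(intervals[, 2])
    t_total <- as.integer(ceiling(horizon - 1e-9))

    e <- rnorm(t_total, sd = innov_sd)
    e[1] <- rnorm(1)  # stationary start, unit variance
    s <- as.numeric(stats::filter(e, phi, method = "recursive"))

    events_l[[i]] <- sim_stay_events(ids[i], s, intervals, ch, treat_tau,
                                     icu_in[i], day_s)

    icu_out[i] <- icu_in[i] + los1 * day_s
    dest[i] <- "general-ward"
    if (cat_i == "icu_death") {
      death_time[i] <- icu_out[i]
      dest[i] <- NA_character_
    } else if (cat_i == "transfer") {
      dest[i] <- sample(c("specialized-unit", "operating-room"), 1)
    }

    rr <- NULL
    if (cat_i == "planned_readmit") {
      rr <- tibble::tibble(
        stay_id = ids[i],
        time = icu_in[i] + intervals[2, 1] * day_s,
        end_time = icu_in[i] + intervals[2, 2] * day_s,
        planned = TRUE
      )
    }

    if (!cat_i %in% c("icu_death", "transfer")) {
      final_out <- icu_in[i] + horizon * day_s
      p <- plogis(cfg$outcome_intercept + cfg$outcome_coeff * s[t_total])
      if (rbinom(1, 1, p) == 1) {
        t_ev <- final_out + runif(1, 0.2, 6.99) * day_s
        if (runif(1) < 0.6) {
          rr <- dplyr::bind_rows(rr, tibble::tibble(
            stay_id = ids[i], time = t_ev,
            end_time = as.POSIXct(NA, tz = "UTC"), planned = FALSE
          ))
        } else {
          death_time[i] <- t_ev
        }
      } else if (runif(1) < 0.08) {
        rr <- dplyr::bind_rows(rr, tibble::tibble(
          stay_id = ids[i], time = final_out + runif(1, 7.05, 28) * day_s,
          end_time = as.POSIXct(NA, tz = "UTC"), planned = FALSE
        ))
      }
    }
    readmits_l[[i]] <- rr
    sev_l[[i]] <- s
  }

  stays <- tibble::tibble(
    stay_id = ids, age = age, sex = sex, admission_source = src,
    icu_in = icu_in, icu_out = icu_out, death_time = death_time,
    discharge_destination = dest, planted_category = cats
  )
  severity <- tibble::tibble(
    stay_id = rep(ids, lengths(sev_l)),
    day = unlist(lapply(sev_l, seq_along), use.names = FALSE),
    severity = unlist(sev_l, use.names = FALSE)
  )
  new_icu_cohort(
    stays = stays,
    events = dplyr::bind_rows(events_l),
    readmissions = dplyr::bind_rows(readmits_l),
    severity = severity,
    config = cfg
  )
}

# Emit the long-format event stream for one stay (vectorized over the
# day x channel grid).
sim_stay_events <- function(id, s, intervals, ch, treat_tau, icu_in, day_s) {
  t_total <- length(s)
  # per-day overlap of bin [t-1, t) with the ICU interval(s)
  w_lo <- rep(NA_real_, t_total); w_hi <- rep(NA_real_, t_total)
  for (t in seq_len(t_total)) {
    lo <- pmax(intervals[, 1], t - 1)
    hi <- pmin(intervals[, 2], t)
    k <- which(hi - lo > 0.02)
    if (length(k) > 0) { w_lo[t] <- lo[k[1]]; w_hi[t] <- hi[k[1]] }
  }
  active <- which(!is.na(w_lo))
  if (length(active) == 0) return(NULL)

  num <- which(ch$kind == "numeric")
  nC <- length(num)
  day_v <- rep(active, each = nC)
  ch_v <- rep(num, times = length(active))
  sig <- ch$weight[ch_v] * s[day_v] + rnorm(length(ch_v), sd = ch$noise_sd[ch_v])
  p_obs <- plogis(ch$obs_intercept[ch_v] + ch$mnar_k[ch_v] * sig / ch$sig_sd[ch_v])
  obs <- runif(length(ch_v)) < p_obs
  obs[ch$day1_missing[ch_v] & day_v == 1] <- FALSE

  oc <- ch_v[obs]; od <- day_v[obs]; osig <- sig[obs]
  val1 <- pmin(pmax(ch$mu[oc] + ch$scale[oc] * osig, ch$lo[oc]), ch$hi[oc])
  t1 <- runif(length(oc), w_lo[od], w_hi[od])
  # extra same-day measurements for frequently charted channels
  extra <- which(ch$n_per_day[oc] > 1)
  oc2 <- oc[extra]; od2 <- od[extra]
  val2 <- pmin(pmax(ch$mu[oc2] + ch$scale[oc2] *
                      (ch$weight[oc2] * s[od2] +
                         rnorm(length(oc2), sd = ch$noise_sd[oc2])),
                    ch$lo[oc2]), ch$hi[oc2])
  t2 <- runif(length(oc2), w_lo[od2], w_hi[od2])

  tr <- which(ch$kind == "treatment")
  day_t <- rep(active, each = length(tr))
  ch_t <- rep(tr, times = length(active))
  flag <- (s[day_t] + rnorm(length(ch_t))) > treat_tau[ch_t]
  ct <- ch_t[flag]; dt <- day_t[flag]
  tt <- runif(length(ct), w_lo[dt], w_hi[dt])

  tibble::tibble(
    stay_id = id,
    channel = ch$name[c(oc, oc2, ct)],
    time = icu_in + c(t1, t2, tt) * day_s,
    value = c(val1, val2, rep(1, length(ct)))
  )
}

empty_readmissions <- function() {
  tibble::tibble(stay_id = character(), time = as.POSIXct(character(), tz = "UTC"),
                 end_time = as.POSIXct(character(), tz = "UTC"),
                 planned = logical())
}

new_icu_cohort <- function(stays, events, readmissions, severity = NULL,
                           config = NULL) {
  if (nrow(readmissions) == 0) readmissions <- empty_readmissions()
  structure(
    list(stays = stays, events = events, readmissions = readmissions,
         severity = severity, config = config),
    class = "icu_cohort"
  )
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort> ", nrow(x$stays), " stays, ",
      nrow(x$events), " events, ",
      sum(!x$readmissions$planned), " unplanned / ",
      sum(x$readmissions$planned), " planned readmission events",
      if (!is.null(x$severity)) " (synthetic: latent severity attached)",
      "\n", sep = "")
  invisible(x)
}

#' Bayes-ceiling AUROC of the latent severity truth
#'
#' Scores every kept stay by its true latent severity on the discharge day
#' and computes the AUROC against the realized 7-day deterioration labels.
#' Because the outcome is generated from a logistic model on exactly this
#' quantity, no trained model can systematically exceed it; it is the
#' reference ceiling for signal-recovery checks.
#'
#' @param cohort An `icu_cohort` carrying latent severity (synthetic only).
#' @param window_days Label window, days.
#' @return A length-one numeric AUROC.
#' @export
oracle_auroc <- function(cohort, window_days = 7) {
  if (is.null(cohort$severity) || nrow(cohort$severity) == 0) {
    stop_posticu("cohort carries no latent severity truth.", "input")
  }
  merged <- merge_planned_readmissions(cohort)
  sel <- select_cohort(merged)
  labs <- label_outcome(sel$cohort, window_days = window_days)
  stays <- sel$cohort$stays
  final_day <- ceiling(as.numeric(difftime(stays$icu_out, stays$icu_in,
                                           units = "days")) - 1e-9)
  key <- dplyr::left_join(
    tibble::tibble(stay_id = stays$stay_id, day = final_day),
    cohort$severity, by = c("stay_id", "day")
  )
  if (anyNA(key$severity)) {
    stop_posticu("latent severity missing for some discharge days.", "input")
  }
  scores <- key$severity[match(labs$stay_id, key$stay_id)]
  auroc(scores, labs$label)
}
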