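# Independent brute-force oracles. These deliberately use the most direct
# O(n^2) / enumeration definitions and share no code with the package.

brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive threshold sweep: precision/recall at every distinct score,
# step-wise area
brute_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(sel & labels == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# direct-definition DeLong placement components
brute_delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(x) {
    sum(x > neg) / n + 0.5 * sum(x == neg) / n
  }, numeric(1))
  v01 <- vapply(neg, function(y) {
    sum(pos > y) / m + 0.5 * sum(pos == y) / m
  }, numeric(1))
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

# staleness by explicit backward scan
brute_delta <- function(M) {
  out <- matrix(0, nrow(M), ncol(M))
  for (d in seq_len(ncol(M))) {
    for (t in seq_len(nrow(M))) {
      if (t == 1) { out[t, d] <- 0; next }
      k <- t - 1
      steps <- 1
      while (k >= 1 && M[k, d] == 0) { k <- k - 1; steps <- steps + 1 }
      out[t, d] <- if (k >= 1) steps else t - 1
    }
  }
  out
}

# Youden J evaluated at an explicit cut
j_at <- function(scores, labels, cut) {
  sens <- sum(scores >= cut & labels == 1) / sum(labels == 1)
  spec <- sum(scores < cut & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a minimal hand-built cohort for cohort/labeling tests
mini_cohort <- function(stays, events = NULL, readmissions = NULL) {
  t0 <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")
  if (is.null(events)) {
    events <- tibble::tibble(stay_id = character(), channel = character(),
                             time = t0[0], value = numeric())
  }
  if (is.null(readmissions)) {
    readmissions <- tibble::tibble(stay_id = character(), time = t0[0],
                                   end_time = t0[0], planned = logical())
  }
  posticu:::new_icu_cohort(stays, events, readmissions)
}

day_time <- function(days) {
  as.POSIXct("2021-06-01 00:00:00", tz = "UTC") + days * 86400
}

default_stay <- function(stay_id = "A", age = 60, sex = 1,
                         admission_source = "emergency",
                         icu_in = day_time(0), icu_out = day_time(3),
                         death_time = as.POSIXct(NA, tz = "UTC"),
                         discharge_destination = "general-ward") {
  tibble::tibble(stay_id = stay_id, age = age, sex = sex,
                 admission_source = admission_source, icu_in = icu_in,
                 icu_out = icu_out, death_time = death_time,
                 discharge_destination = discharge_destination)
}

# small synthetic stay_tensors built directly (independent of the generator)
make_tensors <- function(n = 20, channels = c("a", "b", "c"), seed = 1,
                         t_max = 4, normalized = FALSE, obs_prob = 0.7) {
  withr::with_seed(seed, {
    D <- length(channels)
    rows <- lapply(seq_len(n), function(i) {
      T_ <- sample(seq_len(t_max), 1)
      M <- matrix(rbinom(T_ * D, 1, obs_prob), T_, D,
                  dimnames = list(NULL, channels))
      X <- matrix(rnorm(T_ * D), T_, D, dimnames = list(NULL, channels))
      X[M == 0] <- NaN
      Dl <- posticu::compute_delta(M)
      tibble::tibble(stay_id = sprintf("T%03d", i), n_days = T_,
                     X = list(X), M = list(M),
                     Delta = list(Dl),
                     age = round(runif(1, 30, 90)), sex = rbinom(1, 1, 0.5),
                     los_days = T_ - runif(1, 0, 0.5),
                     label = rbinom(1, 1, 0.3))
    })
    out <- posticu:::new_stay_tensors(dplyr::bind_rows(rows),
                                      channels = channels,
                                      treatment_channels = character())
    if (normalized) {
      stats <- posticu::fit_normalization(out)
      out <- posticu::apply_normalization(out, stats)
    }
    out
  })
}

# cached generated cohorts shared across test files
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n, seed, ...) {
  key <- paste(n, seed, rlang::hash(list(...)), sep = "_")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- posticu::generate_cohort(
      posticu::sim_config(n_stays = n, seed = seed, ...))
  }
  .cohort_cache[[key]]
}

prepped_split <- function(cohort, test_frac = 0.3, seed = 1) {
  sel <- select_cohort(merge_planned_readmissions(cohort))
  tens <- daily_aggregate(sel$cohort)
  withr::with_seed(seed, {
    test_idx <- sample(nrow(tens), round(test_frac * nrow(tens)))
  })
  tr_raw <- tens[-test_idx, ]
  te_raw <- tens[test_idx, ]
  flt <- filter_variables(tr_raw)
  stats <- fit_normalization(flt$tensors)
  list(train = apply_normalization(flt$tensors, stats),
       test = apply_normalization(restrict_channels(te_raw, flt$kept), stats),
       kept = flt$kept, stats = stats, all = tens, cohort = sel$cohort)
}
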