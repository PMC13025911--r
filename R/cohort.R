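#' Merge planned surgical readmissions into one continuous stay
#'
#' A planned ICU return (a flagged interval in `readmissions`) is not a
#' deterioration event: it is concatenated with its parent stay — single stay
#' id, union time range (the ward gap stays inside the stay), events already
#' attributed to the stay, length of stay recomputed from the extended
#' discharge time. Unplanned readmission events are left untouched so the
#' labeler can see them.
#'
#' @param cohort An `icu_cohort`.
#' @return The cohort with planned intervals absorbed into their parent
#'   stays and removed from `readmissions`.
#' @export
merge_planned_readmissions <- function(cohort) {
  rr <- cohort$readmissions
  planned <- rr[rr$planned, , drop = FALSE]
  if (nrow(planned) == 0) return(cohort)
  stays <- cohort$stays
  for (i in seq_len(nrow(planned))) {
    j <- match(planned$stay_id[i], stays$stay_id)
    if (is.na(j)) {
      stop_posticu(sprintf("planned readmission for unknown stay '%s'.",
                           planned$stay_id[i]), "input")
    }
    if (is.na(planned$end_time[i])) {
      stop_posticu("planned readmission interval lacks an end time.", "input")
    }
    if (planned$time[i] <= stays$icu_out[j]) {
      stop_posticu(sprintf(
        "planned readmission interval overlaps parent stay '%s'.",
        planned$stay_id[i]), "overlap")
    }
    stays$icu_out[j] <- max(stays$icu_out[j], planned$end_time[i])
  }
  cohort$stays <- stays
  cohort$readmissions <- rr[!rr$planned, , drop = FALSE]
  cohort
}

#' Apply the cohort selection filters
#'
#' Keeps adult stays (age at ICU admission >= 18) of at least 24 h that ended
#' alive with discharge to a general ward. Removals are partitioned into an
#' audit table by first matching reason, in the order: missing admission or
#' discharge metadata, age under 18, stay under 24 h, death during the ICU
#' stay, discharge destination other than a general ward. Planned
#' readmissions should be merged with [merge_planned_readmissions()] first so
#' the length-of-stay filter sees the full continuous stay.
#'
#' @param cohort An `icu_cohort`.
#' @return A list: `cohort` (the kept stays, with events, readmissions and
#'   severity restricted to them) and `audit`, a tibble of `reason` / `n`
#'   whose counts sum to the number removed.
#' @export
select_cohort <- function(cohort) {
  stays <- cohort$stays
  reason <- rep(NA_character_, nrow(stays))
  meta_bad <- is.na(stays$icu_in) | is.na(stays$icu_out) | is.na(stays$age)
  reason[meta_bad] <- "missing_metadata"
  ok <- is.na(reason)
  reason[ok & stays$age < 18] <- "age_lt_18"
  ok <- is.na(reason)
  los_h <- as.numeric(difftime(stays$icu_out, stays$icu_in, units = "hours"))
  reason[ok & los_h < 24] <- "los_lt_24h"
  ok <- is.na(reason)
  died_in_icu <- !is.na(stays$death_time) & stays$death_time <= stays$icu_out
  reason[ok & died_in_icu] <- "icu_death"
  ok <- is.na(reason)
  not_ward <- is.na(stays$discharge_destination) |
    stays$discharge_destination != "general-ward"
  reason[ok & not_ward] <- "not_ward_transfer"

  keep <- is.na(reason)
  reasons_order <- c("missing_metadata", "age_lt_18", "los_lt_24h",
                     "icu_death", "not_ward_transfer")
  n_by_reason <- vapply(reasons_order,
                        function(r) sum(reason == r, na.rm = TRUE),
                        integer(1))
  audit <- tibble::tibble(reason = reasons_order, n = unname(n_by_reason))
  kept_ids <- stays$stay_id[keep]
  out <- cohort
  out$stays <- stays[keep, , drop = FALSE]
  out$events <- cohort$events[cohort$events$stay_id %in% kept_ids, , drop = FALSE]
  out$readmissions <- cohort$readmissions[
    cohort$readmissions$stay_id %in% kept_ids, , drop = FALSE]
  if (!is.null(cohort$severity)) {
    out$severity <- cohort$severity[cohort$severity$stay_id %in% kept_ids, ,
                                    drop = FALSE]
  }
  list(cohort = out, audit = audit)
}

#' Label the 7-day post-discharge deterioration outcome
#'
#' A stay is labeled 1 if an unplanned ICU readmission or a death occurs in
#' the window `(icu_out, icu_out + window_days]` — a closed right endpoint at
#' exactly `window_days` times 24 h — and 0 otherwise. Planned readmissions
#' never count (they should already have been merged away). A death time at
#' or before ICU discharge is an error: such stays belong to the in-ICU
#' mortality exclusion.
#'
#' @param cohort An `icu_cohort` that has passed [select_cohort()].
#' @param window_days Outcome window in days (default 7).
#' @return A tibble `stay_id`, `label` (integer 0/1).
#' @export
label_outcome <- function(cohort, window_days = 7) {
  stays <- cohort$stays
  if (any(!is.na(stays$death_time) & stays$death_time <= stays$icu_out)) {
    stop_posticu(
      "death during the ICU stay encountered at labeling; run select_cohort() first.",
      "input")
  }
  win_s <- window_days * 86400
  rr <- cohort$readmissions
  rr <- rr[!rr$planned, , drop = FALSE]
  readmit_hit <- vapply(seq_len(nrow(stays)), function(i) {
    k <- rr$stay_id == stays$stay_id[i]
    any(k & rr$time > stays$icu_out[i] &
          as.numeric(difftime(rr$time, stays$icu_out[i], units = "secs")) <= win_s)
  }, logical(1))
  death_hit <- !is.na(stays$death_time) &
    as.numeric(difftime(stays$death_time, stays$icu_out, units = "secs")) <= win_s
  tibble::tibble(stay_id = stays$stay_id,
                 label = as.integer(readmit_hit | death_hit))
}
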