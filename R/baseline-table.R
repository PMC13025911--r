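#' Per-stay characteristics in the 24 h before ICU discharge
#'
#' Builds the wide per-stay table the baseline-characteristics comparison
#' runs on: static covariates, each channel's most recent raw value at or
#' before discharge restricted to the final stay day (missing if nothing was
#' charted that day), treatment flags as any-use on the final day, and the
#' length of stay.
#'
#' @param cohort A selected `icu_cohort` (raw units).
#' @return A tibble: `stay_id`, `age`, `sex`, `los`, then one column per
#'   channel.
#' @export
stay_characteristics <- function(cohort) {
  stays <- cohort$stays
  channels <- if (!is.null(cohort$config)) {
    cohort$config$channels$name
  } else {
    sort(unique(cohort$events$channel))
  }
  treat <- if (!is.null(cohort$config)) {
    cohort$config$channels$name[cohort$config$channels$kind == "treatment"]
  } else {
    character()
  }
  ev <- cohort$events
  si <- match(ev$stay_id, stays$stay_id)
  in_final <- ev$time <= stays$icu_out[si] &
    ev$time >= stays$icu_out[si] - 86400
  ev <- ev[in_final, , drop = FALSE]
  wide <- ev |>
    dplyr::arrange(.data$time) |>
    dplyr::summarise(value = dplyr::last(.data$value),
                     .by = c("stay_id", "channel")) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  out <- tibble::tibble(stay_id = stays$stay_id, age = stays$age,
                        sex = stays$sex,
                        los = as.numeric(difftime(stays$icu_out, stays$icu_in,
                                                  units = "days"))) |>
    dplyr::left_join(wide, by = "stay_id")
  for (ch in setdiff(channels, names(out))) out[[ch]] <- NA_real_
  for (ch in treat) out[[ch]] <- as.integer(!is.na(out[[ch]]) & out[[ch]] > 0)
  out[c("stay_id", "age", "sex", "los", channels)]
}

#' Baseline-characteristics comparison between outcome groups
#'
#' Numeric variables are summarized as median (IQR) per group and compared
#' with the two-sided Mann-Whitney U test; binary variables as count (%)
#' with the two-sided Fisher exact test. A per-variable missing-rate column
#' is included. Variables absent in both groups are omitted with a warning.
#' With identical groups the exact tests return p = 1.
#'
#' @param data A wide per-stay tibble (see [stay_characteristics()]).
#' @param group A binary 0/1 vector aligned with rows (1 = deterioration).
#' @param binary_vars Names of binary variables; defaults to columns with
#'   values in {0, 1}.
#' @return A `baseline_table` tibble: `variable`, `type`, `summary_success`,
#'   `summary_failure`, `missing_rate`, `p_value`.
#' @export
baseline_table <- function(data, group,
                           binary_vars = NULL) {
  if (length(group) != nrow(data)) {
    stop_posticu("`group` must align with `data` rows.", "input")
  }
  if (length(unique(group)) < 2) {
    stop_posticu("both groups must be non-empty.", "degenerate")
  }
  vars <- setdiff(names(data), "stay_id")
  if (is.null(binary_vars)) {
    binary_vars <- vars[vapply(vars, function(v) {
      x <- data[[v]]
      is.numeric(x) && all(x %in% c(0, 1, NA))
    }, logical(1))]
  }
  fmt_num <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
  }
  fmt_bin <- function(x) {
    sprintf("%d (%.2f%%)", sum(x == 1, na.rm = TRUE),
            100 * mean(x == 1, na.rm = TRUE))
  }
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    g1 <- x[group == 1]; g0 <- x[group == 0]
    if (all(is.na(g1)) && all(is.na(g0))) {
      warning(sprintf("variable '%s' absent in both groups; omitted.", v))
      return(NULL)
    }
    miss <- mean(is.na(x))
    if (v %in% binary_vars) {
      tabm <- matrix(c(sum(g0 == 1, na.rm = TRUE), sum(g0 == 0, na.rm = TRUE),
                       sum(g1 == 1, na.rm = TRUE), sum(g1 == 0, na.rm = TRUE)),
                     2, 2)
      p <- fisher.test(tabm)$p.value
      tibble::tibble(variable = v, type = "binary",
                     summary_success = fmt_bin(g0),
                     summary_failure = fmt_bin(g1),
                     missing_rate = miss, p_value = p)
    } else {
      p <- suppressWarnings(
        wilcox.test(g1, g0, correct = FALSE)$p.value)
      tibble::tibble(variable = v, type = "numeric",
                     summary_success = fmt_num(g0),
                     summary_failure = fmt_num(g1),
                     missing_rate = miss, p_value = p)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("baseline_table", class(out)))
}
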