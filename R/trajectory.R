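#' Group-mean risk trajectories around admission or discharge
#'
#' Aligns per-stay daily risk trajectories at the chosen anchor (offset 0 is
#' the first day when aligned at admission, the final day when aligned at
#' discharge, with negative offsets reaching back in time) and summarizes
#' each outcome group per offset: mean, normal-approximation 95% band over
#' the stays contributing to that offset. A single contributing stay yields
#' a zero-width band, flagged degenerate.
#'
#' @param trajectories Output of [risk_trajectory()]: `stay_id`, `label`,
#'   `day`, `n_days`, `risk`.
#' @param align `"discharge"` (default) or `"admission"`.
#' @return A `trajectory_summary` tibble: `group`, `offset`, `n`, `mean`,
#'   `lower`, `upper`, `degenerate`.
#' @export
trajectory_summary <- function(trajectories, align = c("discharge", "admission")) {
  align <- match.arg(align)
  if (nrow(trajectories) == 0) {
    stop_posticu("no trajectories to summarize.", "input")
  }
  tr <- trajectories |>
    dplyr::mutate(
      offset = if (align == "discharge") .data$day - .data$n_days else .data$day - 1L,
      group = ifelse(.data$label == 1, "failure", "success")
    )
  if (length(unique(tr$group)) < 2) {
    stop_posticu("both outcome groups must be non-empty.", "degenerate")
  }
  out <- tr |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$risk),
      se = ifelse(dplyr::n() > 1, stats::sd(.data$risk) / sqrt(dplyr::n()), 0),
      .by = c("group", "offset")
    ) |>
    dplyr::mutate(lower = pmax(0, .data$mean - 1.96 * .data$se),
                  upper = pmin(1, .data$mean + 1.96 * .data$se),
                  degenerate = .data$n < 2) |>
    dplyr::select("group", "offset", "n", "mean", "lower", "upper",
                  "degenerate") |>
    dplyr::arrange(.data$group, .data$offset)
  structure(out, class = c("trajectory_summary", class(out)), align = align)
}
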