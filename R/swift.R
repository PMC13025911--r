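#' The packaged SWIFT point table
#'
#' The Stability and Workload Index for Transfer assigns integer points to
#' five components at ICU discharge: admission source, total ICU length of
#' stay, the last Glasgow Coma Scale, the most recent PaO2/FiO2 ratio, and
#' the most recent PaCO2. The packaged cut-points and points follow the
#' original 2008 derivation (maximum 64 points); a parallel bin set for the
#' SpO2/FiO2 oxygenation proxy uses ratio-conversion-derived cut-points, so
#' the proxy is consumed untransformed. The table ships as versioned JSON so
#' alternative codings can be swapped in; all packaged-score tests pin this
#' version.
#'
#' @param path Optional path to a JSON table overriding the packaged one.
#' @return A `swift_table` list: `version`, and per-component `breaks` /
#'   `points` (bins are left-closed `[a, b)`; the outer breaks are infinite).
#' @export
swift_table_default <- function(path = NULL) {
  path <- path %||% system.file("extdata", "swift_table.json",
                                package = "posticu")
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(tab$components)) {
    if (!is.null(tab$components[[nm]]$breaks)) {
      tab$components[[nm]]$breaks <- as.numeric(tab$components[[nm]]$breaks)
    }
  }
  validate_swift_table(tab)
  structure(tab, class = "swift_table")
}

validate_swift_table <- function(tab) {
  comp <- c("admission_source", "icu_los", "gcs", "pf_ratio", "sf_ratio",
            "paco2")
  if (!all(comp %in% names(tab$components))) {
    stop_posticu("SWIFT table must define all five components (plus the proxy bins).",
                 "config")
  }
  for (nm in setdiff(comp, "admission_source")) {
    cp <- tab$components[[nm]]
    if (length(cp$points) != length(cp$breaks) - 1) {
      stop_posticu(sprintf("SWIFT component '%s': breaks/points mismatch.", nm),
                   "config")
    }
    if (any(cp$points < 0) || any(cp$points != round(cp$points))) {
      stop_posticu(sprintf("SWIFT component '%s': points must be nonnegative integers.",
                           nm), "config")
    }
  }
  invisible(tab)
}

swift_bin_points <- function(value, comp) {
  # left-closed bins: [breaks[i], breaks[i+1])
  i <- findInterval(value, comp$breaks)
  if (i < 1 || i > length(comp$points)) {
    return(NA_integer_)
  }
  comp$points[i]
}

#' Extract SWIFT inputs for one stay at discharge
#'
#' Each component takes its most recent value at or before ICU discharge
#' (forward filling across the stay), with a provenance flag: `measured`
#' when the value comes from the final stay day, `carried-forward` when an
#' older value is carried, `proxy` when SpO2/FiO2 substitutes for an
#' unavailable PaO2/FiO2, and `unavailable` when no value exists at all.
#' When no inspired-oxygen fraction is charted, room air (FiO2 0.21) is
#' assumed and flagged. Oxygenation uses PaO2/FiO2 whenever any arterial gas
#' exists, else the SpO2/FiO2 proxy.
#'
#' @param stay One row of a cohort's `stays` table.
#' @param events The cohort's events, or just this stay's.
#' @param channel_map Channel-name mapping with entries `gcs`, `pao2`,
#'   `paco2`, `spo2`, `fio2`.
#' @return A `swift_inputs` list: `admission_source`, `icu_los` (days),
#'   `gcs`, `pf_ratio`, `sf_ratio`, `paco2` (each possibly `NA`), and a
#'   per-component `provenance` character vector.
#' @export
extract_swift_inputs <- function(stay, events,
                                 channel_map = list(gcs = "gcs", pao2 = "pao2",
                                                    paco2 = "paco2",
                                                    spo2 = "spo2",
                                                    fio2 = "fio2")) {
  ev <- events[events$stay_id == stay$stay_id &
                 events$time <= stay$icu_out, , drop = FALSE]
  final_day_start <- stay$icu_out - 86400
  last_of <- function(channel) {
    e <- ev[ev$channel == channel, , drop = FALSE]
    if (nrow(e) == 0) return(list(value = NA_real_, prov = "unavailable"))
    j <- which.max(as.numeric(e$time))
    prov <- if (e$time[j] >= final_day_start) "measured" else "carried-forward"
    list(value = e$value[j], prov = prov)
  }
  gcs <- last_of(channel_map$gcs)
  pao2 <- last_of(channel_map$pao2)
  paco2 <- last_of(channel_map$paco2)
  spo2 <- last_of(channel_map$spo2)
  fio2 <- last_of(channel_map$fio2)
  fio2_val <- if (is.na(fio2$value)) 0.21 else fio2$value
  fio2_assumed <- is.na(fio2$value)

  pf <- NA_real_; sf <- NA_real_
  oxy_prov <- "unavailable"
  if (!is.na(pao2$value)) {
    pf <- pao2$value / fio2_val
    oxy_prov <- if (fio2_assumed) "room-air-assumed" else pao2$prov
  } else if (!is.na(spo2$value)) {
    sf <- spo2$value / fio2_val
    oxy_prov <- "proxy"
  }
  structure(
    list(
      admission_source = stay$admission_source,
      icu_los = as.numeric(difftime(stay$icu_out, stay$icu_in, units = "days")),
      gcs = gcs$value, pf_ratio = pf, sf_ratio = sf, paco2 = paco2$value,
      provenance = c(admission_source = "measured",
                     icu_los = "measured",
                     gcs = gcs$prov,
                     oxygenation = oxy_prov,
                     paco2 = paco2$prov)
    ),
    class = "swift_inputs")
}

#' Compute the SWIFT score from extracted inputs
#'
#' Sums the per-component points under the given table. Components flagged
#' unavailable score the lowest-risk bin (0 points under the packaged
#' table), recorded as such in the breakdown, so no stay is excluded for
#' missing data. GCS values outside 3-15 or other out-of-domain inputs are
#' errors naming the component.
#'
#' @param inputs A `swift_inputs` from [extract_swift_inputs()].
#' @param table A `swift_table` (default: the packaged one).
#' @return A list: integer `score` and named integer `breakdown`.
#' @export
compute_swift <- function(inputs, table = swift_table_default()) {
  comps <- table$components
  src_pts <- comps$admission_source$points
  if (!inputs$admission_source %in% names(src_pts)) {
    stop_posticu(sprintf("admission source '%s' outside the SWIFT table domain.",
                         inputs$admission_source), "domain")
  }
  p_src <- as.integer(src_pts[[inputs$admission_source]])

  num_pts <- function(value, comp_name, lowest_ok = TRUE) {
    comp <- comps[[comp_name]]
    if (is.na(value)) {
      return(if (lowest_ok) min(comp$points) else NA_integer_)
    }
    p <- swift_bin_points(value, comp)
    if (is.na(p)) {
      stop_posticu(sprintf("value %g outside the SWIFT '%s' domain.",
                           value, comp_name), "domain")
    }
    p
  }
  if (!is.na(inputs$gcs) && (inputs$gcs < 3 || inputs$gcs > 15)) {
    stop_posticu("GCS outside [3, 15].", "domain")
  }
  p_los <- num_pts(inputs$icu_los, "icu_los")
  p_gcs <- num_pts(inputs$gcs, "gcs")
  p_oxy <- if (!is.na(inputs$pf_ratio)) {
    num_pts(inputs$pf_ratio, "pf_ratio")
  } else if (!is.na(inputs$sf_ratio)) {
    num_pts(inputs$sf_ratio, "sf_ratio")
  } else {
    min(comps$pf_ratio$points)
  }
  p_co2 <- num_pts(inputs$paco2, "paco2")
  breakdown <- c(admission_source = p_src, icu_los = p_los, gcs = p_gcs,
                 oxygenation = p_oxy, paco2 = p_co2)
  list(score = as.integer(sum(breakdown)), breakdown = breakdown)
}

#' SWIFT scores for every stay of a cohort
#'
#' @param cohort A selected `icu_cohort` (raw units, pre-normalization).
#' @param table A `swift_table`.
#' @param channel_map See [extract_swift_inputs()].
#' @return A tibble: `stay_id`, `score`, one `pts_*` column per component,
#'   and the oxygenation provenance.
#' @export
swift_scores <- function(cohort, table = swift_table_default(),
                         channel_map = list(gcs = "gcs", pao2 = "pao2",
                                            paco2 = "paco2", spo2 = "spo2",
                                            fio2 = "fio2")) {
  stays <- cohort$stays
  ev_split <- split(cohort$events, cohort$events$stay_id)
  rows <- lapply(seq_len(nrow(stays)), function(i) {
    stay <- stays[i, ]
    ev <- ev_split[[stay$stay_id]]
    if (is.null(ev)) ev <- cohort$events[0, ]
    inp <- extract_swift_inputs(stay, ev, channel_map)
    res <- compute_swift(inp, table)
    tibble::tibble(stay_id = stay$stay_id, score = res$score,
                   pts_admission_source = res$breakdown[["admission_source"]],
                   pts_icu_los = res$breakdown[["icu_los"]],
                   pts_gcs = res$breakdown[["gcs"]],
                   pts_oxygenation = res$breakdown[["oxygenation"]],
                   pts_paco2 = res$breakdown[["paco2"]],
                   oxygenation_provenance = inp$provenance[["oxygenation"]])
  })
  dplyr::bind_rows(rows)
}

#' AUROC/AUPR of the raw SWIFT score
#'
#' Scores every stay and reports ranking performance of the raw integer
#' score against the 7-day deterioration label; ties between integer scores
#' get half credit, exactly as in the pairwise AUROC definition.
#'
#' @param cohort A selected `icu_cohort`.
#' @param table A `swift_table`.
#' @param window_days Label window.
#' @return An `eval_report` (single fold, mode `"swift"`), scores attached.
#' @export
swift_auroc <- function(cohort, table = swift_table_default(),
                        window_days = 7) {
  sc <- swift_scores(cohort, table)
  labs <- label_outcome(cohort, window_days = window_days)
  s <- sc$score[match(labs$stay_id, sc$stay_id)]
  out <- tibble::tibble(fold = 1L, n_test = nrow(labs),
                        auroc = auroc(s, labs$label),
                        aupr = aupr(s, labs$label))
  structure(out, class = c("eval_report", class(out)),
            model = "SWIFT", seed = NA_integer_, mode = "swift",
            scores = tibble::tibble(stay_id = labs$stay_id, fold = 1L,
                                    score = s, label = labs$label))
}
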