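ISO_FMT <- "%Y-%m-%dT%H:%M:%OS3Z"

fmt_time <- function(x) {
  out <- format(x, ISO_FMT, tz = "UTC")
  out[is.na(x)] <- ""
  out
}

parse_time <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  out[!nzchar(x %||% "")] <- NA
  out
}

#' Write a cohort as delimited text
#'
#' Emits `stays.csv`, `events.csv`, `readmissions.csv` (comma-separated,
#' header row, ISO-8601 UTC timestamps) and, for synthetic cohorts,
#' `severity.csv`, into `dir`.
#'
#' @param cohort An `icu_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- cohort$stays
  for (col in c("icu_in", "icu_out", "death_time")) st[[col]] <- fmt_time(st[[col]])
  utils::write.csv(st, file.path(dir, "stays.csv"), row.names = FALSE)
  ev <- cohort$events
  ev$time <- fmt_time(ev$time)
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  rr <- cohort$readmissions
  rr$time <- fmt_time(rr$time)
  rr$end_time <- fmt_time(rr$end_time)
  utils::write.csv(rr, file.path(dir, "readmissions.csv"), row.names = FALSE)
  if (!is.null(cohort$severity)) {
    utils::write.csv(cohort$severity, file.path(dir, "severity.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from delimited text
#'
#' Inverse of [write_cohort_csv()]; any long-format event table matching the
#' documented column contract (`stay_id`, `channel`, `time`, `value`) and
#' stay-metadata contract can be read this way. The generating config is not
#' recoverable from text, so channel kinds must be passed downstream where
#' needed.
#'
#' @param dir Directory holding the CSV files.
#' @return An `icu_cohort`.
#' @export
read_cohort_csv <- function(dir) {
  stays <- tibble::as_tibble(utils::read.csv(file.path(dir, "stays.csv"),
                                             colClasses = "character"))
  stays$age <- as.numeric(stays$age)
  stays$sex <- as.integer(stays$sex)
  for (col in c("icu_in", "icu_out", "death_time")) {
    stays[[col]] <- parse_time(stays[[col]])
  }
  stays$discharge_destination[!nzchar(stays$discharge_destination)] <- NA
  events <- tibble::as_tibble(utils::read.csv(file.path(dir, "events.csv"),
                                              colClasses = "character"))
  events$time <- parse_time(events$time)
  events$value <- as.numeric(events$value)
  rr_path <- file.path(dir, "readmissions.csv")
  readmissions <- if (file.exists(rr_path)) {
    rr <- tibble::as_tibble(utils::read.csv(rr_path, colClasses = "character"))
    if (nrow(rr) > 0) {
      rr$time <- parse_time(rr$time)
      rr$end_time <- parse_time(rr$end_time)
      rr$planned <- as.logical(rr$planned)
      rr
    } else empty_readmissions()
  } else empty_readmissions()
  sev_path <- file.path(dir, "severity.csv")
  severity <- if (file.exists(sev_path)) {
    sv <- tibble::as_tibble(utils::read.csv(sev_path))
    sv$stay_id <- as.character(sv$stay_id)
    sv
  } else NULL
  new_icu_cohort(stays, events, readmissions, severity)
}

#' Save a fitted recurrent model as a JSON checkpoint
#'
#' The checkpoint carries the weights, variant, channel list, normalization
#' statistics and a preprocessing hash; [load_checkpoint()] restores a
#' `grud_fit` that refuses to predict on tensors preprocessed differently.
#'
#' @param object A `grud_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  stats <- object$norm_stats
  payload <- list(
    format = "posticu-checkpoint-v1",
    variant = object$variant, hidden = object$hidden,
    channels = object$channels,
    params = lapply(unclass(object$params), function(m) {
      if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
      else list(dim = NULL, data = as.numeric(m))
    }),
    norm_stats = list(channels = stats$channels, age_mean = stats$age_mean,
                      age_sd = stats$age_sd),
    prep_hash = rlang::hash(list(object$channels, stats)),
    best_epoch = object$best_epoch, stopped_epoch = object$stopped_epoch,
    best_val_loss = object$best_val_loss,
    config = unclass(object$config), seed = object$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted recurrent model from a JSON checkpoint
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return A `grud_fit`.
#' @export
load_checkpoint <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(pl$format, "posticu-checkpoint-v1")) {
    stop_posticu("not a recognized checkpoint file.", "input")
  }
  params <- lapply(pl$params, function(p) {
    d <- suppressWarnings(as.integer(unlist(p$dim)))
    if (length(d) == 2 && !anyNA(d)) {
      matrix(as.numeric(p$data), d[1], d[2])
    } else {
      as.numeric(p$data)
    }
  })
  stats <- structure(list(channels = tibble::as_tibble(pl$norm_stats$channels),
                          age_mean = pl$norm_stats$age_mean,
                          age_sd = pl$norm_stats$age_sd),
                     class = "norm_stats")
  structure(
    list(params = params, variant = pl$variant,
         log = tibble::tibble(), best_epoch = pl$best_epoch,
         stopped_epoch = pl$stopped_epoch, best_val_loss = pl$best_val_loss,
         channels = pl$channels, norm_stats = stats,
         filled = identical(pl$variant, "gru"),
         config = do.call(train_config, as.list(pl$config)),
         seed = pl$seed, hidden = pl$hidden),
    class = "grud_fit")
}
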