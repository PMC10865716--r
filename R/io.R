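#' Trial dataset container
#'
#' Bundles an enclosure configuration, mouse metadata and a time-sorted
#' read table. Downstream verbs all operate on plain tibbles; the container
#' exists so readers and the simulator can hand back everything at once.
#'
#' @param config An [enclosure_config()].
#' @param mice Mouse metadata tibble (`mouse_id`, `sex`, `genotype`,
#'   `cage_id`, `release_zone`, `last_valid_day`, optional tag columns).
#' @param reads Tibble with `mouse_id`, `zone_id`, `t` (trial seconds).
#' @return An object of class `rfid_trial` with elements `config`, `mice`,
#'   `reads`.
#' @export
rfid_trial <- function(config, mice, reads) {
  mice <- tibble::as_tibble(mice)
  reads <- tibble::as_tibble(reads)
  if (nrow(reads) > 0L) {
    if (!all(reads$zone_id %in% config$zone_ids)) {
      abort("Reads reference zones absent from the configuration.")
    }
    if (!all(reads$mouse_id %in% mice$mouse_id)) {
      abort("Reads reference mice absent from the metadata.")
    }
    reads <- dplyr::arrange(reads, .data$t, .data$mouse_id, .data$zone_id)
  }
  structure(list(config = config, mice = mice, reads = reads),
            class = "rfid_trial")
}

#' @export
print.rfid_trial <- function(x, ...) {
  cat("<rfid_trial> ", nrow(x$mice), " mice, ",
      nrow(x$reads), " reads, ", length(x$config$zone_ids), " zones, ",
      x$config$trial_days, " days\n", sep = "")
  invisible(x)
}

#' Apply censoring to a trial dataset
#'
#' Drops every read of a mouse on days after its `last_valid_day`.
#' Metadata is kept intact so daily availability can still be derived.
#' Idempotent.
#'
#' @param trial An [rfid_trial()].
#' @return The trial with censored reads removed.
#' @export
censor_trial <- function(trial) {
  trial$reads <- censor_reads(trial$reads, trial$mice, trial$config)
  trial
}

parse_log_timestamps <- function(x, trial_start) {
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) {
    return(num - as.numeric(trial_start))
  }
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad) > 0L) {
    abort(sprintf("Unparseable timestamp at data line %d: '%s'",
                  bad[1], x[bad[1]]))
  }
  as.numeric(difftime(ts, trial_start, units = "secs"))
}

# Greedy thinning: within one sorted time vector, keep a read only if it is
# > window after the previously kept read.
thin_times <- function(t, window) {
  n <- length(t)
  if (n <= 1L || window <= 0) return(rep(TRUE, n))
  keep <- logical(n)
  keep[1] <- TRUE
  last <- t[1]
  for (i in 2:n) {
    if (t[i] - last > window) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  keep
}

#' Read an RFID detection log
#'
#' Parses a delimited antenna log (columns `timestamp`, `zone_id`,
#' `tag_code`; ISO-8601 or epoch-second timestamps), maps tag codes to
#' animals (animals carry up to two PIT tags, which collapse to one
#' identity), drops scanner bounce by deduplicating detections of the same
#' mouse at the same zone within `dedup_window` seconds, and restricts
#' reads to the trial span.
#'
#' @param path Path to the log file.
#' @param mice Mouse metadata tibble; tag columns `tag_code_1`,
#'   `tag_code_2` (or a single `tag_code_1`) map detections to `mouse_id`.
#' @param config An [enclosure_config()].
#' @param dedup_window Seconds within which repeat detections of one mouse
#'   at one antenna are collapsed to a single read (default 0.5 s,
#'   consistent with a 2-3 Hz scan cycle).
#' @param strict If `TRUE`, a tag code absent from the metadata is an
#'   error; the default warns and drops such ghost reads.
#' @return An [rfid_trial()] whose `reads` are time-sorted.
#' @export
read_rfid_log <- function(path, mice, config = enclosure_config(),
                          dedup_window = 0.5, strict = FALSE) {
  mice <- tibble::as_tibble(mice)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  req <- c("timestamp", "zone_id", "tag_code")
  if (!all(req %in% names(raw))) {
    abort(sprintf("Log must have columns %s.", paste(req, collapse = ", ")))
  }
  t <- parse_log_timestamps(raw$timestamp, config$trial_start)

  bad_zone <- setdiff(unique(raw$zone_id), config$zone_ids)
  if (length(bad_zone) > 0L) {
    abort(sprintf("Unknown zone id(s) in log: %s",
                  paste(bad_zone, collapse = ", ")))
  }

  tag_cols <- intersect(c("tag_code_1", "tag_code_2"), names(mice))
  if (length(tag_cols) == 0L) {
    abort("Metadata must carry tag_code_1 (and optionally tag_code_2).")
  }
  tag_map <- mice |>
    dplyr::select("mouse_id", dplyr::all_of(tag_cols)) |>
    tidyr::pivot_longer(dplyr::all_of(tag_cols), values_to = "tag_code") |>
    dplyr::filter(!is.na(.data$tag_code), .data$tag_code != "")
  if (anyDuplicated(tag_map$tag_code)) {
    abort("Tag codes must be globally unique across mice.")
  }
  mouse_of <- setNames(tag_map$mouse_id, tag_map$tag_code)

  mouse_id <- unname(mouse_of[raw$tag_code])
  unknown <- is.na(mouse_id)
  if (any(unknown)) {
    codes <- unique(raw$tag_code[unknown])
    if (strict) {
      abort(sprintf("Unknown tag code(s): %s", paste(codes, collapse = ", ")))
    }
    warn(sprintf("Dropping %d read(s) with unknown tag code(s): %s",
                 sum(unknown), paste(codes, collapse = ", ")))
  }

  span <- trial_span_seconds(config)
  in_span <- !unknown & t >= 0 & t < span
  n_out <- sum(!unknown) - sum(in_span)
  if (n_out > 0L) {
    inform(sprintf("read_rfid_log: dropped %d read(s) outside the trial span.",
                   n_out))
  }

  reads <- tibble::tibble(
    mouse_id = mouse_id[in_span],
    zone_id = raw$zone_id[in_span],
    t = t[in_span]
  ) |>
    dplyr::arrange(.data$t)

  if (nrow(reads) > 0L && dedup_window > 0) {
    reads <- reads |>
      dplyr::group_by(.data$mouse_id, .data$zone_id) |>
      dplyr::filter(thin_times(.data$t, .env$dedup_window)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$t)
  }
  rfid_trial(config, mice, reads)
}

#' Write reads back out as a canonical RFID log
#'
#' Emits one row per read with epoch-second timestamps and each mouse's
#' primary tag code, so `read_rfid_log()` on the result reproduces the
#' read multiset exactly (no deduplication is triggered because reads were
#' already thinned).
#'
#' @param reads Read tibble (`mouse_id`, `zone_id`, `t`).
#' @param path Output path.
#' @param mice Metadata tibble carrying `tag_code_1`.
#' @param config An [enclosure_config()].
#' @return `path`, invisibly.
#' @export
write_rfid_log <- function(reads, path, mice, config = enclosure_config()) {
  tag1 <- setNames(mice$tag_code_1, mice$mouse_id)
  out <- tibble::tibble(
    timestamp = format(reads$t + as.numeric(config$trial_start),
                       digits = 17, scientific = FALSE, trim = TRUE),
    zone_id = reads$zone_id,
    tag_code = unname(tag1[reads$mouse_id])
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a mouse metadata table
#'
#' @param path CSV with columns `mouse_id`, `tag_code_1`, `tag_code_2`,
#'   `sex`, `genotype`, `cage_id`, `release_zone`, `last_valid_day`.
#' @return A tibble.
#' @export
read_mouse_meta <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            last_valid_day = readr::col_integer(),
                            .default = readr::col_character()
                          ))
  if (!"mouse_id" %in% names(meta)) abort("Metadata needs a mouse_id column.")
  meta
}

#' Read / write an enclosure configuration as YAML
#'
#' @param path YAML file path.
#' @return For `config_from_yaml()`, an [enclosure_config()].
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  coords <- NULL
  if (!is.null(y$zone_coords)) {
    coords <- purrr::map_dfr(y$zone_coords, tibble::as_tibble)
  }
  enclosure_config(
    zone_ids = y$zone_ids %||% paste0("Z", 1:8),
    zone_coords = coords,
    trial_start = as.POSIXct(y$trial_start %||% "1970-01-01", tz = "UTC"),
    trial_days = y$trial_days %||% 10L,
    day_boundary_rule = y$day_boundary_rule %||% "rolling_24h_from_start"
  )
}

#' @rdname config_from_yaml
#' @param config An [enclosure_config()] to serialize.
#' @export
config_to_yaml <- function(config, path) {
  y <- list(
    zone_ids = as.list(config$zone_ids),
    zone_coords = purrr::pmap(config$zone_coords,
                              function(zone_id, x, y) list(zone_id = zone_id, x = x, y = y)),
    trial_start = format(config$trial_start, "%Y-%m-%dT%H:%M:%S"),
    trial_days = config$trial_days,
    day_boundary_rule = config$day_boundary_rule
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
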