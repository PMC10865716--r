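#' Grouped mean / SEM summaries
#'
#' Summarises a tidy long table of per-mouse (or per-mouse-per-day)
#' metrics into grouped mean, standard error of the mean (`sd / sqrt(n)`;
#' reported as 0 when `n = 1`) and group size. Undefined values are
#' dropped before `n` is counted, with a message giving the dropped
#' count; empty groups are omitted.
#'
#' @param data Tidy tibble.
#' @param keys Character vector of grouping column names.
#' @param value Name of the value column (default `"value"`).
#' @return Tibble with the key columns plus `mean`, `sem`, `n`, ordered
#'   by the keys.
#' @examples
#' df <- tibble::tibble(g = c("a", "a", "b"), value = c(0, 1, 0.8))
#' summarize_metric(df, "g")
#' @export
summarize_metric <- function(data, keys, value = "value") {
  data <- tibble::as_tibble(data)
  v <- data[[value]]
  bad <- is.na(v) | is.nan(v)
  if (any(bad)) {
    inform(sprintf("summarize_metric: dropped %d undefined value(s).",
                   sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) sd(.data[[value]]) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
}

#' Assemble a model-ready long-format frame
#'
#' Binds per-mouse-per-day metric tables from any pipeline stages into
#' one tidy frame (`mouse_id`, `sex`, `genotype`, `cage_id`, `day`,
#' `metric`, `value`) consumable by external mixed-model tooling.
#' Censored mouse-days are absent because upstream stages never emit
#' them. Statistical model fitting itself is out of this package's remit.
#'
#' @param mice Metadata tibble.
#' @param ... Named tibbles, each with `mouse_id`, `day` and one value
#'   column; the argument name becomes the `metric` label and the value
#'   column is taken as the last column unless `value_col` is given.
#' @param value_col Optional named character vector mapping metric names
#'   to their value column.
#' @return Long tibble.
#' @export
export_model_frame <- function(mice, ..., value_col = NULL) {
  stages <- list(...)
  if (is.null(names(stages)) || any(names(stages) == "")) {
    abort("All stage tables must be named (name becomes the metric label).")
  }
  meta <- dplyr::select(mice, "mouse_id", "sex", "genotype", "cage_id")
  purrr::imap_dfr(stages, function(tbl, metric) {
    col <- value_col[[metric]] %||% utils::tail(names(tbl), 1)
    tbl |>
      dplyr::select("mouse_id", "day", value = dplyr::all_of(col)) |>
      dplyr::filter(!is.na(.data$day), !is.na(.data$value)) |>
      dplyr::mutate(metric = metric)
  }) |>
    dplyr::left_join(meta, by = "mouse_id") |>
    dplyr::select("mouse_id", "sex", "genotype", "cage_id", "day",
                  "metric", "value") |>
    dplyr::arrange(.data$metric, .data$mouse_id, .data$day)
}

#' Run the full inference pipeline on a trial
#'
#' Censors the reads, infers bouts, associations, priority access /
#' territory structure and daily networks, and returns every stage's
#' table in one list. This is the programmatic equivalent of the `run-all`
#' command-line entry point.
#'
#' @param trial An [rfid_trial()].
#' @param threshold Bout gap threshold in seconds, or `"auto"` to
#'   estimate it from the data at the 99% inter-read-interval quantile.
#' @return Named list: `threshold`, `bouts`, `intervals`, `events`,
#'   `dyads`, `composition`, `alone`, `sex_fractions`, `cagemate`,
#'   `pas_male`, `pas_female`, `contests`, `win_rates`, `overlap_null`,
#'   `networks`, `network_metrics`, `cumulative_partners`.
#' @export
run_pipeline <- function(trial, threshold = DEFAULT_GAP_THRESHOLD) {
  config <- trial$config
  mice <- trial$mice
  reads <- censor_reads(trial$reads, mice, config)
  gaps <- interread_intervals(reads)
  if (identical(threshold, "auto")) {
    threshold <- estimate_threshold(gaps)
  }
  bouts <- group_bouts(reads, threshold, config)
  events <- association_events(bouts, config)
  dyads <- dyad_overlaps(bouts, config)
  pas_m <- priority_access_scores(bouts, mice, "M", config)
  pas_f <- priority_access_scores(bouts, mice, "F", config)
  contests <- detect_contests(bouts, reads, mice, config)
  territorial <- glance(pas_m) |>
    dplyr::filter(.data$status == "territorial") |>
    dplyr::pull("mouse_id")
  nets <- daily_networks(events, mice, config)
  list(
    threshold = threshold,
    bouts = bouts,
    intervals = gaps,
    events = events,
    dyads = dyads,
    composition = group_composition_hours(bouts, mice, config),
    alone = time_alone(bouts, mice, config),
    sex_fractions = sex_association_fractions(bouts, mice, config),
    cagemate = cagemate_preference(dyads, mice, config),
    pas_male = pas_m,
    pas_female = pas_f,
    contests = contests,
    win_rates = home_away_win_rates(contests),
    overlap_null = overlap_null_deviation(bouts, mice, territorial,
                                          config),
    networks = nets,
    network_metrics = network_metrics(nets),
    cumulative_partners = cumulative_partners(events, mice, config)
  )
}
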