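# Residency-event segmentation under the continuous-presence rule.

#' Segment array-level detections into residency events
#'
#' Continuous presence at an array is a run of detections whose
#' inter-detection gaps never exceed `window_h` (default 1.5 h, thirty
#' times the longest nominal tag delay). A detection at a different
#' array always closes the current event, and candidate events with
#' fewer than `min_detections` detections are discarded.
#'
#' @param detections Array-level detection table (`timestamp`,
#'   `array_id`, `tag_id`), sorted by time within each fish.
#' @param window_h Continuation window, hours.
#' @param min_detections Minimum detections for a valid event (2 by
#'   default; some screening conventions use 3).
#' @return Tibble of events: `tag_id`, `array_id`, `start_ts`, `end_ts`,
#'   `n_detections`, `duration_s`.
#' @export
#' @examples
#' det <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + c(0, 1800, 3600),
#'   array_id = "A", tag_id = "f1")
#' segment_events(det)
segment_events <- function(detections, window_h = 1.5, min_detections = 2L) {
  req <- c("timestamp", "array_id", "tag_id")
  if (!all(req %in% names(detections))) {
    abort_coastnet("segment_events needs array-level detections (timestamp, array_id, tag_id)",
                   "coastnet_schema_error")
  }
  empty <- tibble::tibble(tag_id = character(), array_id = character(),
                          start_ts = as_utc(as.POSIXct(character())),
                          end_ts = as_utc(as.POSIXct(character())),
                          n_detections = integer(), duration_s = numeric())
  if (nrow(detections) == 0) return(empty)
  ts <- as.numeric(detections$timestamp)
  new_fish <- c(TRUE, detections$tag_id[-1] != detections$tag_id[-nrow(detections)])
  if (any(diff(ts)[!new_fish[-1]] < 0)) {
    abort_coastnet("detections must be sorted ascending in time within each fish",
                   "coastnet_ordering_error")
  }
  gap <- c(Inf, diff(ts))
  new_array <- c(TRUE, detections$array_id[-1] != detections$array_id[-nrow(detections)])
  brk <- new_fish | new_array | gap > window_h * 3600
  ev <- cumsum(brk)
  out <- tibble::tibble(tag_id = detections$tag_id,
                        array_id = detections$array_id,
                        ts = detections$timestamp, ev = ev) |>
    dplyr::group_by(.data$ev) |>
    dplyr::summarise(tag_id = .data$tag_id[1], array_id = .data$array_id[1],
                     start_ts = min(.data$ts), end_ts = max(.data$ts),
                     n_detections = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_detections >= min_detections) |>
    dplyr::mutate(duration_s = as.numeric(.data$end_ts) - as.numeric(.data$start_ts)) |>
    dplyr::select(-"ev")
  out
}

#' Summarise residency per fish and array
#'
#' Sums event durations per (fish, array), averages the totals per array
#' over the fish that used it, and reports the ranking of arrays by mean
#' residency.
#'
#' @param events Output of [segment_events()].
#' @return List with `per_fish_array` (total residency), `per_array`
#'   (mean over fish, ranked) and `top_array` (array id with the highest
#'   mean residency).
#' @export
summarize_residency <- function(events) {
  per_fa <- events |>
    dplyr::group_by(.data$tag_id, .data$array_id) |>
    dplyr::summarise(total_residency_s = sum(.data$duration_s),
                     n_events = dplyr::n(), .groups = "drop")
  per_a <- per_fa |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(mean_residency_s = mean(.data$total_residency_s),
                     n_fish = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_residency_s))
  list(per_fish_array = per_fa, per_array = per_a,
       top_array = if (nrow(per_a)) per_a$array_id[1] else NA_character_)
}

#' Residency index per fish
#'
#' Fraction of calendar days (UTC) between release and last detection on
#' which the fish was detected at least once. A zero-length track (one
#' detection day, release that same day) returns 1 by convention.
#'
#' @param detections Detection table (station- or array-level).
#' @param fish Fish table with `release_ts`.
#' @return Tibble `tag_id`, `n_days_detected`, `n_days_track`,
#'   `residency_index` (in `[0, 1]`).
#' @export
residency_index <- function(detections, fish) {
  dd <- detections |>
    dplyr::mutate(day = utc_date(.data$timestamp)) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(n_days_detected = dplyr::n_distinct(.data$day),
                     last_day = max(.data$day), .groups = "drop")
  dd <- dplyr::left_join(dd, fish[, c("tag_id", "release_ts")], by = "tag_id")
  dd$n_days_track <- pmax(as.numeric(dd$last_day - utc_date(dd$release_ts)) + 1, 1)
  dd$residency_index <- pmin(dd$n_days_detected / dd$n_days_track, 1)
  dd[, c("tag_id", "n_days_detected", "n_days_track", "residency_index")]
}
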