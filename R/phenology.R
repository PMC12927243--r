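# Spawning-season timing: lagoon emigration peaks, first arrivals at
# spawning stations, and presence at spawning sites per season.

# Home-lagoon name from a release-site label ("Thau Lagoon" -> "Thau").
home_lagoon_of <- function(release_site) {
  ifelse(grepl(" Lagoon$", release_site),
         sub(" Lagoon$", "", release_site), NA_character_)
}

# Spawning-season label: the calendar year of the season's October
# (Oct y -- Apr 14 y+1 is season y); timestamps outside the spawning
# window get NA.
season_year <- function(timestamp) {
  md <- mmdd(timestamp)
  y <- as.POSIXlt(timestamp, tz = "UTC")$year + 1900L
  ifelse(md >= 1001L, y, ifelse(md <= 414L, y - 1L, NA_integer_))
}

#' Lagoon emigration records and peak 7-day bins
#'
#' For each lagoon-tagged fish and year, collapses the fish's
#' home-lagoon detections to calendar days and takes the final such day
#' inside the September--November window as its emigration date. Dates
#' are grouped into `bin_days`-day bins anchored at 1 September; the
#' peak emigration bin per lagoon-year is the bin holding the most
#' individuals, ties broken to the earlier bin.
#'
#' @param detections Array-level detection table.
#' @param fish Fish table (lagoon-tagged fish are those whose
#'   `release_site` ends in "Lagoon").
#' @param arrays Array table with a `lagoon` column naming the lagoon
#'   each lagoon array belongs to.
#' @param bin_days Bin width, days.
#' @param window `c("mm-dd", "mm-dd")` emigration search window.
#' @return List with `records` (one per fish-year), `peaks` (per
#'   lagoon-year: `peak_bin`, `bin_start`, `n_fish`) and `n_excluded`
#'   (lagoon fish-years without in-window home detections).
#' @export
emigration_peaks <- function(detections, fish, arrays, bin_days = 7L,
                             window = c("09-01", "11-30")) {
  fish$home_lagoon <- home_lagoon_of(fish$release_site)
  lag_fish <- fish[!is.na(fish$home_lagoon), ]
  det <- detections[detections$tag_id %in% lag_fish$tag_id, ]
  det$lagoon <- arrays$lagoon[match(det$array_id, arrays$array_id)]
  det$home <- lag_fish$home_lagoon[match(det$tag_id, lag_fish$tag_id)]
  det <- det[!is.na(det$lagoon) & det$lagoon == det$home, ]

  empty <- tibble::tibble(tag_id = character(), home_lagoon = character(),
                          year = integer(),
                          last_detection_date = as.Date(character()),
                          bin = integer())
  if (nrow(det) == 0) {
    return(list(records = empty,
                peaks = tibble::tibble(lagoon = character(), year = integer(),
                                       peak_bin = integer(),
                                       bin_start = as.Date(character()),
                                       n_fish = integer()),
                n_excluded = 0L))
  }
  det$day <- utc_date(det$timestamp)
  det$year <- as.integer(format(det$day, "%Y"))
  w0 <- as.Date(paste0(det$year, "-", window[1]))
  w1 <- as.Date(paste0(det$year, "-", window[2]))
  inw <- det$day >= w0 & det$day <= w1

  # fish-years with any home-lagoon detections vs. those with in-window ones
  all_fy <- dplyr::distinct(det[, c("tag_id", "year")])
  det <- det[inw, ]
  if (nrow(det) == 0) {
    return(list(records = empty,
                peaks = tibble::tibble(lagoon = character(), year = integer(),
                                       peak_bin = integer(),
                                       bin_start = as.Date(character()),
                                       n_fish = integer()),
                n_excluded = nrow(all_fy)))
  }
  records <- det |>
    dplyr::group_by(.data$tag_id, .data$home, .data$year) |>
    dplyr::summarise(last_detection_date = max(.data$day), .groups = "drop") |>
    dplyr::rename(home_lagoon = "home")
  anchor <- as.Date(paste0(records$year, "-09-01"))
  records$bin <- as.integer(floor(as.numeric(records$last_detection_date - anchor) /
                                    bin_days))
  peaks <- records |>
    dplyr::count(lagoon = .data$home_lagoon, .data$year, .data$bin,
                 name = "n_fish") |>
    dplyr::group_by(.data$lagoon, .data$year) |>
    dplyr::slice(which(.data$n_fish == max(.data$n_fish))[1]) |>
    dplyr::ungroup() |>
    dplyr::rename(peak_bin = "bin")
  peaks$bin_start <- as.Date(paste0(peaks$year, "-09-01")) +
    peaks$peak_bin * bin_days
  list(records = records,
       peaks = peaks[, c("lagoon", "year", "peak_bin", "bin_start", "n_fish")],
       n_excluded = nrow(all_fy) - nrow(records))
}

#' First arrivals at spawning stations per spawning season
#'
#' For every fish (tagged anywhere) and spawning season, the earliest
#' detection at a spawning-flagged array, with per-tagging-location
#' arrival summaries (median and IQR of arrival day within the season).
#'
#' @param detections Array-level detection table.
#' @param fish Fish table.
#' @param arrays Array table with `spawning_flag`.
#' @return List with `arrivals` (tag_id, release_site, season,
#'   first_spawning_detection_ts, arrival_day = days since 1 October)
#'   and `summary` (per season x release_site: n, median and IQR of
#'   arrival day).
#' @export
spawning_arrivals <- function(detections, fish, arrays) {
  sp_arrays <- arrays$array_id[arrays$spawning_flag]
  det <- detections[detections$array_id %in% sp_arrays, ]
  det$season <- season_year(det$timestamp)
  det <- det[!is.na(det$season), ]
  arrivals <- det |>
    dplyr::group_by(.data$tag_id, .data$season) |>
    dplyr::summarise(first_spawning_detection_ts = min(.data$timestamp),
                     .groups = "drop")
  arrivals$release_site <- fish$release_site[match(arrivals$tag_id, fish$tag_id)]
  oct1 <- as.Date(paste0(arrivals$season, "-10-01"))
  arrivals$arrival_day <- as.numeric(utc_date(arrivals$first_spawning_detection_ts) -
                                       oct1)
  summary <- arrivals |>
    dplyr::group_by(.data$season, .data$release_site) |>
    dplyr::summarise(n = dplyr::n(),
                     median_arrival_day = median(.data$arrival_day),
                     iqr_arrival_day = stats::IQR(.data$arrival_day),
                     .groups = "drop")
  list(arrivals = arrivals, summary = summary)
}

#' Presence at spawning stations per season, with multi-year returns
#'
#' Daily counts of unique individuals detected at spawning-flagged
#' arrays per spawning season and tagging location; per-fish season
#' sets; counts of fish detected in the spawning region over multiple
#' consecutive seasons; and the peak-presence date per season (ties to
#' the earlier date).
#'
#' @param detections Array-level detection table.
#' @param fish Fish table.
#' @param arrays Array table with `spawning_flag`.
#' @return List with `presence` (date, season, release_site,
#'   n_individuals), `fish_seasons`, `return_summary` (n_multi_year,
#'   n_two_consecutive, n_three_plus_consecutive), `peaks` (per season).
#' @export
spawning_presence <- function(detections, fish, arrays) {
  sp_arrays <- arrays$array_id[arrays$spawning_flag]
  det <- detections[detections$array_id %in% sp_arrays, ]
  det$season <- season_year(det$timestamp)
  det <- det[!is.na(det$season), ]
  det$date <- utc_date(det$timestamp)
  det$release_site <- fish$release_site[match(det$tag_id, fish$tag_id)]

  presence <- det |>
    dplyr::group_by(.data$season, .data$release_site, .data$date) |>
    dplyr::summarise(n_individuals = dplyr::n_distinct(.data$tag_id),
                     .groups = "drop")

  fish_seasons <- det |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(seasons = list(sort(unique(.data$season))),
                     .groups = "drop")
  # longest run of consecutive seasons per fish
  max_run <- vapply(fish_seasons$seasons, function(s) {
    if (!length(s)) return(0L)
    max(rle(cumsum(c(1L, as.integer(diff(s) != 1L))))$lengths)
  }, integer(1))
  fish_seasons$max_consecutive <- max_run
  return_summary <- list(
    n_multi_year = sum(lengths(fish_seasons$seasons) >= 2),
    n_two_consecutive = sum(max_run == 2),
    n_three_plus_consecutive = sum(max_run >= 3))

  peaks <- det |>
    dplyr::group_by(.data$season, .data$date) |>
    dplyr::summarise(n_individuals = dplyr::n_distinct(.data$tag_id),
                     .groups = "drop") |>
    dplyr::group_by(.data$season) |>
    dplyr::slice(which(.data$n_individuals == max(.data$n_individuals))[1]) |>
    dplyr::ungroup() |>
    dplyr::rename(peak_date = "date")
  list(presence = presence, fish_seasons = fish_seasons,
       return_summary = return_summary, peaks = peaks)
}
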