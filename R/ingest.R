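# Reading the three study tables, quality filtering with an audit,
# dead-fish screening, array pooling and fish-record enrichment.

DETECTION_COLS <- c("timestamp", "station_id", "tag_id")
STATION_COLS <- c("station_id", "name", "lon", "lat", "habitat", "array_id",
                  "spawning_flag", "active_from", "active_to")
FISH_COLS <- c("tag_id", "fork_length_mm", "mass_g", "origin", "release_site",
               "release_ts", "tag_model")

#' Load detection, station and fish tables from delimited text
#'
#' Reads the three comma-separated files (UTF-8, optional BOM, LF or
#' CRLF endings), validates the schema and the foreign keys from
#' detections into stations and fish, and returns typed tibbles with all
#' timestamps parsed as UTC.
#'
#' @param detections_path,stations_path,fish_path File paths.
#' @return List with `detections`, `stations`, `fish`; the number of
#'   unparseable rows encountered (dropped and counted) is stored in
#'   `attr(, "n_parse_problems")`.
#' @export
load_tables <- function(detections_path, stations_path, fish_path) {
  rd <- function(path, required) {
    for (p in path) if (!file.exists(p))
      abort_coastnet(paste0("file not found: ", p), "coastnet_io_error")
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(required, names(x))
    if (length(miss)) {
      abort_coastnet(sprintf("schema error in %s: missing column(s) %s",
                             basename(path), paste(miss, collapse = ", ")),
                     "coastnet_schema_error")
    }
    x
  }
  utc_col <- function(x) {
    if (inherits(x, "POSIXct")) as_utc(x) else as_utc(as.character(x))
  }
  det <- rd(detections_path, DETECTION_COLS)
  st <- rd(stations_path, STATION_COLS)
  fi <- rd(fish_path, FISH_COLS)
  n_problems <- sum(nrow(readr::problems(det)), nrow(readr::problems(st)),
                    nrow(readr::problems(fi)))
  det$timestamp <- utc_col(det$timestamp)
  st$active_from <- utc_col(st$active_from)
  st$active_to <- utc_col(st$active_to)
  fi$release_ts <- utc_col(fi$release_ts)
  if ("true_death_ts" %in% names(fi)) fi$true_death_ts <- utc_col(fi$true_death_ts)
  bad <- is.na(det$timestamp) | is.na(det$station_id) | is.na(det$tag_id)
  n_problems <- n_problems + sum(bad)
  det <- det[!bad, ]

  unknown_st <- setdiff(unique(det$station_id), st$station_id)
  if (length(unknown_st)) {
    abort_coastnet(sprintf("referential error: detections reference unknown station(s): %s",
                           paste(head(unknown_st, 10), collapse = ", ")),
                   "coastnet_referential_error")
  }
  unknown_tag <- setdiff(unique(det$tag_id), fi$tag_id)
  if (length(unknown_tag)) {
    abort_coastnet(sprintf("referential error: detections reference unknown tag(s): %s",
                           paste(head(unknown_tag, 10), collapse = ", ")),
                   "coastnet_referential_error")
  }
  out <- list(detections = tibble::as_tibble(det),
              stations = tibble::as_tibble(st),
              fish = tibble::as_tibble(fi))
  attr(out, "n_parse_problems") <- n_problems
  out
}

#' Configuration of the detection quality filter
#'
#' Four switchable rules applied in order: (a) detections before the
#' fish's release or outside the station's active interval; (b) exact
#' duplicate rows; (c) isolated detections with no second detection of
#' the same tag at the same station within `isolated_window_h`;
#' (d) implied swim speeds between consecutive array centroids above
#' `max_speed_kmday`.
#'
#' @param pre_release,station_active,duplicates,isolated,speed Logical
#'   switches for the individual rules.
#' @param isolated_window_h Companion-detection window, hours.
#' @param max_speed_kmday Maximum plausible sustained speed, km/day.
#' @return List of class `coastnet_filter_config`.
#' @export
filter_config <- function(pre_release = TRUE, station_active = TRUE,
                          duplicates = TRUE, isolated = TRUE,
                          isolated_window_h = 24, speed = TRUE,
                          max_speed_kmday = 100) {
  structure(list(pre_release = pre_release, station_active = station_active,
                 duplicates = duplicates, isolated = isolated,
                 isolated_window_h = isolated_window_h, speed = speed,
                 max_speed_kmday = max_speed_kmday),
            class = c("coastnet_filter_config", "list"))
}

#' Array table derived from a station table
#'
#' Stations sharing an `array_id` (pooled receiver clusters at lagoon
#' entrances) are collapsed to their centroid.
#'
#' @param stations Station table.
#' @return Tibble with `array_id`, centroid `lon`/`lat`, `habitat`,
#'   `spawning_flag`, `lagoon`.
#' @export
arrays_from_stations <- function(stations) {
  if (!"lagoon" %in% names(stations)) stations$lagoon <- NA_character_
  stations |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(
      lon = mean(.data$lon), lat = mean(.data$lat),
      habitat = .data$habitat[1],
      spawning_flag = any(.data$spawning_flag),
      lagoon = if (all(is.na(.data$lagoon))) NA_character_ else
        .data$lagoon[!is.na(.data$lagoon)][1],
      .groups = "drop")
}

#' Quality-filter a detection table
#'
#' Applies the enabled rules of [filter_config()] in order and returns
#' the surviving detections together with an audit recording rows
#' removed per rule; input rows always equal output rows plus the sum of
#' removals. Re-running the filter on its own output removes nothing.
#'
#' @param detections Detection table.
#' @param fish Fish table (for release times).
#' @param stations Station table (for active intervals and array
#'   centroids).
#' @param config A [filter_config()].
#' @return List with `detections` and `audit` (named removal counts).
#' @export
basic_filter <- function(detections, fish, stations, config = filter_config()) {
  det <- dplyr::arrange(detections, .data$tag_id, .data$timestamp,
                        .data$station_id)
  audit <- c(pre_release_or_inactive = 0L, duplicates = 0L,
             isolated = 0L, speed = 0L)
  n_input <- nrow(det)

  if (config$pre_release || config$station_active) {
    rel <- fish$release_ts[match(det$tag_id, fish$tag_id)]
    drop <- rep(FALSE, nrow(det))
    if (config$pre_release) drop <- drop | (!is.na(rel) & det$timestamp < rel)
    if (config$station_active) {
      si <- match(det$station_id, stations$station_id)
      drop <- drop | det$timestamp < stations$active_from[si] |
        det$timestamp > stations$active_to[si]
    }
    audit["pre_release_or_inactive"] <- sum(drop)
    det <- det[!drop, ]
  }
  if (config$duplicates) {
    dup <- duplicated(det[, c("timestamp", "station_id", "tag_id")])
    audit["duplicates"] <- sum(dup)
    det <- det[!dup, ]
  }
  if (config$isolated && nrow(det) > 0) {
    w <- config$isolated_window_h * 3600
    det <- dplyr::arrange(det, .data$tag_id, .data$station_id, .data$timestamp)
    ts <- as.numeric(det$timestamp)
    same_grp <- function(a, b) det$tag_id[a] == det$tag_id[b] &
      det$station_id[a] == det$station_id[b]
    n <- nrow(det)
    prev_ok <- next_ok <- rep(FALSE, n)
    if (n > 1) {
      i <- 2:n
      prev_ok[i] <- same_grp(i, i - 1L) & (ts[i] - ts[i - 1L]) <= w
      next_ok[i - 1L] <- prev_ok[i]
    }
    iso <- !(prev_ok | next_ok)
    audit["isolated"] <- sum(iso)
    det <- det[!iso, ]
    det <- dplyr::arrange(det, .data$tag_id, .data$timestamp, .data$station_id)
  }
  if (config$speed && nrow(det) > 1) {
    arrays <- arrays_from_stations(stations)
    ai <- match(stations$array_id[match(det$station_id, stations$station_id)],
                arrays$array_id)
    removed <- 0L
    for (pass in 1:20) {
      n <- nrow(det)
      if (n < 2) break
      i <- 2:n
      same_fish <- det$tag_id[i] == det$tag_id[i - 1L]
      dt <- as.numeric(det$timestamp[i]) - as.numeric(det$timestamp[i - 1L])
      dkm <- haversine_km(arrays$lon[ai[i - 1L]], arrays$lat[ai[i - 1L]],
                          arrays$lon[ai[i]], arrays$lat[ai[i]])
      v <- ifelse(dt > 0, dkm / dt * 86400, ifelse(dkm > 0, Inf, 0))
      viol <- c(FALSE, same_fish & v > config$max_speed_kmday)
      if (!any(viol)) break
      removed <- removed + sum(viol)
      det <- det[!viol, ]
      ai <- ai[!viol]
    }
    audit["speed"] <- removed
  }
  stopifnot(n_input == nrow(det) + sum(audit))
  list(detections = det,
       audit = list(n_input = n_input, removed = as.list(audit),
                    n_output = nrow(det)))
}

#' Configuration of the dead-fish screen
#'
#' Deterministic operationalization of three post-mortem detection
#' patterns: (i) a 30-day window inside the expected-movement season
#' (September--November) whose detections all come from one station;
#' (ii) a long trailing period (> 60 days) confined to at most
#' `confinement_stations` stations whose ranges overlap (pairwise
#' centroid distance below `confinement_km`); (iii) slow unidirectional
#' displacement (monotone distance from start, mean net speed below
#' `drift_max_kmday`) over more than `drift_min_days`.
#'
#' @param single_station_days Window length for criterion (i), days.
#' @param single_station_min_n Minimum detections in the window.
#' @param single_station_min_span Minimum day span of those detections.
#' @param movement_window `c("mm-dd", "mm-dd")` season in which movement
#'   is expected.
#' @param confinement_days,confinement_stations,confinement_km
#'   Criterion (ii) thresholds.
#' @param drift_max_kmday,drift_min_days,drift_min_rho,drift_scan
#'   Criterion (iii): maximum net speed, minimum duration, minimum
#'   Spearman rank correlation between day and distance-from-start, and
#'   number of candidate trailing-window starts scanned.
#' @param drift_min_km,drift_min_stations Minimum net displacement and
#'   minimum distinct stations for the drift pattern -- sustained
#'   unidirectional travel, not jitter among adjacent receivers.
#' @return List of class `coastnet_fate_config`.
#' @export
fate_config <- function(single_station_days = 30, single_station_min_n = 5,
                        single_station_min_span = 24,
                        movement_window = c("09-01", "11-30"),
                        confinement_days = 60, confinement_stations = 3,
                        confinement_km = 1,
                        drift_max_kmday = 0.5, drift_min_days = 30,
                        drift_min_rho = 0.9, drift_scan = 60,
                        drift_min_km = 2, drift_min_stations = 3) {
  structure(list(single_station_days = single_station_days,
                 single_station_min_n = single_station_min_n,
                 single_station_min_span = single_station_min_span,
                 movement_window = movement_window,
                 confinement_days = confinement_days,
                 confinement_stations = confinement_stations,
                 confinement_km = confinement_km,
                 drift_max_kmday = drift_max_kmday,
                 drift_min_days = drift_min_days,
                 drift_min_rho = drift_min_rho,
                 drift_scan = drift_scan,
                 drift_min_km = drift_min_km,
                 drift_min_stations = drift_min_stations),
            class = c("coastnet_fate_config", "list"))
}

#' Flag likely-dead fish from their detection histories
#'
#' Applies the three criteria of [fate_config()] to each fish's filtered
#' detections and records the fate and the first criterion fired. The
#' result doubles as a report for human review.
#'
#' @param detections Filtered detection table.
#' @param fish Fish table.
#' @param stations Station table.
#' @param config A [fate_config()].
#' @return `fish` with columns `fate` (`"alive"`/`"dead"`) and
#'   `fate_criterion` (`"single_station"`, `"confinement"`, `"drift"` or
#'   `NA`).
#' @export
flag_dead_fish <- function(detections, fish, stations, config = fate_config()) {
  det <- dplyr::arrange(detections, .data$tag_id, .data$timestamp)
  si <- match(det$station_id, stations$station_id)
  det$lon <- stations$lon[si]; det$lat <- stations$lat[si]
  fish$fate <- "alive"
  fish$fate_criterion <- NA_character_
  split_idx <- split(seq_len(nrow(det)), det$tag_id)
  for (tid in names(split_idx)) {
    rows <- split_idx[[tid]]
    if (length(rows) < 2) next
    d <- det[rows, ]
    crit <- dead_criterion(d, config)
    if (!is.na(crit)) {
      k <- match(tid, fish$tag_id)
      fish$fate[k] <- "dead"
      fish$fate_criterion[k] <- crit
    }
  }
  fish
}

# The three dead-fish criteria for one fish's sorted detections.
dead_criterion <- function(d, cfg) {
  days <- utc_date(d$timestamp)
  daynum <- as.numeric(days)

  # (i) single station across a rolling window inside the movement season
  yrs <- unique(as.POSIXlt(days)$year + 1900L)
  for (y in yrs) {
    w0 <- as.numeric(as.Date(paste0(y, "-", cfg$movement_window[1])))
    w1 <- as.numeric(as.Date(paste0(y, "-", cfg$movement_window[2])))
    in_season <- which(daynum >= w0 & daynum <= w1)
    if (length(in_season) < cfg$single_station_min_n) next
    sd_ <- daynum[in_season]; st_ <- d$station_id[in_season]
    starts <- unique(sd_[sd_ + cfg$single_station_days - 1 <= w1])
    for (s in starts) {
      inw <- sd_ >= s & sd_ < s + cfg$single_station_days
      if (sum(inw) >= cfg$single_station_min_n &&
          length(unique(st_[inw])) == 1 &&
          diff(range(sd_[inw])) >= cfg$single_station_min_span) {
        return("single_station")
      }
    }
  }

  # (ii) trailing confinement to few overlapping stations
  r <- rle(d$station_id)
  run_end_row <- cumsum(r$lengths)
  run_start_row <- run_end_row - r$lengths + 1L
  seen <- character(0)
  last_day <- daynum[length(daynum)]
  for (j in rev(seq_along(r$values))) {
    seen <- union(seen, r$values[j])
    if (length(seen) > cfg$confinement_stations) break
    span <- last_day - daynum[run_start_row[j]]
    if (span > cfg$confinement_days) {
      pos <- unique(d[d$station_id %in% seen, c("lon", "lat")])
      maxd <- 0
      if (nrow(pos) > 1) {
        pr <- utils::combn(nrow(pos), 2)
        maxd <- max(haversine_km(pos$lon[pr[1, ]], pos$lat[pr[1, ]],
                                 pos$lon[pr[2, ]], pos$lat[pr[2, ]]))
      }
      if (maxd < cfg$confinement_km) return("confinement")
    }
  }

  # (iii) slow monotone trailing drift
  dd <- dplyr::summarise(dplyr::group_by(tibble::tibble(
    day = daynum, lon = d$lon, lat = d$lat), .data$day),
    lon = mean(.data$lon), lat = mean(.data$lat), .groups = "drop")
  m <- nrow(dd)
  if (m >= 3) {
    # distinct stations in each trailing suffix of the detection record
    suffix_distinct <- rev(cumsum(!duplicated(rev(d$station_id))))
    cand <- unique(round(seq(1, m - 2, length.out = min(cfg$drift_scan, m - 2))))
    for (s in cand) {
      span <- dd$day[m] - dd$day[s]
      if (span <= cfg$drift_min_days) next
      first_det <- match(TRUE, daynum >= dd$day[s])
      if (suffix_distinct[first_det] < cfg$drift_min_stations) next
      dist <- haversine_km(dd$lon[s], dd$lat[s], dd$lon[s:m], dd$lat[s:m])
      if (dist[length(dist)] < cfg$drift_min_km) next
      rho <- suppressWarnings(cor(dd$day[s:m], dist, method = "spearman"))
      if (!is.na(rho) && rho >= cfg$drift_min_rho &&
          dist[length(dist)] / span <= cfg$drift_max_kmday) {
        return("drift")
      }
    }
  }
  NA_character_
}

#' Mark fish with no post-release detections as removed
#'
#' @param fish Fish table.
#' @param detections Filtered detection table.
#' @return `fish` with `fate = "removed"` for silent fish (existing
#'   `fate` values are preserved otherwise).
#' @export
drop_undetected <- function(fish, detections) {
  if (!"fate" %in% names(fish)) fish$fate <- "alive"
  silent <- !fish$tag_id %in% unique(detections$tag_id)
  fish$fate[silent] <- "removed"
  fish
}

#' Re-key detections from stations to pooled arrays
#'
#' Replaces each detection's station with its array so that consecutive
#' detections within one pooled cluster can never yield a network
#' transition downstream.
#'
#' @param detections Detection table.
#' @param stations Station table with the station-to-array mapping.
#' @return Detections with an `array_id` column.
#' @export
pool_arrays <- function(detections, stations) {
  ai <- stations$array_id[match(detections$station_id, stations$station_id)]
  if (anyNA(ai)) {
    missing <- unique(detections$station_id[is.na(ai)])
    abort_coastnet(sprintf("referential error: station(s) without array: %s",
                           paste(head(missing, 10), collapse = ", ")),
                   "coastnet_referential_error")
  }
  detections$array_id <- ai
  detections
}

#' Enrich fish records with liberty times and classes
#'
#' Time at liberty runs from release to the earlier of the last
#' detection and the estimated end of tag life; the four liberty classes
#' (short, medium, long, very long) are quartiles of time at liberty
#' across the supplied fish.
#'
#' @param fish Fish table.
#' @param detections Filtered detection table.
#' @param tag_life_days Optional named vector of per-model tag life
#'   caps, days (or a single number applied to all).
#' @return `fish` with `last_detection_ts`, `time_at_liberty_days`,
#'   `liberty_class`.
#' @export
enrich_fish <- function(fish, detections, tag_life_days = NULL) {
  last_det <- detections |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(last_detection_ts = max(.data$timestamp), .groups = "drop")
  fish <- dplyr::left_join(fish, last_det, by = "tag_id")
  end <- as.numeric(fish$last_detection_ts)
  if (!is.null(tag_life_days)) {
    life <- if (length(tag_life_days) == 1 && is.null(names(tag_life_days))) {
      rep(tag_life_days, nrow(fish))
    } else {
      unname(tag_life_days[fish$tag_model])
    }
    cap <- as.numeric(fish$release_ts) + life * 86400
    end <- pmin(end, cap, na.rm = TRUE)
  }
  fish$time_at_liberty_days <- pmax((end - as.numeric(fish$release_ts)) / 86400, 0)
  tl <- fish$time_at_liberty_days
  qs <- quantile(tl, c(0.25, 0.5, 0.75), na.rm = TRUE)
  br <- unique(c(-Inf, qs, Inf))
  labs <- c("short", "medium", "long", "very_long")[seq_len(length(br) - 1)]
  fish$liberty_class <- cut(tl, breaks = br, labels = labs, include.lowest = TRUE)
  fish
}
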