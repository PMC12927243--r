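# Agent-based synthetic telemetry generator.
#
# Fish follow a two-phase annual cycle on a 1-D coastal axis with lagoons
# as off-axis appendages reached through a monitored mouth channel.
# Detections arise from daily in-range "bouts": when a fish's daily
# position lies within the detection radius of a receiver it is available
# for a bounded number of hours, transmits at uniform random delays drawn
# from its tag model, and each transmission is heard independently with
# probability p_detect. The generator logs ground truth (true in-range
# bouts, executed departures, deaths) that downstream tests use as
# oracles.

# Fixed projection of the 1-D coastal axis onto WGS84: eastward along
# latitude 43 N, so great-circle distance between sea stations recovers
# alongshore km.
.LON0 <- 3.0
.LAT0 <- 43.0
.DLON_PER_KM <- 1 / (111.32 * cos(.LAT0 * pi / 180))
.DLAT_PER_KM <- 1 / 110.574

#' Receiver station table for a simulator configuration
#'
#' Sea receivers are spread along the coast with a denser block inside
#' the spawning zone; each lagoon carries a pooled two-receiver mouth
#' array in its channel plus two interior receivers. Lagoon-mouth pairs
#' share an `array_id`; every other station is its own array.
#'
#' @param config A [sim_config()] object.
#' @return Tibble of stations (schema columns plus internal geometry
#'   columns prefixed with a dot).
#' @export
make_stations <- function(config) {
  L <- config$coastline_length_km
  if (!is.null(config$sea_station_km)) {
    sea_km <- sort(config$sea_station_km)
  } else {
    n_zone <- round(config$n_stations_sea * config$spawn_station_frac)
    n_line <- config$n_stations_sea - n_zone
    line_km <- if (n_line > 0) seq(0.01 * L, 0.99 * L, length.out = n_line) else numeric()
    zone <- config$spawning_zone_km
    zone_km <- if (n_zone > 0) {
      seq(zone[1] + 0.2, min(zone[2], L) - 0.2, length.out = n_zone)
    } else numeric()
    # receiver pairs in front of release/aggregation sites and lagoon
    # mouths, mirroring deployments that monitor ingress/egress points
    front_km <- c(outer(config$sea_sites$km, c(-1.2, 1.2), "+"),
                  outer(config$lagoons$mouth_km, c(-1.5, 1.5), "+"))
    front_km <- front_km[front_km > 0 & front_km < L]
    sea_km <- sort(c(line_km, zone_km, front_km))
  }
  in_zone <- sea_km >= config$spawning_zone_km[1] & sea_km <= config$spawning_zone_km[2]
  sea <- tibble::tibble(
    station_id = sprintf("st_sea_%03d", seq_along(sea_km)),
    name = sprintf("sea %.1f km", sea_km),
    lon = .LON0 + sea_km * .DLON_PER_KM,
    lat = .LAT0,
    habitat = "sea",
    array_id = sprintf("ar_sea_%03d", seq_along(sea_km)),
    spawning_flag = in_zone,
    lagoon = NA_character_,
    .zone = 0L, .km = sea_km, .internal_km = NA_real_
  )

  lag_rows <- list()
  for (i in seq_len(nrow(config$lagoons))) {
    lg <- config$lagoons[i, ]
    interior_km <- c(0.35, 0.75) * lg$extent_km
    km_mouth <- lg$mouth_km + c(-0.025, 0.025)
    lag_rows[[i]] <- tibble::tibble(
      station_id = c(sprintf("st_%s_mouth_%d", tolower(lg$name), 1:2),
                     sprintf("st_%s_int_%d", tolower(lg$name), 1:2)),
      name = c(paste(lg$name, "mouth", 1:2), paste(lg$name, "interior", 1:2)),
      lon = .LON0 + lg$mouth_km * .DLON_PER_KM,
      lat = .LAT0 + 0.005 + c(0, 0, interior_km) * .DLAT_PER_KM,
      habitat = "lagoon",
      array_id = c(rep(sprintf("ar_%s_mouth", tolower(lg$name)), 2),
                   sprintf("ar_%s_int_%d", tolower(lg$name), 1:2)),
      spawning_flag = FALSE,
      lagoon = lg$name,
      .zone = i, .km = c(km_mouth, NA, NA), .internal_km = c(0, 0, interior_km)
    )
  }
  st <- dplyr::bind_rows(sea, dplyr::bind_rows(lag_rows))
  st$active_from <- config$study_start
  st$active_to <- config$study_end
  st
}

# Truncated-normal fork lengths (resampling into the configured range).
draw_fork_length <- function(n, cfg) {
  fl <- rnorm(n, cfg$size_mean_mm, cfg$size_sd_mm)
  for (i in 1:20) {
    out <- fl < cfg$size_range_mm[1] | fl > cfg$size_range_mm[2]
    if (!any(out)) break
    fl[out] <- rnorm(sum(out), cfg$size_mean_mm, cfg$size_sd_mm)
  }
  pmin(pmax(fl, cfg$size_range_mm[1]), cfg$size_range_mm[2])
}

make_fish <- function(cfg) {
  n <- cfg$n_fish
  at_sea <- runif(n) < cfg$prop_sea
  lag_idx <- sample.int(nrow(cfg$lagoons), n, replace = TRUE)
  sea_idx <- sample.int(nrow(cfg$sea_sites), n, replace = TRUE)
  fl <- round(draw_fork_length(n, cfg))
  model <- ifelse(fl >= 400, "V13-1x",
                  ifelse(runif(n) < 0.5, "V9-1x", "V9-2x"))
  model[!model %in% names(cfg$tag_models)] <- names(cfg$tag_models)[1]
  release_span <- min(as.numeric(cfg$study_end) - as.numeric(cfg$study_start),
                      60 * 86400)
  release_ts <- cfg$study_start + runif(n, 0, release_span)
  release_ts <- as_utc(as.POSIXct(round(as.numeric(release_ts)),
                                  origin = "1970-01-01", tz = "UTC"))

  home_lagoon <- ifelse(at_sea, NA_character_, cfg$lagoons$name[lag_idx])
  release_site <- ifelse(at_sea, cfg$sea_sites$name[sea_idx],
                         paste(cfg$lagoons$name[lag_idx], "Lagoon"))
  home_km <- ifelse(at_sea, cfg$sea_sites$km[sea_idx], cfg$lagoons$mouth_km[lag_idx])

  dead <- runif(n) < cfg$death_fraction
  # deaths are placed so the post-death pattern has time to express
  d_lo <- as.numeric(release_ts) + 30 * 86400
  d_hi <- as.numeric(cfg$study_end) - 90 * 86400
  death_ts <- rep(as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"), n)
  ok <- dead & d_lo < d_hi
  death_ts[ok] <- as.POSIXct(round(runif(sum(ok), d_lo[ok], d_hi)),
                             origin = "1970-01-01", tz = "UTC")

  tibble::tibble(
    tag_id = sprintf("tag_%03d", seq_len(n)),
    fork_length_mm = fl,
    mass_g = round(1.3e-5 * fl^3 * exp(rnorm(n, 0, 0.08))),
    origin = ifelse(at_sea, "sea", "lagoon"),
    release_site = release_site,
    release_ts = release_ts,
    tag_model = model,
    true_death_ts = as_utc(death_ts),
    true_fate = ifelse(is.na(death_ts), "alive", "dead"),
    true_death_pattern = NA_character_,
    .home_lagoon = home_lagoon,
    .home_zone = ifelse(at_sea, 0L, lag_idx),
    .home_km = home_km,
    .tag_life_days = round(runif(n, cfg$tag_life_days[1], cfg$tag_life_days[2]))
  )
}

# Per fish x autumn-year schedules (departure dates, migration and
# philopatry coin flips, spring return dates).
make_schedule <- function(cfg, fish) {
  yrs <- departure_years(cfg)
  n <- nrow(fish)
  nearest_lagoon <- vapply(fish$.home_km, function(k) {
    which.min(abs(cfg$lagoons$mouth_km - k))
  }, integer(1))
  mode_md <- cfg$lagoons$departure_mode[nearest_lagoon]
  dep <- mig <- ret <- rh <- matrix(NA_real_, n, length(yrs))
  for (j in seq_along(yrs)) {
    mode_date <- as.numeric(as.Date(paste0(yrs[j], "-", mode_md)))
    dep[, j] <- round(rnorm(n, mode_date, cfg$departure_sd_days))
    mig[, j] <- runif(n) < p_migrate(cfg, fish$fork_length_mm)
    rw <- as.numeric(as.Date(paste0(yrs[j] + 1L, "-", cfg$return_window)))
    ret[, j] <- round(runif(n, rw[1], rw[2]))
    rh[, j] <- runif(n) < cfg$p_return_home
  }
  list(years = yrs, depart = dep, migrates = mig == 1,
       ret = ret, returns_home = rh == 1)
}

reflect_into <- function(x, lo, hi) {
  x <- ifelse(x < lo, 2 * lo - x, x)
  x <- ifelse(x > hi, 2 * hi - x, x)
  pmin(pmax(x, lo), hi)
}

#' Simulate a tagged cohort through the receiver network
#'
#' Runs the agent-based movement model over the study window and
#' generates detections under the hard-radius, per-transmission
#' Bernoulli detection model. Dead-fish detection patterns are injected
#' by [inject_dead_fish()]. Output is bit-identical for a fixed
#' configuration and seed.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `coastnet_cohort` with elements `detections`
#'   (timestamp, station_id, tag_id), `stations`, `fish`, `truth` (ground
#'   truth: `bouts` = true in-range intervals at array level,
#'   `departures` = executed lagoon departures, `deaths`), and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(
#'   n_fish = 5, n_stations_sea = 20,
#'   study_end = "2019-09-01", rng_seed = 1))
#' nrow(cohort$detections)
simulate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$rng_seed, {
    stations <- make_stations(config)
    fish <- make_fish(config)
    sched <- make_schedule(config, fish)
    eng <- run_engine(config, fish, stations, sched)
    detections <- expand_bouts(eng$bouts, fish, stations, config)
    out <- inject_dead_fish(detections, fish, stations, config,
                            seed = config$rng_seed + 1L)
    detections <- out$detections
    fish <- out$fish

    # ground truth: pre-death bouts only, at array granularity
    bouts <- eng$bouts
    bouts$array_id <- stations$array_id[bouts$station_idx]
    bouts$tag_id <- fish$tag_id[bouts$tag_idx]
    bouts$start_ts <- as_utc(as.POSIXct(as.numeric(as.POSIXct(bouts$date, tz = "UTC")) +
                                          bouts$start_s, origin = "1970-01-01", tz = "UTC"))
    bouts$end_ts <- bouts$start_ts + bouts$dwell_s
    death <- fish$true_death_ts[bouts$tag_idx]
    bouts <- bouts[is.na(death) | bouts$start_ts <= death, ]
    dep <- eng$departures
    if (nrow(dep) > 0) {
      dep$tag_id <- fish$tag_id[dep$tag_idx]
      ddeath <- fish$true_death_ts[dep$tag_idx]
      dep <- dep[is.na(ddeath) | as.numeric(as.POSIXct(dep$date, tz = "UTC")) <=
                   as.numeric(ddeath), ]
    } else {
      dep$tag_id <- character(0)
    }
    truth <- list(
      bouts = tibble::as_tibble(bouts[, c("tag_id", "array_id", "start_ts",
                                          "end_ts", "dwell_s")]),
      departures = tibble::as_tibble(dep[, c("tag_id", "lagoon", "year", "date")]),
      deaths = fish[fish$true_fate == "dead",
                    c("tag_id", "true_death_ts", "true_death_pattern")]
    )
    structure(list(detections = detections, stations = stations,
                   fish = fish, truth = truth, config = config),
              class = "coastnet_cohort")
  })
}

# Daily movement engine. Loops over days with vectorized per-fish state.
run_engine <- function(cfg, fish, stations, sched) {
  n <- nrow(fish)
  days <- seq(utc_date(fish$release_ts) |> min(),
              utc_date(cfg$study_end), by = "day")
  day_num <- as.numeric(days)
  rel_day <- as.numeric(utc_date(fish$release_ts))
  rel_sec <- as.numeric(fish$release_ts) - rel_day * 86400
  tag_end_day <- rel_day + fish$.tag_life_days

  # sea-side lookup: sea stations plus mouth stations at their coastal km
  sea_side <- which(!is.na(stations$.km))
  sea_km <- stations$.km[sea_side]
  ord <- order(sea_km)
  sea_side <- sea_side[ord]; sea_km <- sea_km[ord]
  # per-lagoon station lookup (mouth at internal 0 + interiors)
  lag_lookup <- lapply(seq_len(nrow(cfg$lagoons)), function(i) {
    idx <- which(stations$.zone == i)
    list(idx = idx, pos = stations$.internal_km[idx])
  })
  mouth_station <- vapply(seq_len(nrow(cfg$lagoons)), function(i) {
    which(stations$.zone == i & stations$.internal_km == 0)[1]
  }, integer(1))

  speed <- size_interp(cfg, fish$fork_length_mm, cfg$swim_speed_kmday)
  spawn_step <- size_interp(cfg, fish$fork_length_mm, cfg$spawn_step_km)
  L <- cfg$coastline_length_km
  zone_lo <- cfg$spawning_zone_km[1]; zone_hi <- min(cfg$spawning_zone_km[2], L)

  zone <- rep(NA_integer_, n); x <- rep(NA_real_, n)
  phase <- rep(1L, n); target <- rep(NA_real_, n)
  active <- rep(FALSE, n)
  yr_of <- function(d) as.POSIXlt(d)$year + 1900L

  bouts <- vector("list", length(days))
  deps <- vector("list", length(days))

  for (di in seq_along(days)) {
    today <- days[di]; tnum <- day_num[di]
    newly <- which(!active & rel_day <= tnum)
    if (length(newly)) {
      active[newly] <- TRUE
      zone[newly] <- fish$.home_zone[newly]
      x[newly] <- ifelse(zone[newly] > 0L, 1.0, fish$.home_km[newly])
    }
    act <- which(active & tag_end_day >= tnum)
    if (!length(act)) next
    forced <- integer(0)  # station idx of forced mouth bouts, parallel to ffish
    ffish <- integer(0)

    yj <- match(yr_of(today), sched$years)
    # --- departures ---
    if (!is.na(yj)) {
      dep_now <- act[phase[act] == 1L & sched$migrates[act, yj] &
                       sched$depart[act, yj] == tnum]
      if (length(dep_now)) {
        in_lag <- dep_now[zone[dep_now] > 0L]
        if (length(in_lag)) {
          ffish <- c(ffish, in_lag)
          forced <- c(forced, mouth_station[zone[in_lag]])
          x[in_lag] <- cfg$lagoons$mouth_km[zone[in_lag]]
          zone[in_lag] <- 0L
          deps[[di]] <- data.frame(tag_idx = in_lag,
                                   lagoon = cfg$lagoons$name[fish$.home_zone[in_lag]],
                                   year = sched$years[yj], date = today)
        }
        phase[dep_now] <- 2L
        target[dep_now] <- runif(length(dep_now), zone_lo + 1, zone_hi - 1)
      }
    }
    # --- spring returns (schedule row is previous autumn's year) ---
    yr_prev <- match(yr_of(today) - 1L, sched$years)
    if (!is.na(yr_prev)) {
      ret_now <- act[phase[act] == 3L & sched$ret[act, yr_prev] == tnum]
      if (length(ret_now)) {
        phase[ret_now] <- 4L
        target[ret_now] <- fish$.home_km[ret_now]
      }
    }
    # --- movement ---
    mg <- act[phase[act] %in% c(2L, 4L)]
    if (length(mg)) {
      stp <- speed[mg] * runif(length(mg), 0.8, 1.2)
      dir <- sign(target[mg] - x[mg]); dir[dir == 0] <- 1
      nx <- x[mg] + dir * stp
      crossed <- (target[mg] - x[mg]) * (target[mg] - nx) <= 0
      nx[crossed] <- target[mg][crossed]
      x[mg] <- nx
      arr_out <- mg[crossed & phase[mg] == 2L]
      phase[arr_out] <- 3L
      arr_home <- mg[crossed & phase[mg] == 4L]
      if (length(arr_home)) {
        if (!is.na(yr_prev)) {
          back <- arr_home[fish$.home_zone[arr_home] > 0L &
                             sched$returns_home[arr_home, yr_prev]]
        } else back <- integer(0)
        if (length(back)) {
          zone[back] <- fish$.home_zone[back]
          x[back] <- 1.0
          ffish <- c(ffish, back)
          forced <- c(forced, mouth_station[zone[back]])
        }
        phase[arr_home] <- 1L
      }
    }
    fg <- act[phase[act] == 3L]
    if (length(fg)) {
      x[fg] <- reflect_into(x[fg] + rnorm(length(fg), 0, spawn_step[fg]),
                            zone_lo, zone_hi)
    }
    fo <- setdiff(act[phase[act] == 1L], ffish)
    if (length(fo)) {
      inl <- fo[zone[fo] > 0L]
      if (length(inl)) {
        ext <- cfg$lagoons$extent_km[zone[inl]]
        x[inl] <- reflect_into(x[inl] + rnorm(length(inl), 0, cfg$forage_step_km),
                               0.25, ext)
      }
      ins <- fo[zone[fo] == 0L]
      if (length(ins)) {
        lo <- pmax(fish$.home_km[ins] - 3, 0)
        hi <- pmin(fish$.home_km[ins] + 3, L)
        x[ins] <- reflect_into(x[ins] + rnorm(length(ins), 0, cfg$forage_step_km),
                               lo, hi)
      }
    }
    # --- detection bouts ---
    b_fish <- integer(0); b_station <- integer(0)
    sea_f <- act[zone[act] == 0L]
    if (length(sea_f) && length(sea_km)) {
      j <- findInterval(x[sea_f], sea_km)
      j1 <- pmax(j, 1L); j2 <- pmin(j + 1L, length(sea_km))
      d1 <- abs(x[sea_f] - sea_km[j1]); d2 <- abs(x[sea_f] - sea_km[j2])
      best <- ifelse(d1 <= d2, j1, j2)
      dist <- pmin(d1, d2)
      hit <- dist <= cfg$detection_radius_km
      b_fish <- c(b_fish, sea_f[hit]); b_station <- c(b_station, sea_side[best[hit]])
    }
    for (i in seq_len(nrow(cfg$lagoons))) {
      lf <- act[zone[act] == i]
      if (!length(lf)) next
      lk <- lag_lookup[[i]]
      dmat <- abs(outer(x[lf], lk$pos, "-"))
      best <- max.col(-dmat, ties.method = "first")
      dist <- dmat[cbind(seq_along(lf), best)]
      hit <- dist <= cfg$detection_radius_km
      b_fish <- c(b_fish, lf[hit]); b_station <- c(b_station, lk$idx[best[hit]])
    }
    b_fish <- c(b_fish, ffish); b_station <- c(b_station, forced)
    if (length(b_fish)) {
      nb <- length(b_fish)
      dwell <- runif(nb, cfg$dwell_hours[1] * 3600, cfg$dwell_hours[2] * 3600)
      is_forced <- seq_len(nb) > (nb - length(ffish))
      dwell[is_forced] <- 3600
      start <- runif(nb, 0, pmax(86400 - dwell, 1))
      # no transmissions before release on the release day
      on_rel <- rel_day[b_fish] == tnum
      start[on_rel] <- pmax(start[on_rel], rel_sec[b_fish][on_rel] + 1)
      dwell <- pmin(dwell, 86400 - start)
      bouts[[di]] <- data.frame(tag_idx = b_fish, date = today,
                                station_idx = b_station,
                                start_s = start, dwell_s = dwell)
    }
  }
  list(bouts = dplyr::bind_rows(bouts),
       departures = dplyr::bind_rows(deps) %||%
         data.frame(tag_idx = integer(), lagoon = character(),
                    year = integer(), date = as.Date(character())))
}

`%||%` <- function(a, b) if (is.null(a) || (is.data.frame(a) && nrow(a) == 0)) b else a

# Expand in-range bouts into detections: renewal process with uniform
# delays from the fish's tag model, thinned by p_detect.
expand_bouts <- function(bouts, fish, stations, cfg) {
  empty <- tibble::tibble(timestamp = as_utc(as.POSIXct(character())),
                          station_id = character(), tag_id = character())
  if (is.null(bouts) || nrow(bouts) == 0 || cfg$p_detect == 0) return(empty)
  delays <- do.call(rbind, cfg$tag_models)
  mrow <- match(fish$tag_model[bouts$tag_idx], rownames(delays))
  dmin <- delays[mrow, 1]; dmax <- delays[mrow, 2]
  n_draw <- pmax(ceiling(bouts$dwell_s / dmin) + 1L, 1L)
  nb <- nrow(bouts)
  idx <- rep.int(seq_len(nb), n_draw)
  u <- runif(length(idx), dmin[idx], dmax[idx])
  cs <- cumsum(u)
  grp_end <- cumsum(n_draw)
  base <- c(0, cs[grp_end[-nb]])
  t_rel <- cs - base[idx]
  keep <- t_rel <= bouts$dwell_s[idx]
  heard <- runif(length(idx)) < cfg$p_detect
  keep <- keep & heard
  idx <- idx[keep]; t_rel <- t_rel[keep]
  ts <- as.numeric(as.POSIXct(bouts$date[idx], tz = "UTC")) +
    bouts$start_s[idx] + t_rel
  out <- tibble::tibble(
    timestamp = as_utc(as.POSIXct(round(ts), origin = "1970-01-01", tz = "UTC")),
    station_id = stations$station_id[bouts$station_idx[idx]],
    tag_id = fish$tag_id[bouts$tag_idx[idx]]
  )
  dplyr::arrange(out, .data$tag_id, .data$timestamp, .data$station_id)
}

#' Inject dead-fish detection patterns
#'
#' For every fish with a death time, detections after death are replaced
#' by one of three post-mortem patterns: `fixed` (all detections at a
#' single station), `overlap` (a pair of stations with overlapping
#' ranges), or `drift` (slow unidirectional displacement past successive
#' sea stations at the configured drift speed). Pattern choice depends on
#' the death habitat (lagoon deaths: fixed/overlap; sea deaths:
#' fixed/drift) and is logged in the returned fish table as ground
#' truth. When `drift_speed_kmday` is 0 all patterns collapse to
#' `fixed`, pinning every dead fish to one station.
#'
#' @param detections Detection table sorted by time within fish.
#' @param fish Fish table with `true_death_ts` set for dying fish.
#' @param stations Station table from [make_stations()].
#' @param config A [sim_config()] object.
#' @param seed RNG seed for the pattern draws.
#' @return List with updated `detections` and `fish` (pattern logged in
#'   `true_death_pattern`, fate in `true_fate`).
#' @export
inject_dead_fish <- function(detections, fish, stations, config,
                             seed = config$rng_seed + 1L) {
  dead_i <- which(!is.na(fish$true_death_ts))
  if (!length(dead_i)) return(list(detections = detections, fish = fish))
  with_seed(seed, {
    sea_st <- stations[stations$habitat == "sea", ]
    end_day <- utc_date(config$study_end)
    keep <- rep(TRUE, nrow(detections))
    new_rows <- list()
    for (k in dead_i) {
      tid <- fish$tag_id[k]
      death <- fish$true_death_ts[k]
      mine <- which(detections$tag_id == tid)
      post <- mine[detections$timestamp[mine] > death]
      keep[post] <- FALSE
      pre <- mine[detections$timestamp[mine] <= death]
      anchor_id <- if (length(pre)) {
        detections$station_id[pre[length(pre)]]
      } else stations$station_id[1]
      a <- match(anchor_id, stations$station_id)
      at_sea <- stations$habitat[a] == "sea"
      pattern <- if (config$drift_speed_kmday == 0) {
        "fixed"
      } else if (at_sea) {
        sample(c("fixed", "drift"), 1)
      } else {
        sample(c("fixed", "overlap"), 1)
      }
      partner <- NA_integer_
      if (pattern == "overlap") {
        d <- haversine_km(stations$lon[a], stations$lat[a],
                          stations$lon, stations$lat)
        d[a] <- Inf
        cand <- which(d <= 0.3)
        if (length(cand)) partner <- cand[which.min(d[cand])] else pattern <- "fixed"
      }
      fish$true_death_pattern[k] <- pattern
      fish$true_fate[k] <- "dead"

      days <- seq(utc_date(death) + 1, end_day, by = "day")
      if (!length(days)) next
      if (pattern == "fixed") {
        st_idx <- rep(a, length(days))
      } else if (pattern == "overlap") {
        st_idx <- ifelse(seq_along(days) %% 2 == 1, a, partner)
      } else { # drift
        a_sea <- match(anchor_id, sea_st$station_id)
        anchor_km <- if (!is.na(a_sea) && !is.na(sea_st$.km[a_sea])) {
          sea_st$.km[a_sea]
        } else {
          sea_st$.km[which.min(haversine_km(stations$lon[a], stations$lat[a],
                                            sea_st$lon, sea_st$lat))]
        }
        dir <- if (anchor_km > config$coastline_length_km / 2) -1 else 1
        pos <- anchor_km + dir * config$drift_speed_kmday * seq_along(days)
        nearest <- vapply(pos, function(p) which.min(abs(sea_st$.km - p)), integer(1))
        dist <- abs(sea_st$.km[nearest] - pos)
        in_rng <- dist <= config$detection_radius_km
        days <- days[in_rng]
        st_idx <- match(sea_st$station_id[nearest[in_rng]], stations$station_id)
      }
      if (!length(days)) next
      nb <- length(days)
      b <- data.frame(tag_idx = k, date = days, station_idx = st_idx,
                      start_s = runif(nb, 0, 86400 - config$dead_dwell_hours * 3600),
                      dwell_s = config$dead_dwell_hours * 3600)
      new_rows[[length(new_rows) + 1]] <- expand_bouts(b, fish, stations, config)
    }
    detections <- dplyr::bind_rows(detections[keep, ], new_rows)
    detections <- dplyr::arrange(detections, .data$tag_id, .data$timestamp,
                                 .data$station_id)
    list(detections = detections, fish = fish)
  })
}

#' Write a simulated cohort to delimited text files
#'
#' Writes `detections.csv`, `stations.csv` and `fish.csv` (ISO-8601 UTC
#' timestamps, comma-separated, header row) into `dir`. Internal
#' geometry columns (dot-prefixed) are dropped.
#'
#' @param cohort A `coastnet_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  det <- dplyr::arrange(cohort$detections, .data$timestamp, .data$station_id,
                        .data$tag_id)
  det$timestamp <- iso(det$timestamp)
  st <- cohort$stations[, c("station_id", "name", "lon", "lat", "habitat",
                            "array_id", "spawning_flag", "lagoon",
                            "active_from", "active_to")]
  st$active_from <- iso(st$active_from); st$active_to <- iso(st$active_to)
  fi <- cohort$fish[, c("tag_id", "fork_length_mm", "mass_g", "origin",
                        "release_site", "release_ts", "tag_model",
                        "true_death_ts", "true_fate")]
  fi$release_ts <- iso(fi$release_ts)
  fi$true_death_ts <- ifelse(is.na(fi$true_death_ts), "",
                             iso(fi$true_death_ts))
  paths <- file.path(dir, c("detections.csv", "stations.csv", "fish.csv"))
  readr::write_csv(det, paths[1])
  readr::write_csv(st, paths[2])
  readr::write_csv(fi, paths[3])
  invisible(paths)
}
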