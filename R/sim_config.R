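# Configuration object for the synthetic telemetry generator.

#' Configuration for the synthetic telemetry generator
#'
#' Builds a validated configuration describing the study system the
#' generator emulates: a ~200 km coastal gradient with estuarine lagoons
#' hanging off the coastline through monitored channels, a sparse sea
#' receiver line densified inside an eastern spawning zone, and a cohort
#' of tagged seabream-like fish following a two-phase annual cycle
#' (summer foraging in lagoons or near sea release sites; autumn eastward
#' migration to the spawning zone; early-spring return with philopatry).
#'
#' Geometry is one-dimensional along the coast: lagoons are off-axis
#' appendages attached at a mouth channel monitored by a pooled pair of
#' receivers; positions are projected onto a fixed west-to-east polyline
#' to obtain WGS84 coordinates, so great-circle distances between arrays
#' recover alongshore km.
#'
#' @param n_fish Number of tagged fish.
#' @param prop_sea Proportion of fish released at sea sites (the rest are
#'   released inside lagoons).
#' @param n_stations_sea Number of sea receivers. A fraction
#'   `spawn_station_frac` of them is packed into the spawning zone,
#'   mirroring dense receiver coverage at aggregation sites; the rest are
#'   spread uniformly along the coast.
#' @param spawn_station_frac Fraction of sea receivers inside the
#'   spawning zone.
#' @param sea_station_km Optional numeric vector of explicit sea-receiver
#'   coastal positions (km); overrides `n_stations_sea` placement.
#' @param n_lagoons Number of lagoons (1--4, drawn from the four named
#'   lagoons in west-to-east order).
#' @param coastline_length_km Length of the coastal gradient in km.
#' @param study_start,study_end Study window (parsed as UTC).
#' @param tag_models Named list of transmitter models, each a
#'   `c(min, max)` transmission delay in seconds.
#' @param tag_life_days Range of nominal tag life, days.
#' @param detection_radius_km Hard detection radius around a receiver.
#' @param p_detect Per-transmission detection probability within range.
#' @param dwell_hours `c(min, max)` hours a fish near a receiver remains
#'   within range on a given day (in-range availability per day).
#' @param size_range_mm Fork-length range of tagged fish, mm.
#' @param size_mean_mm,size_sd_mm Mean and SD of the (truncated normal)
#'   fork-length distribution.
#' @param swim_speed_kmday `c(min, max)` migration speed; an individual's
#'   speed interpolates linearly in fork length across `size_range_mm`.
#' @param forage_step_km Daily random-walk step while foraging.
#' @param spawn_step_km `c(min, max)` daily wandering step inside the
#'   spawning zone, interpolated in fork length.
#' @param size_dependence If `FALSE`, migration propensity, speed and
#'   spawning-zone wandering are size-independent (their midpoint
#'   values), removing the size--connectivity gradient.
#' @param p_migrate_midpoint_mm,p_migrate_scale_mm Logistic parameters of
#'   the probability that a fish undertakes the autumn spawning
#'   migration as a function of fork length (maturity schedule).
#' @param departure_sd_days SD (days) of individual departure dates
#'   around the lagoon's modal date.
#' @param return_window `c("mm-dd", "mm-dd")` window of spring return
#'   migration starts.
#' @param p_return_home Probability that a returning fish re-enters its
#'   home lagoon (philopatry); otherwise it summers at sea off the mouth.
#' @param death_fraction Fraction of fish dying during the study.
#' @param drift_speed_kmday Passive drift speed of dead fish under the
#'   drift pattern; `0` pins all dead fish to a single station.
#' @param dead_dwell_hours Daily in-range hours for a dead fish.
#' @param spawning_zone_km `c(min, max)` coastal extent of the spawning
#'   zone as fractions of `coastline_length_km` if both are <= 1,
#'   otherwise absolute km.
#' @param rng_seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return A list of class `coastnet_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_fish = 10, study_end = "2020-04-30")
#' cfg$lagoons
sim_config <- function(n_fish = 100,
                       prop_sea = 0.3,
                       n_stations_sea = 60,
                       spawn_station_frac = 0.4,
                       sea_station_km = NULL,
                       n_lagoons = 4,
                       coastline_length_km = 200,
                       study_start = "2019-05-01",
                       study_end = "2022-04-30",
                       tag_models = list("V9-1x" = c(130, 230),
                                         "V9-2x" = c(60, 120),
                                         "V13-1x" = c(80, 160)),
                       tag_life_days = c(579, 1739),
                       detection_radius_km = 0.4,
                       p_detect = 0.3,
                       dwell_hours = c(0.5, 1.5),
                       size_range_mm = c(182, 650),
                       size_mean_mm = 420,
                       size_sd_mm = 80,
                       swim_speed_kmday = c(8, 30),
                       forage_step_km = 2,
                       spawn_step_km = c(0.5, 3),
                       size_dependence = TRUE,
                       p_migrate_midpoint_mm = 250,
                       p_migrate_scale_mm = 30,
                       departure_sd_days = 2.5,
                       return_window = c("03-20", "04-10"),
                       p_return_home = 0.8,
                       death_fraction = 0.1,
                       drift_speed_kmday = 0.2,
                       dead_dwell_hours = 1.5,
                       spawning_zone_km = c(0.875, 1),
                       rng_seed = 42L) {
  cfg <- list(
    n_fish = as.integer(n_fish), prop_sea = prop_sea,
    n_stations_sea = as.integer(n_stations_sea),
    spawn_station_frac = spawn_station_frac,
    sea_station_km = sea_station_km,
    n_lagoons = as.integer(n_lagoons),
    coastline_length_km = coastline_length_km,
    study_start = as_utc(study_start), study_end = as_utc(study_end),
    tag_models = tag_models, tag_life_days = tag_life_days,
    detection_radius_km = detection_radius_km,
    p_detect = p_detect, dwell_hours = dwell_hours,
    size_range_mm = size_range_mm,
    size_mean_mm = size_mean_mm, size_sd_mm = size_sd_mm,
    swim_speed_kmday = swim_speed_kmday,
    forage_step_km = forage_step_km, spawn_step_km = spawn_step_km,
    size_dependence = isTRUE(size_dependence),
    p_migrate_midpoint_mm = p_migrate_midpoint_mm,
    p_migrate_scale_mm = p_migrate_scale_mm,
    departure_sd_days = departure_sd_days,
    return_window = return_window,
    p_return_home = p_return_home,
    death_fraction = death_fraction,
    drift_speed_kmday = drift_speed_kmday,
    dead_dwell_hours = dead_dwell_hours,
    rng_seed = as.integer(rng_seed)
  )

  L <- cfg$coastline_length_km
  if (all(spawning_zone_km <= 1)) spawning_zone_km <- spawning_zone_km * L
  cfg$spawning_zone_km <- spawning_zone_km

  # Four named lagoons, west to east, as fractions of the coastline.
  # Modal departure dates sit at the centre of a 7-day bin anchored Sep 1;
  # the westernmost-but-one ... all share mid-October except Berre (the
  # lagoon nearest the spawning zone), which departs earliest.
  all_lagoons <- tibble::tibble(
    name = c("Leucate", "Thau", "Prevost", "Berre"),
    frac = c(0.125, 0.40, 0.50, 0.85),
    extent_km = c(6, 6, 5, 7),
    departure_mode = c("10-16", "10-16", "10-16", "09-25")
  )
  if (cfg$n_lagoons < 1L || cfg$n_lagoons > nrow(all_lagoons)) {
    abort_coastnet("invalid SimConfig field 'n_lagoons': must be 1..4",
                   "coastnet_config_error")
  }
  lag <- all_lagoons[seq_len(cfg$n_lagoons), , drop = FALSE]
  lag$mouth_km <- lag$frac * L
  cfg$lagoons <- lag

  # Sea release sites (fractions of the coastline).
  cfg$sea_sites <- tibble::tibble(
    name = c("Leucate sea", "Thau sea", "Vic sea",
             "Marseille Cote Bleue sea", "Marseille calanques sea"),
    km = c(0.125, 0.40, 0.47, 0.92, 0.97) * L
  )

  validate_sim_config(cfg)
  class(cfg) <- c("coastnet_sim_config", "list")
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort_coastnet(sprintf("invalid SimConfig field '%s': %s", field, why),
                   "coastnet_config_error")
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      bad(field, "must be a probability in [0, 1]")
  }
  for (f in c("prop_sea", "p_detect", "p_return_home", "death_fraction",
              "spawn_station_frac")) chk_prob(f)
  if (cfg$n_fish < 1) bad("n_fish", "must be >= 1")
  if (cfg$coastline_length_km <= 0) bad("coastline_length_km", "must be > 0")
  if (!(cfg$study_start < cfg$study_end))
    bad("study_start", "study_start must precede study_end")
  for (m in names(cfg$tag_models)) {
    d <- cfg$tag_models[[m]]
    if (length(d) != 2 || !(d[1] < d[2]) || d[1] <= 0)
      bad("tag_models", sprintf("delay range of '%s' must satisfy 0 < min < max", m))
  }
  if (cfg$detection_radius_km <= 0) bad("detection_radius_km", "must be > 0")
  if (length(cfg$dwell_hours) != 2 || cfg$dwell_hours[1] > cfg$dwell_hours[2] ||
      cfg$dwell_hours[1] <= 0 || cfg$dwell_hours[2] > 24)
    bad("dwell_hours", "must be 0 < min <= max <= 24")
  if (diff(cfg$size_range_mm) <= 0) bad("size_range_mm", "must be an increasing interval")
  if (cfg$drift_speed_kmday < 0) bad("drift_speed_kmday", "must be >= 0")
  invisible(cfg)
}

# Linear interpolation in fork length over the configured size range,
# collapsed to the midpoint when size dependence is switched off.
size_interp <- function(cfg, fl_mm, range) {
  if (!cfg$size_dependence) return(rep((range[1] + range[2]) / 2, length(fl_mm)))
  fr <- (fl_mm - cfg$size_range_mm[1]) / diff(cfg$size_range_mm)
  fr <- pmin(pmax(fr, 0), 1)
  range[1] + fr * diff(range)
}

p_migrate <- function(cfg, fl_mm) {
  if (!cfg$size_dependence) return(rep(0.85, length(fl_mm)))
  plogis((fl_mm - cfg$p_migrate_midpoint_mm) / cfg$p_migrate_scale_mm)
}

#' Autumn (departure) years covered by a simulator configuration
#'
#' @param config A [sim_config()] object.
#' @return Integer vector of calendar years whose 1 September falls in
#'   the study window.
#' @export
departure_years <- function(config) {
  yrs <- seq(as.POSIXlt(config$study_start, tz = "UTC")$year + 1900L,
             as.POSIXlt(config$study_end, tz = "UTC")$year + 1900L)
  sep1 <- as_utc(paste0(yrs, "-09-01"))
  yrs[sep1 >= config$study_start & sep1 <= config$study_end]
}

#' Configured modal emigration bin per lagoon-year
#'
#' Returns, for each lagoon and departure year, the modal departure date
#' written into the configuration and the 7-day bin (anchored 1
#' September) containing it. Downstream phenology estimates can be
#' compared against these as ground truth.
#'
#' @param config A [sim_config()] object.
#' @param bin_days Bin width in days (default 7).
#' @return Tibble with `lagoon`, `year`, `mode_date`, `bin`.
#' @export
departure_mode_bins <- function(config, bin_days = 7L) {
  yrs <- departure_years(config)
  out <- tidyr::expand_grid(lagoon = config$lagoons$name, year = yrs)
  md <- config$lagoons$departure_mode[match(out$lagoon, config$lagoons$name)]
  out$mode_date <- as.Date(paste0(out$year, "-", md))
  anchor <- as.Date(paste0(out$year, "-09-01"))
  out$bin <- as.integer(floor(as.numeric(out$mode_date - anchor) / bin_days))
  out
}
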