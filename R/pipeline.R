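# Orchestration: simulate -> ingest -> residency -> networks ->
# communities -> phenology -> size effects, from one configuration,
# with a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, applies the quality filter and the
#' dead-fish screen, drops silent fish, pools stations into arrays, and
#' runs residency segmentation, per-fish and seasonal global network
#' layers, community detection with monthly flows, migration phenology
#' and the size/origin models. With `out_dir` set, stage outputs are
#' written as CSV/JSON under one run directory and a manifest of file
#' digests and row counts is written last.
#'
#' @param config A [sim_config()].
#' @param cohort Optional pre-built `coastnet_cohort` (skips
#'   simulation).
#' @param seed Seed overriding `config$rng_seed`.
#' @param out_dir Optional output directory.
#' @param window_h Residency continuous-presence window, hours.
#' @param filter_cfg,fate_cfg Filter and dead-fish screen settings.
#' @param resolution,n_restarts Community-detection settings.
#' @param fit_models Fit the size/origin GAMs (needs >= 20 retained
#'   fish).
#' @return List of class `coastnet_run` with all stage outputs and
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), cohort = NULL, seed = NULL,
                         out_dir = NULL, window_h = 1.5,
                         filter_cfg = filter_config(),
                         fate_cfg = fate_config(),
                         resolution = 1, n_restarts = 20L,
                         fit_models = TRUE) {
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  stations <- cohort$stations
  arrays <- arrays_from_stations(stations)

  filt <- basic_filter(cohort$detections, cohort$fish, stations, filter_cfg)
  fish <- flag_dead_fish(filt$detections, cohort$fish, stations, fate_cfg)
  fish <- drop_undetected(fish, filt$detections)
  retained <- fish$tag_id[fish$fate == "alive"]
  det <- filt$detections[filt$detections$tag_id %in% retained, ]
  fish <- enrich_fish(fish, det)
  det <- pool_arrays(det, stations)
  det <- dplyr::arrange(det, .data$tag_id, .data$timestamp, .data$array_id)

  events <- segment_events(det, window_h = window_h)
  res_summary <- summarize_residency(events)
  monthly <- monthly_detection_series(det)
  global <- seasonal_global_layers(det, arrays, seed = config$rng_seed,
                                   n_restarts = n_restarts)
  metric_tab <- fish_metric_table(det, fish[fish$fate == "alive", ], arrays)

  fish_layers <- lapply(setNames(nm = unique(det$tag_id)), function(tid) {
    build_layer(det[det$tag_id == tid, ], node_universe = arrays$array_id,
                owner = tid)
  })
  agg <- aggregate_network(fish_layers)
  partition <- detect_communities(transform_weights(agg),
                                  resolution = resolution,
                                  seed = config$rng_seed,
                                  n_restarts = n_restarts)
  flows <- community_flows(det, partition, arrays)

  emig <- emigration_peaks(det, fish[fish$fate == "alive", ], arrays)
  arrivals <- spawning_arrivals(det, fish, arrays)
  presence <- spawning_presence(det, fish, arrays)

  models <- NULL
  if (fit_models && nrow(metric_tab) >= 20) {
    models <- fit_metric_models(metric_tab)
  }

  run <- structure(list(
    config = config, cohort = cohort, arrays = arrays,
    detections = det, fish = fish, filter_audit = filt$audit,
    events = events, residency = res_summary, monthly = monthly,
    global_layers = global, metric_table = metric_tab,
    aggregate_graph = agg, partition = partition, flows = flows,
    emigration = emig, arrivals = arrivals, presence = presence,
    models = models), class = "coastnet_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, out_dir)
  }
  run
}

#' @export
print.coastnet_run <- function(x, ...) {
  cat(sprintf(
    "<coastnet_run> %d fish (%d retained), %d detections after filtering, %d arrays\n",
    nrow(x$fish), sum(x$fish$fate == "alive"), nrow(x$detections),
    nrow(x$arrays)))
  cat(sprintf("  communities: %d (Q = %.3f); residency events: %d\n",
              length(unique(x$partition$membership)), x$partition$modularity,
              nrow(x$events)))
  invisible(x)
}

# Serialize the run to CSV/JSON and build the manifest (digests last).
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    df <- as.data.frame(df)
    for (cl in names(df)) {
      if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- iso(df[[cl]])
      if (is.list(df[[cl]])) {
        df[[cl]] <- vapply(df[[cl]], paste, character(1), collapse = ";")
      }
    }
    readr::write_csv(df, p)
    paths[[name]] <<- p
    p
  }
  wr(run$detections, "detections_filtered.csv")
  wr(run$fish, "fish_enriched.csv")
  wr(run$arrays, "arrays.csv")
  wr(run$events, "residency_events.csv")
  wr(run$residency$per_fish_array, "residency_per_fish_array.csv")
  wr(run$monthly, "monthly_detections.csv")
  wr(run$metric_table, "fish_metrics.csv")
  wr(run$global_layers$comparison, "global_layer_comparison.csv")
  wr(tibble::tibble(array_id = names(run$partition$membership),
                    community = unname(run$partition$membership)),
     "communities.csv")
  wr(run$flows$between_fish, "community_flows_fish.csv")
  wr(run$emigration$records, "emigration_records.csv")
  wr(run$emigration$peaks, "emigration_peaks.csv")
  wr(run$arrivals$arrivals, "spawning_arrivals.csv")
  wr(run$presence$presence, "spawning_presence.csv")
  if (!is.null(run$models)) wr(run$models$results, "metric_model_results.csv")
  jsonlite::write_json(run$filter_audit, file.path(out_dir, "filter_audit.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths[["filter_audit.json"]] <- file.path(out_dir, "filter_audit.json")

  cfg_yaml <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(run$config), cfg_yaml)
  paths[["config.yaml"]] <- cfg_yaml

  files <- unlist(paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coastnet")),
    seed = run$config$rng_seed,
    config_digest = unname(tools::md5sum(cfg_yaml)),
    row_counts = list(detections = nrow(run$detections),
                      fish = nrow(run$fish), events = nrow(run$events),
                      metric_table = nrow(run$metric_table)),
    file_digests = as.list(setNames(unname(tools::md5sum(files)),
                                    names(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# Plain-list view of a sim config for YAML round-tripping.
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$study_start <- format(cfg$study_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$study_end <- format(cfg$study_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$lagoons <- NULL
  out$sea_sites <- NULL
  out
}

#' Build a simulator configuration from a YAML file
#'
#' The file may set any argument of [sim_config()]; unknown keys raise
#' a configuration error.
#'
#' @param path YAML file path.
#' @return A [sim_config()] object.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    abort_coastnet(paste0("config file not found: ", path), "coastnet_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_coastnet(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")),
                   "coastnet_config_error")
  }
  if (!is.null(vals$tag_models)) {
    vals$tag_models <- lapply(vals$tag_models, unlist)
  }
  do.call(sim_config, vals)
}

#' Run the whole pipeline from a YAML configuration file
#'
#' @param config_path YAML file of [sim_config()] settings.
#' @param out_dir Output directory for stage files and the manifest.
#' @param seed Optional seed override.
#' @return A `coastnet_run` (invisibly).
#' @export
run_all <- function(config_path, out_dir, seed = NULL) {
  cfg <- config_from_yaml(config_path)
  invisible(run_pipeline(cfg, seed = seed, out_dir = out_dir))
}
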