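# Directed weighted spatial movement networks from array-level detection
# sequences: per-fish layers, season-pooled global layers, and the
# metric suite.

#' Classify timestamps into foraging or spawning season
#'
#' Foraging runs 15 April -- 30 September; spawning runs 1 October --
#' 14 April, wrapping the year boundary. The two windows partition the
#' calendar.
#'
#' @param timestamp POSIXct (or coercible) vector.
#' @return Character vector, `"foraging"` or `"spawning"`.
#' @export
#' @examples
#' classify_season(as.POSIXct(c("2020-10-01", "2020-04-15"), tz = "UTC"))
classify_season <- function(timestamp) {
  md <- mmdd(as_utc(timestamp))
  ifelse(md >= 415L & md <= 930L, "foraging", "spawning")
}

# Count directed transitions between consecutive, distinct array visits.
count_transitions <- function(array_seq) {
  n <- length(array_seq)
  if (n < 2) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = integer()))
  }
  from <- array_seq[-n]; to <- array_seq[-1]
  keep <- from != to
  if (!any(keep)) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = integer()))
  }
  tibble::tibble(from = from[keep], to = to[keep]) |>
    dplyr::count(.data$from, .data$to, name = "weight")
}

#' Build a movement-network layer from a detection sequence
#'
#' Nodes are the arrays available to the owner over its tracked period;
#' a directed edge u -> v gains one unit of weight for every pair of
#' consecutive detections at different arrays (within-array repeats
#' contribute nothing). The optional link from the release location to
#' the first detection is kept in the data model, flagged, and excluded
#' from metrics by default.
#'
#' @param detections Array-level detections for one fish (or a pooled
#'   set; transitions are counted within `tag_id` groups when present),
#'   time-sorted.
#' @param node_universe Character vector of array ids available to the
#'   owner. Endpoints of observed edges are always included.
#' @param owner Label, fish id or `"global"`.
#' @param period Optional period filter: `NULL`, a season name
#'   (`"foraging"`/`"spawning"`), or a length-2 POSIXct range.
#' @param release_array Optional array id of the release location; adds
#'   the flagged release edge to the first detected array.
#' @return A `coastnet_layer`: list with `owner`, `period`, `nodes`,
#'   `edges` (`from`, `to`, `weight`, `release_edge`), `graph` (igraph,
#'   release edges excluded).
#' @export
build_layer <- function(detections, node_universe = NULL, owner = "fish",
                        period = NULL, release_array = NULL) {
  det <- detections
  if (!is.null(period)) {
    if (is.character(period) && length(period) == 1) {
      det <- det[classify_season(det$timestamp) == period, ]
    } else {
      det <- det[det$timestamp >= period[1] & det$timestamp <= period[2], ]
    }
  }
  if (!"tag_id" %in% names(det)) det$tag_id <- owner
  det <- dplyr::arrange(det, .data$tag_id, .data$timestamp)
  edges <- det |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::group_map(~count_transitions(.x$array_id)) |>
    dplyr::bind_rows()
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = integer())
  } else {
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  edges$release_edge <- rep(FALSE, nrow(edges))
  if (!is.null(release_array) && nrow(det)) {
    first_arr <- det$array_id[1]
    if (first_arr != release_array) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        from = release_array, to = first_arr, weight = 1L,
        release_edge = TRUE))
    }
  }
  nodes <- union(node_universe %||chr% character(),
                 unique(c(det$array_id, edges$from, edges$to)))
  structure(list(owner = owner,
                 period = if (is.character(period)) period else "all",
                 nodes = nodes, edges = tibble::as_tibble(edges),
                 graph = layer_graph(nodes, edges)),
            class = "coastnet_layer")
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a

# igraph view of a layer, release edges excluded.
layer_graph <- function(nodes, edges, include_release = FALSE) {
  e <- edges
  if (!include_release && nrow(e)) e <- e[!e$release_edge, ]
  igraph::graph_from_data_frame(e[, c("from", "to", "weight")],
                                directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' @export
print.coastnet_layer <- function(x, ...) {
  cat(sprintf("<coastnet_layer> owner=%s period=%s nodes=%d edges=%d (sum w=%d)\n",
              x$owner, x$period, length(x$nodes), sum(!x$edges$release_edge),
              sum(x$edges$weight[!x$edges$release_edge])))
  invisible(x)
}

#' Metric suite of a movement-network layer
#'
#' Computes the per-layer metric vector. Degree-type means are taken
#' over the layer's full node universe (isolated nodes count zero);
#' `edge_density` divides directed edge count by `n (n - 1)`;
#' `average_path_length` is the mean unweighted hop distance over
#' reachable ordered pairs; centralities are normalized maxima on the
#' directed graph with betweenness using inverse-weight edge costs
#' (heavier flow = shorter); `sum_distance_km` multiplies every traversed
#' edge's weight by the great-circle distance between its array
#' centroids. With `global = TRUE` the vector gains `mean_out_degree`
#' (unique out-neighbours), `mean_edge_value` (mean weight over existing
#' edges, with SDs) and the modularity of the partition found by
#' [detect_communities()] on the log-transformed layer.
#'
#' @param layer A `coastnet_layer`.
#' @param arrays Array table with centroids (for `sum_distance_km`;
#'   `NA` if omitted).
#' @param residency Residency index of the owner (carried through).
#' @param global Add the global-layer metrics.
#' @param seed,n_restarts Community-detection settings for the global
#'   modularity.
#' @return One-row tibble; degenerate (empty-graph) layers return zeros
#'   with `degenerate = TRUE`.
#' @export
layer_metrics <- function(layer, arrays = NULL, residency = NA_real_,
                          global = FALSE, seed = 1L, n_restarts = 20L) {
  g <- layer$graph
  n <- as.integer(igraph::vcount(g))
  m <- as.integer(igraph::ecount(g))
  w <- igraph::E(g)$weight
  degen <- (m == 0)

  und_nb <- igraph::degree(igraph::as_undirected(g, mode = "collapse"))
  mean_degree <- if (n) mean(und_nb) else 0
  strength <- igraph::strength(g, mode = "all", weights = w)
  mean_strength <- if (n) mean(strength) else 0
  density <- if (n > 1) m / (n * (n - 1)) else 0
  apl <- if (m > 0) igraph::mean_distance(g, directed = TRUE, weights = NA) else 0
  if (!is.finite(apl)) apl <- 0
  max_dc <- if (n > 1) max(und_nb) / (n - 1) else 0
  max_bc <- 0
  if (m > 0 && n > 2) {
    bt <- igraph::betweenness(g, directed = TRUE, weights = 1 / w)
    max_bc <- max(bt) / ((n - 1) * (n - 2))
  }
  sum_dist <- NA_real_
  if (!is.null(arrays) && m > 0) {
    e <- layer$edges[!layer$edges$release_edge, ]
    fi <- match(e$from, arrays$array_id); ti <- match(e$to, arrays$array_id)
    sum_dist <- sum(e$weight * haversine_km(arrays$lon[fi], arrays$lat[fi],
                                            arrays$lon[ti], arrays$lat[ti]))
  } else if (!is.null(arrays)) sum_dist <- 0

  out <- tibble::tibble(
    owner = layer$owner, period = layer$period,
    n_nodes = n, edge_count = m,
    mean_degree = mean_degree, mean_graph_strength = mean_strength,
    edge_density = density, average_path_length = apl,
    max_degree_centrality = max_dc, max_betweenness_centrality = max_bc,
    sum_distance_km = sum_dist, residency_index = residency,
    degenerate = degen)
  if (global) {
    # edges are aggregated (no parallels), so out-degree counts unique
    # out-neighbours
    outdeg <- igraph::degree(g, mode = "out")
    part <- detect_communities(transform_weights(g), resolution = 1,
                               seed = seed, n_restarts = n_restarts)
    out$mean_out_degree <- if (n) mean(outdeg) else 0
    out$sd_out_degree <- if (n > 1) sd(outdeg) else 0
    out$mean_edge_value <- if (m) mean(w) else 0
    out$sd_edge_value <- if (m > 1) sd(w) else 0
    out$modularity <- part$modularity
  }
  out
}

#' Season-pooled global network layers
#'
#' Splits the pooled detections of all retained fish into the spawning
#' and foraging windows (all years combined), builds one global layer
#' per season over the full array universe, and reports the comparison
#' metrics (mean out-degree, mean edge value, modularity).
#'
#' @param detections Array-level detections of all retained fish.
#' @param arrays Array table.
#' @param seed,n_restarts Community-detection settings for layer
#'   modularity.
#' @return List with `spawning`, `foraging` (layers) and `comparison`
#'   (two-row metric tibble).
#' @export
seasonal_global_layers <- function(detections, arrays, seed = 1L,
                                   n_restarts = 20L) {
  layers <- lapply(c(spawning = "spawning", foraging = "foraging"), function(s) {
    build_layer(detections, node_universe = arrays$array_id,
                owner = "global", period = s)
  })
  comparison <- dplyr::bind_rows(lapply(layers, layer_metrics, arrays = arrays,
                                        global = TRUE, seed = seed,
                                        n_restarts = n_restarts))
  list(spawning = layers$spawning, foraging = layers$foraging,
       comparison = comparison)
}

#' Monthly detection counts
#'
#' Calendar-month totals, zero-filled across the observed span.
#'
#' @param detections Detection table.
#' @return Tibble `month` (first day of month) and `n_detections`.
#' @export
monthly_detection_series <- function(detections) {
  if (nrow(detections) == 0) {
    return(tibble::tibble(month = as.Date(character()), n_detections = integer()))
  }
  d <- utc_date(detections$timestamp)
  mo <- as.Date(format(d, "%Y-%m-01"))
  rng <- range(mo)
  grid <- seq(rng[1], rng[2], by = "month")
  counts <- table(factor(as.character(mo), levels = as.character(grid)))
  tibble::tibble(month = grid, n_detections = as.integer(counts))
}

#' Per-fish metric table
#'
#' Builds one layer per retained fish over its full tracked period and
#' returns the metric vector joined to the fish's covariates, the input
#' for the size/origin models.
#'
#' @param detections Array-level detections (filtered, retained fish).
#' @param fish Enriched fish table (fork length, origin, liberty class).
#' @param arrays Array table.
#' @param node_universe Optional shared node universe; defaults to all
#'   arrays in `arrays`.
#' @return Tibble, one row per fish with detections.
#' @export
fish_metric_table <- function(detections, fish, arrays,
                              node_universe = arrays$array_id) {
  ri <- residency_index(detections, fish)
  ids <- intersect(fish$tag_id, unique(detections$tag_id))
  rows <- lapply(ids, function(tid) {
    d <- detections[detections$tag_id == tid, ]
    lay <- build_layer(d, node_universe = node_universe, owner = tid)
    layer_metrics(lay, arrays = arrays,
                  residency = ri$residency_index[match(tid, ri$tag_id)])
  })
  met <- dplyr::bind_rows(rows)
  cols <- intersect(c("tag_id", "fork_length_mm", "origin", "liberty_class",
                      "time_at_liberty_days"), names(fish))
  dplyr::left_join(met, fish[, cols], by = c(owner = "tag_id"))
}
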