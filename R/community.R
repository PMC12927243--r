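# Community detection on the aggregate movement network and monthly
# inter-community flows.

#' Aggregate per-fish layers into one weighted network
#'
#' Edge-wise weight sums across all layers, release edges excluded,
#' spanning the full study duration regardless of season.
#'
#' @param layers List of `coastnet_layer` objects.
#' @return igraph directed weighted graph over the union of node sets.
#' @export
aggregate_network <- function(layers) {
  edges <- dplyr::bind_rows(lapply(layers, function(l) {
    l$edges[!l$edges$release_edge, c("from", "to", "weight")]
  }))
  nodes <- unique(unlist(lapply(layers, `[[`, "nodes")))
  if (nrow(edges)) {
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Log-transform edge weights
#'
#' Applies `w -> log(1 + w)` (natural log) to compress the dynamic range
#' of movement counts before community detection; zero maps to zero and
#' order is preserved.
#'
#' @param graph igraph with non-negative `weight` edge attribute.
#' @return The graph with transformed weights.
#' @export
transform_weights <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) return(graph)
  if (any(w < 0)) {
    abort_coastnet("edge weights must be non-negative", "coastnet_data_error")
  }
  igraph::E(graph)$weight <- log1p(w)
  graph
}

#' Detect spatial communities with the Louvain algorithm
#'
#' Symmetrizes the graph to undirected (reciprocal weights summed), runs
#' Louvain multilevel modularity optimization at the given resolution
#' with `n_restarts` seeded restarts, and keeps the partition with the
#' highest modularity. Louvain is order-dependent, so the seed and
#' restart count are recorded with the result.
#'
#' @param graph igraph (typically [transform_weights()] output).
#' @param resolution Louvain resolution parameter.
#' @param seed Base RNG seed.
#' @param n_restarts Number of seeded restarts.
#' @return List of class `coastnet_partition`: `membership` (named
#'   integer vector), `modularity`, `resolution`, `seed`, `n_restarts`.
#' @export
detect_communities <- function(graph, resolution = 1, seed = 1L,
                               n_restarts = 50L) {
  if (igraph::vcount(graph) == 0) {
    return(structure(list(membership = integer(0), modularity = NA_real_,
                          resolution = resolution, seed = seed,
                          n_restarts = n_restarts),
                     class = "coastnet_partition"))
  }
  gu <- igraph::as_undirected(graph, mode = "collapse",
                              edge.attr.comb = list(weight = "sum"))
  w <- igraph::E(gu)$weight
  if (igraph::ecount(gu) == 0) {
    memb <- setNames(seq_len(igraph::vcount(gu)), igraph::V(gu)$name)
    return(structure(list(membership = memb, modularity = 0,
                          resolution = resolution, seed = seed,
                          n_restarts = n_restarts),
                     class = "coastnet_partition"))
  }
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    memb <- with_seed(seed + r - 1L, {
      igraph::membership(igraph::cluster_louvain(gu, weights = w,
                                                 resolution = resolution))
    })
    q <- igraph::modularity(gu, memb, weights = w)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  structure(list(membership = setNames(as.integer(best), names(best)),
                 modularity = best_q, resolution = resolution,
                 seed = seed, n_restarts = n_restarts),
            class = "coastnet_partition")
}

#' @export
print.coastnet_partition <- function(x, ...) {
  cat(sprintf("<coastnet_partition> %d nodes, %d communities, Q = %.4f (resolution %g, seed %d)\n",
              length(x$membership),
              length(unique(x$membership)), x$modularity,
              x$resolution, x$seed))
  invisible(x)
}

# Per-fish inter-array relocations with timestamps of both endpoints.
relocation_table <- function(detections) {
  det <- dplyr::arrange(detections, .data$tag_id, .data$timestamp)
  n <- nrow(det)
  if (n < 2) {
    return(tibble::tibble(tag_id = character(), from = character(),
                          to = character(),
                          t_from = as_utc(as.POSIXct(character())),
                          t_to = as_utc(as.POSIXct(character()))))
  }
  i <- 2:n
  same_fish <- det$tag_id[i] == det$tag_id[i - 1L]
  moved <- same_fish & det$array_id[i] != det$array_id[i - 1L]
  idx <- i[moved]
  tibble::tibble(tag_id = det$tag_id[idx],
                 from = det$array_id[idx - 1L], to = det$array_id[idx],
                 t_from = det$timestamp[idx - 1L], t_to = det$timestamp[idx])
}

#' Monthly movement flows within and between spatial communities
#'
#' Assigns each inter-array relocation to the calendar month of its
#' arrival detection. Returns within-community movement counts per
#' community per month, between-community movement counts per ordered
#' community pair per month (these two jointly conserve the total
#' relocation count), and the number of unique fish moving between each
#' ordered pair within every two-consecutive-month window. Ordered pairs
#' are labelled eastward/westward from community centroid longitudes.
#' Arrays absent from the partition are assigned fresh singleton
#' communities and reported.
#'
#' @param detections Array-level detections.
#' @param partition A `coastnet_partition`.
#' @param arrays Array table (centroids for direction labels).
#' @return List with `within`, `between_moves`, `between_fish`,
#'   `months`, `n_singletons`.
#' @export
community_flows <- function(detections, partition, arrays) {
  memb <- partition$membership
  missing <- setdiff(unique(detections$array_id), names(memb))
  if (length(missing)) {
    extra <- setNames(max(c(memb, 0L)) + seq_along(missing), missing)
    memb <- c(memb, extra)
  }
  rel <- relocation_table(detections)
  rel$month <- format(rel$t_to, "%Y-%m", tz = "UTC")
  rel$c_from <- memb[rel$from]
  rel$c_to <- memb[rel$to]

  months <- if (nrow(detections)) {
    mo <- sort(unique(format(detections$timestamp, "%Y-%m", tz = "UTC")))
    first <- as.Date(paste0(mo[1], "-01"))
    last <- as.Date(paste0(mo[length(mo)], "-01"))
    format(seq(first, last, by = "month"), "%Y-%m")
  } else character()

  within <- rel |>
    dplyr::filter(.data$c_from == .data$c_to) |>
    dplyr::count(.data$month, community = .data$c_from, name = "n_moves")
  between_moves <- rel |>
    dplyr::filter(.data$c_from != .data$c_to) |>
    dplyr::count(.data$month, .data$c_from, .data$c_to, name = "n_moves")

  cent <- arrays |>
    dplyr::mutate(community = memb[.data$array_id]) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(lon = mean(.data$lon), .groups = "drop")
  btw <- rel[rel$c_from != rel$c_to, ]
  between_fish <- tibble::tibble(window_start = character(),
                                 window_end = character(),
                                 c_from = integer(), c_to = integer(),
                                 n_fish = integer(), direction = character())
  if (length(months) > 1 && nrow(btw)) {
    wins <- lapply(seq_len(length(months) - 1), function(j) {
      inw <- btw[btw$month %in% months[j:(j + 1)], ]
      if (!nrow(inw)) return(NULL)
      inw |>
        dplyr::distinct(.data$tag_id, .data$c_from, .data$c_to) |>
        dplyr::count(.data$c_from, .data$c_to, name = "n_fish") |>
        dplyr::mutate(window_start = months[j], window_end = months[j + 1])
    })
    wf <- dplyr::bind_rows(wins)
    if (nrow(wf)) {
      lon_from <- cent$lon[match(wf$c_from, cent$community)]
      lon_to <- cent$lon[match(wf$c_to, cent$community)]
      wf$direction <- ifelse(lon_to >= lon_from, "eastward", "westward")
      between_fish <- wf[, c("window_start", "window_end", "c_from", "c_to",
                             "n_fish", "direction")]
    }
  }
  list(within = within, between_moves = between_moves,
       between_fish = between_fish, months = months,
       n_singletons = length(missing))
}
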