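# Independent reference implementations used as oracles. These are
# deliberately naive (loops, dense matrices, Floyd-Warshall) and share
# no code with the package internals they check.

# Plain sequential segmentation of one fish's (time, array) sequence.
bf_segment <- function(times, arrays, window_s = 1.5 * 3600, min_n = 2L) {
  n <- length(times)
  events <- list()
  if (n == 0) return(events)
  start <- 1L
  close_event <- function(s, e) {
    if (e - s + 1L >= min_n) {
      events[[length(events) + 1L]] <<- list(
        array = arrays[s], start = times[s], end = times[e], n = e - s + 1L)
    }
  }
  for (i in seq_len(n)[-1]) {
    extend <- arrays[i] == arrays[i - 1L] && (times[i] - times[i - 1L]) <= window_s
    if (!extend) {
      close_event(start, i - 1L)
      start <- i
    }
  }
  close_event(start, n)
  events
}

# Pair-scan transition counts for an array sequence.
bf_transitions <- function(arrays) {
  out <- list()
  for (i in seq_along(arrays)[-1]) {
    if (arrays[i] != arrays[i - 1L]) {
      key <- paste0(arrays[i - 1L], "->", arrays[i])
      out[[key]] <- (out[[key]] %||0% 0L) + 1L
    }
  }
  out
}
`%||0%` <- function(a, b) if (is.null(a)) 0L else a

# Dense-matrix recomputation of the layer metric vector.
# nodes: character universe; edges: data.frame(from, to, weight).
oracle_metrics <- function(nodes, edges, arrays = NULL) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- edges$weight[r]
  }
  und <- (A + t(A)) > 0
  nb <- rowSums(und)
  strength <- rowSums(A) + colSums(A)
  m <- sum(A > 0)

  # hop distances, Floyd-Warshall
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  off <- D[row(D) != col(D)]
  apl <- if (any(is.finite(off))) mean(off[is.finite(off)]) else 0

  # directed weighted betweenness (costs 1/w) with path counting
  eps <- 1e-12
  C <- matrix(Inf, n, n)
  C[A > 0] <- 1 / A[A > 0]
  S <- matrix(0, n, n)
  S[A > 0] <- 1
  DW <- C
  diag(DW) <- 0
  diag(S) <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- DW[i, k] + DW[k, j]
    if (alt < DW[i, j] - eps) {
      DW[i, j] <- alt
      S[i, j] <- S[i, k] * S[k, j]
    } else if (is.finite(alt) && abs(alt - DW[i, j]) <= eps) {
      S[i, j] <- S[i, j] + S[i, k] * S[k, j]
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == v || t == v || !is.finite(DW[s, t])) next
    if (is.finite(DW[s, v]) && is.finite(DW[v, t]) &&
        abs(DW[s, v] + DW[v, t] - DW[s, t]) <= eps) {
      btw[v] <- btw[v] + (S[s, v] * S[v, t]) / S[s, t]
    }
  }

  sum_dist <- NA_real_
  if (!is.null(arrays)) {
    sum_dist <- 0
    for (r in seq_len(nrow(edges))) {
      fi <- match(edges$from[r], arrays$array_id)
      ti <- match(edges$to[r], arrays$array_id)
      sum_dist <- sum_dist + edges$weight[r] *
        coastnet::haversine_km(arrays$lon[fi], arrays$lat[fi],
                               arrays$lon[ti], arrays$lat[ti])
    }
  }
  list(
    mean_degree = mean(nb),
    mean_graph_strength = mean(strength),
    edge_count = m,
    edge_density = if (n > 1) m / (n * (n - 1)) else 0,
    average_path_length = apl,
    max_degree_centrality = if (n > 1) max(nb) / (n - 1) else 0,
    max_betweenness_centrality = if (n > 2) max(btw) / ((n - 1) * (n - 2)) else 0,
    sum_distance_km = sum_dist,
    mean_out_degree = mean(rowSums(A > 0)),
    mean_edge_value = if (m > 0) mean(A[A > 0]) else 0
  )
}

# Newman modularity from the symmetrized weight matrix and a membership
# vector (named by node).
oracle_modularity <- function(nodes, edges, membership) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- A[edges$from[r], edges$to[r]] + edges$weight[r]
  }
  S <- A + t(A)
  two_m <- sum(S)
  if (two_m == 0) return(0)
  k <- rowSums(S)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[nodes[i]] == membership[nodes[j]]) {
      q <- q + S[i, j] - k[i] * k[j] / two_m
    }
  }
  unname(q / two_m)
}

# Random directed weighted graph on n nodes; weights from {1, 2, 4} so
# that inverse-weight path lengths are exact in binary floating point
# (no spurious shortest-path ties between oracle and implementation).
random_graph_fixture <- function(n, p = 0.3) {
  nodes <- paste0("a", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, ]
  edges$weight <- sample(c(1L, 2L, 4L), nrow(edges), replace = TRUE)
  list(nodes = nodes, edges = edges)
}

# Layer object from an explicit edge table (for metric comparisons).
layer_from_edges <- function(nodes, edges, owner = "x") {
  det_like <- NULL
  e <- edges
  e$release_edge <- rep(FALSE, nrow(e))
  structure(list(owner = owner, period = "all", nodes = nodes,
                 edges = tibble::as_tibble(e),
                 graph = coastnet:::layer_graph(nodes, e)),
            class = "coastnet_layer")
}

# Synthetic array geometry on a straight coast (for distance metrics).
toy_arrays <- function(ids, km = seq_along(ids) * 3) {
  tibble::tibble(array_id = ids,
                 lon = 3 + km / (111.32 * cos(43 * pi / 180)),
                 lat = 43, habitat = "sea", spawning_flag = FALSE,
                 lagoon = NA_character_)
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Planted-partition benchmark: k blocks of size b, directed like the
# movement graphs the community module operates on (each ordered pair
# draws an edge; detect_communities symmetrizes before Louvain).
planted_partition_graph <- function(k = 7, b = 10, p_in = 0.3, p_out = 0.01) {
  n <- k * b
  labels <- rep(seq_len(k), each = b)
  from <- c(); to <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p <- if (labels[i] == labels[j]) p_in else p_out
    if (runif(1) < p) { from <- c(from, i); to <- c(to, j) }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("v", from), to = paste0("v", to), weight = 1),
    directed = TRUE, vertices = data.frame(name = paste0("v", seq_len(n))))
  list(graph = g, labels = setNames(labels, paste0("v", seq_len(n))))
}
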