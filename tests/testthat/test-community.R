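# Community detection and inter-community flows.

test_that("aggregation sums edge weights across fish", {
  l1 <- build_layer(det_tbl(1:2 * 600, c("A", "B"), "f1"))
  l2 <- build_layer(det_tbl(1:2 * 600, c("A", "B"), "f2"))
  g <- aggregate_network(list(l1, l2))
  e <- igraph::as_data_frame(g)
  expect_identical(nrow(e), 1L)
  expect_identical(as.integer(e$weight), 2L)

  # disjoint ranges aggregate to their disjoint union
  l3 <- build_layer(det_tbl(1:2 * 600, c("C", "D"), "f3"))
  g2 <- aggregate_network(list(l1, l3))
  expect_identical(as.integer(igraph::ecount(g2)), 2L)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C", "D"))
})

test_that("five-fish aggregate equals the hand-summed matrix", {
  set.seed(301)
  dets <- lapply(1:5, function(i) {
    n <- sample(5:25, 1)
    det_tbl(seq_len(n) * 600, sample(c("A", "B", "C", "D"), n, replace = TRUE),
            tag = paste0("f", i))
  })
  layers <- lapply(dets, build_layer)
  g <- aggregate_network(layers)
  hand <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                          c("A", "B", "C", "D")))
  for (d in dets) {
    a <- d$array_id
    for (i in seq_along(a)[-1]) {
      if (a[i] != a[i - 1]) hand[a[i - 1], a[i]] <- hand[a[i - 1], a[i]] + 1
    }
  }
  e <- igraph::as_data_frame(g)
  for (r in seq_len(nrow(e))) {
    expect_identical(as.numeric(e$weight[r]), hand[e$from[r], e$to[r]])
  }
  expect_identical(as.numeric(sum(e$weight)), sum(hand))
})

test_that("log(1+x) weight transform has the closed-form fixed points", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
               weight = c(0, exp(1) - 1, 5)))
  tg <- transform_weights(g)
  w <- igraph::E(tg)$weight
  expect_identical(w[1], 0)
  expect_equal(w[2], 1)
  expect_equal(w[3], log1p(5))
  # order preserved on random weights
  set.seed(302)
  ww <- sort(runif(50, 0, 100))
  expect_true(all(diff(log1p(ww)) > 0))
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "A", to = "B", weight = -1))
  expect_error(transform_weights(g2), class = "coastnet_data_error")
})

test_that("two cliques joined by one weak edge split into the planted pair", {
  edges <- rbind(
    t(utils::combn(paste0("x", 1:4), 2)),
    t(utils::combn(paste0("y", 1:4), 2)),
    c("x1", "y1"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
    directed = FALSE)
  part <- detect_communities(g, resolution = 1, seed = 1, n_restarts = 10)
  memb <- part$membership
  expect_identical(length(unique(memb)), 2L)
  expect_identical(length(unique(memb[paste0("x", 1:4)])), 1L)
  expect_identical(length(unique(memb[paste0("y", 1:4)])), 1L)
  # brute force over all bipartitions: the clique split maximizes Q
  nodes <- igraph::V(g)$name
  e_df <- igraph::as_data_frame(g)
  best_q <- -Inf
  for (mask in 0:(2^8 - 1)) {
    lab <- setNames(bitwAnd(bitwShiftR(mask, 0:7), 1), nodes)
    q <- oracle_modularity(nodes, e_df, lab)
    best_q <- max(best_q, q)
  }
  expect_equal(part$modularity, best_q, tolerance = 1e-12)
})

test_that("a uniform complete graph collapses to one community", {
  pairs <- t(utils::combn(paste0("n", 1:6), 2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = 1),
    directed = FALSE)
  part <- detect_communities(g, seed = 2, n_restarts = 10)
  expect_identical(length(unique(part$membership)), 1L)
  expect_equal(part$modularity, 0, tolerance = 1e-12)
})

test_that("returned modularity beats the trivial partition and is reproducible", {
  set.seed(303)
  for (rep in 1:10) {
    fx <- random_graph_fixture(sample(4:10, 1), p = 0.4)
    g <- igraph::graph_from_data_frame(fx$edges, directed = TRUE,
                                       vertices = data.frame(name = fx$nodes))
    p1 <- detect_communities(transform_weights(g), seed = 7, n_restarts = 5)
    p2 <- detect_communities(transform_weights(g), seed = 7, n_restarts = 5)
    expect_gte(p1$modularity, 0)
    expect_identical(p1$membership, p2$membership)
  }
})

test_that("planted seven-block partitions are recovered across seeds", {
  aris <- vapply(1:5, function(s) {
    pp <- with_seed_test(1000 + s, planted_partition_graph())
    part <- detect_communities(pp$graph, resolution = 1, seed = s,
                               n_restarts = 20)
    ari(part$membership[names(pp$labels)], pp$labels)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("a between-community move lands in both adjacent month windows", {
  det <- tibble::tibble(
    timestamp = as_utc_t(c("2020-10-15 10:00:00", "2020-11-10 10:00:00",
                           "2020-12-05 10:00:00")),
    array_id = c("A", "B", "B"), tag_id = "f1")
  part <- structure(list(membership = c(A = 1L, B = 2L)),
                    class = "coastnet_partition")
  fl <- community_flows(det, part, toy_arrays(c("A", "B")))
  bf <- fl$between_fish
  expect_identical(nrow(bf), 2L)
  expect_setequal(bf$window_start, c("2020-10", "2020-11"))
  expect_true(all(bf$n_fish == 1L))
  expect_true(all(bf$direction == "eastward"))
})

test_that("within-community movers produce no between-community counts", {
  det <- det_tbl(1:5 * 3600, c("A", "B", "A", "B", "A"))
  part <- structure(list(membership = c(A = 1L, B = 1L)),
                    class = "coastnet_partition")
  fl <- community_flows(det, part, toy_arrays(c("A", "B")))
  expect_identical(nrow(fl$between_moves), 0L)
  expect_identical(sum(fl$within$n_moves), 4L)
})

test_that("flow counts conserve the total number of relocations", {
  set.seed(304)
  det <- dplyr::bind_rows(lapply(1:6, function(i) {
    n <- sample(10:40, 1)
    tibble::tibble(
      timestamp = as_utc_t("2020-01-01 00:00:00") +
        sort(runif(n, 0, 300 * 86400)),
      array_id = sample(c("A", "B", "C", "D", "E"), n, replace = TRUE),
      tag_id = paste0("f", i))
  }))
  part <- structure(list(membership = c(A = 1L, B = 1L, C = 2L, D = 2L,
                                        E = 3L)),
                    class = "coastnet_partition")
  fl <- community_flows(det, part, toy_arrays(c("A", "B", "C", "D", "E")))
  total_reloc <- det |>
    dplyr::group_by(tag_id) |>
    dplyr::summarise(k = sum(array_id[-1] != array_id[-dplyr::n()])) |>
    dplyr::pull(k) |> sum()
  expect_identical(sum(fl$within$n_moves) + sum(fl$between_moves$n_moves),
                   as.integer(total_reloc))
})

test_that("arrays missing from the partition become logged singletons", {
  det <- det_tbl(1:3 * 3600, c("A", "B", "Z"))
  part <- structure(list(membership = c(A = 1L, B = 1L)),
                    class = "coastnet_partition")
  fl <- community_flows(det, part, toy_arrays(c("A", "B", "Z")))
  expect_identical(fl$n_singletons, 1L)
  expect_identical(sum(fl$between_moves$n_moves), 1L)
})
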