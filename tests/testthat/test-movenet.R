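# Layer construction, the metric suite and season handling.

test_that("season classification follows the calendar split", {
  expect_identical(classify_season(as_utc_t("2020-10-01 00:00:00")), "spawning")
  expect_identical(classify_season(as_utc_t("2020-04-15 00:00:00")), "foraging")
  expect_identical(classify_season(as_utc_t("2020-02-29 12:00:00")), "spawning")
  expect_identical(classify_season(as_utc_t("2020-09-30 23:59:59")), "foraging")
  expect_identical(classify_season(as_utc_t("2020-04-14 23:59:59")), "spawning")
})

test_that("consecutive distinct arrays become directed weighted edges", {
  lay <- build_layer(det_tbl(1:3 * 3600, c("A", "B", "A")), owner = "f1")
  e <- dplyr::arrange(lay$edges, from)
  expect_identical(e$from, c("A", "B"))
  expect_identical(e$to, c("B", "A"))
  expect_identical(as.integer(e$weight), c(1L, 1L))

  lay2 <- build_layer(det_tbl(1:5 * 3600, c("A", "A", "B", "B", "C")))
  e2 <- dplyr::arrange(lay2$edges, from)
  expect_identical(e2$from, c("A", "B"))
  expect_identical(e2$to, c("B", "C"))
  expect_identical(as.integer(e2$weight), c(1L, 1L))

  lay3 <- build_layer(det_tbl(1:4 * 3600, rep("A", 4)))
  expect_identical(nrow(lay3$edges), 0L)
})

test_that("an empty sequence keeps the owner's node universe", {
  lay <- build_layer(det_tbl(numeric(0), character(0)),
                     node_universe = c("A", "B"), owner = "f9")
  expect_identical(lay$nodes, c("A", "B"))
  expect_identical(nrow(lay$edges), 0L)
})

test_that("release edges are flagged and excluded from the metric graph", {
  lay <- build_layer(det_tbl(1:2 * 3600, c("B", "C")), release_array = "A")
  expect_true(any(lay$edges$release_edge))
  expect_false("A" %in% igraph::as_data_frame(lay$graph)$from)
  expect_true("A" %in% lay$nodes)
})

test_that("edge weights match the brute-force pair scan on random sequences", {
  set.seed(201)
  for (rep in 1:300) {
    n <- sample(2:40, 1)
    arrays <- sample(LETTERS[1:5], n, replace = TRUE)
    lay <- build_layer(det_tbl(seq_len(n) * 600, arrays))
    bf <- bf_transitions(arrays)
    expect_identical(sum(lay$edges$weight), sum(unlist(bf)))
    for (key in names(bf)) {
      ft <- strsplit(key, "->", fixed = TRUE)[[1]]
      w <- lay$edges$weight[lay$edges$from == ft[1] & lay$edges$to == ft[2]]
      expect_identical(as.integer(w), as.integer(bf[[key]]))
    }
    # weight conservation: sum of weights = inter-array relocations
    expect_identical(as.integer(sum(lay$edges$weight)),
                     sum(arrays[-1] != arrays[-n]))
  }
})

test_that("edge-wise merge of per-fish layers equals the pooled global layer", {
  set.seed(202)
  dets <- lapply(1:5, function(i) {
    n <- sample(5:30, 1)
    det_tbl(seq_len(n) * 600, sample(LETTERS[1:6], n, replace = TRUE),
            tag = paste0("f", i))
  })
  per_fish <- lapply(dets, build_layer)
  merged <- dplyr::bind_rows(lapply(per_fish, `[[`, "edges")) |>
    dplyr::group_by(from, to) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop") |>
    dplyr::arrange(from, to)
  pooled <- build_layer(dplyr::bind_rows(dets), owner = "global")
  pe <- dplyr::arrange(pooled$edges[, c("from", "to", "weight")], from, to)
  expect_identical(as.data.frame(merged), as.data.frame(pe))
  # deleting one fish reduces the total weight by its relocations
  k <- sum(per_fish[[3]]$edges$weight)
  pooled_wo <- build_layer(dplyr::bind_rows(dets[-3]), owner = "global")
  expect_identical(sum(pooled$edges$weight) - sum(pooled_wo$edges$weight),
                   as.integer(k))
})

test_that("metric vector matches hand evaluation on a three-node layer", {
  lay <- layer_from_edges(c("A", "B", "C"),
                          data.frame(from = c("A", "B"), to = c("B", "C"),
                                     weight = c(2L, 1L)))
  m <- layer_metrics(lay, global = TRUE)
  expect_identical(m$edge_count, 2L)
  expect_equal(m$edge_density, 2 / 6)
  expect_equal(m$mean_out_degree, 2 / 3)
  expect_equal(m$mean_degree, 4 / 3)           # neighbours: 1, 2, 1
  expect_equal(m$mean_graph_strength, 2)       # 2, 3, 1
  expect_equal(m$average_path_length, 4 / 3)   # A>B 1, B>C 1, A>C 2
  expect_equal(m$mean_edge_value, 1.5)
})

test_that("single-node layers degrade to flagged zeros", {
  lay <- layer_from_edges("A", data.frame(from = character(),
                                          to = character(),
                                          weight = integer()))
  m <- layer_metrics(lay)
  expect_true(m$degenerate)
  expect_identical(m$edge_density, 0)
  expect_identical(m$average_path_length, 0)
})

test_that("metric suite agrees with the dense-matrix oracle", {
  set.seed(203)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    fx <- random_graph_fixture(n)
    arrays <- toy_arrays(fx$nodes)
    lay <- layer_from_edges(fx$nodes, fx$edges)
    m <- layer_metrics(lay, arrays = arrays, global = TRUE, seed = rep)
    o <- oracle_metrics(fx$nodes, fx$edges, arrays)
    for (f in c("mean_degree", "mean_graph_strength", "edge_count",
                "edge_density", "average_path_length",
                "max_degree_centrality", "max_betweenness_centrality",
                "sum_distance_km", "mean_out_degree", "mean_edge_value")) {
      expect_equal(m[[f]], o[[f]], tolerance = 1e-9, ignore_attr = TRUE,
                   label = paste0(f, " (rep ", rep, ")"))
    }
  }
})

test_that("identical detections in both seasons give identical layers", {
  arrays <- c("A", "B", "C", "A")
  det <- tibble::tibble(
    timestamp = c(as_utc_t("2020-06-01 00:00:00") + (1:4) * 3600,   # foraging
                  as_utc_t("2020-11-01 00:00:00") + (1:4) * 3600),  # spawning
    array_id = rep(arrays, 2), tag_id = "f1")
  g <- seasonal_global_layers(det, toy_arrays(c("A", "B", "C")))
  cmp <- g$comparison
  for (f in c("mean_out_degree", "mean_edge_value", "edge_count")) {
    expect_equal(cmp[[f]][1], cmp[[f]][2])
  }
})

test_that("a year-round commuter has two edges in each seasonal layer", {
  det <- tibble::tibble(
    timestamp = as_utc_t("2020-01-01 12:00:00") + (0:364) * 86400,
    array_id = rep(c("A", "B"), length.out = 365), tag_id = "f1")
  g <- seasonal_global_layers(det, toy_arrays(c("A", "B")))
  expect_identical(as.integer(g$comparison$edge_count), c(2L, 2L))
})

test_that("monthly series zero-fills the study span", {
  det <- dplyr::bind_rows(
    det_tbl(rep(0, 10), "A"),                       # 10 in Jan 2020
    det_tbl(rep(61 * 86400, 5), "A"))               # 5 in Mar 2020
  mo <- monthly_detection_series(det)
  expect_identical(mo$n_detections, c(10L, 0L, 5L))
})

test_that("winter detections dominate summer under default study conditions", {
  run <- shared_default_run()
  mo <- run$monthly
  m <- as.integer(format(mo$month, "%m"))
  expect_gt(sum(mo$n_detections[m %in% c(11, 12, 1, 2)]),
            sum(mo$n_detections[m %in% c(6, 7, 8, 9)]))
})
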