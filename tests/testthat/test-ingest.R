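# Loading, quality filtering with audit, dead-fish screening, array
# pooling and fish enrichment.

toy_stations <- function() {
  tibble::tibble(
    station_id = c("A", "B", "C"),
    name = c("a", "b", "c"),
    lon = 3 + c(0, 0.037, 0.074), lat = 43,  # ~3 km apart
    habitat = "sea",
    array_id = c("arA", "arB", "arC"),
    spawning_flag = FALSE, lagoon = NA_character_,
    active_from = as.POSIXct("2019-01-01", tz = "UTC"),
    active_to = as.POSIXct("2021-01-01", tz = "UTC"))
}

toy_fish <- function(release = "2020-01-01") {
  tibble::tibble(tag_id = "f1", fork_length_mm = 400, mass_g = 900,
                 origin = "sea", release_site = "Thau sea",
                 release_ts = as.POSIXct(release, tz = "UTC"),
                 tag_model = "V9-1x")
}

test_that("filter removes the hand-enumerated rows with a conserving audit", {
  st <- toy_stations(); fi <- toy_fish()
  base <- as.POSIXct("2020-01-02 00:00:00", tz = "UTC")
  det <- tibble::tibble(
    timestamp = c(base + (0:5) * 3600,          # 6 good rows at A
                  base, base,                   # 2 exact duplicates
                  as.POSIXct("2019-12-31 12:00:00", tz = "UTC"),  # pre-release
                  as.POSIXct("2020-02-01 00:00:00", tz = "UTC")), # isolated at B
    station_id = c(rep("A", 9), "B"),
    tag_id = "f1")
  out <- basic_filter(det, fi, st)
  expect_identical(out$audit$removed,
                   list(pre_release_or_inactive = 1L, duplicates = 2L,
                        isolated = 1L, speed = 0L))
  expect_identical(nrow(out$detections), 6L)
  expect_identical(out$audit$n_input,
                   out$audit$n_output + sum(unlist(out$audit$removed)))
  # idempotence: a second pass removes nothing
  again <- basic_filter(out$detections, fi, st)
  expect_identical(sum(unlist(again$audit$removed)), 0L)
})

test_that("speed rule removes physically impossible relocations", {
  st <- toy_stations(); fi <- toy_fish()
  base <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC")
  # A and C are ~6 km apart; 30 s between detections implies >17,000 km/day
  det <- tibble::tibble(
    timestamp = base + c(0, 60, 90, 150, 7200, 7260),
    station_id = c("A", "A", "C", "C", "A", "A"),
    tag_id = "f1")
  out <- basic_filter(det, fi, st)
  expect_identical(out$audit$removed$speed, 2L)
  expect_false("C" %in% out$detections$station_id)
})

test_that("loader enforces schema and referential integrity", {
  co <- shared_small_cohort()
  dir <- withr::local_tempdir()
  write_cohort_csv(co, dir)
  # missing column
  st <- readr::read_csv(file.path(dir, "stations.csv"), show_col_types = FALSE)
  readr::write_csv(st[, setdiff(names(st), "habitat")],
                   file.path(dir, "stations_bad.csv"))
  expect_error(load_tables(file.path(dir, "detections.csv"),
                           file.path(dir, "stations_bad.csv"),
                           file.path(dir, "fish.csv")),
               "habitat", class = "coastnet_schema_error")
  # unknown tag
  det <- readr::read_csv(file.path(dir, "detections.csv"), show_col_types = FALSE)
  det$tag_id[1] <- "tag_999"
  readr::write_csv(det, file.path(dir, "detections_bad.csv"))
  expect_error(load_tables(file.path(dir, "detections_bad.csv"),
                           file.path(dir, "stations.csv"),
                           file.path(dir, "fish.csv")),
               "tag_999", class = "coastnet_referential_error")
})

test_that("files with BOM and CRLF endings parse identically", {
  plain <- paste0("timestamp,station_id,tag_id\n",
                  "2020-01-02T00:00:00Z,A,f1\n",
                  "2020-01-02T01:00:00Z,B,f1\n")
  crlf <- gsub("\n", "\r\n", plain)
  dir <- withr::local_tempdir()
  writeLines(plain, file.path(dir, "plain.csv"), sep = "")
  con <- file(file.path(dir, "bom.csv"), "wb")
  writeBin(c(as.raw(c(0xEF, 0xBB, 0xBF)), charToRaw(crlf)), con)
  close(con)
  st <- toy_stations(); fi <- toy_fish(release = "2019-06-01")
  readr::write_csv(st, file.path(dir, "st.csv"))
  readr::write_csv(fi, file.path(dir, "fi.csv"))
  a <- load_tables(file.path(dir, "plain.csv"), file.path(dir, "st.csv"),
                   file.path(dir, "fi.csv"))
  b <- load_tables(file.path(dir, "bom.csv"), file.path(dir, "st.csv"),
                   file.path(dir, "fi.csv"))
  expect_identical(a$detections, b$detections)
})

test_that("array pooling silences within-cluster movement", {
  st <- toy_stations()
  st$array_id <- c("arAB", "arAB", "arC")  # A and B pooled
  base <- as.POSIXct("2020-01-02 00:00:00", tz = "UTC")
  det <- tibble::tibble(timestamp = base + (0:5) * 600,
                        station_id = rep(c("A", "B"), 3), tag_id = "f1")
  pooled <- pool_arrays(det, st)
  expect_true(all(pooled$array_id == "arAB"))
  lay <- build_layer(pooled, owner = "f1")
  expect_identical(nrow(lay$edges), 0L)
  # 1:1 mapping is the identity on keys
  st2 <- toy_stations()
  pooled2 <- pool_arrays(det, st2)
  expect_identical(pooled2$array_id, paste0("ar", det$station_id))
  # unmapped station errors
  expect_error(pool_arrays(tibble::tibble(
    timestamp = base, station_id = "Z", tag_id = "f1"), st),
    "Z", class = "coastnet_referential_error")
})

test_that("transition counts at array granularity match a hand count", {
  st <- toy_stations()
  st$array_id <- c("mouth", "mouth", "arC")
  base <- as.POSIXct("2020-01-02 00:00:00", tz = "UTC")
  seqs <- c("A", "B", "A", "C", "B", "A", "C")  # pooled: m,m,m,C,m,m,C
  det <- tibble::tibble(timestamp = base + seq_along(seqs) * 3600,
                        station_id = seqs, tag_id = "f1")
  lay <- build_layer(pool_arrays(det, st), owner = "f1")
  e <- dplyr::arrange(lay$edges, from, to)
  expect_identical(e$from, c("arC", "mouth"))
  expect_identical(e$to, c("mouth", "arC"))
  expect_identical(as.integer(e$weight), c(1L, 2L))
})

test_that("silent fish are removed, detected fish retained", {
  fi <- dplyr::bind_rows(lapply(1:5, function(i) {
    f <- toy_fish(); f$tag_id <- paste0("f", i); f
  }))
  det <- tibble::tibble(
    timestamp = as.POSIXct("2020-02-01", tz = "UTC") + 1:3,
    station_id = "A", tag_id = c("f1", "f2", "f3"))
  out <- drop_undetected(fi, det)
  expect_identical(sum(out$fate == "removed"), 2L)
  expect_setequal(out$tag_id[out$fate != "removed"], c("f1", "f2", "f3"))
})

test_that("dead-fish screen recovers simulated fates on study-scale data", {
  run <- shared_default_run()
  co <- run$cohort
  filt <- basic_filter(co$detections, co$fish, co$stations)
  fish <- flag_dead_fish(filt$detections, co$fish, co$stations)
  truth_dead <- co$fish$true_fate == "dead"
  expect_gt(sum(truth_dead), 0)
  recall <- mean(fish$fate[truth_dead] == "dead")
  fpr <- mean(fish$fate[!truth_dead] == "dead")
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.1)
})

test_that("a constructed slow drifter is flagged under the drift criterion", {
  st <- tibble::tibble(
    station_id = sprintf("s%02d", 1:10), name = sprintf("s%02d", 1:10),
    lon = 3 + (1:10) * 1.5 / (111.32 * cos(43 * pi / 180)), lat = 43,
    habitat = "sea", array_id = sprintf("ar%02d", 1:10),
    spawning_flag = FALSE, lagoon = NA_character_,
    active_from = as.POSIXct("2019-01-01", tz = "UTC"),
    active_to = as.POSIXct("2021-01-01", tz = "UTC"))
  # 0.2 km/day across stations 1.5 km apart: ~7.5 days per station
  days <- 0:60
  st_idx <- pmin(1 + floor(days * 0.2 / 1.5), 10)
  base <- as.POSIXct("2020-05-01 12:00:00", tz = "UTC")
  det <- tibble::tibble(
    timestamp = rep(base + days * 86400, each = 2) + c(0, 600),
    station_id = rep(st$station_id[st_idx], each = 2),
    tag_id = "f1")
  fi <- toy_fish()
  out <- flag_dead_fish(det, fi, st)
  expect_identical(out$fate, "dead")
  expect_identical(out$fate_criterion, "drift")
})

test_that("a migratory fish crossing arrays in October is not flagged", {
  st <- toy_stations()
  base <- as.POSIXct("2020-10-05 00:00:00", tz = "UTC")
  det <- tibble::tibble(
    timestamp = base + rep(0:5, each = 3) * 86400 + (0:17) * 60,
    station_id = rep(c("A", "B", "C", "B", "A", "C"), each = 3),
    tag_id = "f1")
  out <- flag_dead_fish(det, toy_fish(), st)
  expect_identical(out$fate, "alive")
})

test_that("liberty classes are quartiles of time at liberty", {
  fi <- dplyr::bind_rows(lapply(1:8, function(i) {
    f <- toy_fish(); f$tag_id <- paste0("f", i); f
  }))
  rel <- as.POSIXct("2020-01-01", tz = "UTC")
  det <- tibble::tibble(
    timestamp = rel + c(10, 20, 40, 60, 100, 150, 220, 300) * 86400,
    station_id = "A", tag_id = paste0("f", 1:8))
  out <- enrich_fish(fi, det)
  expect_identical(as.character(table(out$liberty_class)),
                   as.character(c(2, 2, 2, 2)))
  expect_identical(levels(out$liberty_class),
                   c("short", "medium", "long", "very_long"))
  # tag-life cap bounds liberty
  capped <- enrich_fish(fi, det, tag_life_days = 50)
  expect_true(all(capped$time_at_liberty_days <= 50))
})
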