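test_that("recording start times parse from GPS-stamped filenames", {
  t <- parse_recording_start("CAR01_20210902_223835.wav")
  expect_equal(t, as.numeric(as.POSIXct("2021-09-02 22:38:35", tz = "UTC")))
  # a within-file offset shifts the absolute time by exactly that amount
  expect_equal(t + 12.34, parse_recording_start("CAR01_20210902_223835.wav") + 12.34)
  expect_error(parse_recording_start("notes.txt"), "pattern")
})

test_that("deployment and salient-point tables read with validation", {
  dep_path <- withr::local_tempfile(fileext = ".csv")
  dep <- square_deployment()
  write.csv(data.frame(site_id = dep$site_id, lat = dep$lat, lon = dep$lon,
                       active_from = "2021-08-31T00:00:00",
                       active_to = "2021-09-07T00:00:00"),
            dep_path, row.names = FALSE)
  got <- read_deployment(dep_path)
  expect_equal(got$site_id, c("A", "B", "C", "D"))
  expect_true(all(got$active_from < got$active_to))

  sp_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(event_id = "e1", howl_id = "h1",
                       site_id = c("A", "B", "C"),
                       arrival_time_iso = c("2021-09-01T01:00:00",
                                            "2021-09-01T01:00:01.5",
                                            "2021-09-01T01:00:02")),
            sp_path, row.names = FALSE)
  sp <- read_salient_points(sp_path, deployment = got)
  expect_equal(nrow(sp), 3)
  expect_equal(diff(sp$arrival_time), c(1.5, 0.5))

  # unknown recorder rejected
  write.csv(data.frame(event_id = "e1", howl_id = "h1",
                       site_id = c("A", "Z", "C"),
                       arrival_time_iso = "2021-09-01T01:00:00"),
            sp_path, row.names = FALSE)
  expect_error(read_salient_points(sp_path, deployment = got), "Z")

  # duplicate (howl, site) rejected
  write.csv(data.frame(event_id = "e1", howl_id = "h1",
                       site_id = c("A", "A", "C"),
                       arrival_time_iso = "2021-09-01T01:00:00"),
            sp_path, row.names = FALSE)
  expect_error(read_salient_points(sp_path), "duplicate")

  # missing column named in the error
  write.csv(data.frame(event_id = "e1", howl_id = "h1"), sp_path, row.names = FALSE)
  expect_error(read_salient_points(sp_path), "site_id")
})

test_that("Raven-style selection tables resolve against file start times", {
  path <- withr::local_tempfile(fileext = ".txt")
  tab <- data.frame(
    Selection = 1:3,
    `Begin Time (s)` = c(5.00, 7.25, 9.50),
    site_id = c("A", "B", "C"),
    file = "CAR01_20210902_223835.wav",
    check.names = FALSE
  )
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- read_salient_points(path, dialect = "raven")
  start <- parse_recording_start("CAR01_20210902_223835.wav")
  expect_equal(sp$arrival_time, start + c(5.00, 7.25, 9.50))
})

test_that("howls group into events at the one-minute silence rule", {
  ev <- group_events(paste0("h", 1:4), c(0, 30, 50, 200))
  expect_equal(ev$event_id, c("e1", "e1", "e1", "e2"))
  # exactly 59 s apart: still one event (gap < 60)
  ev2 <- group_events(paste0("h", 1:4), c(0, 59, 118, 177))
  expect_equal(unique(ev2$event_id), "e1")
  # a gap of exactly 60 s starts a new event
  ev3 <- group_events(c("a", "b"), c(0, 60))
  expect_equal(ev3$event_id, c("e1", "e2"))
  expect_equal(nrow(group_events(character(), numeric())), 0)
})

test_that("event grouping is order-independent and idempotent", {
  set.seed(21)
  t <- cumsum(runif(40, 0, 120))
  ids <- paste0("h", seq_along(t))
  ref <- group_events(ids, t)
  for (k in 1:5) {
    perm <- sample(seq_along(t))
    expect_equal(group_events(ids[perm], t[perm]), ref)
  }
  again <- group_events(ref$howl_id, ref$time)
  expect_equal(again, ref)
  # within events all gaps < 60; across boundaries >= 60
  gaps <- diff(ref$time)
  same <- ref$event_id[-1] == ref$event_id[-nrow(ref)]
  expect_true(all(gaps[same] < 60))
  expect_true(all(gaps[!same] >= 60))
})

test_that("results round-trip through CSV and export to GeoJSON", {
  dep <- square_deployment()
  sal <- forward_arrivals(dep, 46.1505, 21.1945)
  res <- localise_howls(sal, dep)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, path)
  back <- read_results_csv(path)
  expect_equal(back$howl_id, res$howl_id)
  expect_equal(back$lat, res$lat)
  expect_equal(back$recorder_subset, res$recorder_subset)

  gj_path <- withr::local_tempfile(fileext = ".geojson")
  write_results_geojson(res, gj_path)
  gj <- jsonlite::read_json(gj_path)
  expect_equal(gj$type, "FeatureCollection")
  coords <- unlist(gj$features[[1]]$geometry$coordinates)
  # GeoJSON order is (lon, lat)
  expect_equal(coords[1], res$lon[1])
  expect_equal(coords[2], res$lat[1])
})
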