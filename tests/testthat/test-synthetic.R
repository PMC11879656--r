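test_that("generated arrays respect the nearest-neighbour spacing band", {
  dep <- generate_array(10, seed = 5)
  proj <- make_projection(mean(dep$lat), mean(dep$lon))
  d <- as.matrix(dist(project(proj, dep$lat, dep$lon)))
  diag(d) <- NA
  nn <- apply(d, 1, min, na.rm = TRUE)
  expect_true(all(nn >= 800 & nn <= 1200))

  # identical seed, identical coordinates
  dep2 <- generate_array(10, seed = 5)
  expect_identical(dep, dep2)

  # three sites form a usable (non-collinear) triangle
  tri <- generate_array(3, seed = 6)
  proj3 <- make_projection(mean(tri$lat), mean(tri$lon))
  sv <- svd(scale(project(proj3, tri$lat, tri$lon), scale = FALSE))$d
  expect_gt(min(sv), 50)

  expect_error(generate_array(30, spacing_min = 800, spacing_max = 801,
                              max_attempts = 50), "widen")
})

test_that("detection probability is a decreasing curve through its anchors", {
  m <- detection_model(p_max = 0.95, d50 = 1200, steepness = 4)
  expect_equal(detection_probability(m, 0), 0.95)
  expect_equal(detection_probability(m, 1200), 0.95 / 2)
  p <- detection_probability(m, seq(0, 5000, by = 50))
  expect_true(all(diff(p) <= 0))
  # the default model leaves both tails non-trivial: detections possible
  # beyond 2 km, misses possible under 1 km
  expect_gt(detection_probability(m, 2500), 0.01)
  expect_lt(detection_probability(m, 900), 0.99)
})

test_that("arrival times follow emit time + distance over speed of sound", {
  proj <- make_projection(46.147, 21.19)
  # one recorder exactly 343 m due north of the source
  ll <- unproject(proj, c(0, 0, 400, -400), c(343, 0, 0, 0))
  dep <- data.frame(site_id = c("N", "O", "E", "W"),
                    lat = ll[, "lat"], lon = ll[, "lon"],
                    active_from = 0, active_to = 2e9)
  src <- data.frame(source_id = "s1", lat = 46.147, lon = 21.19)
  sc <- make_scenario(dep, src, jitter_sd = 0,
                      model = detection_model(p_max = 1, d50 = 1e9),
                      t0 = "2021-08-31T20:00:00", seed = 1)
  sim <- simulate_howls(sc)
  tN <- sim$salient$arrival_time[sim$salient$site_id == "N"]
  expect_equal(tN - sc$emit$emit_time[1], 1.000, tolerance = 1e-9)
})

test_that("simulation is byte-identical under a fixed seed", {
  dep <- generate_array(8, seed = 9)
  src <- sample_sources_in_hull(6, dep, seed = 10)
  sc <- make_scenario(dep, src, seed = 11)
  sim1 <- simulate_howls(sc)
  sim2 <- simulate_howls(sc)
  expect_identical(sim1, sim2)
})

test_that("weak detection models leave some howls not localisable", {
  dep <- generate_array(10, seed = 12)
  src <- sample_sources_in_hull(30, dep, seed = 13)
  sc <- make_scenario(dep, src, model = detection_model(p_max = 0.7, d50 = 900),
                      seed = 14)
  sim <- simulate_howls(sc)
  expect_true(any(!sim$truth$localisable))
  expect_true(any(sim$truth$localisable))
  # every truth row accounted for even when undetected everywhere
  expect_equal(nrow(sim$truth), 30)
})

test_that("simulated salient tables round-trip through the reader", {
  dep <- generate_array(6, seed = 15)
  src <- sample_sources_in_hull(4, dep, seed = 16)
  sim <- simulate_howls(make_scenario(dep, src, seed = 17))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(sim$salient, path, row.names = FALSE)
  back <- read_salient_points(path, deployment = dep)
  expect_equal(back, sim$salient)
})

test_that("scenario emission times exercise the event-grouping rule", {
  dep <- generate_array(6, seed = 18)
  src <- sample_sources_in_hull(12, dep, seed = 19)
  sc <- make_scenario(dep, src, n_events = 3, seed = 20)
  ev <- group_events(sc$emit$source_id, sc$emit$emit_time)
  got <- ev$event_id[match(sc$emit$source_id, ev$howl_id)]
  expect_equal(got, sc$emit$event_id)
})

test_that("closer spacing makes howls more often localisable", {
  curve <- spacing_design_curve(c(300, 2000), n_reps = 60, seed = 22,
                                localise = FALSE)
  expect_gt(curve$p_localisable[1], curve$p_localisable[2])
  expect_gt(curve$p_localisable[1], 0.95)
})
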