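test_that("TDOAs are referenced to the earliest arrival", {
  td <- compute_tdoa(c("A", "B", "C"), c(10.00, 10.50, 11.00))
  expect_equal(td$reference_site, "A")
  expect_equal(td$deltas, c(B = 0.50, C = 1.00))

  td0 <- compute_tdoa(c("A", "B", "C"), c(5, 5, 5))
  expect_equal(unname(td0$deltas), c(0, 0))

  # absolute emission time is a nuisance parameter
  td_shift <- compute_tdoa(c("A", "B", "C"), c(10.00, 10.50, 11.00) + 7.3)
  expect_equal(td_shift, td)

  expect_error(compute_tdoa(c("A", "B"), c(1, 2)), "not localisable")
  expect_error(compute_tdoa(c("A", "B", "C"), c(0, 1, 30)), "spread")
  expect_error(compute_tdoa(c("A", "A", "C"), c(0, 1, 2)), "duplicate")
})

test_that("zero deltas on an equilateral triangle localise to its centre", {
  proj <- make_projection(46.147, 21.19)
  r <- 1000
  th <- c(90, 210, 330) * pi / 180
  ll <- unproject(proj, r * cos(th), r * sin(th))
  dep <- data.frame(site_id = c("A", "B", "C"), lat = ll[, "lat"], lon = ll[, "lon"])
  td <- compute_tdoa(dep$site_id, c(0, 0, 0) + 100)
  res <- multilaterate(td, dep)
  expect_lt(geo_distance(res$lat, res$lon, 46.147, 21.19), 1)
  expect_lt(res$rms_residual_s, 1e-6)
  expect_true(res$converged)
})

test_that("noise-free forward-simulated sources are recovered to < 1 m", {
  dep <- square_deployment(1000)
  set.seed(31)
  for (k in 1:5) {
    proj <- make_projection(46.147, 21.19)
    sxy <- runif(2, 150, 850)
    sll <- unproject(proj, sxy[1], sxy[2])
    sal <- forward_arrivals(dep, sll[, "lat"], sll[, "lon"])
    td <- compute_tdoa(sal$site_id, sal$arrival_time)
    res <- multilaterate(td, dep)
    expect_lt(geo_distance(res$lat, res$lon, sll[, "lat"], sll[, "lon"]), 1)
  }
})

test_that("collinear recorder geometries are rejected", {
  proj <- make_projection(46.147, 21.19)
  ll <- unproject(proj, c(0, 500, 1000), c(0, 0, 0))
  dep <- data.frame(site_id = c("A", "B", "C"), lat = ll[, "lat"], lon = ll[, "lon"])
  td <- list(reference_site = "A", deltas = c(B = 0.1, C = 0.2))
  expect_error(multilaterate(td, dep), "collinear")
})

test_that("hull classification matches geometry for simple cases", {
  dep <- square_deployment(1000)
  ctr_lat <- mean(dep$lat); ctr_lon <- mean(dep$lon)
  expect_true(local_hull_classification(ctr_lat, ctr_lon, dep))
  expect_false(local_hull_classification(ctr_lat + 0.1, ctr_lon, dep))
  # a point on a hull edge counts as inside
  edge_lat <- mean(dep$lat[1:2]); edge_lon <- mean(dep$lon[1:2])
  expect_true(local_hull_classification(edge_lat, edge_lon, dep))
  # collinear subset: degenerate hull warns and uses the on-segment rule
  proj <- make_projection(46.147, 21.19)
  ll <- unproject(proj, c(0, 500, 1000), c(0, 0, 0))
  line <- data.frame(site_id = c("A", "B", "C"), lat = ll[, "lat"], lon = ll[, "lon"])
  on_seg <- unproject(proj, 250, 0)
  off_seg <- unproject(proj, 250, 300)
  expect_warning(got_on <- local_hull_classification(on_seg[, "lat"], on_seg[, "lon"], line),
                 "collinear")
  expect_true(got_on)
  expect_warning(got_off <- local_hull_classification(off_seg[, "lat"], off_seg[, "lon"], line),
                 "collinear")
  expect_false(got_off)
})

test_that("multiple howling locations within an event are flagged", {
  proj <- make_projection(46.147, 21.19)
  near <- unproject(proj, c(0, 50, 100), c(0, 80, 20))
  one <- flag_multiple_sources(near[, "lat"], near[, "lon"])
  expect_equal(one$n_sources, 1L)

  two_xy <- unproject(proj, c(0, 30, 2000), c(0, 40, 2000))
  two <- flag_multiple_sources(two_xy[, "lat"], two_xy[, "lon"])
  expect_equal(two$n_sources, 2L)

  three_xy <- unproject(proj, c(0, 40, 1500, 1540, -1500, -1450),
                        c(0, 30, 1500, 1460, 1500, 1530))
  three <- flag_multiple_sources(three_xy[, "lat"], three_xy[, "lon"])
  expect_equal(three$n_sources, 3L)
  expect_equal(three$group[1], three$group[2])
})

test_that("translation of all arrival times leaves the estimate unchanged", {
  dep <- square_deployment(1000)
  sal <- forward_arrivals(dep, 46.1492, 21.1938, t0 = 1e9)
  res1 <- localise_howls(sal, dep)
  sal2 <- sal
  sal2$arrival_time <- sal$arrival_time + 12345.678
  res2 <- localise_howls(sal2, dep)
  expect_equal(res1$lat, res2$lat, tolerance = 1e-10)
  expect_equal(res1$lon, res2$lon, tolerance = 1e-10)
})

test_that("howls on fewer than three recorders are reported not localisable", {
  dep <- square_deployment(1000)
  sal <- forward_arrivals(dep, 46.1492, 21.1938)
  sal_few <- sal[1:2, ]
  sal_few$howl_id <- "h2"
  res <- localise_howls(rbind(sal, sal_few), dep)
  expect_equal(nrow(res), 2)
  h2 <- res[res$howl_id == "h2", ]
  expect_true(is.na(h2$lat))
  expect_equal(h2$n_recorders, 2)
  expect_false(is.na(res$lat[res$howl_id == "h1"]))
})
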