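# Shared fixtures and independent oracles, built in code.

# A square array of four recorders, `spacing` metres on a side, anchored
# near the Mures floodplain coordinates used throughout the examples.
square_deployment <- function(spacing = 1000,
                              origin_lat = 46.147, origin_lon = 21.19) {
  proj <- make_projection(origin_lat, origin_lon)
  xy <- rbind(c(0, 0), c(spacing, 0), c(spacing, spacing), c(0, spacing))
  ll <- unproject(proj, xy[, 1], xy[, 2])
  data.frame(
    site_id = c("A", "B", "C", "D"),
    lat = ll[, "lat"], lon = ll[, "lon"],
    active_from = as.numeric(as.POSIXct("2021-08-31 00:00:00", tz = "UTC")),
    active_to = as.numeric(as.POSIXct("2021-09-07 00:00:00", tz = "UTC")),
    stringsAsFactors = FALSE
  )
}

# Forward model: exact arrival times t_i = t0 + d_i / c for a source at
# (lat, lon). This is the oracle the solver is checked against; it never
# calls the solver.
forward_arrivals <- function(deployment, lat, lon, t0 = 1e9, c_sound = 343,
                             howl_id = "h1", event_id = "e1") {
  d <- geo_distance(lat, lon, deployment$lat, deployment$lon)
  data.frame(
    event_id = event_id, howl_id = howl_id,
    site_id = deployment$site_id,
    arrival_time = t0 + d / c_sound,
    stringsAsFactors = FALSE
  )
}

# Independent point-in-polygon oracle: ray casting (even-odd rule),
# written without reference to the package's half-plane test.
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive grid minimiser of the TDOA least-squares objective, written
# independently of the solver's internals.
brute_force_tdoa_min <- function(rec_xy, ref_idx, deltas_xy_order, c_sound,
                                 box, cell = 1) {
  gx <- seq(box[1], box[2], by = cell)
  gy <- seq(box[3], box[4], by = cell)
  best <- Inf
  dref_row <- function(px, py, r) sqrt((px - r[1])^2 + (py - r[2])^2)
  for (y in gy) {
    d_ref <- sqrt((gx - rec_xy[ref_idx, 1])^2 + (y - rec_xy[ref_idx, 2])^2)
    sse <- 0
    k <- 1
    for (i in seq_len(nrow(rec_xy))[-ref_idx]) {
      d_i <- sqrt((gx - rec_xy[i, 1])^2 + (y - rec_xy[i, 2])^2)
      sse <- sse + ((d_i - d_ref) / c_sound - deltas_xy_order[k])^2
      k <- k + 1
    }
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}
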