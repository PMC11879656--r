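# Synthetic acoustic surveys: recorder arrays, howling sources, arrival
# times with marking jitter, and distance-dependent detection.
#
# The generator mirrors the structure of a short field deployment: ~10
# GPS-synchronised recorders placed with 800-1200 m nearest-neighbour
# spacing, sources emitting howls grouped into events separated by >= 60 s
# of silence, per-recorder arrival times t = t0 + d/c plus Gaussian
# marking jitter (sd ~50 ms, the accuracy of manual salient-point
# marking), and a detection probability that decays with distance such
# that detections beyond 2 km and non-detections under 1 km both occur.

#' Distance-dependent detection model
#'
#' Detection probability follows the log-logistic (Hill) curve
#' `p(d) = p_max / (1 + (d / d50)^steepness)`: `p(0) = p_max`,
#' `p(d50) = p_max / 2`, non-increasing in distance. The defaults are a
#' stand-in calibrated qualitatively to observed canid-howl detection
#' ranges (detections out to ~2.5 km, non-detections from ~0.9 km, both
#' with non-trivial probability); no field-fitted curve is published for
#' this design.
#'
#' @param p_max detection probability at distance 0 (0 < p_max <= 1).
#' @param d50 distance at which probability halves, metres.
#' @param steepness dimensionless slope of the decay.
#' @return an object of class `howloc_detection_model`.
#' @export
detection_model <- function(p_max = 0.95, d50 = 1200, steepness = 4) {
  stopifnot(p_max > 0, p_max <= 1, d50 > 0, steepness > 0)
  structure(list(p_max = p_max, d50 = d50, steepness = steepness),
            class = "howloc_detection_model")
}

#' Detection probability at given distances
#' @param model a [detection_model()].
#' @param distance_m distances in metres (vectorised).
#' @return probabilities in `[0, p_max]`.
#' @export
detection_probability <- function(model, distance_m) {
  stopifnot(inherits(model, "howloc_detection_model"), all(distance_m >= 0))
  model$p_max / (1 + (distance_m / model$d50)^model$steepness)
}

#' Generate a random recorder array
#'
#' Sequential random placement with rejection: each new site must have
#' its nearest neighbour within `[spacing_min, spacing_max]` (and every
#' neighbour at least `spacing_min` away), reproducing the "random in
#' the field but roughly evenly spaced" character of real deployments.
#' The first three sites are additionally rejected if collinear.
#'
#' @param n number of recorders (>= 3).
#' @param spacing_min,spacing_max nearest-neighbour spacing bounds,
#'   metres.
#' @param origin_lat,origin_lon geographic anchor of the array.
#' @param seed integer seed; identical seeds give identical arrays.
#' @param active_from,active_to deployment interval (ISO 8601 strings).
#' @param max_attempts rejection-sampling budget per site.
#' @return a deployment data frame (`site_id`, `lat`, `lon`,
#'   `active_from`, `active_to` in epoch seconds).
#' @export
generate_array <- function(n, spacing_min = 800, spacing_max = 1200,
                           origin_lat = 46.147, origin_lon = 21.19,
                           seed = 20210831,
                           active_from = "2021-08-31T00:00:00",
                           active_to = "2021-09-07T00:00:00",
                           max_attempts = 5000) {
  stopifnot(n >= 3, spacing_min > 0, spacing_max > spacing_min)
  set.seed(seed)
  proj <- make_projection(origin_lat, origin_lon)
  pts <- matrix(c(0, 0), ncol = 2)
  attempts <- 0L
  while (nrow(pts) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " recorders after ", max_attempts,
           " attempts; widen [spacing_min, spacing_max]")
    # propose near a randomly chosen existing site, at a spacing drawn
    # uniformly from the allowed band
    anchor <- pts[sample.int(nrow(pts), 1), ]
    r <- stats::runif(1, spacing_min, spacing_max)
    th <- stats::runif(1, 0, 2 * pi)
    cand <- anchor + r * c(cos(th), sin(th))
    d <- sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
    if (min(d) < spacing_min || min(d) > spacing_max) next
    trial <- rbind(pts, cand)
    if (nrow(trial) == 3) {
      sv <- svd(scale(trial, scale = FALSE))$d
      if (min(sv) < 50) next  # reject near-collinear triangles
    }
    pts <- trial
  }
  ll <- unproject(proj, pts[, 1], pts[, 2])
  data.frame(
    site_id = as.character(seq_len(n)),
    lat = ll[, "lat"], lon = ll[, "lon"],
    active_from = parse_iso_time(active_from),
    active_to = parse_iso_time(active_to),
    stringsAsFactors = FALSE
  )
}

#' Draw random source positions within the array's convex hull
#'
#' Rejection sampling over the hull bounding box.
#'
#' @param n number of sources.
#' @param deployment deployment data frame.
#' @param seed integer seed.
#' @param margin_m optional inward/outward buffer: positive places
#'   sources only where every hull edge is at least this far (crude
#'   shrink via scaling towards the centroid); 0 uses the hull as is.
#' @return data frame `source_id`, `lat`, `lon`.
#' @export
sample_sources_in_hull <- function(n, deployment, seed = 20210831, margin_m = 0) {
  set.seed(seed)
  proj <- make_projection(mean(deployment$lat), mean(deployment$lon))
  rec_xy <- project(proj, deployment$lat, deployment$lon)
  hull <- rec_xy[grDevices::chull(rec_xy), , drop = FALSE]
  if (margin_m > 0) {
    ctr <- colMeans(hull)
    span <- mean(sqrt((hull[, 1] - ctr[1])^2 + (hull[, 2] - ctr[2])^2))
    shrink <- max(0.1, 1 - margin_m / span)
    hull <- sweep(sweep(hull, 2, ctr) * shrink, 2, ctr, "+")
  }
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    cand <- cbind(stats::runif(4 * n, min(hull[, 1]), max(hull[, 1])),
                  stats::runif(4 * n, min(hull[, 2]), max(hull[, 2])))
    keep <- vapply(seq_len(nrow(cand)),
                   function(i) point_in_convex_hull(cand[i, 1], cand[i, 2], hull),
                   TRUE)
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  ll <- unproject(proj, out[, 1], out[, 2])
  data.frame(source_id = paste0("s", seq_len(n)),
             lat = ll[, "lat"], lon = ll[, "lon"],
             stringsAsFactors = FALSE)
}

#' Build a synthetic survey scenario
#'
#' @param deployment deployment data frame (see [generate_array()]).
#' @param sources data frame `source_id`, `lat`, `lon`; one howl is
#'   emitted per source row.
#' @param n_events number of howling events to spread the howls over;
#'   within-event inter-howl gaps are drawn < 60 s and events are
#'   separated by >= 60 s of silence.
#' @param speed_of_sound m/s.
#' @param jitter_sd per-recorder Gaussian marking-error sd, seconds.
#' @param model detection model from [detection_model()].
#' @param t0 survey start, ISO 8601.
#' @param seed integer seed.
#' @return an object of class `howloc_scenario`: a list with the inputs
#'   plus `emit` (per-howl emission times and event ids).
#' @export
make_scenario <- function(deployment, sources, n_events = NULL,
                          speed_of_sound = 343, jitter_sd = 0.05,
                          model = detection_model(),
                          t0 = "2021-08-31T20:00:00",
                          seed = 20210831) {
  set.seed(seed)
  n <- nrow(sources)
  if (is.null(n_events)) n_events <- max(1L, ceiling(n / 4))
  event_of <- sort(rep_len(seq_len(n_events), n))
  t <- numeric(n)
  clock <- parse_iso_time(t0)
  for (i in seq_len(n)) {
    gap <- if (i == 1) 0
    else if (event_of[i] != event_of[i - 1]) stats::runif(1, 90, 300)
    else stats::runif(1, 5, 45)
    clock <- clock + gap
    t[i] <- clock
  }
  structure(list(
    deployment = deployment,
    sources = sources,
    emit = data.frame(source_id = sources$source_id,
                      emit_time = t,
                      event_id = paste0("e", event_of),
                      stringsAsFactors = FALSE),
    speed_of_sound = speed_of_sound,
    jitter_sd = jitter_sd,
    model = model,
    seed = seed
  ), class = "howloc_scenario")
}

#' Simulate salient-point, truth and detection tables from a scenario
#'
#' For every source-recorder pair a detection is drawn from the scenario's
#' detection model at the true ground distance; detected pairs receive an
#' arrival time `emit_time + distance / c + N(0, jitter_sd)`. Sources
#' detected on fewer than three recorders are still emitted (they appear
#' in the truth and detection tables) but cannot be localised, as in real
#' surveys where most heard events are not markable on enough devices.
#'
#' @param scenario from [make_scenario()].
#' @return a list of data frames:
#'   `salient` (`event_id`, `howl_id`, `site_id`, `arrival_time`),
#'   `truth` (`howl_id`, `lat`, `lon`, `emit_time`, `event_id`,
#'   `n_detections`, `localisable`), and
#'   `detections` (`howl_id`, `site_id`, `distance_m`, `detected`).
#' @export
simulate_howls <- function(scenario) {
  stopifnot(inherits(scenario, "howloc_scenario"))
  set.seed(scenario$seed + 1L)
  dep <- scenario$deployment
  src <- scenario$sources
  emit <- scenario$emit
  sal <- list(); det <- list()
  for (i in seq_len(nrow(src))) {
    d <- geo_distance(src$lat[i], src$lon[i], dep$lat, dep$lon)
    p <- detection_probability(scenario$model, d)
    hit <- stats::runif(length(d)) < p
    det[[i]] <- data.frame(howl_id = src$source_id[i], site_id = dep$site_id,
                           distance_m = d, detected = hit,
                           stringsAsFactors = FALSE)
    if (any(hit)) {
      arr <- emit$emit_time[i] + d[hit] / scenario$speed_of_sound +
        stats::rnorm(sum(hit), 0, scenario$jitter_sd)
      sal[[i]] <- data.frame(event_id = emit$event_id[i],
                             howl_id = src$source_id[i],
                             site_id = dep$site_id[hit],
                             arrival_time = arr,
                             stringsAsFactors = FALSE)
    }
  }
  detections <- do.call(rbind, det)
  n_det <- vapply(det, function(x) sum(x$detected), 1L)
  truth <- data.frame(howl_id = src$source_id, lat = src$lat, lon = src$lon,
                      emit_time = emit$emit_time, event_id = emit$event_id,
                      n_detections = n_det,
                      localisable = n_det >= 3,
                      stringsAsFactors = FALSE)
  salient <- if (length(sal)) do.call(rbind, sal) else
    data.frame(event_id = character(), howl_id = character(),
               site_id = character(), arrival_time = numeric())
  rownames(salient) <- rownames(truth) <- rownames(detections) <- NULL
  list(salient = salient, truth = truth, detections = detections)
}

#' Monte-Carlo design curve for recorder spacing
#'
#' For each candidate spacing, simulates arrays and in-hull sources and
#' reports the probability a howl is detected on >= 3 recorders (hence
#' localisable) and the median localisation error among localised howls.
#' Useful to choose a deployment spacing before going to the field.
#'
#' @param spacings vector of nominal spacings, metres; each array uses
#'   `[0.8, 1.2] * spacing` as its nearest-neighbour band.
#' @param model detection model.
#' @param n_reps sources simulated per spacing (>= 100 recommended for
#'   stable estimates).
#' @param n_recorders array size.
#' @param jitter_sd marking jitter sd, seconds.
#' @param seed integer seed.
#' @param localise whether to run the (slower) solver for the error
#'   column; if `FALSE`, `median_error_m` is `NA`.
#' @return data frame `spacing_m`, `p_localisable`, `median_error_m`.
#' @export
spacing_design_curve <- function(spacings, model = detection_model(),
                                 n_reps = 100, n_recorders = 10,
                                 jitter_sd = 0.05, seed = 20210831,
                                 localise = TRUE) {
  rows <- lapply(seq_along(spacings), function(k) {
    s <- spacings[k]
    dep <- generate_array(n_recorders, spacing_min = 0.8 * s,
                          spacing_max = 1.2 * s,
                          seed = seed + 97L * k)
    src <- sample_sources_in_hull(n_reps, dep, seed = seed + 97L * k + 1L)
    sc <- make_scenario(dep, src, jitter_sd = jitter_sd, model = model,
                        seed = seed + 97L * k + 2L)
    sim <- simulate_howls(sc)
    p_loc <- mean(sim$truth$localisable)
    med <- NA_real_
    if (localise && any(sim$truth$localisable)) {
      res <- localise_howls(sim$salient, dep,
                            cfg = solver_config(grid_cell = max(50, s / 10)))
      ev <- evaluate_localisations(res, sim$truth)
      med <- stats::median(ev$per_howl$error_m)
    }
    data.frame(spacing_m = s, p_localisable = p_loc, median_error_m = med)
  })
  do.call(rbind, rows)
}
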