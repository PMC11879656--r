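# Hyperbolic TDOA localisation.
#
# Each time difference of arrival constrains the source to one branch of
# a hyperbola with the two recorders as foci. With >= 3 recorders the
# source position s is estimated by minimising
#
#   SSE(s) = sum_i [ (|s - r_i| - |s - r_ref|) / c - dt_i ]^2
#
# over the plane, where r_ref is the earliest-arrival recorder and dt_i
# the observed delays. The objective is multimodal (three-recorder sets
# are exactly determined and can have two hyperbola-intersection
# solutions), so the solver enumerates basins with a coarse grid over a
# bounding box and refines the best cells with Nelder-Mead. Ties are
# broken by lowest RMS residual, then by proximity to the recorder
# centroid; a surviving far-apart near-tie is flagged ambiguous.

#' Default solver configuration
#'
#' @param speed_of_sound speed of sound in air, m/s. Must lie in the
#'   plausible range 300--360; the default 343 corresponds to ~20 degC
#'   (see [speed_of_sound_at()]).
#' @param grid_cell coarse grid spacing in metres.
#' @param max_range padding of the search box beyond the recorder
#'   bounding box, metres. The default 4 km covers the farthest
#'   non-detections seen in field deployments of this design (~3.7 km).
#' @param n_refine number of best grid cells refined by Nelder-Mead.
#' @param residual_tol RMS residual (seconds) below which the fit is
#'   considered converged.
#' @param max_tdoa_window maximum allowed arrival-time spread within one
#'   howl, seconds; guards against mismatched salient points joined under
#'   one howl id (~15 s is ~5 km of path difference).
#' @param min_recorders minimum number of distinct recorders per howl.
#' @param ambiguity_sep_m two refined minima further apart than this with
#'   near-equal residuals mark the solution ambiguous.
#' @return a named list of solver settings.
#' @export
solver_config <- function(speed_of_sound = 343,
                          grid_cell = 50,
                          max_range = 4000,
                          n_refine = 3,
                          residual_tol = 1e-6,
                          max_tdoa_window = 15,
                          min_recorders = 3,
                          ambiguity_sep_m = 100) {
  if (speed_of_sound < 300 || speed_of_sound > 360)
    stop("speed_of_sound outside plausible air range [300, 360] m/s")
  stopifnot(grid_cell > 0, max_range > 0, n_refine >= 1,
            residual_tol > 0, max_tdoa_window > 0, min_recorders >= 3)
  list(speed_of_sound = speed_of_sound, grid_cell = grid_cell,
       max_range = max_range, n_refine = n_refine,
       residual_tol = residual_tol, max_tdoa_window = max_tdoa_window,
       min_recorders = min_recorders, ambiguity_sep_m = ambiguity_sep_m)
}

#' Speed of sound in dry air at a given temperature
#'
#' Linear approximation c(T) = 331.3 + 0.606 T, T in degrees Celsius.
#'
#' @param temp_c air temperature, degC.
#' @return speed of sound, m/s.
#' @export
speed_of_sound_at <- function(temp_c) 331.3 + 0.606 * temp_c

#' Compute time differences of arrival for one howl
#'
#' The reference recorder is the earliest arrival, so all deltas are
#' non-negative; adding a constant to every arrival time leaves the
#' result unchanged (the absolute emission time is a nuisance parameter).
#'
#' @param site_id character vector of recorder ids (distinct).
#' @param arrival_time numeric arrival times, seconds.
#' @param max_tdoa_window maximum allowed spread, seconds.
#' @param min_recorders minimum number of recorders.
#' @return a list with `reference_site` and `deltas` (named numeric,
#'   seconds, the reference omitted).
#' @examples
#' compute_tdoa(c("A", "B", "C"), c(10, 10.5, 11))
#' @export
compute_tdoa <- function(site_id, arrival_time,
                         max_tdoa_window = 15, min_recorders = 3) {
  stopifnot(length(site_id) == length(arrival_time))
  if (anyDuplicated(site_id))
    stop("duplicate site_id within one howl")
  if (length(site_id) < min_recorders)
    stop("not localisable: salient points on ", length(site_id),
         " recorder(s); need at least ", min_recorders)
  spread <- max(arrival_time) - min(arrival_time)
  if (spread > max_tdoa_window)
    stop(sprintf("arrival-time spread %.2f s exceeds the %.1f s window; salient points are unlikely to belong to one howl",
                 spread, max_tdoa_window))
  ref <- which.min(arrival_time)
  deltas <- arrival_time[-ref] - arrival_time[ref]
  names(deltas) <- site_id[-ref]
  list(reference_site = site_id[ref], deltas = deltas)
}

# TDOA sum-of-squares objective, vectorised over candidate positions.
# xy: n x 2 candidate matrix; rec_xy: recorder coords with rownames =
# site ids; returns SSE in s^2 per candidate.
tdoa_objective <- function(xy, rec_xy, ref_site, deltas, c_sound) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  ref <- rec_xy[ref_site, ]
  d_ref <- sqrt((xy[, 1] - ref[1])^2 + (xy[, 2] - ref[2])^2)
  sse <- 0
  for (s in names(deltas)) {
    ri <- rec_xy[s, ]
    d_i <- sqrt((xy[, 1] - ri[1])^2 + (xy[, 2] - ri[2])^2)
    sse <- sse + ((d_i - d_ref) / c_sound - deltas[[s]])^2
  }
  sse
}

#' Localise one howl by TDOA multilateration
#'
#' Minimises the hyperbolic least-squares objective by coarse grid search
#' over the recorder bounding box padded by `max_range`, followed by
#' Nelder-Mead refinement from the best `n_refine` grid cells.
#'
#' @param tdoa a TDOA set from [compute_tdoa()].
#' @param recorders data frame with columns `site_id`, `lat`, `lon`
#'   covering every site in the TDOA set.
#' @param cfg solver settings from [solver_config()].
#' @return a one-row data frame: `lat`, `lon`, `rms_residual_s`,
#'   `n_recorders`, `recorder_subset` (list column), `in_local_hull`
#'   (`NA`, filled by [local_hull_classification()] /
#'   [localise_howls()]), `converged`, `ambiguous`, plus attribute
#'   `"candidates"` holding the refined local minima.
#' @export
multilaterate <- function(tdoa, recorders, cfg = solver_config()) {
  sites <- c(tdoa$reference_site, names(tdoa$deltas))
  rec <- recorders[match(sites, recorders$site_id), , drop = FALSE]
  if (any(is.na(rec$site_id)))
    stop("recorders table is missing site(s): ",
         paste(setdiff(sites, recorders$site_id), collapse = ", "))
  if (any(abs(tdoa$deltas) > cfg$max_tdoa_window))
    stop("TDOA delta exceeds max_tdoa_window")

  proj <- make_projection(mean(rec$lat), mean(rec$lon))
  rec_xy <- project(proj, rec$lat, rec$lon)
  rownames(rec_xy) <- rec$site_id

  # collinear arrays give an objective flat along the perpendicular axis
  sv <- svd(scale(rec_xy, scale = FALSE))$d
  if (min(sv) < 1)
    stop("recorder geometry is collinear (smallest singular value ",
         signif(min(sv), 3), " m); the position is not identifiable")

  # coarse grid over the padded bounding box
  gx <- seq(min(rec_xy[, 1]) - cfg$max_range, max(rec_xy[, 1]) + cfg$max_range,
            by = cfg$grid_cell)
  gy <- seq(min(rec_xy[, 2]) - cfg$max_range, max(rec_xy[, 2]) + cfg$max_range,
            by = cfg$grid_cell)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  obj <- tdoa_objective(grid, rec_xy, tdoa$reference_site, tdoa$deltas,
                        cfg$speed_of_sound)
  if (!any(is.finite(obj)))
    stop("not localisable: no grid cell with a finite objective")

  # refine from the best cells, keeping them mutually distinct so both
  # basins of a two-solution geometry are explored
  ord <- order(obj)
  starts <- matrix(numeric(0), ncol = 2)
  for (k in ord) {
    if (nrow(starts) >= cfg$n_refine) break
    if (nrow(starts) == 0 ||
        all(sqrt((starts[, 1] - grid[k, 1])^2 + (starts[, 2] - grid[k, 2])^2) >
            2 * cfg$grid_cell)) {
      starts <- rbind(starts, grid[k, ])
    }
  }

  refine <- function(p0) {
    fit <- stats::optim(p0, function(p)
      tdoa_objective(p, rec_xy, tdoa$reference_site, tdoa$deltas,
                     cfg$speed_of_sound),
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 2000))
    # restart once: Nelder-Mead simplexes can collapse early
    stats::optim(fit$par, function(p)
      tdoa_objective(p, rec_xy, tdoa$reference_site, tdoa$deltas,
                     cfg$speed_of_sound),
      method = "Nelder-Mead",
      control = list(reltol = 1e-14, maxit = 2000))
  }
  fits <- apply(starts, 1, refine, simplify = FALSE)
  cand <- data.frame(
    x = vapply(fits, function(f) f$par[1], 1),
    y = vapply(fits, function(f) f$par[2], 1),
    sse = vapply(fits, function(f) f$value, 1)
  )
  n_dt <- length(tdoa$deltas)
  cand$rms <- sqrt(cand$sse / n_dt)

  # primary: lowest RMS; among near-ties, nearest to the recorder centroid
  centroid <- colMeans(rec_xy)
  tie <- cand$rms <= min(cand$rms) + cfg$residual_tol
  cand$centroid_dist <- sqrt((cand$x - centroid[1])^2 + (cand$y - centroid[2])^2)
  pick <- which(tie)[which.min(cand$centroid_dist[tie])]
  sep <- sqrt((cand$x[tie] - cand$x[pick])^2 + (cand$y[tie] - cand$y[pick])^2)
  ambiguous <- any(sep > cfg$ambiguity_sep_m)

  ll <- unproject(proj, cand$x[pick], cand$y[pick])
  geo <- unproject(proj, cand$x, cand$y)
  cand$lat <- geo[, "lat"]; cand$lon <- geo[, "lon"]

  res <- data.frame(
    lat = ll[, "lat"], lon = ll[, "lon"],
    rms_residual_s = cand$rms[pick],
    n_recorders = length(sites),
    in_local_hull = NA,
    converged = cand$rms[pick] < cfg$residual_tol ||
      all(vapply(fits, function(f) f$convergence == 0L, TRUE)),
    ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
  res$recorder_subset <- list(sites)
  attr(res, "candidates") <- cand
  res
}

# Point-in-convex-polygon for a point and hull vertices in a planar
# frame. The hull is taken counter-clockwise; a point is inside iff it is
# on the left of (or on, within eps metres) every edge.
point_in_convex_hull <- function(px, py, hull_xy, eps = 1e-9) {
  n <- nrow(hull_xy)
  if (n < 3) return(FALSE)
  cross <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross[i] <- (hull_xy[j, 1] - hull_xy[i, 1]) * (py - hull_xy[i, 2]) -
      (hull_xy[j, 2] - hull_xy[i, 2]) * (px - hull_xy[i, 1])
  }
  all(cross >= -eps) || all(cross <= eps)
}

#' Classify a position against the local convex hull of its recorders
#'
#' "Local" hull: the convex hull of only those recorders that
#' contributed to the localisation of this howl. Positions on the hull
#' boundary count as inside. A degenerate (collinear) recorder subset has
#' no interior; the point is classified outside unless it lies on the
#' segment, with a warning.
#'
#' @param lat,lon position to classify, WGS84 degrees.
#' @param recorders data frame `site_id`, `lat`, `lon` of the recorders
#'   used for the localisation (>= 3 rows).
#' @return `TRUE` (inside or on the boundary) or `FALSE`.
#' @export
local_hull_classification <- function(lat, lon, recorders) {
  stopifnot(nrow(recorders) >= 3)
  proj <- make_projection(mean(recorders$lat), mean(recorders$lon))
  rec_xy <- project(proj, recorders$lat, recorders$lon)
  p <- project(proj, lat, lon)
  sv <- svd(scale(rec_xy, scale = FALSE))$d
  if (min(sv) < 1) {
    warning("recorder subset is collinear; hull is degenerate")
    # on-segment test: distance from the point to the segment spanned by
    # the extreme recorders along the principal axis
    v <- svd(scale(rec_xy, scale = FALSE))$v[, 1]
    t_rec <- rec_xy %*% v
    t_p <- p %*% v
    # on the segment iff within 1 m of the line through the centroid
    # along v and between the extreme recorders' projections
    ctr <- colMeans(rec_xy)
    d_line <- abs((p[1] - ctr[1]) * (-v[2]) + (p[2] - ctr[2]) * v[1])
    on_seg <- d_line < 1 && drop(t_p) >= min(t_rec) - 1 && drop(t_p) <= max(t_rec) + 1
    return(on_seg)
  }
  hull_idx <- grDevices::chull(rec_xy)
  # chull returns clockwise order; point_in_convex_hull accepts either
  point_in_convex_hull(p[1], p[2], rec_xy[hull_idx, , drop = FALSE], eps = 1e-6)
}

#' Flag multiple howling locations within one event
#'
#' Single-linkage clustering of the estimated positions of all howls in
#' an event; clusters whose mutual separation is at least `separation_m`
#' are reported as distinct howling locations (different individuals or
#' groups vocalising during the same event).
#'
#' @param lat,lon estimated positions of the howls in one event.
#' @param separation_m clustering cut height in metres (default 500).
#' @return a list with `n_sources` (number of distinct locations) and
#'   `group` (integer cluster id per howl).
#' @export
flag_multiple_sources <- function(lat, lon, separation_m = 500) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1)
  if (length(lat) == 1L) return(list(n_sources = 1L, group = 1L))
  proj <- make_projection(mean(lat), mean(lon))
  xy <- project(proj, lat, lon)
  hc <- stats::hclust(stats::dist(xy), method = "single")
  grp <- stats::cutree(hc, h = separation_m)
  list(n_sources = length(unique(grp)), group = as.integer(grp))
}

#' Localise every eligible howl in a salient-point table
#'
#' Groups the salient points by howl, computes TDOAs, multilaterates each
#' howl observed on at least `cfg$min_recorders` distinct recorders, and
#' classifies each estimate against the local convex hull of the
#' recorders it used. Howls seen on fewer recorders are reported as not
#' localisable (`converged = NA`), mirroring field practice where most
#' events are heard but only some are markable on three or more devices.
#'
#' @param salient data frame from [read_salient_points()] (columns
#'   `event_id`, `howl_id`, `site_id`, `arrival_time`).
#' @param deployment data frame from [read_deployment()] or any table
#'   with `site_id`, `lat`, `lon`.
#' @param cfg solver settings from [solver_config()].
#' @return a data frame with one row per howl: `howl_id`, `event_id`,
#'   `lat`, `lon`, `rms_residual_s`, `n_recorders`, `recorder_subset`
#'   (list column), `in_local_hull`, `converged`, `ambiguous`.
#' @export
localise_howls <- function(salient, deployment, cfg = solver_config()) {
  stopifnot(all(c("event_id", "howl_id", "site_id", "arrival_time") %in% names(salient)))
  howls <- split(salient, salient$howl_id)
  rows <- lapply(howls, function(h) {
    base <- data.frame(howl_id = h$howl_id[1], event_id = h$event_id[1],
                       stringsAsFactors = FALSE)
    if (nrow(h) < cfg$min_recorders) {
      out <- cbind(base, data.frame(
        lat = NA_real_, lon = NA_real_, rms_residual_s = NA_real_,
        n_recorders = nrow(h), in_local_hull = NA,
        converged = NA, ambiguous = NA))
      out$recorder_subset <- list(h$site_id)
      return(out)
    }
    tdoa <- compute_tdoa(h$site_id, h$arrival_time,
                         max_tdoa_window = cfg$max_tdoa_window,
                         min_recorders = cfg$min_recorders)
    est <- multilaterate(tdoa, deployment, cfg)
    subset_rec <- deployment[deployment$site_id %in% h$site_id, , drop = FALSE]
    est$in_local_hull <- local_hull_classification(est$lat, est$lon, subset_rec)
    cbind(base, est)
  })
  out <- do.call(rbind, rows)
  # stable presentation: order by first arrival
  first <- vapply(howls, function(h) min(h$arrival_time), 1)
  out <- out[order(first), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("howl_id", "event_id", "lat", "lon", "rms_residual_s",
            "n_recorders", "recorder_subset", "in_local_hull",
            "converged", "ambiguous")
  out[, cols]
}
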