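# Accuracy and detection-distance analyses against known source
# positions (howl-survey sites) and recorder activity.

#' Localisation error against a known source position
#'
#' @param result one-row results data frame (or any list with `howl_id`,
#'   `lat`, `lon`).
#' @param truth one-row truth record with `howl_id`, `lat`, `lon` of the
#'   true source position.
#' @return error in metres, rounded to the nearest metre.
#' @export
localisation_error <- function(result, truth) {
  if (!identical(as.character(result$howl_id), as.character(truth$howl_id)))
    stop("howl_id mismatch: result ", result$howl_id, " vs truth ", truth$howl_id)
  round(geo_distance(result$lat, result$lon, truth$lat, truth$lon))
}

#' Summarise localisation errors
#'
#' @param errors numeric vector of per-howl errors in metres (>= 1 value).
#' @return a list `mean` (rounded to the nearest metre), `min`, `max`,
#'   `n`.
#' @export
summarize_errors <- function(errors) {
  if (length(errors) == 0) stop("no errors to summarise")
  stopifnot(is.numeric(errors), all(is.finite(errors)))
  list(mean = round(mean(errors)), min = min(errors), max = max(errors),
       n = length(errors))
}

#' Distances from a howl position to detecting and non-detecting recorders
#'
#' For every recorder active at the howl's timestamp, the ground distance
#' from the howl position is computed and attributed to the detection or
#' non-detection list. By convention the position is the *true* survey
#' location for howls with known ground truth and the *estimated*
#' position otherwise (wild animals' true positions are unavailable); the
#' caller chooses by passing the appropriate `lat`/`lon`.
#'
#' @param lat,lon howl position (true or estimated; see Details).
#' @param timestamp epoch seconds of the howl (used to restrict to active
#'   recorders).
#' @param deployment data frame from [read_deployment()].
#' @param detected_sites character vector of site ids on which a salient
#'   point could be marked for this howl.
#' @return a data frame `site_id`, `distance_m`, `detected` with one row
#'   per active recorder.
#' @export
detection_profile <- function(lat, lon, timestamp, deployment, detected_sites) {
  active <- deployment[deployment$active_from <= timestamp &
                         deployment$active_to >= timestamp, , drop = FALSE]
  inactive_detected <- setdiff(detected_sites, active$site_id)
  if (length(inactive_detected))
    stop("detected site(s) not active at the howl's timestamp: ",
         paste(inactive_detected, collapse = ", "))
  data.frame(
    site_id = active$site_id,
    distance_m = geo_distance(lat, lon, active$lat, active$lon),
    detected = active$site_id %in% detected_sites,
    stringsAsFactors = FALSE
  )
}

#' Summarise detection distances over many howls
#'
#' @param profiles a list of data frames from [detection_profile()], one
#'   per howl.
#' @return a list with
#'   \describe{
#'     \item{`mean_detection_m`}{pooled mean over all detection
#'       distances;}
#'     \item{`min_detection_m`, `max_detection_m`}{pooled extremes of the
#'       detection distances;}
#'     \item{`mean_max_detection_m`}{per-howl maximum detection distance,
#'       averaged over howls;}
#'     \item{`min_nondetection_m`, `max_nondetection_m`}{pooled extremes
#'       of the non-detection distances (`NA` if none);}
#'     \item{`n_closer_nondetections`}{number of non-detections on
#'       recorders closer to the howl than the furthest recorder on which
#'       that same howl was detected.}
#'   }
#' @export
detection_summary <- function(profiles) {
  if (length(profiles) == 0) stop("no detection profiles to summarise")
  det <- unlist(lapply(profiles, function(p) p$distance_m[p$detected]))
  nondet <- unlist(lapply(profiles, function(p) p$distance_m[!p$detected]))
  if (length(det) == 0) stop("profiles contain no detections")
  per_howl_max <- vapply(profiles, function(p) {
    d <- p$distance_m[p$detected]
    if (length(d)) max(d) else NA_real_
  }, 1)
  n_closer <- sum(vapply(profiles, function(p) {
    d <- p$distance_m[p$detected]
    if (!length(d)) return(0L)
    sum(p$distance_m[!p$detected] < max(d))
  }, 1L))
  list(
    mean_detection_m = mean(det),
    min_detection_m = min(det),
    max_detection_m = max(det),
    mean_max_detection_m = mean(per_howl_max, na.rm = TRUE),
    min_nondetection_m = if (length(nondet)) min(nondet) else NA_real_,
    max_nondetection_m = if (length(nondet)) max(nondet) else NA_real_,
    n_closer_nondetections = n_closer
  )
}

#' Human howl-survey reference table
#'
#' The 16 human howls localised during the 2021 Lunca Muresului CARACAL
#' deployment: timestamp, true howl-survey position, estimated position,
#' the published localisation error, the recorder subset used, and the
#' local-hull flag. Shipped as a plain-text fixture; columns `true_lat`,
#' `true_lon`, `est_lat`, `est_lon` are WGS84 decimal degrees,
#' `distance_m` is the published error in metres, `recorder_sites` is
#' semicolon-separated.
#'
#' @return a data frame with 16 rows.
#' @examples
#' t1 <- howl_survey_reference()
#' summarize_errors(t1$distance_m)
#' @export
howl_survey_reference <- function() {
  path <- system.file("extdata", "howl_survey_reference.csv", package = "howloc",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$howl_id <- as.character(df$howl_id)
  df
}

#' Evaluate localisation results against ground truth
#'
#' Joins results to a truth table by `howl_id`, computes per-howl errors
#' and the overall summary.
#'
#' @param results results data frame from [localise_howls()].
#' @param truth data frame with `howl_id`, `lat`, `lon` (true positions).
#' @return a list with `per_howl` (data frame `howl_id`, `error_m`) and
#'   `summary` (from [summarize_errors()]).
#' @export
evaluate_localisations <- function(results, truth) {
  ok <- !is.na(results$lat)
  res <- results[ok, , drop = FALSE]
  idx <- match(res$howl_id, as.character(truth$howl_id))
  if (any(is.na(idx)))
    stop("truth table is missing howl(s): ",
         paste(res$howl_id[is.na(idx)], collapse = ", "))
  err <- round(geo_distance(res$lat, res$lon, truth$lat[idx], truth$lon[idx]))
  list(
    per_howl = data.frame(howl_id = res$howl_id, error_m = err,
                          stringsAsFactors = FALSE),
    summary = summarize_errors(err)
  )
}
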