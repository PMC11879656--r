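# Reading deployment and salient-point tables, parsing recording start
# times out of filenames, grouping howls into events, and writing results.
#
# All timestamps are held internally as UTC epoch seconds (GPS time is
# UTC); ISO 8601 strings are accepted on input and emitted on output.

#' Parse an ISO 8601 timestamp to UTC epoch seconds
#' @param x character vector, e.g. `"2021-09-02T22:38:35"` (the `T` may be
#'   a space).
#' @return numeric epoch seconds.
#' @keywords internal
parse_iso_time <- function(x) {
  out <- as.POSIXct(sub("T", " ", x), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable ISO 8601 timestamp: ", paste(x[is.na(out)], collapse = ", "))
  as.numeric(out)
}

#' Format UTC epoch seconds as ISO 8601
#' @keywords internal
format_iso_time <- function(t) {
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"), "%Y-%m-%dT%H:%M:%OS2")
}

#' Parse a recording start time from an audio filename
#'
#' GPS-synchronised recorders embed the recording start time in the file
#' name; salient-point offsets within a file are added to this to get
#' absolute arrival times. The default pattern matches a
#' `YYYYMMDD_HHMMSS` token anywhere in the name (e.g.
#' `"CAR01_20210902_223835.wav"`); supply `pattern` with two capture
#' groups (date, time) for other conventions.
#'
#' @param filename character vector of file names.
#' @param pattern regular expression with two capture groups: an 8-digit
#'   `YYYYMMDD` date and a 6-digit `HHMMSS` time.
#' @return numeric UTC epoch seconds of each recording start.
#' @examples
#' parse_recording_start("CAR01_20210902_223835.wav")
#' @export
parse_recording_start <- function(filename,
                                  pattern = "(\\d{8})_(\\d{6})") {
  m <- regmatches(filename, regexec(pattern, filename))
  bad <- vapply(m, length, 1L) < 3L
  if (any(bad))
    stop("cannot find a recording timestamp in: ",
         paste(filename[bad], collapse = ", "),
         " (expected pattern ", pattern, ", e.g. 20210902_223835)")
  iso <- vapply(m, function(g) {
    paste0(substr(g[2], 1, 4), "-", substr(g[2], 5, 6), "-", substr(g[2], 7, 8),
           "T", substr(g[3], 1, 2), ":", substr(g[3], 3, 4), ":", substr(g[3], 5, 6))
  }, character(1))
  parse_iso_time(iso)
}

#' Read a recorder deployment table
#'
#' Expects CSV columns `site_id`, `lat`, `lon`, `active_from`,
#' `active_to` (ISO 8601).
#'
#' @param path CSV file path.
#' @return a data frame with `site_id` (character), `lat`, `lon`
#'   (degrees) and `active_from`, `active_to` (epoch seconds).
#' @export
read_deployment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "lat", "lon", "active_from", "active_to")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("deployment table missing column(s): ", paste(miss, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in deployment table")
  check_geopoint(df$lat, df$lon)
  df$active_from <- parse_iso_time(df$active_from)
  df$active_to <- parse_iso_time(df$active_to)
  if (any(df$active_from >= df$active_to))
    stop("active_from must precede active_to for every recorder")
  df[, need]
}

#' Read a salient-point table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"csv"`}{comma-separated with columns `event_id`, `howl_id`,
#'     `site_id` and one of: `arrival_time` (UTC epoch seconds),
#'     `arrival_time_iso` (ISO 8601), or the pair `file`, `begin_time_s`
#'     (filename carrying the recording start, plus the offset within the
#'     file in seconds).}
#'   \item{`"raven"`}{a Raven-style tab-separated selection table with
#'     columns `Selection` (used as howl id) and `Begin Time (s)`, plus a
#'     `site_id` column and either a `file` column or a single `file`
#'     argument; `event_id` defaults to `"e1"` and is usually reassigned
#'     by [group_events()].}
#' }
#'
#' @param path file path.
#' @param deployment optional deployment data frame from
#'   [read_deployment()]; if given, rows referencing unknown site ids are
#'   rejected.
#' @param dialect `"csv"` or `"raven"`.
#' @param file for the Raven dialect, the audio filename providing the
#'   recording start time when the table has no `file` column.
#' @param filename_pattern passed to [parse_recording_start()].
#' @return a data frame with columns `event_id`, `howl_id`, `site_id`
#'   (character) and `arrival_time` (epoch seconds).
#' @export
read_salient_points <- function(path, deployment = NULL,
                                dialect = c("csv", "raven"),
                                file = NULL,
                                filename_pattern = "(\\d{8})_(\\d{6})") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("event_id", "howl_id", "site_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("salient-point table missing column(s): ", paste(miss, collapse = ", "))
    if ("arrival_time" %in% names(df)) {
      arrival <- as.numeric(df$arrival_time)
    } else if ("arrival_time_iso" %in% names(df)) {
      arrival <- parse_iso_time(df$arrival_time_iso)
    } else if (all(c("file", "begin_time_s") %in% names(df))) {
      arrival <- parse_recording_start(df$file, filename_pattern) + df$begin_time_s
    } else {
      stop("salient-point table needs an 'arrival_time' (epoch seconds) or 'arrival_time_iso' column, or 'file' + 'begin_time_s'")
    }
    out <- data.frame(
      event_id = as.character(df$event_id),
      howl_id = as.character(df$howl_id),
      site_id = as.character(df$site_id),
      arrival_time = arrival,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("Selection", "Begin Time (s)", "site_id")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("Raven selection table missing column(s): ", paste(miss, collapse = ", "))
    src <- if ("file" %in% names(df)) df$file else file
    if (is.null(src)) stop("Raven dialect needs a 'file' column or the 'file' argument for the recording start time")
    arrival <- parse_recording_start(src, filename_pattern) + df[["Begin Time (s)"]]
    out <- data.frame(
      event_id = "e1",
      howl_id = as.character(df$Selection),
      site_id = as.character(df$site_id),
      arrival_time = arrival,
      stringsAsFactors = FALSE
    )
  }
  dup <- duplicated(out[, c("howl_id", "site_id")])
  if (any(dup))
    stop("duplicate salient point for (howl_id, site_id): ",
         paste(unique(paste(out$howl_id[dup], out$site_id[dup], sep = "/")), collapse = ", "))
  if (!is.null(deployment)) {
    unknown <- setdiff(out$site_id, deployment$site_id)
    if (length(unknown))
      stop("salient points reference site_id(s) not in the deployment: ",
           paste(unknown, collapse = ", "))
  }
  out
}

#' Group howls into events by silence gaps
#'
#' A howling event runs until there is a period of silence of `gap_s`
#' seconds or more between consecutive howls; a gap of at least `gap_s`
#' starts a new event. Gaps are measured start-to-start by default (howl
#' end times are rarely annotated; with howls much shorter than the gap
#' the assignment is the same). Event ids are assigned in time order.
#'
#' @param howl_id character vector of howl labels.
#' @param time numeric start time of each howl (epoch seconds). One entry
#'   per howl; if a howl id repeats (salient points on several recorders),
#'   its earliest time is used.
#' @param gap_s silence threshold in seconds (default 60).
#' @return a data frame `howl_id`, `time`, `event_id` sorted by time,
#'   with event ids `"e1"`, `"e2"`, ... in time order.
#' @examples
#' group_events(c("h1", "h2", "h3", "h4"), c(0, 30, 50, 200))
#' @export
group_events <- function(howl_id, time, gap_s = 60) {
  stopifnot(length(howl_id) == length(time), gap_s > 0)
  if (length(howl_id) == 0L)
    return(data.frame(howl_id = character(), time = numeric(),
                      event_id = character(), stringsAsFactors = FALSE))
  t0 <- tapply(time, howl_id, min)
  df <- data.frame(howl_id = names(t0), time = as.numeric(t0), stringsAsFactors = FALSE)
  df <- df[order(df$time, df$howl_id), , drop = FALSE]
  new_event <- c(TRUE, diff(df$time) >= gap_s)
  df$event_id <- paste0("e", cumsum(new_event))
  rownames(df) <- NULL
  df
}

#' Write localisation results as CSV
#'
#' @param results a results data frame from [localise_howls()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  out <- results
  out$recorder_subset <- vapply(results$recorder_subset, paste, character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read localisation results written by [write_results_csv()]
#' @param path CSV path.
#' @return results data frame (recorder subsets as list column).
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$howl_id <- as.character(df$howl_id)
  df$event_id <- as.character(df$event_id)
  df$recorder_subset <- strsplit(as.character(df$recorder_subset), ";", fixed = TRUE)
  df
}

#' Write localisation results as a GeoJSON FeatureCollection
#'
#' Point features in WGS84, coordinates in GeoJSON (lon, lat) order; all
#' other result fields are carried in `properties`.
#'
#' @param results a results data frame from [localise_howls()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_geojson <- function(results, path) {
  features <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    props <- list(
      howl_id = r$howl_id,
      event_id = r$event_id,
      rms_residual_s = r$rms_residual_s,
      n_recorders = r$n_recorders,
      recorder_subset = unlist(r$recorder_subset),
      in_local_hull = r$in_local_hull,
      converged = r$converged
    )
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(r$lon, r$lat)),
      properties = props
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
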