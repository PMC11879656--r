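# End-to-end wiring: localise a salient-point table, evaluate against
# truth where available, and write a structured report. The numbered
# scripts under analysis/ are thin drivers over this function.

#' Run the localise-then-evaluate pipeline
#'
#' Reads the deployment and salient-point tables, localises every
#' eligible howl, optionally evaluates against a truth table, and writes
#' the results (CSV + GeoJSON) and a JSON report echoing the
#' configuration for provenance.
#'
#' @param deployment_path deployment CSV (see [read_deployment()]).
#' @param salient_path salient-point CSV (see [read_salient_points()]).
#' @param truth_path optional truth CSV with columns `howl_id`, `lat`,
#'   `lon`.
#' @param out_dir output directory (created if absent).
#' @param cfg solver settings from [solver_config()].
#' @param seed integer seed recorded in the report (the deterministic
#'   pipeline itself draws no random numbers).
#' @return the report, invisibly: a list with `results`, `evaluation`
#'   (or `NULL`), `config`, `n_howls`, `n_localised`.
#' @export
run_pipeline <- function(deployment_path, salient_path, truth_path = NULL,
                         out_dir = tempfile("howloc_run_"),
                         cfg = solver_config(), seed = 20210831) {
  for (p in c(deployment_path, salient_path, truth_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  deployment <- read_deployment(deployment_path)
  salient <- read_salient_points(salient_path, deployment = deployment)
  results <- localise_howls(salient, deployment, cfg = cfg)

  evaluation <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    need <- c("howl_id", "lat", "lon")
    miss <- setdiff(need, names(truth))
    if (length(miss)) stop("truth table missing column(s): ", paste(miss, collapse = ", "))
    evaluation <- evaluate_localisations(results, truth)
  }

  write_results_csv(results, file.path(out_dir, "results.csv"))
  write_results_geojson(results[!is.na(results$lat), , drop = FALSE],
                        file.path(out_dir, "results.geojson"))

  report <- list(
    package_version = as.character(utils::packageVersion("howloc")),
    seed = seed,
    config = cfg,
    n_howls = nrow(results),
    n_localised = sum(!is.na(results$lat)),
    evaluation = if (is.null(evaluation)) NULL else evaluation$summary
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, evaluation = evaluation,
                 config = cfg, n_howls = report$n_howls,
                 n_localised = report$n_localised, out_dir = out_dir))
}
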