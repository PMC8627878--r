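# -- pipeline configuration --------------------------------------------------

pipeline_defaults <- function() {
  list(input = NULL, format = "auto",
       min_nodes = 4L, max_nodes = Inf,
       assume_unknown_inhibitory = FALSE,
       model_params = list(),
       t_end = 500, n_points = 2000L, rtol = 1e-8, atol = 1e-10,
       detection = list(),
       scan = NULL,  # list(h = ..., K = ...)
       output_dir = ".")
}

#' Build and validate a pipeline configuration
#'
#' Settings for the find/build/simulate/classify pipeline. Unknown keys are
#' rejected; numeric settings are range-checked. `config_file` (YAML) is
#' read first, then `...` overrides individual keys (flag > file > default
#' precedence).
#'
#' @param ... configuration keys (see [pipeline_defaults] in the source for
#'   the full set: `input`, `format`, `min_nodes`, `max_nodes`,
#'   `assume_unknown_inhibitory`, `model_params`, `t_end`, `n_points`,
#'   `rtol`, `atol`, `detection`, `scan`, `output_dir`).
#' @param config_file optional YAML file with the same keys.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    file_cfg <- yaml::read_yaml(config_file)
    bad <- setdiff(names(file_cfg), names(cfg))
    if (length(bad) > 0L)
      stop("unknown config key(s) in ", config_file, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (is.null(cfg$max_nodes) || identical(cfg$max_nodes, "Inf"))
    cfg$max_nodes <- Inf
  if (cfg$min_nodes < 4L) stop("min_nodes must be >= 4", call. = FALSE)
  if (cfg$max_nodes < cfg$min_nodes)
    stop("max_nodes must be >= min_nodes", call. = FALSE)
  if (cfg$t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (cfg$n_points < 100L) stop("n_points must be >= 100", call. = FALSE)
  if (cfg$rtol <= 0 || cfg$atol <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

load_graph_auto <- function(path, format = "auto") {
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sbml = , xml = "sbml",
                     graphml = "graphml",
                     "tsv")
  }
  switch(format,
         sbml = load_sbml(path),
         graphml = load_graphml(path),
         tsv = load_edge_table(path),
         stop("unknown graph format '", format, "'", call. = FALSE))
}

#' Find contours in a graph file and write reports
#'
#' Stage one of the pipeline: loads the typed graph (SBML, GraphML or
#' TSV edge table, chosen by `format` or file extension), enumerates
#' potentially oscillating contours, and writes `contours.tsv`,
#' `contours.json` and one GraphML subgraph per contour into `output_dir`.
#'
#' @param input graph file.
#' @param output_dir output directory (created if missing).
#' @param format `"auto"`, `"sbml"`, `"graphml"` or `"tsv"`.
#' @param min_nodes,max_nodes contour size bounds (cycle node counts).
#' @param assume_unknown_inhibitory treat unsigned regulator edges as
#'   inhibitory closures.
#' @return invisibly, the list of contours found.
#' @export
cmd_find <- function(input, output_dir = ".", format = "auto",
                     min_nodes = 4L, max_nodes = Inf,
                     assume_unknown_inhibitory = FALSE) {
  graph <- load_graph_auto(input, format)
  contours <- enumerate_contours(graph, min_nodes = min_nodes,
                                 max_nodes = max_nodes,
                                 assume_unknown_inhibitory =
                                   assume_unknown_inhibitory)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rep_df <- contour_report(contours, graph)
  utils::write.table(rep_df, file.path(output_dir, "contours.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep_df, file.path(output_dir, "contours.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(contours)) {
    write_graphml(contour_subgraph(contours[[i]], graph),
                  file.path(output_dir, sprintf("contour_%03d.graphml", i)))
  }
  invisible(contours)
}

#' Run the full find/build/simulate/classify pipeline
#'
#' For every contour found in the input graph: generates the Goodwin-type
#' ODE model, exports it as SBML, integrates it, classifies the trajectory,
#' optionally scans the `(h, K)` grid, and writes per-contour artifacts
#' (`model_NNN.sbml`, `trajectory_NNN.csv`, `report_NNN.json`, and
#' `scan_NNN.tsv` when a scan grid is configured) plus a one-row-per-
#' contour `summary.tsv`. Per-contour failures are recorded in the summary
#' and do not abort the pipeline. The effective configuration is echoed to
#' `config_used.yaml` for reproducibility.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary data.frame.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input)) stop("config$input is required", call. = FALSE)
  graph <- load_graph_auto(config$input, config$format)
  contours <- enumerate_contours(
    graph, min_nodes = config$min_nodes, max_nodes = config$max_nodes,
    assume_unknown_inhibitory = config$assume_unknown_inhibitory)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  echo <- config
  echo$max_nodes <- if (is.infinite(echo$max_nodes)) "Inf" else echo$max_nodes
  yaml::write_yaml(unclass(echo),
                   file.path(config$output_dir, "config_used.yaml"))
  det <- do.call(detection_settings, config$detection)
  rows <- list()
  for (i in seq_along(contours)) {
    x <- contours[[i]]
    row <- data.frame(canonical_id = x$canonical_id, n_nodes = x$n_nodes,
                      overall_label = NA_character_, period = NA_real_,
                      error = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      model <- build_contour_model(x, graph, params = config$model_params)
      export_sbml(model, file.path(config$output_dir,
                                   sprintf("model_%03d.sbml", i)))
      tr <- integrate_model(model, t_end = config$t_end,
                            n_points = config$n_points,
                            rtol = config$rtol, atol = config$atol)
      write_trajectory_csv(tr, file.path(config$output_dir,
                                         sprintf("trajectory_%03d.csv", i)))
      rep_i <- detect_oscillation(tr, det)
      write_report(rep_i, file.path(config$output_dir,
                                    sprintf("report_%03d.json", i)))
      if (!is.null(config$scan)) {
        sc <- scan_parameters(model, h_values = config$scan$h,
                              K_values = config$scan$K,
                              t_end = config$t_end,
                              n_points = config$n_points, settings = det)
        utils::write.table(sc, file.path(config$output_dir,
                                         sprintf("scan_%03d.tsv", i)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      rep_i
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$overall_label <- res$overall_label
      row$period <- res$period
    }
    rows[[i]] <- row
  }
  summary <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(canonical_id = character(), n_nodes = integer(),
               overall_label = character(), period = numeric(),
               error = character(), stringsAsFactors = FALSE)
  utils::write.table(summary, file.path(config$output_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Simulate and classify a classical oscillator model
#'
#' @param name registry name (see [classic_registry()]).
#' @param output_dir output directory for `trajectory.csv` and
#'   `report.json`.
#' @param overrides named parameter overrides.
#' @param t_end,n_points simulation window (model default horizon when
#'   `t_end` is NULL).
#' @return invisibly, the [detect_oscillation()] report.
#' @export
cmd_classic <- function(name, output_dir = ".", overrides = NULL,
                        t_end = NULL, n_points = 2000L) {
  sys <- make_classic(name, overrides = overrides)
  tr <- integrate_model(sys, t_end = t_end, n_points = n_points)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectory_csv(tr, file.path(output_dir,
                                     paste0(name, "_trajectory.csv")))
  rep <- detect_oscillation(tr)
  write_report(rep, file.path(output_dir, paste0(name, "_report.json")))
  if (name == "lotka_volterra") {
    inv <- lotka_volterra_invariant(tr, sys$parameters)
    message(sprintf("conservation diagnostic: first integral drift %.3g",
                    max(abs(inv - inv[1]))))
  }
  invisible(rep)
}
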