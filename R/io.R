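#' Load a run configuration from a YAML file
#'
#' The file may contain the blocks `scenario`, `fluid`, `agent`, `run`
#' and `experiment`. Every omitted key falls back to the package default
#' (the calibrated parameter set), so an empty file yields the default
#' configuration. Unknown keys are rejected with a message listing them.
#'
#' @param path path to a YAML configuration file.
#' @param overrides named list applied after the file (e.g. from
#'   command-line flags); names use the same `block.key` convention,
#'   flattened as `agent.eps_U0 = 1`.
#' @return a [run_config()]; the provenance (file path and applied
#'   overrides) is attached as attributes.
#' @export
load_config <- function(path, overrides = list()) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path)
  if (is.null(cfg)) cfg <- list()
  known_blocks <- c("scenario", "fluid", "agent", "run", "experiment")
  bad <- setdiff(names(cfg), known_blocks)
  if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))

  for (ov in names(overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("override keys use block.key form: ", ov)
    cfg[[parts[1]]][[parts[2]]] <- overrides[[ov]]
  }

  check_keys <- function(block, allowed) {
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad))
      stop("unknown keys in '", block, "' block: ", paste(bad, collapse = ", "))
  }
  check_keys("fluid", names(formals(fluid_params)))
  check_keys("agent", names(formals(model_params)))
  # n_agents / k_runs rather than bare N / K: YAML reads those as booleans
  check_keys("run", c("n_agents", "k_runs", "dt_agent", "record_every",
                      "t_total", "seed", "flow", "init_region", "twin"))
  check_keys("scenario", c("name", "nx", "ny", "x_min", "x_max", "y_min", "y_max"))

  sc <- cfg$scenario %||% list()
  geometry <- do.call(tank_geometry,
                      c(list(scenario = sc$name %||% "cavity"),
                        sc[setdiff(names(sc), "name")]))
  params <- do.call(model_params, cfg$agent %||% list())
  fluid <- do.call(fluid_params, cfg$fluid %||% list())
  run_block <- cfg$run %||% list()
  names(run_block)[names(run_block) == "n_agents"] <- "N"
  names(run_block)[names(run_block) == "k_runs"] <- "K"
  rc <- do.call(run_config,
                c(list(scenario = geometry$scenario, params = params,
                       fluid = fluid, geometry = geometry),
                  run_block))
  attr(rc, "source") <- normalizePath(path)
  attr(rc, "overrides") <- overrides
  attr(rc, "experiment") <- cfg$experiment %||% list()
  rc
}

# flatten a run_config back to the YAML block structure
config_to_list <- function(config) {
  g <- config$geometry
  num_params <- config$params[!vapply(config$params, is.logical, logical(1))]
  tog <- config$params[vapply(config$params, is.logical, logical(1))]
  list(scenario = list(name = g$scenario, nx = g$nx, ny = g$ny,
                       x_min = g$x_min, x_max = g$x_max,
                       y_min = g$y_min, y_max = g$y_max),
       fluid = unclass(config$fluid),
       agent = c(num_params, tog),
       run = list(n_agents = config$N, k_runs = config$K,
                  dt_agent = config$dt_agent,
                  record_every = config$record_every,
                  t_total = config$t_total, seed = config$seed,
                  flow = config$flow, init_region = config$init_region,
                  twin = config$twin))
}

#' Write simulation outputs to a directory
#'
#' Writes the trajectory record as tidy CSV (one row per record time and
#' agent), any metric series as a tidy CSV keyed by time, a JSON summary,
#' and an echo of the configuration as YAML. Every file name is prefixed
#' with the run tag; the summary carries the seed and the MD5 of the
#' echoed configuration so any output directory suffices to re-run the
#' experiment.
#'
#' @param result a [run_simulation()] result.
#' @param dir output directory (created if missing).
#' @param metrics optional data frame of metric series.
#' @param tag file name prefix; default `"run"`.
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(result, dir, metrics = NULL, tag = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  cfg_path <- file.path(dir, paste0(tag, "_config.yaml"))
  yaml::write_yaml(config_to_list(result$config), cfg_path)
  files <- c(files, cfg_path)

  flatten <- function(rec, time) {
    n <- ncol(rec$x)
    df <- data.frame(time = rep(time, each = n),
                     agent = rep(seq_len(n), times = length(time)))
    for (nm in names(rec)) df[[nm]] <- as.vector(t(rec[[nm]]))
    df
  }
  traj_path <- file.path(dir, paste0(tag, "_trajectories.csv"))
  utils::write.csv(flatten(result$active, result$time), traj_path,
                   row.names = FALSE)
  files <- c(files, traj_path)
  if (!is.null(result$twin)) {
    twin_path <- file.path(dir, paste0(tag, "_twin.csv"))
    utils::write.csv(flatten(result$twin, result$time), twin_path,
                     row.names = FALSE)
    files <- c(files, twin_path)
  }
  if (!is.null(metrics)) {
    m_path <- file.path(dir, paste0(tag, "_metrics.csv"))
    utils::write.csv(metrics, m_path, row.names = FALSE)
    files <- c(files, m_path)
  }
  summary_path <- file.path(dir, paste0(tag, "_summary.json"))
  jsonlite::write_json(
    list(tag = tag, seed = result$config$seed,
         N = result$config$N, t_total = result$config$t_total,
         scenario = result$config$scenario,
         config_md5 = unname(tools::md5sum(cfg_path)),
         files = basename(files)),
    summary_path, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, summary_path)
  invisible(files)
}

#' Write a field snapshot as tidy CSV
#'
#' Long-format export of the cell-centered flow velocity, pressure and
#' (optionally) prey concentration: columns `x, y, u, v, p[, F]`.
#'
#' @param flow a `flow_field`.
#' @param path output CSV path.
#' @param prey optional `prey_field` on the same grid.
#' @return invisibly, `path`.
#' @export
write_field_snapshot <- function(flow, path, prey = NULL) {
  g <- flow$geometry
  cc <- cell_centers(g)
  ctr <- flow_at_centers(flow)
  df <- data.frame(x = rep(cc$x, times = length(cc$y)),
                   y = rep(cc$y, each = length(cc$x)),
                   u = as.vector(ctr$u), v = as.vector(ctr$v),
                   p = as.vector(flow$p))
  if (!is.null(prey)) df$F <- as.vector(prey$F)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a field snapshot written by [write_field_snapshot()]
#'
#' @param path CSV path.
#' @param geometry the [tank_geometry()] the snapshot was written on.
#' @return list with matrices `u`, `v`, `p` and optionally `F` on cell
#'   centers.
#' @export
read_field_snapshot <- function(path, geometry) {
  df <- utils::read.csv(path)
  ncx <- geometry$nx - 1L; ncy <- geometry$ny - 1L
  shape <- function(col) matrix(col, ncx, ncy)
  out <- list(u = shape(df$u), v = shape(df$v), p = shape(df$p))
  if ("F" %in% names(df)) out$F <- shape(df$F)
  out
}
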