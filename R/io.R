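timeseries_cols <- c("t", "N_C", "N_D", "rho", "rho_C", "rho_D", "m",
                     "payoff_C", "payoff_D", "basal_C", "basal_D",
                     "births_C", "births_D", "deaths_C", "deaths_D",
                     "mean_energy", "immigration")

#' Write simulation outputs to a directory
#'
#' Writes the fixed file set of a run: `timeseries.csv` (one row per step,
#' the exact 17-column contract ending in an `immigration` 0/1 flag),
#' `lifespans.csv` (`strategy, birth_time, death_time, lifespan`),
#' `metadata.json` (all parameters, seed, package version, wall-clock start)
#' and, when the run recorded snapshots, `snapshots.txt` (per dump a
#' `# t=<step>` header and `L` rows by `L` columns of `nC:nD` tokens).
#' Output is deterministic given identical results.
#'
#' @param sim An `"ecoflow_sim"` object.
#' @param dir Output directory (created if missing; must be writable).
#' @param wall_start Optional POSIXct start time recorded in the metadata.
#' @return Invisibly, the named character vector of files written.
#' @export
write_sim_outputs <- function(sim, dir, wall_start = Sys.time()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir),
                  call. = FALSE)
  }
  if (file.access(dir, 2) != 0) {
    stop(sprintf("output directory '%s' is not writable", dir), call. = FALSE)
  }
  files <- c(timeseries = file.path(dir, "timeseries.csv"),
             lifespans = file.path(dir, "lifespans.csv"),
             metadata = file.path(dir, "metadata.json"))
  ts <- sim$steps[, timeseries_cols]
  ts$immigration <- as.integer(ts$immigration)
  readr::write_csv(ts, files[["timeseries"]], progress = FALSE)
  readr::write_csv(sim$lifespans, files[["lifespans"]], progress = FALSE)
  meta <- c(unclass(sim$params),
            list(package_version = as.character(utils::packageVersion("ecoflow")),
                 wall_start = format(wall_start, "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(meta, files[["metadata"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(sim$snapshots) && length(sim$snapshots) > 0) {
    files <- c(files, snapshots = file.path(dir, "snapshots.txt"))
    write_snapshots(sim$snapshots, files[["snapshots"]])
  }
  invisible(files)
}

#' Write per-site count snapshots as plain text
#'
#' @param snapshots List of snapshot grids as stored by [run_sim()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_snapshots <- function(snapshots, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in snapshots) {
    writeLines(sprintf("# t=%d", sn$t), con)
    lines <- apply(matrix(sprintf("%d:%d", sn$n_C, sn$n_D),
                          nrow(sn$n_C), ncol(sn$n_C)),
                   1, paste, collapse = " ")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a written time series
#'
#' @param path A `timeseries.csv` written by [write_sim_outputs()].
#' @return Tibble with the 17 contract columns.
#' @export
read_timeseries <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read back a written lifespan table
#'
#' @param path A `lifespans.csv` written by [write_sim_outputs()].
#' @return Tibble of death events.
#' @export
read_lifespans <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(strategy = readr::col_character()))
}

#' Resolve a run configuration from flags, file and defaults
#'
#' Field-wise precedence: command-line flag over config-file entry over
#' default. The config file is flat YAML/JSON key-value; unknown keys in
#' either source are rejected. The result is a validated [sim_params()]
#' record plus any recognised output options.
#'
#' @param flags Named list of values supplied on the command line (only
#'   non-`NULL` entries take effect).
#' @param file Optional path to a YAML or JSON config file.
#' @return A list with `params` (validated `"ecoflow_params"`) and `output`
#'   (list of `out_dir`, `snapshot_every`).
#' @export
resolve_config <- function(flags = list(), file = NULL) {
  param_keys <- c("lambda", "eta", "d", "r", "cost", "nu", "q", "L",
                  "topology", "steps", "burn_in", "seed", "init_pop",
                  "init_energy")
  output_keys <- c("out_dir", "snapshot_every")
  known <- c(param_keys, output_keys)
  from_file <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop(sprintf("config file '%s' not found", file),
                                 call. = FALSE)
    from_file <- if (grepl("\\.json$", file)) jsonlite::read_json(file,
                                                simplifyVector = TRUE)
                 else yaml::read_yaml(file)
    if (is.null(from_file)) from_file <- list()
  }
  flags <- flags[!vapply(flags, is.null, logical(1))]
  for (src in list(file = from_file, flag = flags)) {
    bad <- setdiff(names(src), known)
    if (length(bad) > 0) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  merged <- utils::modifyList(from_file, flags)
  params <- do.call(sim_params, merged[intersect(names(merged), param_keys)])
  output <- merged[intersect(names(merged), output_keys)]
  list(params = params, output = output)
}
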