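# Configuration files, snapshots and run directories. All artifacts are
# plain text: YAML configs, CSV agent tables and summaries, whitespace-
# delimited field matrices. Floats are written with 17 significant digits,
# which round-trips IEEE doubles exactly.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Load a simulation configuration from a YAML file
#'
#' The file is flat key-value YAML whose keys are the model symbols
#' (`f`, `AspU`, `Y`, `Pf`, `secretion_cap`, `ExN`, `g`, `Cmax`, `T_DL`,
#' `P_DL`, `T_LD`, `P_LD`, `D_eff`) plus the runtime keys (`grid_shape`,
#' `n_steps`, `seed`, `init_radius`, `init_dark_fraction`,
#' `boundary_condition`, `light_rule`, `on_boundary_contact`). Keys left
#' out take their defaults; unknown keys are an error (they are almost
#' always typos for a model parameter). An empty file yields the default
#' configuration.
#'
#' @param path path to the YAML file.
#' @return a validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("failed to parse configuration file ", path, ": ",
         conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration file ", path, " must contain a key-value mapping",
         call. = FALSE)
  if (!is.null(raw$grid_shape)) raw$grid_shape <- as.integer(unlist(raw$grid_shape))
  do.call(sim_config, raw)
}

#' Write a simulation configuration to a YAML file
#'
#' @param cfg a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_config(cfg)), path)
  invisible(path)
}

.agents_file <- function(step) sprintf("agents_%d.csv", step)
.field_file <- function(step) sprintf("field_%d.txt", step)

#' Write a colony snapshot
#'
#' Writes the agent table to `agents_<step>.csv` (columns `step`, `x`, `y`,
#' `state`, `C`, `N`; pools at 17 significant digits) and the trehalose
#' field to `field_<step>.txt` (one whitespace-delimited row per grid row).
#'
#' @param state a `colony_state`.
#' @param step integer step label for the snapshot files.
#' @param dir output directory (created if missing).
#' @return character vector of the two paths written, invisibly.
#' @export
write_snapshot <- function(state, step, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  agents <- agent_table(state, step)
  agents$C <- .fmt17(agents$C)
  agents$N <- .fmt17(agents$N)
  agents_path <- file.path(dir, .agents_file(step))
  utils::write.csv(agents, agents_path, row.names = FALSE, quote = FALSE)

  field_path <- file.path(dir, .field_file(step))
  txt <- apply(state$field, 1L, function(row) paste(.fmt17(row), collapse = " "))
  writeLines(txt, field_path)
  invisible(c(agents = agents_path, field = field_path))
}

#' Read a colony snapshot
#'
#' Rebuilds a `colony_state` from the files written by [write_snapshot()].
#' Validates the state invariants: no two blocks on one site, all pools
#' non-negative, all field entries non-negative. `last_division_step`
#' bookkeeping is not serialized and comes back as `NA`.
#'
#' @param dir snapshot directory.
#' @param step integer step label.
#' @return a `colony_state`.
#' @export
read_snapshot <- function(dir, step) {
  agents_path <- file.path(dir, .agents_file(step))
  field_path <- file.path(dir, .field_file(step))
  for (p in c(agents_path, field_path))
    if (!file.exists(p)) stop("snapshot file not found: ", p, call. = FALSE)

  agents <- utils::read.csv(agents_path, stringsAsFactors = FALSE)
  needed <- c("step", "x", "y", "state", "C", "N")
  if (!all(needed %in% names(agents)))
    stop("malformed agents file ", agents_path, ": expected columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (!all(agents$state %in% .state_labels))
    stop("malformed agents file ", agents_path,
         ": state must be \"dark\" or \"light\"", call. = FALSE)
  if (any(agents$C < 0) || any(agents$N < 0))
    stop("invalid snapshot: negative internal pool in ", agents_path,
         call. = FALSE)

  rows <- lapply(strsplit(trimws(readLines(field_path)), "[[:space:]]+"),
                 as.numeric)
  if (length(unique(lengths(rows))) != 1L)
    stop("malformed field file ", field_path, ": ragged rows", call. = FALSE)
  field <- do.call(rbind, rows)
  if (anyNA(field))
    stop("malformed field file ", field_path, ": non-numeric entries",
         call. = FALSE)
  if (any(field < 0))
    stop("invalid snapshot: negative trehalose concentration in ",
         field_path, call. = FALSE)

  shape <- dim(field)
  n <- nrow(agents)
  if (n > 0 && (any(agents$x < 0) || any(agents$x >= shape[1]) ||
                any(agents$y < 0) || any(agents$y >= shape[2])))
    stop("invalid snapshot: block outside the grid in ", agents_path,
         call. = FALSE)
  occ <- matrix(0L, shape[1], shape[2])
  idx <- cbind(agents$x + 1L, agents$y + 1L)
  if (anyDuplicated(idx))
    stop("invalid snapshot: two blocks share a lattice site in ",
         agents_path, call. = FALSE)
  occ[idx] <- seq_len(n)
  new_colony_state(agents$x, agents$y,
                   match(agents$state, .state_labels),
                   agents$C, agents$N,
                   rep(NA_integer_, n), occ, field)
}

#' Write a complete run directory
#'
#' Writes `summary.csv` (one row per step, including step 0),
#' `config_resolved.yaml` (the fully resolved configuration, seed
#' included), every stored snapshot, a final-state snapshot, and
#' `manifest.json` with the package version and MD5 checksums of every
#' file, so a run can be re-verified by re-simulating from the resolved
#' config and comparing checksums.
#'
#' @param trajectory a `colony_trajectory`.
#' @param dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_run <- function(trajectory, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summary_path <- file.path(dir, "summary.csv")
  rec <- trajectory$records
  rec$total_trehalose <- .fmt17(rec$total_trehalose)
  rec$colony_radius <- .fmt17(rec$colony_radius)
  utils::write.csv(rec, summary_path, row.names = FALSE, quote = FALSE)
  write_config(trajectory$config, file.path(dir, "config_resolved.yaml"))

  for (snap in trajectory$snapshots) {
    snap_state <- new_colony_state(
      snap$agents$x, snap$agents$y,
      match(snap$agents$state, .state_labels),
      snap$agents$C, snap$agents$N,
      rep(NA_integer_, nrow(snap$agents)),
      occ = {
        occ <- matrix(0L, nrow(snap$field), ncol(snap$field))
        occ[cbind(snap$agents$x + 1L, snap$agents$y + 1L)] <-
          seq_len(nrow(snap$agents))
        occ
      },
      field = snap$field)
    write_snapshot(snap_state, snap$step, dir)
  }
  final_step <- max(trajectory$records$step)
  write_snapshot(trajectory$state, final_step, dir)

  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    package = "colonysim",
    version = as.character(utils::packageVersion("colonysim")),
    seed = trajectory$seed,
    n_steps = trajectory$config$n_steps,
    final_step = final_step,
    config = unclass(trajectory$config),
    checksums = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write sweep results to CSV
#'
#' @param sweep a `sweep_result` from [sweep_param()].
#' @param dir output directory (created if missing).
#' @return path of `sweep_results.csv`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "sweep_results.csv")
  utils::write.csv(sweep$results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
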