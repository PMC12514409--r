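# canonical JSON: names sorted recursively, fixed digits -> byte-stable output
canonicalize <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      x <- x[order(names(x))]
    }
    return(lapply(x, canonicalize))
  }
  x
}

canonical_json <- function(x) {
  jsonlite::toJSON(canonicalize(x), auto_unbox = TRUE, digits = 10,
                   na = "null", pretty = TRUE)
}

#' Hash a configuration
#'
#' md5 of the canonical (recursively name-sorted) JSON serialization, so the
#' hash is stable under field reordering.
#'
#' @param config A `crc_config`.
#' @return Hex md5 string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(canonical_json(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run manifest for a set of outputs
#'
#' @param config The `crc_config` used.
#' @param life_table_source Description of the life-table input.
#' @param files Character vector of output files written.
#' @return List of class `crc_manifest` with the config hash, software
#'   version, timestamp and file list.
#' @export
run_manifest <- function(config, life_table_source = "synthetic", files = character()) {
  structure(list(
    config_hash = config_hash(config),
    life_table_source = life_table_source,
    package_version = as.character(utils::packageVersion("crcscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.character(files)
  ), class = "crc_manifest")
}

outcome_record <- function(o) {
  list(strategy_id = o$strategy_id, crc_cases = o$crc_cases,
       cancer_lyl = o$cancer_lyl,
       cancer_lyl_undiscounted = o$cancer_lyl_undiscounted,
       total_cost = o$total_cost, procedures = o$procedures,
       complications = o$complications)
}

#' Run strategies and write a results directory
#'
#' Runs the cohort model for the requested strategies and writes, per
#' strategy, the cycle trace and cost ledger as CSV; plus a deterministic
#' `summary.json` (outcomes and comparison; byte-identical across re-runs
#' with identical inputs) and a `manifest.json` naming every output file and
#' the configuration hash.
#'
#' @param config A `crc_config`, or the path of a YAML configuration file.
#' @param strategies Strategy ids to run.
#' @param out_dir Output directory (created if needed).
#' @param life_table Optional `life_table`; also written to the directory.
#' @return The fitted `crc_model`, invisibly.
#' @export
cea_run <- function(config = crc_basecase(), strategies = crc_strategies(),
                    out_dir, life_table = NULL) {
  if (is.character(config)) config <- load_config(config)
  viol <- validate_config(config)
  if (nrow(viol)) {
    stop("invalid configuration: ",
         paste(sprintf("%s (%s)", viol$field, viol$rule), collapse = "; "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lt_src <- if (is.null(life_table)) "synthetic" else "user-supplied"
  fit <- crc_model(config, strategies, life_table)
  files <- character()
  for (s in fit$strategies) {
    f_trace <- file.path(out_dir, paste0("trace_", s, ".csv"))
    utils::write.csv(as.data.frame(fit$traces[[s]]), f_trace, row.names = FALSE)
    f_cost <- file.path(out_dir, paste0("costs_", s, ".csv"))
    utils::write.csv(fit$costs[[s]]$ledger, f_cost, row.names = FALSE)
    files <- c(files, f_trace, f_cost)
  }
  f_lt <- file.path(out_dir, "life_table.csv")
  write_life_table(fit$life_table, f_lt)
  f_sum <- file.path(out_dir, "summary.json")
  summary_obj <- list(
    config_hash = config_hash(config),
    strategies = fit$strategies,
    outcomes = lapply(fit$outcomes, outcome_record),
    comparison = fit$comparison$table,
    icer_matrix = as.data.frame(fit$comparison$icer_matrix),
    icer_flags = as.data.frame(fit$comparison$icer_flags)
  )
  writeLines(canonical_json(summary_obj), f_sum)
  files <- c(files, f_lt, f_sum)
  f_man <- file.path(out_dir, "manifest.json")
  man <- run_manifest(config, lt_src, c(files, f_man))
  writeLines(jsonlite::toJSON(unclass(man), auto_unbox = TRUE, pretty = TRUE), f_man)
  f_cfg <- file.path(out_dir, "config.yaml")
  write_config(config, f_cfg)
  invisible(fit)
}

#' Compare previously written run directories
#'
#' Reads `summary.json` from each directory, refuses to compare runs whose
#' configuration hashes differ, pools their outcome records, and rebuilds the
#' comparison table.
#'
#' @param dirs Character vector of directories written by [cea_run()].
#' @return A `crc_comparison`.
#' @export
cea_compare_runs <- function(dirs) {
  sums <- lapply(dirs, function(d) {
    f <- file.path(d, "summary.json")
    if (!file.exists(f)) stop("no summary.json in ", d, call. = FALSE)
    jsonlite::read_json(f, simplifyVector = FALSE)
  })
  hashes <- vapply(sums, function(s) s$config_hash, character(1))
  if (length(unique(hashes)) > 1) {
    stop("runs use different configurations (config_hash mismatch): ",
         paste(unique(hashes), collapse = " vs "), call. = FALSE)
  }
  outcomes <- list()
  for (s in sums) {
    for (o in s$outcomes) {
      outcomes[[o$strategy_id]] <- o
    }
  }
  comparison_table(unname(outcomes))
}

#' Run a sensitivity sweep from a spec and write it out
#'
#' The sweep spec is a list (or YAML file) with fields `parameter`, `grid`
#' (or `from`/`to`/`steps`), and optional `parameter_b`/`grid_b` for a
#' two-way sweep.  Output is a long-format CSV, seedless and deterministic.
#'
#' @param config A `crc_config` or YAML path.
#' @param spec Sweep spec list or YAML path.
#' @param out_dir Output directory.
#' @param strategies Strategies to evaluate.
#' @param life_table Optional `life_table`.
#' @return The `crc_sweep`, invisibly.
#' @export
cea_sweep <- function(config = crc_basecase(), spec, out_dir,
                      strategies = crc_strategies(), life_table = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  expand_grid_spec <- function(sp_grid, from, to, steps) {
    if (!is.null(sp_grid)) return(unlist(sp_grid))
    seq(from, to, length.out = steps)
  }
  if (is.null(spec$parameter)) stop("sweep spec needs a parameter", call. = FALSE)
  grid <- expand_grid_spec(spec$grid, spec$from, spec$to, spec$steps)
  if (!length(grid)) stop("sweep grid is empty", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(spec$parameter_b)) {
    grid_b <- expand_grid_spec(spec$grid_b, spec$from_b, spec$to_b, spec$steps_b)
    sw <- two_way_sweep(config, spec$parameter, grid, spec$parameter_b, grid_b,
                        strategies, life_table)
  } else {
    sw <- one_way_sweep(config, spec$parameter, grid, strategies, life_table)
  }
  utils::write.csv(as.data.frame(sw), file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)
  invisible(sw)
}
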