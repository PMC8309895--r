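RUN_CHANNELS <- c("ambient", "t_sen", "t_z1_dist", "t_z2_dist",
                  "t_z1_undist", "t_z2_undist")

default_manifest_path <- function(path) sub("\\.csv$", ".manifest.yaml", path)

#' Write a rig run to CSV with a sidecar manifest
#'
#' RFC-4180 CSV: header row, elapsed seconds in the first column, one row per
#' timestamp.  Temperatures are stored at 1e-4 degC precision (finer than any
#' logger resolution, so storage adds no quantization).  Run metadata
#' (coverage, velocity, replicate, seed and all physical parameters) goes to
#' a YAML sidecar manifest.
#'
#' @param run A `rig_run` tibble.
#' @param path Output CSV path.
#' @param manifest_path Sidecar path; defaults to `*.manifest.yaml` next to
#'   the CSV.
#'
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path,
                          manifest_path = default_manifest_path(path)) {
  out <- dplyr::mutate(run, dplyr::across(-"time_s", \(x) round(x, 4)))
  readr::write_csv(tibble::as_tibble(out), path)
  yaml::write_yaml(attr(run, "meta"), manifest_path)
  invisible(path)
}

#' Load a rig run from CSV
#'
#' Validates the layout (elapsed-seconds first column, known channel names,
#' strictly increasing timestamps) and re-attaches the sidecar manifest as
#' run metadata.
#'
#' @param path CSV path written by [write_run_csv()].
#' @param manifest_path Sidecar manifest path.
#'
#' @return A `rig_run` tibble.
#' @export
load_run_csv <- function(path, manifest_path = default_manifest_path(path)) {
  run <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(run)[1] != "time_s") {
    abort("First column must be `time_s` (elapsed seconds).",
          class = "thermoskin_parse_error")
  }
  unknown <- setdiff(names(run)[-1], RUN_CHANNELS)
  if (length(unknown)) {
    abort(paste0("Unknown channel(s): ", paste(unknown, collapse = ", ")),
          class = "thermoskin_parse_error")
  }
  bad <- which(diff(run$time_s) <= 0)
  if (length(bad)) {
    abort(sprintf("Timestamps not strictly increasing at data line %d.",
                  bad[1] + 2L),  # +1 header, +1 offending row
          class = "thermoskin_parse_error")
  }
  if (!file.exists(manifest_path)) {
    abort(paste0("Missing sidecar manifest: ", manifest_path),
          class = "thermoskin_parse_error")
  }
  attr(run, "meta") <- yaml::read_yaml(manifest_path)
  class(run) <- c("rig_run", class(run))
  run
}

#' Write a simulated design to a directory of run CSVs
#'
#' One CSV + manifest per run, plus a design manifest (`design.yaml`) listing
#' every run file with its coverage, velocity, replicate and seed.
#'
#' @param design A `rig_design`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_design_csv <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::map2_chr(design$runs, names(design$runs), function(run, id) {
    f <- file.path(dir, paste0(id, ".csv"))
    write_run_csv(run, f)
    basename(f)
  })
  manifest <- design$manifest
  manifest$file <- unname(files[manifest$run_id])
  yaml::write_yaml(list(created = format(Sys.time(), tz = "UTC"),
                        runs = purrr::transpose(as.list(manifest))),
                   file.path(dir, "design.yaml"))
  invisible(dir)
}

#' Load a design directory, checking the manifest first
#'
#' Every file referenced by `design.yaml` must be present before any run is
#' parsed.
#'
#' @param dir Directory written by [write_design_csv()].
#' @return A `rig_design` list (`manifest`, `runs`).
#' @export
load_design_csv <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "design.yaml"))$runs
  manifest <- dplyr::bind_rows(purrr::map(man, tibble::as_tibble))
  paths <- file.path(dir, manifest$file)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("Manifest references missing file(s): ",
                 paste(basename(missing), collapse = ", ")),
          class = "thermoskin_parse_error")
  }
  runs <- purrr::map(paths, load_run_csv)
  names(runs) <- manifest$run_id
  structure(list(manifest = dplyr::select(manifest, -"file"), runs = runs),
            class = "rig_design")
}

#' Write the analysis tables of a results bundle
#'
#' Emits the steady-state table, the long-format disturbance/bias table
#' (coverage, velocity, form, step, value, gradient), the fixed-temperature
#' bias summary, the per-sensor reference fits, the run manifest, and a
#' metadata YAML with the seeds and analysis decisions.
#'
#' @param results A `rig_results` from [run_rig_suite()].
#' @param dir Output directory (created if needed).
#' @param comparison Optional [compare_with_trial()] tibble.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir, comparison = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(dir, paste0(name, ".csv")))
  }
  wr(results$manifest, "manifest")
  wr(results$steady_states, "steady_states")
  long <- results$paired |>
    tidyr::pivot_longer(c("disturbance", "bias_from_td", "bias_from_tu"),
                        names_to = "form", values_to = "value") |>
    dplyr::select("run_id", "coverage", "velocity", "replicate", "step",
                  "form", "value", "gradient")
  wr(long, "disturbance_bias")
  wr(results$gradient_fits, "gradient_fits")
  wr(results$table1, "table1_summary")
  wr(dplyr::select(results$sensor_fits, -"fit"), "sensor_fits")
  if (!is.null(comparison)) wr(comparison, "intersensor_comparison")
  yaml::write_yaml(results$params, file.path(dir, "metadata.yaml"))
  invisible(dir)
}
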