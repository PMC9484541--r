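# End-to-end orchestration: each command resolves its configuration,
# runs the corresponding module, writes its outputs, and records a JSON
# run manifest so deterministic runs are reproducible from the manifest.

write_manifest <- function(command, config, seed, inputs, outputs, out_path) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    input_digests = digests,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(packageVersion("ebtsim"))
  )
  jsonlite::write_json(manifest, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(out_path)
}

#' Fit pipeline: dataset CSV to coefficient database
#'
#' Reads a viability dataset, runs the two-step fit for every
#' (cell line, pulse duration) block present, and writes a JSON
#' coefficient database, a publication-style coefficient CSV (with the
#' computed \eqn{E_c(100)} column) and a run manifest into `out_dir`.
#'
#' @param data_path Path to a viability CSV (see [read_viability()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest (the fit itself is
#'   deterministic).
#' @param strict Error (rather than warn) if any block fails to fit.
#' @return The `ep_pf_fit` object, invisibly.
#' @export
pipeline_fit <- function(data_path, out_dir, seed = 20220905,
                         strict = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_viability(data_path)
  fit <- fit_peleg_fermi(data)
  if (strict && nrow(fit$failures) > 0) {
    abort(paste0(nrow(fit$failures), " fit failure(s) in strict mode."),
          class = "ebtsim_fit_failure")
  }
  db_path <- file.path(out_dir, "coefficients.json")
  table_path <- file.path(out_dir, "coefficient_table.csv")
  stage1_path <- file.path(out_dir, "stage1_fits.csv")
  write_coefficient_db(fit$coefficients, db_path)
  readr::write_csv(coefficient_table(fit$coefficients), table_path)
  readr::write_csv(fit$stage1, stage1_path)
  write_manifest("fit", list(data_path = data_path, strict = strict), seed,
                 list(data = data_path),
                 list(database = db_path, table = table_path,
                      stage1 = stage1_path),
                 file.path(out_dir, "manifest.json"))
  invisible(fit)
}

#' Synthesis pipeline: truth coefficients to dataset CSV
#'
#' Generates a synthetic viability dataset from a generator configuration
#' (a YAML file or an equivalent list) and writes it, plus a manifest,
#' into `out_dir`. Configuration keys: `cell_lines` and `durations_us`
#' select truth rows from the bundled coefficient database (defaults: all
#' complete rows); `efs`, `pulse_numbers`, `replicates`, `noise_sd`,
#' `stimulation` (`efs_cutoff`, `boost`) mirror [generator_config()].
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory.
#' @param seed Integer seed driving all randomness.
#' @return The generated tibble, invisibly.
#' @export
pipeline_synth <- function(config = list(), out_dir, seed = 20220905) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  truth <- pf_coefficients(complete_only = TRUE)
  if (!is.null(config$cell_lines)) {
    missing <- setdiff(config$cell_lines, truth$cell_line)
    if (length(missing) > 0) {
      abort(paste0("Unknown cell line(s) in config: ",
                   paste(missing, collapse = ", ")),
            class = "ebtsim_config_error")
    }
    truth <- dplyr::filter(truth, .data$cell_line %in% config$cell_lines)
  }
  if (!is.null(config$durations_us)) {
    truth <- dplyr::filter(truth,
                           .data$pulse_duration_us %in% config$durations_us)
  }
  gc_args <- list(truth = truth, seed = seed)
  for (key in c("efs", "pulse_numbers", "replicates", "noise_sd",
                "stimulation")) {
    if (!is.null(config[[key]])) gc_args[[key]] <- config[[key]]
  }
  data <- generate_dataset(do.call(generator_config, gc_args))
  data_path <- file.path(out_dir, "viability.csv")
  write_viability(data, data_path)
  write_manifest("synth", config, seed,
                 if (is.null(config_path)) list() else list(config = config_path),
                 list(dataset = data_path),
                 file.path(out_dir, "manifest.json"))
  invisible(data)
}

#' Simulation pipeline: configuration to injury ratio series and maps
#'
#' Resolves a simulation configuration (YAML file or list), runs
#' [run_injury_analysis()], and writes the per-pulse injury ratio series
#' (`pulse_number`, `s_ei_ratio`, `s_ti_ratio`, `peak_T_C`), the final
#' probability maps as TSV grids, and a run manifest. Configuration keys:
#' `cell_line`, `duration_us`, `organ` (defaults to the cell line's
#' organ), `domain` (passed to [domain_spec()]), `protocol` (passed to
#' [pulse_protocol()]), `arrhenius` (passed to [arrhenius_params()]),
#' `dt`, `threshold`.
#'
#' @param config Path to a YAML file, or a named list. Must name a
#'   `cell_line` with an entry in the bundled coefficient database.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest (the simulation is
#'   deterministic).
#' @return The `ep_injury` object, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir, seed = 20220905) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$cell_line)) {
    abort("config must name a cell_line.", class = "ebtsim_config_error")
  }
  duration <- config$duration_us %||% 100
  coeffs <- pf_coefficients(complete_only = TRUE) |>
    dplyr::filter(.data$cell_line == config$cell_line,
                  .data$pulse_duration_us == duration)
  if (nrow(coeffs) == 0) {
    abort(paste0("No coefficient entry for ", config$cell_line, " at ",
                 duration, " us."), class = "ebtsim_config_error")
  }
  organ <- config$organ %||% coeffs$organ
  if (!organ %in% tissue_properties()$organ) {
    abort(paste0("Unknown organ: ", organ), class = "ebtsim_config_error")
  }
  domain <- do.call(domain_spec, config$domain %||% list())
  protocol <- do.call(pulse_protocol, config$protocol %||% list())
  arr <- do.call(arrhenius_params, config$arrhenius %||% list())
  res <- run_injury_analysis(
    coeffs, organ = organ, domain = domain, protocol = protocol,
    arrhenius = arr, dt = config$dt %||% 0.1,
    threshold = config$threshold %||% 0.5
  )
  series_path <- file.path(out_dir, "injury_series.csv")
  readr::write_csv(res$series, series_path)
  map_paths <- list()
  for (nm in c("p_ei", "p_ti", "emag_v_cm", "temperature_c")) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(res[[nm]], p, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    map_paths[[nm]] <- p
  }
  write_manifest("simulate", config, seed,
                 if (is.null(config_path)) list() else list(config = config_path),
                 c(list(series = series_path), map_paths),
                 file.path(out_dir, "manifest.json"))
  invisible(res)
}
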