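#' Cell viability from CCK-8 optical densities
#'
#' Converts optical-density (OD, 450 nm) readings from a CCK-8 assay to a
#' viability percentage by blank-subtracted normalisation against the
#' untreated control:
#' \deqn{S = 100 \cdot \frac{A_{exp} - A_{blank}}{A_{control} - A_{blank}}}
#'
#' Values above 100% are legitimate (low-field stimulation can increase
#' proliferation) and are returned as-is, never clipped.
#'
#' @param od_exp Mean OD of the experimental wells.
#' @param od_blank Mean OD of blank medium.
#' @param od_control Mean OD of the untreated control. Must exceed
#'   `od_blank`, otherwise viability is undefined.
#' @return Viability in percent (numeric, vectorised).
#' @export
#' @examples
#' compute_viability(0.8, 0.1, 1.1) # 70
compute_viability <- function(od_exp, od_blank, od_control) {
  vals <- c(od_exp, od_blank, od_control)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    abort("OD values must be finite and non-negative.",
          class = "ebtsim_od_error")
  }
  if (any(od_control <= od_blank)) {
    abort("Degenerate control: od_control must exceed od_blank.",
          class = "ebtsim_degenerate_control")
  }
  100 * (od_exp - od_blank) / (od_control - od_blank)
}

viability_key_cols <- function() {
  c("cell_line", "pulse_duration_us", "pulse_number", "efs_v_cm", "replicate")
}

#' Validate a viability dataset
#'
#' Enforces the dataset invariants: known cell lines with consistent organ
#' assignment, non-negative viability, unique
#' (cell_line, duration, pulse number, field, replicate) keys, and — when
#' `check_rectangular` — a rectangular pulse-number-by-field design per
#' cell line within each pulse duration (required by the two-step fit).
#'
#' @param data A data frame with columns `cell_line`, `organ`,
#'   `pulse_duration_us`, `pulse_number`, `efs_v_cm`, `replicate`,
#'   `viability_pct`.
#' @param check_rectangular Require every pulse number of a
#'   (cell line, duration) block to be measured at the same set of field
#'   strengths.
#' @return The validated data, invisibly coerced to a tibble.
#' @export
validate_viability <- function(data, check_rectangular = TRUE) {
  data <- tibble::as_tibble(data)
  needed <- c("cell_line", "organ", "pulse_duration_us", "pulse_number",
              "efs_v_cm", "replicate", "viability_pct")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "ebtsim_validation_error")
  }
  reg <- cell_lines()
  unknown <- setdiff(unique(data$cell_line), reg$cell_line)
  if (length(unknown) > 0) {
    abort(paste0("Unknown cell line(s): ", paste(unknown, collapse = ", ")),
          class = "ebtsim_validation_error")
  }
  chk <- dplyr::left_join(
    dplyr::distinct(data, .data$cell_line, .data$organ),
    reg, by = "cell_line", suffix = c("", "_registry")
  )
  bad_organ <- dplyr::filter(chk, .data$organ != .data$organ_registry)
  if (nrow(bad_organ) > 0) {
    abort(paste0("Organ mismatch for: ",
                 paste(bad_organ$cell_line, collapse = ", ")),
          class = "ebtsim_validation_error")
  }
  if (any(data$viability_pct < 0, na.rm = TRUE)) {
    abort("Negative viability_pct found.", class = "ebtsim_validation_error")
  }
  if (any(data$efs_v_cm < 0) || any(data$pulse_number < 0)) {
    abort("efs_v_cm and pulse_number must be non-negative.",
          class = "ebtsim_validation_error")
  }
  dup <- dplyr::count(data, dplyr::across(dplyr::all_of(viability_key_cols())))
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("Duplicate record keys, e.g.: ",
                 paste(utils::capture.output(print(head(dup, 3))),
                       collapse = "\n")),
          class = "ebtsim_validation_error")
  }
  if (check_rectangular) {
    grid <- dplyr::distinct(data, .data$cell_line, .data$pulse_duration_us,
                            .data$pulse_number, .data$efs_v_cm)
    bad <- grid |>
      dplyr::group_by(.data$cell_line, .data$pulse_duration_us,
                      .data$pulse_number) |>
      dplyr::summarise(efs_set = paste(sort(.data$efs_v_cm), collapse = ","),
                       .groups = "drop_last") |>
      dplyr::summarise(n_sets = dplyr::n_distinct(.data$efs_set),
                       .groups = "drop") |>
      dplyr::filter(.data$n_sets > 1)
    if (nrow(bad) > 0) {
      abort(paste0("Non-rectangular field-strength design for: ",
                   paste(paste0(bad$cell_line, "/", bad$pulse_duration_us,
                                " us"), collapse = ", ")),
            class = "ebtsim_validation_error")
    }
  }
  invisible(data)
}

#' Read a viability dataset from CSV
#'
#' The file must carry a header with columns `cell_line`, `organ`,
#' `pulse_duration_us`, `pulse_number`, `efs_v_cm`, `replicate`, and either
#' `viability_pct` directly or an OD triplet `od_exp`, `od_blank`,
#' `od_control` which is converted per [compute_viability()] row by row.
#'
#' @param path Path to a UTF-8 CSV file ('.' decimal separator).
#' @param check_rectangular Passed to [validate_viability()].
#' @return A validated viability tibble (one row per replicate measurement).
#' @export
read_viability <- function(path, check_rectangular = TRUE) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  od_cols <- c("od_exp", "od_blank", "od_control")
  if (!"viability_pct" %in% names(data)) {
    if (!all(od_cols %in% names(data))) {
      abort("Need either a viability_pct column or od_exp/od_blank/od_control.",
            class = "ebtsim_validation_error")
    }
    data <- dplyr::mutate(
      data,
      viability_pct = compute_viability(.data$od_exp, .data$od_blank,
                                        .data$od_control)
    )
  }
  validate_viability(data, check_rectangular = check_rectangular)
  tibble::as_tibble(data)
}

#' Write a viability dataset to CSV
#'
#' Emits the same schema [read_viability()] accepts, so a write/read
#' round-trip reproduces the records.
#'
#' @param data A viability tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Replicate summary per experimental condition
#'
#' Collapses replicates to mean viability, sample standard deviation
#' (0 when a single replicate is present) and the replicate count, one row
#' per (cell line, organ, pulse duration, pulse number, field strength).
#'
#' @param data A viability tibble.
#' @return A tibble with `mean_viability_pct`, `sd_viability_pct`, `n_rep`.
#' @export
summarize_replicates <- function(data) {
  data |>
    dplyr::group_by(.data$cell_line, .data$organ, .data$pulse_duration_us,
                    .data$pulse_number, .data$efs_v_cm) |>
    dplyr::summarise(
      mean_viability_pct = mean(.data$viability_pct),
      sd_viability_pct = ifelse(dplyr::n() > 1, sd(.data$viability_pct), 0),
      n_rep = dplyr::n(),
      .groups = "drop"
    )
}
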