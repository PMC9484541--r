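#' Bundled cell-specific coefficient database
#'
#' The published coefficient sets of the 20 digestive-system cell lines at
#' pulse durations of 25, 50, 75 and 100 microseconds: for each row the
#' stage-2 parameters \eqn{E_0}, \eqn{k_1} (with \eqn{R^2}) of the
#' half-lethality field and \eqn{A_0}, \eqn{k_2} (with \eqn{R^2}) of the
#' slope constant, plus the published \eqn{E_c(100)} value
#' (`ec100_printed`). The PANC-1 / 25 microsecond entry is NA: that dataset
#' required the modified (double-exponential) model and its coefficients
#' were not published.
#'
#' @param complete_only Drop rows with missing coefficients (default FALSE).
#' @return A tibble with columns `organ`, `cell_line`, `pulse_duration_us`,
#'   `e0`, `k1`, `r2_e`, `a0`, `k2`, `r2_a`, `ec100_printed`.
#' @export
#' @examples
#' pf_coefficients() |> ec_threshold(n = 100) |> head()
pf_coefficients <- function(complete_only = FALSE) {
  path <- system.file("extdata", "peleg_fermi_coefficients.csv",
                      package = "ebtsim", mustWork = TRUE)
  db <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          organ = "c", cell_line = "c",
                          .default = readr::col_double()))
  if (complete_only) db <- dplyr::filter(db, !is.na(.data$e0))
  db
}

#' Bundled tissue electrical and thermal properties
#'
#' Per-organ constants used by the injury simulator: electrical
#' conductivity (S/m), density (kg/m^3), heat capacity (J/(kg C)), thermal
#' conductivity (W/(m C)), blood perfusion rate (ml/(min kg)) and metabolic
#' heat generation (W/kg), plus the electrode material row (perfusion and
#' metabolism NA).
#'
#' @param organ Optional organ name to select a single row.
#' @return A tibble (all organs) or a one-row tibble.
#' @export
tissue_properties <- function(organ = NULL) {
  path <- system.file("extdata", "tissue_properties.csv",
                      package = "ebtsim", mustWork = TRUE)
  tp <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(organ)) return(tp)
  row <- dplyr::filter(tp, .data$organ == !!organ)
  if (nrow(row) == 0) {
    abort(paste0("Unknown organ: ", organ), class = "ebtsim_config_error")
  }
  row
}

#' Render coefficient sets as a publication-style table
#'
#' Arranges coefficient rows in the canonical organ/cell-line/duration
#' order and appends a computed `ec100` column
#' (\eqn{E_0 e^{-100 k_1}}, never stored).
#'
#' @param coeffs A coefficient tibble (columns `organ`, `cell_line`,
#'   `pulse_duration_us`, `e0`, `k1`, `r2_e`, `a0`, `k2`, `r2_a`).
#' @return A tibble with those nine columns plus `ec100`, sorted for
#'   display; empty input yields an empty table.
#' @export
coefficient_table <- function(coeffs) {
  cols <- c("organ", "cell_line", "pulse_duration_us",
            "e0", "k1", "r2_e", "a0", "k2", "r2_a")
  out <- tibble::as_tibble(coeffs) |>
    dplyr::select(dplyr::all_of(cols)) |>
    dplyr::mutate(ec100 = ec_of_n(.data$e0, .data$k1, 100)) |>
    dplyr::arrange(factor(.data$organ, levels = organ_levels()),
                   .data$cell_line, .data$pulse_duration_us)
  out
}

#' Write / read a coefficient database as JSON
#'
#' Serialises one object per (cell line, duration) with keys
#' `organ`, `cell_line`, `duration_us`, `model`, `E0`, `k1`, `A0`, `k2`,
#' `r2_e`, `r2_a`. `read_coefficient_db()` restores the internal column
#' names used throughout the package.
#'
#' @param coeffs A coefficient tibble.
#' @param path JSON file path.
#' @param model Model label stored with each entry.
#' @return `path` invisibly (write); a coefficient tibble (read).
#' @export
write_coefficient_db <- function(coeffs, path, model = "peleg_fermi") {
  out <- tibble::as_tibble(coeffs) |>
    dplyr::transmute(
      organ = .data$organ, cell_line = .data$cell_line,
      duration_us = .data$pulse_duration_us, model = model,
      E0 = .data$e0, k1 = .data$k1, A0 = .data$a0, k2 = .data$k2,
      r2_e = .data$r2_e, r2_a = .data$r2_a
    )
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_coefficient_db
#' @export
read_coefficient_db <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(raw) |>
    dplyr::transmute(
      organ = .data$organ, cell_line = .data$cell_line,
      pulse_duration_us = .data$duration_us, model = .data$model,
      e0 = .data$E0, k1 = .data$k1, a0 = .data$A0, k2 = .data$k2,
      r2_e = .data$r2_e, r2_a = .data$r2_a
    )
}
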