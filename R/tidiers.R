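#' Tidy a two-step Peleg-Fermi fit
#'
#' @param x An `ep_pf_fit` object.
#' @param ... Unused.
#' @return The coefficient tibble (one row per fitted cell line and
#'   duration).
#' @method tidy ep_pf_fit
#' @export
tidy.ep_pf_fit <- function(x, ...) {
  x$coefficients
}

#' Glance at a two-step Peleg-Fermi fit
#'
#' @param x An `ep_pf_fit` object.
#' @param ... Unused.
#' @return A one-row tibble summarising fit counts and goodness-of-fit
#'   ranges.
#' @method glance ep_pf_fit
#' @export
glance.ep_pf_fit <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x$coefficients),
    n_stage1 = nrow(x$stage1),
    n_failures = nrow(x$failures),
    min_r2_e = min(x$coefficients$r2_e),
    min_r2_a = min(x$coefficients$r2_a)
  )
}

#' Tidy an injury analysis
#'
#' @param x An `ep_injury` object.
#' @param ... Unused.
#' @return The per-pulse series tibble (`pulse_number`, `s_ei_ratio`,
#'   `s_ti_ratio`, `peak_T_C`).
#' @method tidy ep_injury
#' @export
tidy.ep_injury <- function(x, ...) {
  x$series
}

#' Glance at an injury analysis
#'
#' @param x An `ep_injury` object.
#' @param ... Unused.
#' @return A one-row tibble with the endpoint area ratios and peak
#'   temperature.
#' @method glance ep_injury
#' @export
glance.ep_injury <- function(x, ...) {
  tibble::tibble(
    cell_line = x$coeffs$cell_line,
    organ = x$organ,
    pulse_duration_us = x$coeffs$pulse_duration_us,
    s_ei_final = x$series$s_ei_ratio[x$protocol$n_pulses_ei],
    s_ti_final = x$series$s_ti_ratio[nrow(x$series)],
    peak_T_C = max(x$series$peak_T_C)
  )
}
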