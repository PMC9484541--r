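#' Configuration for the synthetic viability generator
#'
#' Bundles the ground-truth coefficient rows, the experimental design and
#' the noise model used by [generate_dataset()]. The default design spans
#' the reversible-electroporation range (fields below 500-800 V/cm) up to
#' strongly irreversible fields, with the 10 replicates of the emulated
#' assay protocol.
#'
#' @param truth A coefficient tibble (columns `cell_line`, `organ`,
#'   `pulse_duration_us`, `e0`, `k1`, `a0`, `k2`), e.g. rows of
#'   [pf_coefficients()].
#' @param efs Field-strength design, V/cm.
#' @param pulse_numbers Pulse-number design.
#' @param replicates Replicates per condition (default 10).
#' @param noise_sd SD of additive Gaussian noise on the survival fraction
#'   (default 0.03).
#' @param stimulation Optional list `list(efs_cutoff =, boost =)` adding a
#'   low-field proliferation boost `boost * exp(-efs/efs_cutoff)` so mean
#'   viability can exceed 100% at fields well under the cutoff.
#' @param seed Integer seed; every stochastic routine in the package takes
#'   one (default 20220905).
#' @return A list of class `ep_generator_config`.
#' @export
generator_config <- function(truth,
                             efs = c(250, 500, 750, 1000, 1250, 1500,
                                     2000, 2500, 3000),
                             pulse_numbers = seq(10, 90, by = 10),
                             replicates = 10,
                             noise_sd = 0.03,
                             stimulation = NULL,
                             seed = 20220905) {
  truth <- tibble::as_tibble(truth)
  needed <- c("cell_line", "organ", "pulse_duration_us", "e0", "k1", "a0", "k2")
  if (!all(needed %in% names(truth))) {
    abort(paste0("truth must have columns: ", paste(needed, collapse = ", ")),
          class = "ebtsim_config_error")
  }
  if (replicates < 1 || noise_sd < 0) {
    abort("replicates must be >= 1 and noise_sd >= 0.",
          class = "ebtsim_config_error")
  }
  if (!is.null(stimulation) &&
      !all(c("efs_cutoff", "boost") %in% names(stimulation))) {
    abort("stimulation needs efs_cutoff and boost.",
          class = "ebtsim_config_error")
  }
  structure(list(truth = truth, efs = efs, pulse_numbers = pulse_numbers,
                 replicates = replicates, noise_sd = noise_sd,
                 stimulation = stimulation, seed = as.integer(seed)),
            class = "ep_generator_config")
}

#' Generate a synthetic viability dataset
#'
#' For each truth row, pulse number and field strength, the true survival
#' fraction is the Peleg-Fermi value (plus the optional low-field
#' stimulation term); each replicate adds Gaussian noise on the fraction
#' scale, truncated at zero, and is stored as a percentage. Deterministic
#' given the config seed.
#'
#' @param config An [generator_config()] object.
#' @return A validated viability tibble.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ep_generator_config"))
  withr_seed <- config$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(restore_seed(old), add = TRUE)
  grid <- tidyr::expand_grid(
    config$truth,
    pulse_number = config$pulse_numbers,
    efs_v_cm = config$efs
  )
  s_true <- survival_probability(
    grid$efs_v_cm,
    ec_of_n(grid$e0, grid$k1, grid$pulse_number),
    ac_of_n(grid$a0, grid$k2, grid$pulse_number)
  )
  if (!is.null(config$stimulation)) {
    s_true <- s_true + config$stimulation$boost *
      exp(-grid$efs_v_cm / config$stimulation$efs_cutoff)
  }
  out <- tidyr::expand_grid(
    dplyr::mutate(grid, .s_true = s_true),
    replicate = seq_len(config$replicates)
  )
  noise <- if (config$noise_sd > 0) {
    rnorm(nrow(out), 0, config$noise_sd)
  } else {
    0
  }
  out <- out |>
    dplyr::mutate(viability_pct = 100 * pmax(0, .data$.s_true + noise)) |>
    dplyr::select("cell_line", "organ", "pulse_duration_us", "pulse_number",
                  "efs_v_cm", "replicate", "viability_pct")
  validate_viability(out)
  out
}

#' Generate a synthetic dataset in optical-density form
#'
#' Emits OD triplets that invert the viability normalisation exactly:
#' `od_exp = od_blank + S * (od_control - od_blank)` with the survival
#' fraction `S` from [generate_dataset()], so reading the file back through
#' [read_viability()] reproduces the generated viabilities.
#'
#' @param config An [generator_config()] object.
#' @param od_control,od_blank Control and blank OD levels
#'   (`od_control > od_blank`).
#' @return A tibble with `od_exp`, `od_blank`, `od_control` in place of
#'   `viability_pct`.
#' @export
generate_od_dataset <- function(config, od_control = 1.1, od_blank = 0.1) {
  if (od_control <= od_blank) {
    abort("od_control must exceed od_blank.",
          class = "ebtsim_degenerate_control")
  }
  data <- generate_dataset(config)
  data |>
    dplyr::mutate(
      od_blank = od_blank, od_control = od_control,
      od_exp = od_blank + (.data$viability_pct / 100) *
        (od_control - od_blank)
    ) |>
    dplyr::select(-"viability_pct")
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
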