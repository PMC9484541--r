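# Shared fixtures, built in code.

truth_row <- function(cell_line, duration_us = 100) {
  db <- pf_coefficients(complete_only = TRUE)
  row <- db[db$cell_line == cell_line &
              db$pulse_duration_us == duration_us, ]
  stopifnot(nrow(row) == 1)
  row
}

# a tiny hand-built viability tibble on a 2-N x 3-EFS grid, 2 replicates
tiny_viability <- function() {
  tidyr::expand_grid(
    cell_line = "KYSE-150", organ = "esophagus", pulse_duration_us = 100,
    pulse_number = c(10, 20), efs_v_cm = c(500, 1000, 2000),
    replicate = 1:2
  ) |>
    dplyr::mutate(viability_pct = 90 - 0.02 * efs_v_cm -
                    0.2 * pulse_number + replicate)
}

# full-height plate electrodes spanning the left and right domain edges
plate_dirichlet <- function(domain, voltage) {
  mask <- matrix(FALSE, domain$nx, domain$ny)
  mask[1, ] <- TRUE
  mask[domain$nx, ] <- TRUE
  values <- matrix(0, domain$nx, domain$ny)
  values[1, ] <- voltage
  list(mask = mask, values = values)
}

# analytic two-line-source potential for the needle-electrode problem,
# using the equal-area effective radius of the rasterized electrode disk;
# returns the analytic potential matrix and the comparison window (cells
# within 15 mm of centre, > 2 mm from either electrode centre)
twowire_analytic <- function(domain, voltage) {
  masks <- ebtsim:::electrode_masks(domain)
  a_eff <- sqrt(sum(masks$anode) * domain$spacing^2 / pi)
  gap <- domain$electrode_gap
  cc <- sqrt((gap / 2)^2 - a_eff^2)
  k_amp <- (voltage / 2) / log((gap / 2 + cc) / a_eff)
  xm <- matrix(domain$x, domain$nx, domain$ny)
  ym <- matrix(domain$y, domain$nx, domain$ny, byrow = TRUE)
  x0 <- domain$width / 2
  y0 <- domain$height / 2
  r_anode <- sqrt((xm - (x0 - cc))^2 + (ym - y0)^2)
  r_cathode <- sqrt((xm - (x0 + cc))^2 + (ym - y0)^2)
  potential <- voltage / 2 + k_amp * log(r_cathode / r_anode)
  window <- abs(xm - x0) < 0.015 & abs(ym - y0) < 0.015 &
    sqrt((xm - (x0 - gap / 2))^2 + (ym - y0)^2) > 2e-3 &
    sqrt((xm - (x0 + gap / 2))^2 + (ym - y0)^2) > 2e-3
  list(potential = potential, window = window)
}
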