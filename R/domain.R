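#' Two-dimensional simulation domain with two needle electrodes
#'
#' A regular finite-difference grid over a rectangular tissue domain. Two
#' needle electrodes (circular cross-sections) sit on the horizontal
#' midline, symmetric about the centre. The defaults — 40 mm x 40 mm
#' domain, 1 mm electrode diameter, 10 mm centre-to-centre gap, 0.25 mm
#' spacing — are the package's own configuration of the unpublished
#' geometry, not literature values.
#'
#' Grid nodes are cell centres of an `nx` x `ny` lattice with the physical
#' origin at the lower-left corner; matrices returned by the solvers are
#' indexed `[i, j]` = (x index, y index).
#'
#' @param width,height Domain size, m.
#' @param spacing Grid spacing, m; must resolve the electrode radius with
#'   at least 4 cells across a diameter (`spacing <= radius / 2`).
#' @param electrode_gap Centre-to-centre electrode distance, m.
#' @param electrode_radius Electrode radius, m.
#' @return A list of class `ep_domain` with grid coordinates and electrode
#'   geometry.
#' @export
domain_spec <- function(width = 0.04, height = 0.04, spacing = 2.5e-4,
                        electrode_gap = 0.01, electrode_radius = 5e-4) {
  if (width <= 0 || height <= 0 || spacing <= 0) {
    abort("Domain dimensions and spacing must be positive.",
          class = "ebtsim_config_error")
  }
  if (spacing > electrode_radius / 2) {
    abort("spacing must be <= electrode_radius / 2 (>= 4 cells per diameter).",
          class = "ebtsim_config_error")
  }
  if (electrode_gap <= 2 * electrode_radius) {
    abort("Electrodes overlap: gap must exceed the electrode diameter.",
          class = "ebtsim_config_error")
  }
  centers <- list(
    anode = c(width / 2 - electrode_gap / 2, height / 2),
    cathode = c(width / 2 + electrode_gap / 2, height / 2)
  )
  for (ctr in centers) {
    if (ctr[1] - electrode_radius < 0 || ctr[1] + electrode_radius > width ||
        ctr[2] - electrode_radius < 0 || ctr[2] + electrode_radius > height) {
      abort("Electrodes must lie inside the domain.",
            class = "ebtsim_config_error")
    }
  }
  nx <- round(width / spacing) + 1L
  ny <- round(height / spacing) + 1L
  structure(
    list(width = width, height = height, spacing = spacing,
         electrode_gap = electrode_gap, electrode_radius = electrode_radius,
         nx = nx, ny = ny,
         x = seq(0, width, length.out = nx),
         y = seq(0, height, length.out = ny),
         centers = centers),
    class = "ep_domain"
  )
}

# logical [nx, ny] masks of the two electrode interiors and their union
electrode_masks <- function(domain) {
  xm <- matrix(domain$x, domain$nx, domain$ny)
  ym <- matrix(domain$y, domain$nx, domain$ny, byrow = TRUE)
  inside <- function(ctr) {
    (xm - ctr[1])^2 + (ym - ctr[2])^2 <= domain$electrode_radius^2
  }
  anode <- inside(domain$centers$anode)
  cathode <- inside(domain$centers$cathode)
  list(anode = anode, cathode = cathode, any = anode | cathode)
}

#' Pulse protocol for the injury simulation
#'
#' Defaults follow the reference protocol: 2000 V, 100 microsecond pulses
#' at 1 Hz; 100 pulses define the electrical-injury endpoint and 200
#' pulses (200 s at 1 Hz) the thermal-injury endpoint. The duty factor
#' (duration x frequency) must not exceed 1; with defaults it is 1e-4.
#'
#' @param voltage Applied voltage between the electrodes, V.
#' @param duration_us Pulse duration, microseconds.
#' @param frequency_hz Pulse repetition frequency, Hz.
#' @param n_pulses_ei Pulses for the electrical-injury analysis.
#' @param n_pulses_ti Pulses (= seconds at 1 Hz) for the thermal analysis.
#' @return A list of class `ep_protocol` (includes the computed `duty`).
#' @export
pulse_protocol <- function(voltage = 2000, duration_us = 100,
                           frequency_hz = 1, n_pulses_ei = 100,
                           n_pulses_ti = 200) {
  if (voltage < 0 || duration_us <= 0 || frequency_hz <= 0 ||
      n_pulses_ei < 1 || n_pulses_ti < 1) {
    abort("Protocol parameters out of range.", class = "ebtsim_config_error")
  }
  duty <- duration_us * 1e-6 * frequency_hz
  if (duty > 1) {
    abort("Duty factor duration * frequency exceeds 1.",
          class = "ebtsim_config_error")
  }
  structure(list(voltage = voltage, duration_us = duration_us,
                 frequency_hz = frequency_hz, n_pulses_ei = n_pulses_ei,
                 n_pulses_ti = n_pulses_ti, duty = duty),
            class = "ep_protocol")
}

#' Arrhenius thermal-damage kinetics
#'
#' First-order damage kinetics \eqn{\Omega(t) = \int \zeta
#' e^{-E_a/(R T)} dt} with injury probability \eqn{1 - e^{-\Omega}}. The
#' default frequency factor and activation energy are widely used
#' soft-tissue (liver protein-coagulation) values; they are an external
#' modelling assumption, configurable per organ.
#'
#' @param zeta Frequency factor, 1/s.
#' @param ea Activation energy, J/mol.
#' @param r_gas Gas constant, J/(mol K).
#' @return A list of class `ep_arrhenius`.
#' @export
arrhenius_params <- function(zeta = 7.39e39, ea = 2.577e5, r_gas = 8.314) {
  if (zeta <= 0 || ea <= 0) {
    abort("zeta and ea must be positive.", class = "ebtsim_config_error")
  }
  structure(list(zeta = zeta, ea = ea, r_gas = r_gas),
            class = "ep_arrhenius")
}
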