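# Pennes bioheat conduction in perfused tissue:
#   rho c dT/dt = div(k grad T) + rho_b c_b omega_b (T_b - T)
#                 + rho q_met + q_joule
# Discretised on the domain grid; implicit (backward Euler) stepping with
# the outer boundary held at body temperature and electrode interiors
# treated as electrode material (conducting, no perfusion, no sources).

# blood constants used to convert the tabulated perfusion rate
# (ml/(min kg of tissue)) into a volumetric heat sink coefficient
BLOOD_RHO <- 1050    # kg/m^3
BLOOD_C <- 3617      # J/(kg C)
T_BLOOD <- 37        # arterial/body temperature, C

# perfusion sink coefficient rho_b c_b omega, W/(m^3 C);
# omega [1/s] = w_b * rho_tissue / (60 * 1e6)
perfusion_coefficient <- function(w_b_ml_min_kg, rho_tissue) {
  omega <- w_b_ml_min_kg * rho_tissue / 6e7
  BLOOD_RHO * BLOOD_C * omega
}

# Assemble the implicit system for one tissue (+ optional electrode mask).
# Free nodes are all non-outer-boundary nodes; the outer boundary is
# Dirichlet at t_boundary.
build_bioheat_system <- function(domain, tissue, dt, electrode = NULL,
                                 t_boundary = T_BLOOD) {
  nx <- domain$nx; ny <- domain$ny
  n <- nx * ny
  h <- domain$spacing
  boundary <- matrix(FALSE, nx, ny)
  boundary[1, ] <- TRUE; boundary[nx, ] <- TRUE
  boundary[, 1] <- TRUE; boundary[, ny] <- TRUE
  emask <- if (is.null(electrode)) matrix(FALSE, nx, ny) else electrode
  el <- tissue_properties("electrode")
  k_node <- matrix(tissue$k_w_m_c, nx, ny)
  rhoc <- matrix(tissue$rho_kg_m3 * tissue$c_j_kg_c, nx, ny)
  perf <- matrix(perfusion_coefficient(tissue$w_b_ml_min_kg,
                                       tissue$rho_kg_m3), nx, ny)
  qmet <- matrix(tissue$rho_kg_m3 * tissue$q_met_w_kg, nx, ny)
  k_node[emask] <- el$k_w_m_c
  rhoc[emask] <- el$rho_kg_m3 * el$c_j_kg_c
  perf[emask] <- 0
  qmet[emask] <- 0
  idx <- matrix(seq_len(n), nx, ny)
  free <- !boundary
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- numeric(n)
  b_fixed <- numeric(n)  # boundary-coupling contribution, constant in time
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    di <- d[1]; dj <- d[2]
    ic <- pmax(1L, 1L - di):pmin(nx, nx - di)
    jc <- pmax(1L, 1L - dj):pmin(ny, ny - dj)
    ctr <- idx[ic, jc, drop = FALSE]
    nb <- idx[ic + di, jc + dj, drop = FALSE]
    use <- free[ctr]
    ctr <- ctr[use]; nb <- nb[use]
    kf <- (k_node[ctr] + k_node[nb]) / 2 / h^2  # face conductivity
    diag_acc[ctr] <- diag_acc[ctr] + kf
    nb_free <- free[nb]
    rows <- c(rows, ctr[nb_free]); cols <- c(cols, nb[nb_free])
    vals <- c(vals, -kf[nb_free])
    # Dirichlet neighbours contribute a constant source
    b_fixed[ctr[!nb_free]] <- b_fixed[ctr[!nb_free]] +
      kf[!nb_free] * t_boundary
  }
  m_over_dt <- as.numeric(rhoc) / dt
  diag_entries <- diag_acc + m_over_dt + as.numeric(perf)
  # boundary nodes: identity rows at t_boundary
  bn <- idx[boundary]
  diag_entries[bn] <- 1
  vals_all <- c(vals, diag_entries)
  A <- Matrix::sparseMatrix(
    i = c(rows, seq_len(n)), j = c(cols, seq_len(n)), x = vals_all,
    dims = c(n, n)
  )
  fac <- Matrix::lu(A)
  list(fac = fac, m_over_dt = m_over_dt, perf = as.numeric(perf),
       qmet = as.numeric(qmet), b_fixed = b_fixed, boundary = boundary,
       t_boundary = t_boundary, nx = nx, ny = ny, dt = dt)
}

bioheat_advance <- function(system, temp, q_joule) {
  b <- system$m_over_dt * as.numeric(temp) +
    system$perf * T_BLOOD + system$qmet + as.numeric(q_joule) +
    system$b_fixed
  b[system$boundary] <- system$t_boundary
  matrix(as.numeric(Matrix::solve(system$fac, b)), system$nx, system$ny)
}

#' One implicit step of the Pennes bioheat equation
#'
#' Advances the temperature field by `dt` seconds with backward Euler:
#' conduction (5-point stencil, face-averaged conductivity), the blood
#' perfusion sink \eqn{\rho_b c_b \omega_b (T_b - T)} (blood at 37 C,
#' density 1050 kg/m^3, heat capacity 3617 J/(kg C)), metabolic heat
#' \eqn{\rho q_{met}}, and the supplied Joule source. The outer boundary
#' is held at 37 C; electrode interiors use electrode material properties
#' with no perfusion or sources.
#'
#' Temperatures are in degrees Celsius throughout.
#'
#' @param temp `[nx, ny]` temperature matrix, C.
#' @param domain An [domain_spec()] object.
#' @param tissue A one-row tissue tibble (see [tissue_properties()]).
#' @param source Joule heating matrix, W/m^3 (0 for none).
#' @param dt Time step, s.
#' @param electrode Optional logical electrode mask (default: none).
#' @return The temperature matrix after one step.
#' @export
step_bioheat <- function(temp, domain, tissue, source, dt,
                         electrode = NULL) {
  if (dt <= 0) abort("dt must be positive.", class = "ebtsim_config_error")
  if (length(source) == 1) source <- matrix(source, domain$nx, domain$ny)
  sys <- build_bioheat_system(domain, tissue, dt, electrode = electrode)
  out <- bioheat_advance(sys, temp, source)
  if (!all(is.finite(out))) {
    abort("Non-finite temperature after step.", class = "ebtsim_solver_error")
  }
  out
}
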