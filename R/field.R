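# Electrostatic solve: div(sigma grad V) = 0 on the regular grid.
# With homogeneous tissue conductivity the solution is independent of
# sigma, so the Laplacian is assembled unscaled.

#' Solve the electric potential on the domain
#'
#' Solves the Laplace problem with Dirichlet electrodes (anode at
#' `voltage`, cathode at 0 V) and zero-flux outer boundaries, using a
#' 5-point finite-difference stencil and a sparse direct solve. The
#' conductivity is homogeneous within the tissue so the potential does not
#' depend on its value.
#'
#' Custom Dirichlet sets (e.g. full-height plate electrodes) can be
#' supplied through `dirichlet` as a list with logical `mask` and numeric
#' `values` matrices of grid shape; this replaces the needle electrodes.
#'
#' @param domain An [domain_spec()] object.
#' @param voltage Anode potential, V (cathode at 0).
#' @param dirichlet Optional custom Dirichlet specification.
#' @return A list of class `ep_field`: `potential` (`[nx, ny]` matrix, V),
#'   `domain`, `voltage`, `dirichlet_mask`, `electrodes` (needle masks, or
#'   NULL when custom Dirichlet was used), and the solve `residual`
#'   (max abs).
#' @export
solve_potential <- function(domain, voltage = 2000, dirichlet = NULL) {
  nx <- domain$nx; ny <- domain$ny
  n <- nx * ny
  if (is.null(dirichlet)) {
    masks <- electrode_masks(domain)
    if (!any(masks$anode) || !any(masks$cathode)) {
      abort("Electrode rasterization is empty; refine the grid.",
            class = "ebtsim_solver_error")
    }
    dmask <- masks$any
    dvals <- matrix(0, nx, ny)
    dvals[masks$anode] <- voltage
  } else {
    masks <- NULL
    dmask <- dirichlet$mask
    dvals <- dirichlet$values
    stopifnot(all(dim(dmask) == c(nx, ny)), all(dim(dvals) == c(nx, ny)))
    if (!any(dmask)) {
      abort("Dirichlet set is empty; the system is singular.",
            class = "ebtsim_solver_error")
    }
  }
  idx <- matrix(seq_len(n), nx, ny)
  free <- !dmask
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- numeric(n)
  b <- numeric(n)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    di <- d[1]; dj <- d[2]
    ic <- pmax(1L, 1L - di):pmin(nx, nx - di)  # centre i range with neighbour
    jc <- pmax(1L, 1L - dj):pmin(ny, ny - dj)
    ctr <- idx[ic, jc, drop = FALSE]
    nb <- idx[ic + di, jc + dj, drop = FALSE]
    use <- free[ctr]  # only free centres get stencil rows
    ctr <- ctr[use]; nb <- nb[use]
    diag_acc[ctr] <- diag_acc[ctr] - 1
    rows <- c(rows, ctr); cols <- c(cols, nb); vals <- c(vals, rep(1, length(nb)))
  }
  # Dirichlet rows: identity
  dn <- idx[dmask]
  diag_entries <- diag_acc
  diag_entries[dn] <- 1
  b[dn] <- dvals[dmask]
  A <- Matrix::sparseMatrix(
    i = c(rows, seq_len(n)), j = c(cols, seq_len(n)),
    x = c(vals, diag_entries), dims = c(n, n)
  )
  v <- as.numeric(Matrix::solve(A, b))
  residual <- max(abs(A %*% v - b))
  structure(
    list(potential = matrix(v, nx, ny), domain = domain, voltage = voltage,
         dirichlet_mask = dmask, electrodes = masks, residual = residual),
    class = "ep_field"
  )
}

#' Electric field magnitude from a solved potential
#'
#' Central-difference gradient magnitude (one-sided at the outer
#' boundaries), converted from V/m to V/cm to match the half-lethality
#' thresholds.
#'
#' @param field An `ep_field` object from [solve_potential()].
#' @return An `[nx, ny]` matrix of |E| in V/cm.
#' @export
field_magnitude <- function(field) {
  v <- field$potential
  h <- field$domain$spacing
  nx <- nrow(v); ny <- ncol(v)
  ex <- matrix(0, nx, ny); ey <- matrix(0, nx, ny)
  ex[2:(nx - 1), ] <- (v[3:nx, ] - v[1:(nx - 2), ]) / (2 * h)
  ex[1, ] <- (v[2, ] - v[1, ]) / h
  ex[nx, ] <- (v[nx, ] - v[nx - 1, ]) / h
  ey[, 2:(ny - 1)] <- (v[, 3:ny] - v[, 1:(ny - 2)]) / (2 * h)
  ey[, 1] <- (v[, 2] - v[, 1]) / h
  ey[, ny] <- (v[, ny] - v[, ny - 1]) / h
  sqrt(ex^2 + ey^2) / 100  # V/m -> V/cm
}

#' Duty-cycle-averaged Joule heating
#'
#' Volumetric heat source \eqn{q = \sigma |E|^2 \cdot d} in W/m^3, where
#' the duty factor \eqn{d} = pulse duration x frequency averages the
#' pulsed deposition over each repetition period (1e-4 with the default
#' protocol). Per-pulse microsecond transients are not resolved.
#'
#' @param emag_v_cm Field magnitude matrix in V/cm (from
#'   [field_magnitude()]).
#' @param sigma Tissue electrical conductivity, S/m.
#' @param protocol An [pulse_protocol()] object.
#' @return A matrix of volumetric heating, W/m^3.
#' @export
joule_source <- function(emag_v_cm, sigma, protocol) {
  sigma * (emag_v_cm * 100)^2 * protocol$duty
}
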