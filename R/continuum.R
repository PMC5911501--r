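# Unified-continuum constitutive model: one set of conservation laws over the
# whole domain, with a binary per-cell phase function theta selecting the
# constitutive stress -- Newtonian fluid (theta = 1) or rate-form neo-Hookean
# solid (theta = 0).  The total stress is tau = tauD - p*I with the deviatoric
# blend tauD = theta*tau_f + (1 - theta)*tau_s.

#' Material constants of the two-phase continuum
#'
#' Defaults: blood density 1060 kg/m^3 and viscosity 0.0027 Pa s; solid
#' density 1000 kg/m^3.  The solid shear modulus defaults to the native-valve
#' value 3.3e9 Pa; the bileaflet-mechanical-valve leaflets use 6.5e11 Pa
#' (pass `mu_s` explicitly).  These stiffnesses are working values for
#' capturing flow and valve dynamics, not measured tissue properties.
#'
#' @param rho_fluid fluid density (kg/m^3).
#' @param rho_solid solid density (kg/m^3).
#' @param mu_f dynamic viscosity (Pa s).
#' @param mu_s solid shear modulus (Pa).
#' @return a list of class `material_constants`.
#' @export
material_constants <- function(rho_fluid = 1060, rho_solid = 1000,
                               mu_f = 0.0027, mu_s = 3.3e9) {
  stopifnot(rho_fluid > 0, rho_solid > 0, mu_f > 0, mu_s > 0)
  structure(list(rho_fluid = rho_fluid, rho_solid = rho_solid,
                 mu_f = mu_f, mu_s = mu_s), class = "material_constants")
}

#' Strain-rate tensor
#'
#' The symmetric part of the velocity gradient, eps(u) = (grad u + grad u^T)/2.
#'
#' @param grad_u square velocity-gradient matrix (1/s).
#' @return symmetric matrix of the same dimension.
#' @export
strain_rate <- function(grad_u) {
  grad_u <- as.matrix(grad_u)
  stopifnot(nrow(grad_u) == ncol(grad_u))
  (grad_u + t(grad_u)) / 2
}

#' Newtonian fluid deviatoric stress
#'
#' tau_f = 2 mu_f eps(u).
#'
#' @param grad_u velocity-gradient matrix (1/s).
#' @param mu_f dynamic viscosity (Pa s).
#' @return deviatoric stress tensor (Pa).
#' @export
fluid_stress <- function(grad_u, mu_f) {
  2 * mu_f * strain_rate(grad_u)
}

#' One explicit step of the solid stress rate equation
#'
#' The incompressible neo-Hookean solid is carried in rate form: the material
#' derivative of the solid stress is
#' `D_t tau_s = 2 mu_s eps(u) + grad(u) tau_s + tau_s grad(u)^T`
#' (an upper-convected Oldroyd rate driven by the strain rate).  One time step
#' advances `tau_s <- tau_s + dt * rhs`, with the velocity gradient evaluated
#' at the slab midpoint and `tau_s` on the right-hand side frozen at the
#' previous level; the result is symmetrized against rounding.
#'
#' @param tau_s_prev symmetric solid stress at the previous level (Pa).
#' @param grad_u_mid midpoint velocity gradient (1/s).
#' @param mu_s solid shear modulus (Pa).
#' @param dt time step (s).
#' @return updated symmetric stress tensor.
#' @export
advance_solid_stress <- function(tau_s_prev, grad_u_mid, mu_s, dt) {
  stopifnot(dt > 0)
  tau_s_prev <- as.matrix(tau_s_prev); g <- as.matrix(grad_u_mid)
  if (any(!is.finite(tau_s_prev)) || any(!is.finite(g)))
    stop("advance_solid_stress: non-finite input", call. = FALSE)
  rot <- g %*% tau_s_prev
  new <- tau_s_prev + dt * (2 * mu_s * strain_rate(g) + rot + t(rot))
  (new + t(new)) / 2
}

#' Composite stress of the two-phase continuum
#'
#' tauD = theta tau_f + (1 - theta) tau_s;  tau = tauD - p I.  The phase is
#' binary, so the blend is exact selection, never interpolation.
#'
#' @param theta phase value, 0 (solid) or 1 (fluid).
#' @param tau_f fluid deviatoric stress.
#' @param tau_s solid stress.
#' @param p pressure (Pa).
#' @return list with `total` (tau) and `deviatoric` (tauD).
#' @export
composite_stress <- function(theta, tau_f, tau_s, p) {
  stopifnot(theta %in% c(0, 1))
  tauD <- if (theta == 1) as.matrix(tau_f) else as.matrix(tau_s)
  list(total = tauD - diag(p, nrow(tauD)), deviatoric = tauD)
}

#' Von Mises stress
#'
#' tau_v = sqrt( sum_ij | tau_ij - delta_ij tr(tau)/3 |^2 ), the Frobenius
#' norm of the stress deviator.  2D tensors are embedded into 3D with a zero
#' third row/column, so a 2D pure pressure still has a nonzero in-plane
#' deviator unless embedded -- which is why the embedding is always applied.
#'
#' @param tau symmetric stress tensor, 2x2 or 3x3.
#' @return scalar von Mises stress (Pa), invariant under addition of any
#'   isotropic tensor and under orthogonal conjugation.
#' @export
von_mises <- function(tau) {
  tau <- as.matrix(tau)
  if (nrow(tau) == 2L) {
    t3 <- matrix(0, 3L, 3L); t3[1:2, 1:2] <- tau; tau <- t3
  }
  dev <- tau - diag(sum(diag(tau)) / 3, 3L)
  sqrt(sum(dev * dev))
}

# ---- per-cell tensor fields ------------------------------------------------
# Solid stress is stored per cell as an m x (d*d) matrix (row-major tensor
# entries); with P1 velocity the gradient, hence the stress rate, is constant
# per cell, so a single quadrature point is exact.

zero_cell_tensors <- function(m, d) matrix(0, m, d * d)

# advance all solid cells at once; grad_u is m x (d*d) (entries of grad U per
# cell, row-major: g[i,j] at column (i-1)*d + j)
advance_solid_stress_cells <- function(tau, grad_u, mu_s, dt, solid_idx, d) {
  for (c in solid_idx) {
    g <- matrix(grad_u[c, ], d, d, byrow = TRUE)
    tc <- matrix(tau[c, ], d, d, byrow = TRUE)
    tau[c, ] <- as.vector(t(advance_solid_stress(tc, g, mu_s, dt)))
  }
  tau
}
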