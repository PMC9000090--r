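#' Biochemical parameters of the RhoA-actomyosin circuit
#'
#' Constructs the parameter set for the reaction terms of the RhoA /
#' actomyosin activator-inhibitor circuit. Defaults are the calibrated
#' constants for the *C. elegans* cortex. Concentrations are dimensionless
#' throughout; all rates are per second.
#'
#' @param S basal RhoA activation rate (Rho-GEF activity), 1/s.
#' @param a autocatalytic RhoA production rate, 1/s.
#' @param n Hill exponent of the autocatalytic term (default 1, the
#'   Michaelis form).
#' @param r_a RhoA concentration at half-maximal autocatalysis.
#' @param g negative-feedback rate (F-actin-recruited GAP activity), 1/s.
#' @param r_g RhoA concentration at half-maximal inactivation.
#' @param S_m basal actomyosin production rate, 1/s.
#' @param k_a actomyosin assembly rate, 1/s.
#' @param k_d actomyosin disassembly rate, 1/s.
#'
#' @return An object of class `chem_params` (a named list).
#' @seealso [rr_rate()], [rm_rate()], [find_fixed_points()]
#' @examples
#' p <- chem_params(S = 0.002)
#' rr_rate(0.5, 0.3, p)
#' @export
chem_params <- function(S = 0, a = 0.1609, n = 1, r_a = 0.3833,
                        g = 0.1787, r_g = 0.01, S_m = 0.0076,
                        k_a = 0.1408, k_d = 0.0828) {
  p <- list(S = S, a = a, n = n, r_a = r_a, g = g, r_g = r_g,
            S_m = S_m, k_a = k_a, k_d = k_d)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("chem_params: '", nm, "' must be a finite scalar")
    if (p[[nm]] < 0) stop("chem_params: '", nm, "' must be >= 0")
  }
  if (p$r_a <= 0) stop("chem_params: r_a must be > 0")
  if (p$r_g <= 0) stop("chem_params: r_g must be > 0")
  structure(p, class = "chem_params")
}

#' Mechanical parameters of the well-mixed viscoelastic model
#'
#' Parameters for the local (well-mixed) model in which a homogeneous patch
#' of cortex is an active viscoelastic element with strain `u`. The element
#' relaxes on the timescale `tau_local` = eta_L/E and is compressed by
#' actomyosin active stress saturating at `sigma_over_E`.
#'
#' @param sigma_over_E dimensionless contractility sigma_a/E (>= 0).
#' @param tau_local viscoelastic relaxation time eta_L/E in seconds.
#' @param m0 actomyosin concentration at half-maximum active stress. Not a
#'   directly measured quantity; defaults to 1, the order of the steady-state
#'   actomyosin concentration.
#'
#' @return An object of class `local_mech_params`.
#' @export
local_mech_params <- function(sigma_over_E = 0.2, tau_local = 5, m0 = 1) {
  stopifnot(sigma_over_E >= 0, tau_local > 0, m0 > 0)
  structure(list(sigma_over_E = sigma_over_E, tau_local = tau_local, m0 = m0),
            class = "local_mech_params")
}

#' Mechanical parameters of the continuum active-gel model
#'
#' Parameters for the one-dimensional Maxwell active gel. The momentum
#' equation is drag-scaled, so only the hydrodynamic length
#' `lam` = sqrt(eta/gamma), the Maxwell time `tau`, and the scaled active
#' stress `sigma_prime` = sigma_a/gamma enter.
#'
#' @param tau Maxwell relaxation time, s.
#' @param lam hydrodynamic length sqrt(eta/gamma), micrometres.
#' @param sigma_prime drag-scaled active stress sigma_a/gamma, um^2/s.
#' @param D_r RhoA diffusivity, um^2/s.
#' @param D_m actomyosin diffusivity, um^2/s.
#' @param m0 actomyosin concentration at half-maximum active stress.
#' @param L_over_lam domain length in units of `lam` (periodic box).
#' @param N number of grid points.
#'
#' @return An object of class `gel_params`.
#' @export
gel_params <- function(tau = 5, lam = 14.3, sigma_prime = 49.8,
                       D_r = 0.1, D_m = 0.01, m0 = 1,
                       L_over_lam = 10, N = 150) {
  stopifnot(tau > 0, lam > 0, sigma_prime >= 0, D_r >= 0, D_m >= 0,
            m0 > 0, L_over_lam > 0, N >= 8)
  structure(list(tau = tau, lam = lam, sigma_prime = sigma_prime,
                 D_r = D_r, D_m = D_m, m0 = m0,
                 L_over_lam = L_over_lam, N = as.integer(N)),
            class = "gel_params")
}

#' Mechanical parameters of the two-dimensional active gel
#'
#' Extends [gel_params()] with the split of the total viscosity eta into
#' shear and bulk parts. By default the bulk viscosity is three times the
#' shear viscosity (eta_b = 3/4 eta, eta_s = 1/4 eta), both relaxing on the
#' same Maxwell time.
#'
#' @inheritParams gel_params
#' @param eta_b_frac bulk fraction of the total viscosity.
#' @param eta_s_frac shear fraction of the total viscosity.
#'
#' @return An object of class `gel2d_params` (also inherits `gel_params`).
#' @export
gel2d_params <- function(tau = 5, lam = 14.3, sigma_prime = 49.8,
                         D_r = 0.1, D_m = 0.01, m0 = 1,
                         L_over_lam = 10, N = 150,
                         eta_b_frac = 3 / 4, eta_s_frac = 1 / 4) {
  stopifnot(eta_b_frac > 0, eta_s_frac > 0)
  if (abs(eta_b_frac + eta_s_frac - 1) > 1e-12)
    warning("gel2d_params: eta_b_frac + eta_s_frac != 1; ",
            "total viscosity differs from eta")
  gp <- gel_params(tau, lam, sigma_prime, D_r, D_m, m0, L_over_lam, N)
  gp$eta_b_frac <- eta_b_frac
  gp$eta_s_frac <- eta_s_frac
  class(gp) <- c("gel2d_params", "gel_params")
  gp
}

#' @export
print.chem_params <- function(x, ...) {
  cat("RhoA-actomyosin chemistry parameters (rates 1/s):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.gel_params <- function(x, ...) {
  cat("Active-gel mechanical parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}
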