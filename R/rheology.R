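#' Casson rheology parameters
#'
#' Blood is modeled as a Casson yield-stress fluid,
#' \eqn{\sqrt{\tau} = \sqrt{\tau_y} + \sqrt{\mu_p \dot\gamma}}, regularized
#' with a shear-rate floor so the effective viscosity stays bounded in
#' unyielded (plug) regions. A `literal_constant` mode is also provided in
#' which the effective viscosity is the shear-rate-independent constant
#' \eqn{(\sqrt\zeta - \sqrt{m})^2}; it exists for comparison runs and
#' reduces the model to a Newtonian fluid.
#'
#' Defaults are standard blood-analog Casson constants:
#' plastic viscosity 3.45e-3 Pa s, yield stress 5e-3 Pa, density
#' 1050 kg/m^3, regularization floor 1e-3 1/s. The literal-mode constants
#' default to \eqn{\zeta = 4m} with \eqn{m} = 3.45e-3 Pa s so that the
#' literal viscosity equals the default plastic viscosity.
#'
#' @param mu_p plastic viscosity (Pa s, > 0).
#' @param tau_y yield stress (Pa, >= 0).
#' @param rho density (kg/m^3, > 0).
#' @param gammadot_floor regularization shear rate (1/s, > 0).
#' @param mode `"casson"` (default) or `"literal_constant"`.
#' @param zeta,m literal-mode constants (Pa s).
#' @return An object of class `casson_params`.
#' @export
casson_params <- function(mu_p = 3.45e-3, tau_y = 5e-3, rho = 1050,
                          gammadot_floor = 1e-3,
                          mode = c("casson", "literal_constant"),
                          zeta = 1.38e-2, m = 3.45e-3) {
  mode <- match.arg(mode)
  if (!is.finite(mu_p) || mu_p <= 0) stop("rheology error: mu_p must be > 0", call. = FALSE)
  if (!is.finite(tau_y) || tau_y < 0) stop("rheology error: tau_y must be >= 0", call. = FALSE)
  if (!is.finite(rho) || rho <= 0) stop("rheology error: rho must be > 0", call. = FALSE)
  if (!is.finite(gammadot_floor) || gammadot_floor <= 0)
    stop("rheology error: gammadot_floor must be > 0", call. = FALSE)
  if (mode == "literal_constant" && (sqrt(zeta) - sqrt(m))^2 <= 0)
    stop("rheology error: literal_constant mode needs (sqrt(zeta) - sqrt(m))^2 > 0",
         call. = FALSE)
  structure(list(mu_p = mu_p, tau_y = tau_y, rho = rho,
                 gammadot_floor = gammadot_floor, mode = mode,
                 zeta = zeta, m = m),
            class = "casson_params")
}

#' Shear-rate invariant of an axisymmetric flow
#'
#' \eqn{\dot\gamma = \sqrt{2\,\mathrm{tr}\,D^2}} with the axisymmetric
#' rate-of-strain components \eqn{D_{rr} = \partial u/\partial r},
#' \eqn{D_{\theta\theta} = u/r}, \eqn{D_{zz} = \partial w/\partial z},
#' \eqn{D_{rz} = (\partial u/\partial z + \partial w/\partial r)/2}.
#'
#' @param du_dr,du_dz,dw_dr,dw_dz,u_over_r strain-rate components (1/s);
#'   vectors/arrays of a common shape are accepted.
#' @return \eqn{\dot\gamma \ge 0} (1/s), same shape as the inputs.
#' @export
#' @examples
#' shear_rate_invariant(0, 0, 5, 0, 0)  # simple shear: 5
shear_rate_invariant <- function(du_dr = 0, du_dz = 0, dw_dr = 0, dw_dz = 0,
                                 u_over_r = 0) {
  d_rz <- (du_dz + dw_dr) / 2
  sqrt(2 * (du_dr^2 + u_over_r^2 + dw_dz^2 + 2 * d_rz^2))
}

#' Effective viscosity of the regularized Casson model
#'
#' In `casson` mode,
#' \eqn{\mu_{eff}(\dot\gamma) = (\sqrt{\mu_p} +
#' \sqrt{\tau_y / \max(\dot\gamma, \dot\gamma_{floor})})^2}: monotonically
#' non-increasing in \eqn{\dot\gamma}, tending to \eqn{\mu_p} at high shear
#' and capped at \eqn{(\sqrt{\mu_p} + \sqrt{\tau_y/\dot\gamma_{floor}})^2}
#' in the plug. In `literal_constant` mode it is the shear-independent
#' \eqn{(\sqrt\zeta - \sqrt m)^2}.
#'
#' @param gammadot shear rate(s), 1/s, >= 0.
#' @param params a [casson_params()].
#' @return Effective viscosity (Pa s), same shape as `gammadot`.
#' @export
effective_viscosity <- function(gammadot, params) {
  stopifnot(inherits(params, "casson_params"))
  if (any(!is.finite(gammadot)) || any(gammadot < 0))
    stop("domain error: shear rate must be finite and >= 0", call. = FALSE)
  if (params$mode == "literal_constant") {
    out <- gammadot
    out[] <- (sqrt(params$zeta) - sqrt(params$m))^2
    return(out)
  }
  g <- pmax(gammadot, params$gammadot_floor)
  (sqrt(params$mu_p) + sqrt(params$tau_y / g))^2
}

#' Extra-stress components from strain rates
#'
#' Viscous stresses of the (regularized) Casson model in the conventional
#' cylindrical form: \eqn{S_{rr} = 2\mu_{eff}\,\partial u/\partial r},
#' \eqn{S_{zz} = 2\mu_{eff}\,\partial w/\partial z},
#' \eqn{S_{rz} = \mu_{eff}(\partial u/\partial z + \partial w/\partial r)},
#' plus the hoop stress \eqn{S_{\theta\theta} = 2\mu_{eff}\,u/r} needed by
#' the radial momentum balance. Linear in each strain-rate component at
#' fixed \eqn{\mu_{eff}}, and reducing to the standard Newtonian viscous
#' stress tensor when the yield stress vanishes.
#'
#' @inheritParams shear_rate_invariant
#' @param mu_eff effective viscosity (Pa s, > 0).
#' @return A list with components `S_rr`, `S_zz`, `S_rz`, `S_tt` (Pa).
#' @export
stress_components <- function(du_dr = 0, du_dz = 0, dw_dr = 0, dw_dz = 0,
                              u_over_r = 0, mu_eff) {
  stopifnot(all(mu_eff > 0))
  list(S_rr = 2 * mu_eff * du_dr,
       S_zz = 2 * mu_eff * dw_dz,
       S_rz = mu_eff * (du_dz + dw_dr),
       S_tt = 2 * mu_eff * u_over_r)
}
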