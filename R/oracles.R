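#' Annular Poiseuille flow (closed form)
#'
#' Steady, fully developed Newtonian flow between concentric cylinders
#' driven by a constant pressure gradient `G` (= -dp/dz, Pa/m):
#' \deqn{w(r) = \frac{G}{4\mu}\left[R_o^2 - r^2 -
#'   (R_o^2 - R_i^2)\frac{\ln(R_o/r)}{\ln(R_o/R_i)}\right]}
#' with flow rate
#' \deqn{Q = \frac{\pi G}{8\mu}\left[R_o^4 - R_i^4 -
#'   \frac{(R_o^2 - R_i^2)^2}{\ln(R_o/R_i)}\right].}
#' Serves as the Newtonian verification oracle for the solver.
#'
#' @param R_i inner radius (m), `0 < R_i < R_o`.
#' @param R_o outer radius (m).
#' @param G pressure gradient -dp/dz (Pa/m).
#' @param mu dynamic viscosity (Pa s, > 0).
#' @return An object of class `annulus_flow` with fields `R_i`, `R_o`, `G`,
#'   `mu`, velocity function `w(r)`, wall-shear function `tau(r)`
#'   (\eqn{\mu\,dw/dr}, signed) and closed-form flow rate `Q` (m^3/s).
#' @export
annular_poiseuille <- function(R_i, R_o, G, mu) {
  if (!is.finite(R_i) || !is.finite(R_o) || R_i <= 0 || R_i >= R_o)
    stop("domain error: need 0 < R_i < R_o", call. = FALSE)
  if (mu <= 0) stop("domain error: mu must be > 0", call. = FALSE)
  lnr <- log(R_o / R_i)
  A <- R_o^2 - R_i^2
  w <- function(r) (G / (4 * mu)) * (R_o^2 - r^2 - A * log(R_o / r) / lnr)
  tau <- function(r) (G / 4) * (-2 * r + A / (r * lnr))
  Q <- (pi * G / (8 * mu)) * (R_o^4 - R_i^4 - A^2 / lnr)
  structure(list(R_i = R_i, R_o = R_o, G = G, mu = mu, w = w, tau = tau, Q = Q),
            class = "annulus_flow")
}

#' Casson flow in a circular tube (Buckingham-Reiner closed form)
#'
#' Steady, fully developed Casson flow in a tube of radius `R` driven by a
#' constant pressure gradient `G` (= -dp/dz). The wall stress is
#' \eqn{\tau_w = GR/2}; the core moves as a rigid plug for
#' \eqn{r \le r_p = 2\tau_y/G}. The flow rate follows the
#' Buckingham-Reiner relation
#' \deqn{Q = \frac{\pi G R^4}{8\mu_p}\left[1 - \frac{16}{7}\xi^{1/2} +
#'   \frac{4}{3}\xi - \frac{1}{21}\xi^4\right], \quad \xi = r_p/R.}
#'
#' @param R tube radius (m, > 0).
#' @param G pressure gradient -dp/dz (Pa/m, > 0).
#' @param mu_p plastic viscosity (Pa s).
#' @param tau_y yield stress (Pa, >= 0).
#' @return An object of class `casson_tube_flow` with plug radius `r_p`,
#'   velocity function `w(r)` (flat for `r <= r_p`), closed-form `Q`
#'   (m^3/s) and a `no_flow` flag (TRUE when `r_p >= R`, in which case
#'   `Q = 0`).
#' @export
casson_tube_flow <- function(R, G, mu_p, tau_y) {
  stopifnot(R > 0, G > 0, mu_p > 0, tau_y >= 0)
  r_p <- 2 * tau_y / G
  if (r_p >= R) {
    w <- function(r) rep(0, length(r))
    return(structure(list(R = R, G = G, mu_p = mu_p, tau_y = tau_y,
                          r_p = r_p, w = w, Q = 0, no_flow = TRUE),
                     class = "casson_tube_flow"))
  }
  # yielded-region profile, integrated from the wall inward
  w_yield <- function(r) {
    (1 / mu_p) * (G * (R^2 - r^2) / 4 + tau_y * (R - r) -
                    (2 / 3) * sqrt(2 * G * tau_y) * (R^1.5 - r^1.5))
  }
  w_plug <- w_yield(r_p)
  w <- function(r) {
    out <- numeric(length(r))
    yld <- r > r_p
    out[yld] <- w_yield(r[yld])
    out[!yld] <- w_plug
    out
  }
  xi <- r_p / R
  Q <- (pi * G * R^4 / (8 * mu_p)) *
    (1 - (16 / 7) * sqrt(xi) + (4 / 3) * xi - (1 / 21) * xi^4)
  structure(list(R = R, G = G, mu_p = mu_p, tau_y = tau_y, r_p = r_p,
                 w = w, Q = Q, no_flow = FALSE),
            class = "casson_tube_flow")
}
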