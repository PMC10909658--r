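# shared fixtures and run cache (heavy runs executed once per test session)

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

reference_geometry <- function() coronary_case(2.0)$geometry

annulus_geometry <- function() {
  channel_geometry(
    stenosis_spec(R_mm = 2, delta_star_mm = 0, a_mm = 4, b_mm = 2,
                  n = 2, L_mm = 10),
    catheter_spec(c = 0.25, delta_b_mm = 0))
}

# a snapshot assembled by hand from analytic fields
make_snapshot <- function(grid, w_of_r = function(r) 0 * r, u = NULL,
                          p = NULL, mu = 3.45e-3, t = 0) {
  w <- matrix(0, grid$Nz + 1, grid$Ns)
  for (i in seq_len(grid$Nz + 1)) w[i, ] <- w_of_r(grid$rw[i, ])
  structure(list(
    grid = grid,
    u = if (is.null(u)) matrix(0, grid$Nz, grid$Ns + 1) else u,
    w = w,
    p = if (is.null(p)) matrix(0, grid$Nz, grid$Ns) else p,
    mu = matrix(mu, grid$Nz, grid$Ns),
    gammadot = matrix(0, grid$Nz, grid$Ns),
    t = t), class = "flow_snapshot")
}

# pressure gradient G that drives flow rate Q through a Newtonian annulus
annulus_G_for_Q <- function(Q_si, R_i, R_o, mu) {
  Q_si / annular_poiseuille(R_i, R_o, 1, mu)$Q
}

# gap-averaged axial pressure gradient of a steady snapshot (Pa/m),
# fitted over the central portion of the segment
fitted_pressure_gradient <- function(snapshot, z_lo = 3, z_hi = 9) {
  pr <- pressure_drop(snapshot)$profile
  sel <- pr$z_mm > z_lo & pr$z_mm < z_hi
  -unname(stats::coef(stats::lm(p_Pa ~ z_mm, data = pr[sel, ]))[2]) * 1e3
}

# w interpolated to (z_mm, sigma) by bilinear interpolation on w-points
w_at <- function(snapshot, z_mm, sigma) {
  g <- snapshot$grid
  zf <- g$xf * 1e3
  i2 <- max(min(findInterval(z_mm, zf) + 1L, g$Nz + 1L), 2L)
  i1 <- i2 - 1L
  tz <- (z_mm - zf[i1]) / (zf[i2] - zf[i1])
  j2 <- max(min(findInterval(sigma, g$sc) + 1L, g$Ns), 2L)
  j1 <- j2 - 1L
  ts <- (sigma - g$sc[j1]) / (g$sc[j2] - g$sc[j1])
  (1 - tz) * ((1 - ts) * snapshot$w[i1, j1] + ts * snapshot$w[i1, j2]) +
    tz * ((1 - ts) * snapshot$w[i2, j1] + ts * snapshot$w[i2, j2])
}

# independent 1-D oracle: fully developed regularized-Casson flow in an
# annulus (no-slip at both radii) at pressure gradient G, by quadrature of
# the inverted constitutive law; used to validate the solver where the
# Buckingham-Reiner tube formula does not apply
casson_annulus_1d <- function(G, r_i, R, params, n = 20000) {
  mu_max <- (sqrt(params$mu_p) + sqrt(params$tau_y / params$gammadot_floor))^2
  tau_fl <- mu_max * params$gammadot_floor
  gdot <- function(tau) {
    ifelse(tau <= tau_fl, tau / mu_max,
           (sqrt(tau) - sqrt(params$tau_y))^2 / params$mu_p)
  }
  r <- seq(r_i, R, length.out = n)
  w_end <- function(C) {
    dwdr <- sign(-G * r / 2 + C / r) * gdot(abs(-G * r / 2 + C / r))
    sum((dwdr[-1] + dwdr[-n]) / 2 * diff(r))
  }
  C <- stats::uniroot(w_end, c(0, G * R^2), tol = 1e-16)$root
  dwdr <- sign(-G * r / 2 + C / r) * gdot(abs(-G * r / 2 + C / r))
  w <- cumsum(c(0, (dwdr[-1] + dwdr[-n]) / 2 * diff(r)))
  Q <- 2 * pi * sum(((w * r)[-1] + (w * r)[-n]) / 2 * diff(r))
  list(r = r, w = w, Q = Q, C = C)
}
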