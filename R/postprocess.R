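#' @export
print.flow_snapshot <- function(x, ...) {
  cat(sprintf("<flow_snapshot> t = %.4g s, grid %d x %d, max |w| = %.4g m/s\n",
              x$t, x$grid$Nz, x$grid$Ns, max(abs(x$w))))
  invisible(x)
}

#' Stokes stream function
#'
#' \eqn{\psi(z, \sigma) = \int_{\epsilon}^{r} w\,r'\,dr'} (m^3/s per
#' radian), accumulated by the trapezoidal-consistent midpoint rule on the
#' mapped grid from the inner wall, where \eqn{\psi = 0}. At the outer
#' wall \eqn{\psi = Q(z)/2\pi}. Contours of \eqn{\psi} are streamlines of
#' the axisymmetric velocity field.
#'
#' @param snapshot a `flow_snapshot`.
#' @return A matrix (`Nz + 1` z-faces by `Ns + 1` sigma-faces) of stream
#'   function values at the grid nodes.
#' @export
stream_function <- function(snapshot) {
  g <- snapshot$grid
  w <- snapshot$w
  psi <- matrix(0, g$Nz + 1, g$Ns + 1)
  for (j in seq_len(g$Ns)) {
    psi[, j + 1] <- psi[, j] + w[, j] * g$rw[, j] * g$h_f * g$ds[j]
  }
  psi
}

#' Volumetric flow rate along the segment
#'
#' \eqn{Q(z) = 2\pi \int w\,r\,dr} across the local gap. The quadrature
#' integrates the staggered finite-volume representation exactly (each
#' axial-velocity sample weighted by its annular cell area), which is the
#' trapezoidal rule applied to the stream function: `Q(z)` equals
#' \eqn{2\pi} times the outer-wall value of [stream_function()], so the
#' flow-rate audit, the streamlines and the solver's discrete continuity
#' equation are mutually consistent.
#'
#' @param snapshot a `flow_snapshot`.
#' @param z_mm optional axial positions (mm) at which to interpolate; by
#'   default the profile at every z-face is returned.
#' @return A tibble with `z_mm` and `Q_ml_s`.
#' @export
flow_rate <- function(snapshot, z_mm = NULL) {
  g <- snapshot$grid
  Q <- vapply(seq_len(g$Nz + 1), function(i) {
    2 * pi * sum(snapshot$w[i, ] * g$rw[i, ] * g$h_f[i] * g$ds) * 1e6
  }, numeric(1))
  prof <- tibble::tibble(z_mm = g$xf * 1e3, Q_ml_s = Q)
  if (is.null(z_mm)) return(prof)
  if (any(z_mm < 0 | z_mm > max(prof$z_mm)))
    stop("domain error: z outside the segment", call. = FALSE)
  tibble::tibble(z_mm = z_mm,
                 Q_ml_s = stats::approx(prof$z_mm, prof$Q_ml_s, z_mm)$y)
}

#' Wall shear stress profiles
#'
#' Signed wall shear stress on both walls:
#' \eqn{\tau_w = \mu_{eff}\,\partial v_t/\partial n} with the
#' wall-tangential velocity \eqn{v_t = (w + u\,r_z)/\sqrt{1 + r_z^2}},
#' the outward wall normal pointing into the fluid, and a one-sided
#' second-order (two-point quadratic) stencil. Positive values mean
#' forward-dragging flow on either wall. The wall viscosity is re-evaluated
#' from the wall shear rate when the snapshot carries rheology parameters,
#' otherwise taken from the wall-adjacent effective-viscosity samples.
#'
#' @param snapshot a `flow_snapshot` (needs at least 3 wall-normal points).
#' @return A tibble with `z_mm`, `tau_inner_Pa`, `tau_outer_Pa`.
#' @export
wall_shear_stress <- function(snapshot) {
  g <- snapshot$grid
  if (g$Ns < 3) stop("resolution error: need >= 3 wall-normal points", call. = FALSE)
  Nz <- g$Nz; Ns <- g$Ns
  # tangential velocity at the w-points nearest each wall
  u_at_w <- function(i, j) {
    il <- max(i - 1, 1); ir <- min(i, Nz)
    0.25 * (snapshot$u[il, j] + snapshot$u[il, j + 1] +
            snapshot$u[ir, j] + snapshot$u[ir, j + 1])
  }
  deta_f <- g$deps_f + g$dh_f
  tau_of <- function(side) {
    j1 <- if (side == "inner") 1L else Ns
    j2 <- if (side == "inner") 2L else Ns - 1L
    rz <- if (side == "inner") g$deps_f else deta_f
    vapply(seq_len(Nz + 1), function(i) {
      sec <- sqrt(1 + rz[i]^2)
      s1 <- if (side == "inner") g$sc[j1] else 1 - g$sc[j1]
      s2 <- if (side == "inner") g$sc[j2] else 1 - g$sc[j2]
      d1 <- s1 * g$h_f[i] / sec
      d2 <- s2 * g$h_f[i] / sec
      v1 <- (snapshot$w[i, j1] + u_at_w(i, j1) * rz[i]) / sec
      v2 <- (snapshot$w[i, j2] + u_at_w(i, j2) * rz[i]) / sec
      dvdn <- (v1 * d2^2 - v2 * d1^2) / (d1 * d2 * (d2 - d1))
      mu_w <- if (!is.null(snapshot$rheology)) {
        effective_viscosity(abs(dvdn), snapshot$rheology)
      } else {
        jj <- if (side == "inner") 1L else Ns
        snapshot$mu[min(max(i - 1, 1), Nz), jj]
      }
      mu_w * dvdn
    }, numeric(1))
  }
  tibble::tibble(z_mm = g$xf * 1e3,
                 tau_inner_Pa = if (isTRUE(g$axis)) NA_real_
                                else tau_of("inner"),
                 tau_outer_Pa = tau_of("outer"))
}

#' Pressure drop and axial mean-pressure profile
#'
#' Gap-averaged (area-weighted) pressure at each axial station, and the
#' inlet-to-outlet difference.
#'
#' @param snapshot a `flow_snapshot`.
#' @return A list: `dp_Pa` (inlet average minus outlet average) and
#'   `profile`, a tibble with `z_mm` and `p_Pa`.
#' @export
pressure_drop <- function(snapshot) {
  g <- snapshot$grid
  wgt <- g$rc * matrix(g$ds, g$Nz, g$Ns, byrow = TRUE)
  pavg <- rowSums(snapshot$p * wgt) / rowSums(wgt)
  list(dp_Pa = pavg[1] - pavg[g$Nz],
       profile = tibble::tibble(z_mm = g$xc * 1e3, p_Pa = pavg))
}

#' Detect recirculation zones
#'
#' Finds axial intervals where the axial velocity reverses sign
#' (\eqn{w < 0} beyond a small relative threshold) and quantifies each
#' zone's strength as the largest excursion of the stream function outside
#' its through-flow range \eqn{[0, Q/2\pi]} - a positive strength means a
#' closed streamline loop (in-plane recirculation) exists inside the zone.
#'
#' @param snapshot a `flow_snapshot`.
#' @param rel_tol reversal threshold relative to the peak axial velocity.
#' @param min_strength_rel zones whose stream-function excursion is below
#'   this fraction of the global stream-function scale are discarded:
#'   sub-0.1 percent excursions (the default cut) are corner ripples with
#'   no hemodynamic meaning, not recirculation zones.
#' @return A tibble with one row per zone: `z_start_mm`, `z_end_mm`,
#'   `strength_m3_s_rad`, `closed_streamlines`. Zero rows when the flow is
#'   unidirectional.
#' @export
detect_recirculation <- function(snapshot, rel_tol = 1e-6,
                                 min_strength_rel = 1e-3) {
  g <- snapshot$grid
  wmax <- max(abs(snapshot$w))
  if (wmax == 0) {
    return(tibble::tibble(z_start_mm = numeric(0), z_end_mm = numeric(0),
                          strength_m3_s_rad = numeric(0),
                          closed_streamlines = logical(0)))
  }
  empty <- tibble::tibble(z_start_mm = numeric(0), z_end_mm = numeric(0),
                          strength_m3_s_rad = numeric(0),
                          closed_streamlines = logical(0))
  rev_face <- apply(snapshot$w < -rel_tol * wmax, 1, any)
  runs <- rle(as.vector(rev_face))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  if (length(keep) == 0) return(empty)
  psi <- stream_function(snapshot)
  rows <- lapply(keep, function(k) {
    i1 <- starts[k]; i2 <- ends[k]
    sub <- psi[i1:i2, , drop = FALSE]
    lo <- pmin(0, sub[, g$Ns + 1])
    hi <- pmax(0, sub[, g$Ns + 1])
    excess <- pmax(sweep(sub, 1, hi, "-"), sweep(-sub, 1, -lo, "+"), 0)
    tibble::tibble(z_start_mm = g$xf[i1] * 1e3, z_end_mm = g$xf[i2] * 1e3,
                   strength_m3_s_rad = max(excess),
                   closed_streamlines = max(excess) > 0)
  })
  out <- do.call(rbind, rows)
  psi_scale <- max(abs(psi))
  out[out$strength_m3_s_rad >= min_strength_rel * psi_scale, , drop = FALSE]
}

#' Cell-centered field table of a snapshot
#'
#' Interpolates the staggered fields to cell centers and returns one row
#' per cell, ready for plotting or export.
#'
#' @param snapshot a `flow_snapshot`.
#' @return A tibble with `z_mm`, `r_mm`, `sigma`, `u`, `w`, `speed`,
#'   `p_Pa`, `mu_Pa_s`, `gammadot`.
#' @export
field_table <- function(snapshot) {
  g <- snapshot$grid
  w_c <- (snapshot$w[-(g$Nz + 1), ] + snapshot$w[-1, ]) / 2
  u_c <- (snapshot$u[, -(g$Ns + 1)] + snapshot$u[, -1]) / 2
  tibble::tibble(
    z_mm = rep(g$xc * 1e3, g$Ns),
    r_mm = as.vector(g$rc) * 1e3,
    sigma = rep(g$sc, each = g$Nz),
    u = as.vector(u_c),
    w = as.vector(w_c),
    speed = as.vector(sqrt(u_c^2 + w_c^2)),
    p_Pa = as.vector(snapshot$p),
    mu_Pa_s = as.vector(snapshot$mu),
    gammadot = as.vector(snapshot$gammadot)
  )
}

#' Location and value of the peak velocity magnitude
#'
#' @param snapshot a `flow_snapshot`.
#' @return A one-row tibble: `z_mm`, `r_mm`, `speed`.
#' @export
peak_velocity <- function(snapshot) {
  ft <- field_table(snapshot)
  ft[which.max(ft$speed), c("z_mm", "r_mm", "speed")]
}
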