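#' Stenosis (outer wall) specification
#'
#' Describes a single symmetric plaque bump on the arterial wall of an
#' otherwise uniform segment. The outer wall radius is
#' \deqn{\eta(z) = R\,[1 - \kappa\{b^{n-1}(z-a) - (z-a)^n\}]}
#' for \eqn{a \le z \le a+b} and \eqn{\eta(z) = R} elsewhere, where the
#' severity coefficient \eqn{\kappa} is chosen so that the minimum of
#' \eqn{\eta} equals \eqn{R - \delta^*} (see [stenosis_kappa()]).
#'
#' @param R_mm normal arterial radius (mm).
#' @param delta_star_mm maximum stenosis height \eqn{\delta^*} (mm),
#'   strictly between 0 and `R_mm` (0 allowed: no stenosis).
#' @param a_mm axial position where the stenosis starts (mm).
#' @param b_mm stenosis length (mm).
#' @param n shape factor (dimensionless, `n >= 2`); `n = 2` gives the
#'   symmetric member of the family.
#' @param L_mm length of the arterial segment (mm).
#' @return An object of class `stenosis_spec`.
#' @export
#' @examples
#' stenosis_spec(R_mm = 2, delta_star_mm = 0.82, a_mm = 4, b_mm = 2)
stenosis_spec <- function(R_mm = 2, delta_star_mm = 0.82, a_mm = 4, b_mm = 2,
                          n = 2, L_mm = 10) {
  spec <- list(R = R_mm, delta_star = delta_star_mm, a = a_mm, b = b_mm,
               n = n, L = L_mm)
  class(spec) <- "stenosis_spec"
  validate_stenosis_spec(spec)
  spec
}

validate_stenosis_spec <- function(spec) {
  with(spec, {
    if (!is.finite(R) || R <= 0) stop("geometry error: R_mm must be > 0", call. = FALSE)
    if (!is.finite(delta_star) || delta_star < 0 || delta_star >= R)
      stop("geometry error: delta_star_mm must satisfy 0 <= delta_star < R", call. = FALSE)
    if (!is.finite(b) || b <= 0) stop("geometry error: b_mm must be > 0", call. = FALSE)
    if (!is.finite(n) || n < 2) stop("geometry error: shape factor n must be >= 2", call. = FALSE)
    if (a < 0 || a + b > L)
      stop("geometry error: stenosis [a, a+b] must lie inside [0, L]", call. = FALSE)
  })
  invisible(spec)
}

#' Catheter and balloon (inner wall) specification
#'
#' The inner wall of the annular channel is a catheter of radius `c * R`
#' carrying a balloon bump co-located with the stenosis:
#' \deqn{\epsilon(z) = R\,[c + f_1(z)]}
#' on \eqn{[a, a+b]} and \eqn{\epsilon(z) = cR} elsewhere. The bump shape
#' \eqn{f_1} is a smooth symmetric profile that vanishes with zero slope at
#' both ends of the stenosis interval and peaks at its midpoint with height
#' `delta_b_mm`.
#'
#' @param c catheter-to-artery radius ratio (dimensionless,
#'   `0 <= c < 1`). The limiting value `c = 0` removes the catheter
#'   entirely: the inner boundary becomes the symmetry axis of an open
#'   tube (requires `delta_b_mm = 0`), which is how the tube-flow
#'   verification oracles are exercised.
#' @param delta_b_mm balloon height (mm, `>= 0`).
#' @param bump_profile `"sin2"` (default, \eqn{\sin^2}) or `"sin4"` (a
#'   sharper \eqn{\sin^4} alternative).
#' @return An object of class `catheter_spec`.
#' @export
catheter_spec <- function(c = 0.25, delta_b_mm = 0.53,
                          bump_profile = c("sin2", "sin4")) {
  bump_profile <- match.arg(bump_profile)
  spec <- list(c = c, delta_b = delta_b_mm, bump_profile = bump_profile)
  class(spec) <- "catheter_spec"
  if (!is.finite(c) || c < 0 || c >= 1)
    stop("geometry error: catheter ratio c must satisfy 0 <= c < 1", call. = FALSE)
  if (!is.finite(delta_b_mm) || delta_b_mm < 0)
    stop("geometry error: delta_b_mm must be >= 0", call. = FALSE)
  if (c == 0 && delta_b_mm > 0)
    stop("geometry error: a balloon (delta_b > 0) requires a catheter (c > 0)",
         call. = FALSE)
  spec
}

#' Stenosis severity coefficient
#'
#' Computes \eqn{\kappa = \delta^* n^{n/(n-1)} / (R\,b^n\,(n-1))}
#' (units mm^(1-n)), the unique coefficient for which the wall profile
#' attains its minimum \eqn{R - \delta^*} inside the stenosis interval.
#' The minimum sits at \eqn{z = a + b / n^{1/(n-1)}} (the midpoint when
#' `n = 2`).
#'
#' @param stenosis a [stenosis_spec()].
#' @return The severity coefficient (scalar).
#' @export
#' @examples
#' stenosis_kappa(stenosis_spec(R_mm = 2, delta_star_mm = 0.82, b_mm = 2, n = 2))
stenosis_kappa <- function(stenosis) {
  stopifnot(inherits(stenosis, "stenosis_spec"))
  validate_stenosis_spec(stenosis)
  with(stenosis, delta_star * n^(n / (n - 1)) / (R * b^n * (n - 1)))
}

#' Channel geometry: stenosed artery with balloon-tipped catheter
#'
#' Combines outer (arterial) and inner (catheter + balloon) wall
#' specifications, derives the severity coefficient, and validates that the
#' channel stays open (\eqn{\eta(z) > \epsilon(z)} for all z).
#'
#' @param stenosis a [stenosis_spec()].
#' @param catheter a [catheter_spec()].
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(stenosis = stenosis_spec(),
                             catheter = catheter_spec()) {
  stopifnot(inherits(stenosis, "stenosis_spec"), inherits(catheter, "catheter_spec"))
  validate_stenosis_spec(stenosis)
  geom <- list(stenosis = stenosis, catheter = catheter,
               kappa = stenosis_kappa(stenosis))
  class(geom) <- "channel_geometry"
  # positive throat: cR + delta_b < R - delta_star is necessary for co-located
  # bumps; the dense scan below is the authoritative check for any profile.
  z <- seq(0, stenosis$L, length.out = 4001)
  gap <- eta_wall(geom, z) - eps_wall(geom, z)
  if (any(gap <= 0)) {
    zbad <- z[which.min(gap)]
    stop(sprintf(
      "geometry error: channel closes (eta <= eps), gap %.4g mm at z = %.4g mm",
      min(gap), zbad), call. = FALSE)
  }
  geom
}

#' @export
print.channel_geometry <- function(x, ...) {
  tg <- throat_gap(x)
  cat("<channel_geometry>\n")
  cat(sprintf("  artery: R = %g mm, L = %g mm\n", x$stenosis$R, x$stenosis$L))
  cat(sprintf("  stenosis: delta* = %g mm over [%g, %g] mm, n = %g, kappa = %g\n",
              x$stenosis$delta_star, x$stenosis$a, x$stenosis$a + x$stenosis$b,
              x$stenosis$n, x$kappa))
  cat(sprintf("  catheter: radius %g mm, balloon height %g mm (%s bump)\n",
              x$catheter$c * x$stenosis$R, x$catheter$delta_b,
              x$catheter$bump_profile))
  cat(sprintf("  throat: gap %g mm at z = %g mm\n", tg$gap_mm, tg$z_mm))
  invisible(x)
}

check_z_domain <- function(z_mm, L) {
  if (any(!is.finite(z_mm)) || any(z_mm < 0) || any(z_mm > L))
    stop(sprintf("domain error: z must lie in [0, %g] mm", L), call. = FALSE)
}

#' Outer (arterial) wall radius
#'
#' Evaluates the stenosed outer wall \eqn{\eta(z)} (mm). Returns `R`
#' outside the stenosis interval and the polynomial bump profile inside;
#' continuous everywhere, bounded in \eqn{[R - \delta^*, R]}.
#'
#' @param geom a [channel_geometry()].
#' @param z_mm axial position(s) in mm, within `[0, L]`.
#' @return Outer wall radius (mm), vectorized over `z_mm`.
#' @export
eta_wall <- function(geom, z_mm) {
  stopifnot(inherits(geom, "channel_geometry"))
  st <- geom$stenosis
  check_z_domain(z_mm, st$L)
  eta <- rep(st$R, length(z_mm))
  inside <- z_mm >= st$a & z_mm <= st$a + st$b
  if (any(inside)) {
    zz <- z_mm[inside] - st$a
    eta[inside] <- st$R * (1 - geom$kappa * (st$b^(st$n - 1) * zz - zz^st$n))
  }
  eta
}

#' Axial slope of the outer wall
#'
#' Analytic derivative \eqn{d\eta/dz} (dimensionless), used for the
#' body-fitted grid metric terms.
#'
#' @inheritParams eta_wall
#' @return Wall slope, vectorized over `z_mm`.
#' @export
deta_wall <- function(geom, z_mm) {
  st <- geom$stenosis
  check_z_domain(z_mm, st$L)
  d <- rep(0, length(z_mm))
  inside <- z_mm >= st$a & z_mm <= st$a + st$b
  if (any(inside)) {
    zz <- z_mm[inside] - st$a
    d[inside] <- -st$R * geom$kappa * (st$b^(st$n - 1) - st$n * zz^(st$n - 1))
  }
  d
}

bump_f1 <- function(catheter, R, zz, b, deriv = FALSE) {
  # zz = z - a within [0, b]; returns f1 (dimensionless) or its z-derivative
  amp <- catheter$delta_b / R
  ph <- pi * zz / b
  if (catheter$bump_profile == "sin2") {
    if (deriv) amp * (pi / b) * sin(2 * ph) else amp * sin(ph)^2
  } else { # sin4
    if (deriv) amp * (4 * pi / b) * sin(ph)^3 * cos(ph) else amp * sin(ph)^4
  }
}

#' Inner (catheter + balloon) wall radius
#'
#' Evaluates \eqn{\epsilon(z)} (mm): the catheter radius `c * R` outside the
#' stenosis interval, plus the smooth balloon bump inside it, peaking at
#' `c * R + delta_b` mid-interval.
#'
#' @inheritParams eta_wall
#' @return Inner wall radius (mm), vectorized over `z_mm`.
#' @export
eps_wall <- function(geom, z_mm) {
  stopifnot(inherits(geom, "channel_geometry"))
  st <- geom$stenosis
  check_z_domain(z_mm, st$L)
  eps <- rep(geom$catheter$c * st$R, length(z_mm))
  inside <- z_mm >= st$a & z_mm <= st$a + st$b
  if (any(inside)) {
    eps[inside] <- st$R * (geom$catheter$c +
      bump_f1(geom$catheter, st$R, z_mm[inside] - st$a, st$b))
  }
  eps
}

#' Axial slope of the inner wall
#'
#' Analytic derivative \eqn{d\epsilon/dz} (dimensionless).
#'
#' @inheritParams eta_wall
#' @return Wall slope, vectorized over `z_mm`.
#' @export
deps_wall <- function(geom, z_mm) {
  st <- geom$stenosis
  check_z_domain(z_mm, st$L)
  d <- rep(0, length(z_mm))
  inside <- z_mm >= st$a & z_mm <= st$a + st$b
  if (any(inside)) {
    d[inside] <- st$R * bump_f1(geom$catheter, st$R, z_mm[inside] - st$a,
                                st$b, deriv = TRUE)
  }
  d
}

#' Throat gap: narrowest channel width and its location
#'
#' Minimizes \eqn{\eta(z) - \epsilon(z)} over the segment by dense scan
#' followed by local refinement.
#'
#' @param geom a [channel_geometry()].
#' @param n_scan number of scan points (default 4001).
#' @return A list with `gap_mm` and `z_mm`.
#' @export
throat_gap <- function(geom, n_scan = 4001) {
  st <- geom$stenosis
  z <- seq(0, st$L, length.out = n_scan)
  gap <- eta_wall(geom, z) - eps_wall(geom, z)
  k <- which.min(gap)
  lo <- z[max(1, k - 1)]; hi <- z[min(n_scan, k + 1)]
  if (hi > lo) {
    opt <- stats::optimize(function(zz) eta_wall(geom, zz) - eps_wall(geom, zz),
                           interval = c(lo, hi), tol = 1e-12)
    gmin <- opt$objective; zmin <- opt$minimum
    if (gap[k] < gmin) { gmin <- gap[k]; zmin <- z[k] }
  } else {
    gmin <- gap[k]; zmin <- z[k]
  }
  if (gmin <= 0)
    stop(sprintf("geometry error: non-positive throat gap at z = %.4g mm", zmin),
         call. = FALSE)
  list(gap_mm = gmin, z_mm = zmin)
}

#' Wall profile table
#'
#' Tabulates both wall radii and the local gap along the segment.
#'
#' @param geom a [channel_geometry()].
#' @param n number of axial sample points.
#' @return A tibble with columns `z_mm`, `eta_mm`, `eps_mm`, `gap_mm`.
#' @export
wall_profiles <- function(geom, n = 201) {
  z <- seq(0, geom$stenosis$L, length.out = n)
  eta <- eta_wall(geom, z)
  eps <- eps_wall(geom, z)
  tibble::tibble(z_mm = z, eta_mm = eta, eps_mm = eps, gap_mm = eta - eps)
}

#' Write wall profiles as CSV
#'
#' Header `z_mm,eta_mm,eps_mm,gap_mm`.
#'
#' @param geom a [channel_geometry()].
#' @param path output file path.
#' @param n number of axial sample points.
#' @return The path, invisibly.
#' @export
write_wall_profiles_csv <- function(geom, path, n = 201) {
  utils::write.csv(as.data.frame(wall_profiles(geom, n)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
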