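run_config_schema <- list(
  geometry = c("R_mm", "L_mm", "a_mm", "b_mm", "n", "delta_star_mm", "c",
               "delta_b_mm", "bump_profile"),
  rheology = c("mode", "mu_p", "tau_y", "rho", "gammadot_floor", "zeta", "m"),
  flow = c("Q_ml_s", "profile", "ramp_s"),
  numerics = c("Nz", "Nsigma", "courant_max", "dt_init_s", "t_end_s",
               "poisson_rel_tol", "max_outer_iters", "output_interval_s",
               "steady_tol", "stop_at_steady", "cluster"),
  top = c("scenario", "label", "seed", "output_dir", "log_level")
)

#' Serialize a scenario to a run-config list
#'
#' Inverse of [scenario_from_config()]: a nested list with `geometry`,
#' `rheology`, `flow` and `numerics` blocks using the unit-suffixed keys
#' of the config format.
#'
#' @param scenario a [flow_scenario()].
#' @return A named list.
#' @export
as_run_config <- function(scenario) {
  st <- scenario$geometry$stenosis
  ca <- scenario$geometry$catheter
  rh <- scenario$rheology
  fl <- scenario$inflow
  nu <- scenario$numerics
  list(
    label = scenario$label,
    geometry = list(R_mm = st$R, L_mm = st$L, a_mm = st$a, b_mm = st$b,
                    n = st$n, delta_star_mm = st$delta_star, c = ca$c,
                    delta_b_mm = ca$delta_b, bump_profile = ca$bump_profile),
    rheology = list(mode = rh$mode, mu_p = rh$mu_p, tau_y = rh$tau_y,
                    rho = rh$rho, gammadot_floor = rh$gammadot_floor,
                    zeta = rh$zeta, m = rh$m),
    flow = list(Q_ml_s = fl$Q_ml_s, profile = fl$profile,
                ramp_s = fl$ramp_s),
    numerics = list(Nz = nu$Nz, Nsigma = nu$Nsigma,
                    courant_max = nu$courant_max,
                    dt_init_s = nu$dt_init_s, t_end_s = nu$t_end_s,
                    poisson_rel_tol = nu$poisson_rel_tol,
                    max_outer_iters = nu$max_outer_iters,
                    output_interval_s = nu$output_interval_s,
                    steady_tol = nu$steady_tol,
                    stop_at_steady = nu$stop_at_steady,
                    cluster = nu$cluster)
  )
}

check_unknown_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("configuration error: unknown key%s %s in %s",
                 if (length(bad) > 1) "s" else "",
                 paste0(where, ".", bad, collapse = ", "), where),
         call. = FALSE)
}

num_key <- function(block, key, default, where, positive = FALSE) {
  v <- block[[key]]
  if (is.null(v)) v <- default
  if (!is.numeric(v) || !is.finite(v) || (positive && v <= 0))
    stop(sprintf("configuration error: %s.%s must be a %snumber",
                 where, key, if (positive) "positive " else ""),
         call. = FALSE)
  v
}

#' Build a scenario from a run-config list
#'
#' Validates the nested config (unknown keys rejected, physical values
#' checked, defaults filled) and assembles the corresponding
#' [flow_scenario()]. A top-level `scenario:` key
#' (`"coronary_case"`, `"straight_annulus"` or `"near_tube"`) selects a
#' canonical case whose fields individual blocks may then override.
#'
#' @param cfg a named list (e.g. from [parse_run_config()]).
#' @return A `flow_scenario`.
#' @export
scenario_from_config <- function(cfg) {
  check_unknown_keys(cfg, c(names(run_config_schema)[1:4],
                            run_config_schema$top), "config")
  for (blk in names(run_config_schema)[1:4])
    if (!is.null(cfg[[blk]]))
      check_unknown_keys(cfg[[blk]], run_config_schema[[blk]], blk)

  base <- NULL
  if (!is.null(cfg$scenario)) {
    q <- cfg$flow$Q_ml_s
    base <- switch(as.character(cfg$scenario),
      coronary_case = as_run_config(coronary_case(if (is.null(q)) 2.0 else q)),
      straight_annulus = as_run_config(straight_annulus_case(
        Q_ml_s = if (is.null(q)) 2.0 else q)),
      near_tube = as_run_config(near_tube_case(
        Q_ml_s = if (is.null(q)) 1.0 else q)),
      stop(sprintf("configuration error: unknown scenario '%s'",
                   cfg$scenario), call. = FALSE))
    for (blk in c("geometry", "rheology", "flow", "numerics"))
      cfg[[blk]] <- utils::modifyList(base[[blk]],
                                      if (is.null(cfg[[blk]])) list()
                                      else cfg[[blk]])
    if (is.null(cfg$label)) cfg$label <- base$label
  }

  g <- if (is.null(cfg$geometry)) list() else cfg$geometry
  geom <- channel_geometry(
    stenosis_spec(R_mm = num_key(g, "R_mm", 2, "geometry", TRUE),
                  delta_star_mm = num_key(g, "delta_star_mm", 0.82, "geometry"),
                  a_mm = num_key(g, "a_mm", 4, "geometry"),
                  b_mm = num_key(g, "b_mm", 2, "geometry", TRUE),
                  n = num_key(g, "n", 2, "geometry", TRUE),
                  L_mm = num_key(g, "L_mm", 10, "geometry", TRUE)),
    catheter_spec(c = num_key(g, "c", 0.25, "geometry", TRUE),
                  delta_b_mm = num_key(g, "delta_b_mm", 0.53, "geometry"),
                  bump_profile = if (is.null(g$bump_profile)) "sin2"
                                 else g$bump_profile))
  r <- if (is.null(cfg$rheology)) list() else cfg$rheology
  rheo <- casson_params(
    mu_p = num_key(r, "mu_p", 3.45e-3, "rheology", TRUE),
    tau_y = num_key(r, "tau_y", 5e-3, "rheology"),
    rho = num_key(r, "rho", 1050, "rheology", TRUE),
    gammadot_floor = num_key(r, "gammadot_floor", 1e-3, "rheology", TRUE),
    mode = if (is.null(r$mode)) "casson" else r$mode,
    zeta = num_key(r, "zeta", 1.38e-2, "rheology"),
    m = num_key(r, "m", 3.45e-3, "rheology"))
  f <- if (is.null(cfg$flow)) list() else cfg$flow
  infl <- inflow_spec(
    Q_ml_s = num_key(f, "Q_ml_s", 2.0, "flow", TRUE),
    profile = if (is.null(f$profile)) "annular_poiseuille_shape" else f$profile,
    ramp_s = num_key(f, "ramp_s", 0.1, "flow"))
  n <- if (is.null(cfg$numerics)) list() else cfg$numerics
  num <- solver_config(
    Nz = num_key(n, "Nz", 200, "numerics", TRUE),
    Nsigma = num_key(n, "Nsigma", 48, "numerics", TRUE),
    courant_max = num_key(n, "courant_max", 0.5, "numerics", TRUE),
    dt_init_s = num_key(n, "dt_init_s", 1e-3, "numerics", TRUE),
    t_end_s = num_key(n, "t_end_s", 10, "numerics", TRUE),
    poisson_rel_tol = num_key(n, "poisson_rel_tol", 1e-6, "numerics", TRUE),
    max_outer_iters = num_key(n, "max_outer_iters", 40, "numerics", TRUE),
    output_interval_s = num_key(n, "output_interval_s", 1, "numerics", TRUE),
    steady_tol = num_key(n, "steady_tol", 1e-3, "numerics", TRUE),
    stop_at_steady = if (is.null(n$stop_at_steady)) TRUE
                     else isTRUE(n$stop_at_steady),
    cluster = if (is.null(n$cluster)) TRUE else isTRUE(n$cluster))
  flow_scenario(geom, rheo, infl, num,
                label = if (is.null(cfg$label)) "config run" else cfg$label,
                seed = cfg$seed)
}

#' Parse a YAML run configuration
#'
#' @param path a YAML file with `geometry`, `rheology`, `flow` and
#'   `numerics` blocks (all optional; defaults are the reference case
#'   values) and optionally a top-level `scenario:` shorthand.
#' @return A validated `flow_scenario`.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("configuration error: no such file '%s'", path), call. = FALSE)
  scenario_from_config(yaml::read_yaml(path))
}

#' Write a scenario as a YAML run configuration
#'
#' @param scenario a [flow_scenario()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_run_config <- function(scenario, path) {
  yaml::write_yaml(as_run_config(scenario), path, precision = 17)
  invisible(path)
}

#' Write a snapshot as a legacy ASCII VTK structured grid
#'
#' One STRUCTURED_GRID dataset with points at the cell centers
#' (`Nsigma` varying fastest), coordinates (z, r, 0) in meters, and point
#' data: `velocity` (3 components: axial, radial, azimuthal = 0),
#' `pressure`, `viscosity`, `shear_rate` and `stream_function`.
#'
#' @param snapshot a `flow_snapshot`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_snapshot_vtk <- function(snapshot, path) {
  g <- snapshot$grid
  Nz <- g$Nz; Ns <- g$Ns
  w_c <- (snapshot$w[-(Nz + 1), ] + snapshot$w[-1, ]) / 2
  u_c <- (snapshot$u[, -(Ns + 1)] + snapshot$u[, -1]) / 2
  psi <- stream_function(snapshot)
  psi_c <- (psi[-(Nz + 1), -(Ns + 1)] + psi[-1, -(Ns + 1)] +
            psi[-(Nz + 1), -1] + psi[-1, -1]) / 4
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(x) format(x, digits = 10, scientific = TRUE, trim = TRUE)
  wl("# vtk DataFile Version 3.0")
  wl("stenoflow snapshot t = %.6g s (axes: x = z, y = r, z = theta)",
     snapshot$t)
  wl("ASCII")
  wl("DATASET STRUCTURED_GRID")
  wl("DIMENSIONS %d %d 1", Ns, Nz)
  wl("POINTS %d double", Ns * Nz)
  # sigma index varies fastest
  zz <- rep(g$xc, each = Ns)
  rr <- as.vector(t(g$rc))
  writeLines(paste(num(zz), num(rr), "0"), con)
  wl("POINT_DATA %d", Ns * Nz)
  wl("VECTORS velocity double")
  writeLines(paste(num(as.vector(t(w_c))), num(as.vector(t(u_c))), "0"), con)
  scalar <- function(name, m) {
    wl("SCALARS %s double 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(num(as.vector(t(m))), con)
  }
  scalar("pressure", snapshot$p)
  scalar("viscosity", snapshot$mu)
  scalar("shear_rate", snapshot$gammadot)
  scalar("stream_function", psi_c)
  invisible(path)
}

#' Read back a legacy ASCII VTK structured grid
#'
#' Minimal reader for the files produced by [write_snapshot_vtk()]
#' (and any conforming legacy STRUCTURED_GRID file with point data).
#'
#' @param path VTK file.
#' @return A list: `dims`, `points` (n x 3 matrix), `vectors` (named list
#'   of n x 3 matrices), `scalars` (named list of vectors).
#' @export
read_snapshot_vtk <- function(path) {
  lines <- readLines(path)
  splitnum <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  i_dim <- grep("^DIMENSIONS", lines)[1]
  dims <- splitnum(sub("DIMENSIONS", "", lines[i_dim]))
  i_pts <- grep("^POINTS", lines)[1]
  npts <- as.integer(strsplit(lines[i_pts], "\\s+")[[1]][2])
  pts <- matrix(unlist(lapply(lines[(i_pts + 1):(i_pts + npts)], splitnum)),
                ncol = 3, byrow = TRUE)
  vectors <- list(); scalars <- list()
  k <- i_pts + npts + 1
  while (k <= length(lines)) {
    ln <- lines[k]
    if (grepl("^VECTORS", ln)) {
      nm <- strsplit(ln, "\\s+")[[1]][2]
      vectors[[nm]] <- matrix(unlist(lapply(lines[(k + 1):(k + npts)],
                                            splitnum)),
                              ncol = 3, byrow = TRUE)
      k <- k + npts + 1
    } else if (grepl("^SCALARS", ln)) {
      nm <- strsplit(ln, "\\s+")[[1]][2]
      scalars[[nm]] <- unlist(lapply(lines[(k + 2):(k + 1 + npts)], splitnum))
      k <- k + npts + 2
    } else {
      k <- k + 1
    }
  }
  list(dims = dims, points = pts, vectors = vectors, scalars = scalars)
}

#' Write per-station CSV summaries
#'
#' One row per z-face with header
#' `z_mm,Q_ml_s,p_gap_avg_Pa,tau_w_inner_Pa,tau_w_outer_Pa`.
#'
#' @param snapshot a `flow_snapshot`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_station_csv <- function(snapshot, path) {
  g <- snapshot$grid
  q <- flow_rate(snapshot)
  pr <- pressure_drop(snapshot)$profile
  # interpolate gap-averaged pressure from centers to faces
  p_face <- stats::approx(pr$z_mm, pr$p_Pa, xout = q$z_mm, rule = 2)$y
  tw <- wall_shear_stress(snapshot)
  df <- data.frame(z_mm = q$z_mm, Q_ml_s = q$Q_ml_s, p_gap_avg_Pa = p_face,
                   tau_w_inner_Pa = tw$tau_inner_Pa,
                   tau_w_outer_Pa = tw$tau_outer_Pa)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
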