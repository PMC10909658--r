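#' Inflow specification
#'
#' Volumetric inflow prescribed at the inlet plane. The velocity profile
#' shape is either the annular Poiseuille shape for the local annulus
#' (default) or a plug; the shape is scaled at every step so the discrete
#' inlet flux \eqn{2\pi \int w\,r\,dr} matches the (ramped) target exactly.
#'
#' @param Q_ml_s target volumetric flow rate (ml/s, > 0).
#' @param profile `"annular_poiseuille_shape"` or `"plug"`.
#' @param ramp_s smooth-step ramp duration in seconds (0 = impulsive).
#' @return An object of class `inflow_spec`.
#' @export
inflow_spec <- function(Q_ml_s = 2.0,
                        profile = c("annular_poiseuille_shape", "plug"),
                        ramp_s = 0.1) {
  profile <- match.arg(profile)
  if (!is.finite(Q_ml_s) || Q_ml_s < 0)
    stop("configuration error: flow.Q_ml_s must be >= 0", call. = FALSE)
  if (ramp_s < 0) stop("configuration error: flow.ramp_s must be >= 0", call. = FALSE)
  structure(list(Q_ml_s = Q_ml_s, profile = profile, ramp_s = ramp_s),
            class = "inflow_spec")
}

#' Solver configuration
#'
#' Numerical parameters of the projection solver. The time step adapts so
#' that the per-cell Courant number `|w|*dt/dz + |u|*dt/dr` never exceeds
#' `courant_max` (0.5 by default), starting from `dt_init_s` (1e-3 s).
#' `poisson_rel_tol` controls the discrete-divergence target of the
#' pressure correction, relative to the characteristic divergence scale
#' (inlet mean velocity / throat gap). A run is flagged steady when the
#' relative change of the axial velocity field over one transit time drops
#' below `steady_tol`.
#'
#' @param Nz,Nsigma grid resolution (cells), see [build_grid()].
#' @param courant_max CFL bound, in (0, 1].
#' @param dt_init_s initial/maximum time step (s).
#' @param t_end_s simulated end time (s).
#' @param poisson_rel_tol relative divergence tolerance of the projection.
#' @param max_outer_iters maximum pressure-correction outer iterations per
#'   step.
#' @param output_interval_s snapshot interval (s).
#' @param steady_tol steady-state detection tolerance.
#' @param stop_at_steady stop the run once steady (default TRUE).
#' @param cluster enable grid clustering (default TRUE).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(Nz = 200, Nsigma = 48, courant_max = 0.5,
                          dt_init_s = 1e-3, t_end_s = 10,
                          poisson_rel_tol = 1e-6, max_outer_iters = 40,
                          output_interval_s = 1, steady_tol = 1e-3,
                          stop_at_steady = TRUE, cluster = TRUE) {
  if (!is.finite(courant_max) || courant_max <= 0 || courant_max > 1)
    stop("configuration error: numerics.courant_max must be in (0, 1]", call. = FALSE)
  for (nm in c("dt_init_s", "t_end_s", "poisson_rel_tol", "steady_tol")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0)
      stop(sprintf("configuration error: numerics.%s must be > 0", nm), call. = FALSE)
  }
  structure(list(Nz = as.integer(Nz), Nsigma = as.integer(Nsigma),
                 courant_max = courant_max, dt_init_s = dt_init_s,
                 t_end_s = t_end_s, poisson_rel_tol = poisson_rel_tol,
                 max_outer_iters = as.integer(max_outer_iters),
                 output_interval_s = output_interval_s,
                 steady_tol = steady_tol, stop_at_steady = stop_at_steady,
                 cluster = cluster),
            class = "solver_config")
}

#' Initialize a quiescent flow state
#'
#' @param grid a [build_grid()] result.
#' @param t initial time (s).
#' @return A `flow_state`: axial velocity `w` on z-faces, radial velocity
#'   `u` on sigma-faces, pressure `p` at cell centers (all SI), and time `t`.
#' @export
flow_state <- function(grid, t = 0) {
  structure(list(u = matrix(0, grid$Nz, grid$Ns + 1),
                 w = matrix(0, grid$Nz + 1, grid$Ns),
                 p = matrix(0, grid$Nz, grid$Ns),
                 t = t),
            class = "flow_state")
}

as_flow_state <- function(lst) {
  structure(lst[c("u", "w", "p", "t")], class = "flow_state")
}

# inlet shape vector + SI payload for the C++ core
inflow_payload <- function(inflow, grid) {
  Ns <- grid$Ns
  if (inflow$profile == "plug") {
    shape <- rep(1, Ns)
  } else if (isTRUE(grid$axis)) {
    # open tube: Hagen-Poiseuille shape
    shape <- pmax(1 - (grid$rw[1, ] / grid$eta_f[1])^2, 0)
  } else {
    Ri <- grid$eps_f[1]; Ro <- grid$eta_f[1]
    ann <- annular_poiseuille(Ri, Ro, G = 1, mu = 1)
    shape <- pmax(ann$w(grid$rw[1, ]), 0)
  }
  if (sum(shape * grid$rw[1, ] * grid$h_f[1] * grid$ds) <= 0)
    stop("configuration error: inflow profile incompatible with inlet gap",
         call. = FALSE)
  list(Q_si = inflow$Q_ml_s * 1e-6, ramp_s = inflow$ramp_s, shape = shape)
}

# characteristic scales used for tolerances and steady detection
flow_scales <- function(grid, inflow) {
  area <- pi * (grid$eta_f[1]^2 - grid$eps_f[1]^2)
  U_in <- max(inflow$Q_ml_s * 1e-6 / area, 1e-12)
  gap <- min(grid$h_f)
  L <- max(grid$xf)
  list(U_in = U_in, gap = gap, t_transit = L / U_in,
       div_ref = U_in / gap)
}

solver_cfg_payload <- function(config, grid, inflow, dt_prev = -1) {
  sc <- flow_scales(grid, inflow)
  list(courant_max = config$courant_max,
       dt_init = config$dt_init_s,
       t_end = config$t_end_s,
       div_tol_abs = config$poisson_rel_tol * sc$div_ref,
       max_outer_iters = config$max_outer_iters,
       output_interval = config$output_interval_s,
       steady_tol = config$steady_tol,
       stop_at_steady = config$stop_at_steady,
       t_transit = sc$t_transit,
       t_min_steady = inflow$ramp_s + 2 * sc$t_transit,
       steady_check_every = 200L,
       max_steps = 2e7,
       dt_prev = dt_prev)
}

#' Apply boundary conditions to a flow state
#'
#' Enforces no-slip on both walls, prescribes the inlet axial-velocity
#' profile scaled so the discrete inlet flux matches the ramped target flow
#' rate, and sets a zero-gradient outlet.
#'
#' @param state a [flow_state()].
#' @param grid a [build_grid()] result.
#' @param inflow an [inflow_spec()].
#' @param t time at which to evaluate the inflow ramp (defaults to the
#'   state's own time).
#' @return The updated `flow_state`.
#' @export
apply_boundary_conditions <- function(state, grid, inflow, t = state$t) {
  as_flow_state(cpp_apply_bcs(unclass(state), unclass(grid),
                              inflow_payload(inflow, grid), t))
}

#' Wall velocities of a state
#'
#' Velocity on the two walls after boundary application: the radial
#' component is stored on the wall faces; the axial wall value is the
#' no-slip boundary value used by every wall stencil (identically zero).
#'
#' @param state a [flow_state()].
#' @param grid the grid.
#' @return A list with `inner` and `outer` matrices (rows: z-faces,
#'   columns: u, w).
#' @export
wall_velocities <- function(state, grid) {
  nz <- grid$Nz
  list(inner = cbind(u = state$u[, 1], w = rep(0, nz)),
       outer = cbind(u = state$u[, grid$Ns + 1], w = rep(0, nz)))
}

#' CFL-limited time step
#'
#' \eqn{\Delta t = \min(dt_{init},\;
#' C_{max} / \max_{cells}(|w|/\Delta z + |u|/\Delta r))}.
#'
#' @param state a [flow_state()].
#' @param grid the grid.
#' @param config a [solver_config()].
#' @return Time step in seconds.
#' @export
cfl_timestep <- function(state, grid, config) {
  cpp_cfl_dt(unclass(state), unclass(grid), config$courant_max,
             config$dt_init_s)
}

#' Momentum predictor
#'
#' Advances the velocity field by one semi-implicit momentum step
#' (explicit advection and old-pressure gradient, implicit principal
#' diffusion in both grid directions) without enforcing continuity.
#'
#' @param state a [flow_state()].
#' @param grid the grid.
#' @param rheology a [casson_params()].
#' @param dt time step (s).
#' @return The provisional `flow_state`.
#' @export
momentum_predictor <- function(state, grid, rheology, dt) {
  as_flow_state(cpp_predict(unclass(state), unclass(grid),
                            unclass(rheology), dt))
}

#' Solver context (factored pressure operator)
#'
#' Factors the pressure-Poisson operator for a grid once so repeated
#' correction steps reuse the banded LU decomposition.
#'
#' @param grid a [build_grid()] result.
#' @return An opaque handle consumed by [pressure_correction()],
#'   [step_flow()] and [run_simulation()].
#' @export
solver_context <- function(grid) {
  structure(list(fac = cpp_poisson_factor(unclass(grid)), grid = grid),
            class = "solver_context")
}

#' Pressure correction (projection)
#'
#' Solves the variable-geometry pressure-Poisson problem and corrects the
#' provisional velocities so the discrete axisymmetric divergence vanishes
#' to tolerance; the pressure field is updated incrementally.
#'
#' @param state provisional [flow_state()].
#' @param grid the grid.
#' @param rheology a [casson_params()] (provides the density).
#' @param dt time step (s).
#' @param config a [solver_config()] (tolerances).
#' @param context optional [solver_context()] to reuse.
#' @param div_ref reference divergence scale (1/s); defaults to
#'   max(|w|)/throat gap of the supplied state.
#' @return A list: `state` (corrected), `div_linf` (1/s), `iters`,
#'   `history` (divergence after each outer iteration).
#' @export
pressure_correction <- function(state, grid, rheology, dt,
                                config = solver_config(), context = NULL,
                                div_ref = NULL) {
  if (is.null(context)) context <- solver_context(grid)
  if (is.null(div_ref)) {
    div_ref <- max(max(abs(state$w)), 1e-12) / min(grid$h_f)
  }
  out <- cpp_project(unclass(state), unclass(grid), context$fac,
                     rheology$rho, dt,
                     config$poisson_rel_tol * div_ref,
                     config$max_outer_iters)
  if (out$div_linf > 10 * config$poisson_rel_tol * div_ref)
    warning(sprintf(
      "pressure correction stagnated: residual divergence %.3g 1/s after %d iterations",
      out$div_linf, out$iters))
  list(state = as_flow_state(out$state), div_linf = out$div_linf,
       iters = out$iters, history = out$history)
}

#' Advance the flow by one time step
#'
#' One CFL-limited predictor/corrector cycle: boundary conditions at the
#' new time, semi-implicit momentum predictor, incremental pressure
#' projection.
#'
#' @inheritParams pressure_correction
#' @param inflow an [inflow_spec()].
#' @param dt_prev previous accepted step (s), used to limit step growth;
#'   -1 for the first step.
#' @return A list: `state` (at `t + dt`), `dt`, `courant` (max per-cell
#'   Courant number of the step), `div_linf`, `outer_iters`.
#' @export
step_flow <- function(state, grid, rheology, config, inflow,
                      context = NULL, dt_prev = -1) {
  if (is.null(context)) context <- solver_context(grid)
  cfg <- solver_cfg_payload(config, grid, inflow, dt_prev)
  out <- cpp_step(unclass(state), unclass(grid), context$fac,
                  unclass(rheology), inflow_payload(inflow, grid), cfg)
  out$state <- as_flow_state(out$state)
  out
}

#' Run a scenario to completion
#'
#' Builds the grid, factors the pressure operator, and integrates the flow
#' from rest with CFL-limited steps until `t_end_s`, steady state (if
#' `stop_at_steady`), or blowup. Snapshots are stored at the configured
#' output interval plus the final time.
#'
#' @param scenario a [flow_scenario()] (see also [coronary_case()]).
#' @param grid optional pre-built grid (otherwise built from the scenario
#'   numerics).
#' @return A `flow_run` object: `scenario`, `grid`, `snapshots` (list of
#'   `flow_snapshot`), and `summary` with `n_steps`, `t_final`,
#'   `max_courant`, `final_divergence_linf`, `q_conservation_rel_err`,
#'   `steady`, `snapshot_times`, `dt_history`, `outer_iters`.
#' @export
run_simulation <- function(scenario, grid = NULL) {
  stopifnot(inherits(scenario, "flow_scenario"))
  num <- scenario$numerics
  if (is.null(grid))
    grid <- build_grid(scenario$geometry, num$Nz, num$Nsigma,
                       cluster = num$cluster)
  ctx <- solver_context(grid)
  cfg <- solver_cfg_payload(num, grid, scenario$inflow)
  out <- cpp_run(unclass(grid), ctx$fac, unclass(scenario$rheology),
                 inflow_payload(scenario$inflow, grid), cfg)
  snaps <- lapply(out$snapshots, function(s) {
    s$grid <- grid
    class(s) <- "flow_snapshot"
    s
  })
  summ <- out$summary
  final <- snaps[[length(snaps)]]
  qprof <- flow_rate(final)
  q0 <- qprof$Q_ml_s[1]
  summ$q_conservation_rel_err <-
    if (abs(q0) > 0) max(abs(qprof$Q_ml_s - q0)) / abs(q0) else 0
  summ$dp_Pa <- pressure_drop(final)$dp_Pa
  structure(list(scenario = scenario, grid = grid, snapshots = snaps,
                 summary = summ),
            class = "flow_run")
}

#' @export
print.flow_run <- function(x, ...) {
  s <- x$summary
  cat("<flow_run>", x$scenario$label, "\n")
  cat(sprintf("  %d steps to t = %.4g s (%s)\n", as.integer(s$n_steps),
              s$t_final, if (isTRUE(s$steady)) "steady" else "not steady"))
  cat(sprintf("  max Courant %.3f | divergence %.3g 1/s | Q drift %.3g\n",
              s$max_courant, s$final_divergence_linf,
              s$q_conservation_rel_err))
  cat(sprintf("  pressure drop %.4g Pa\n", s$dp_Pa))
  invisible(x)
}

#' Final snapshot of a run
#'
#' @param run a `flow_run`.
#' @return The last `flow_snapshot`.
#' @export
final_snapshot <- function(run) {
  run$snapshots[[length(run$snapshots)]]
}

#' Write the run summary as JSON
#'
#' Records the conservation audit, Courant discipline, divergence norm and
#' step history of a run in a machine-readable form.
#'
#' @param run a `flow_run`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_run_summary <- function(run, path) {
  s <- run$summary
  out <- list(label = run$scenario$label,
              n_steps = s$n_steps,
              t_final = s$t_final,
              max_courant = s$max_courant,
              final_divergence_linf = s$final_divergence_linf,
              q_conservation_rel_err = s$q_conservation_rel_err,
              dp_Pa = s$dp_Pa,
              steady = s$steady,
              snapshot_times = s$snapshot_times)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
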