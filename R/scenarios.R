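#' Assemble a runnable scenario
#'
#' Bundles geometry, rheology, inflow and numerics into one validated,
#' self-contained case.
#'
#' @param geometry a [channel_geometry()].
#' @param rheology a [casson_params()].
#' @param inflow an [inflow_spec()].
#' @param numerics a [solver_config()].
#' @param label short description.
#' @param seed integer seed recorded for sweep bookkeeping (the solver
#'   itself is deterministic).
#' @return An object of class `flow_scenario`.
#' @export
flow_scenario <- function(geometry, rheology = casson_params(),
                          inflow = inflow_spec(),
                          numerics = solver_config(),
                          label = "scenario", seed = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(rheology, "casson_params"),
            inherits(inflow, "inflow_spec"),
            inherits(numerics, "solver_config"))
  throat_gap(geometry)  # re-validates the channel stays open
  structure(list(geometry = geometry, rheology = rheology, inflow = inflow,
                 numerics = numerics, label = label, seed = seed),
            class = "flow_scenario")
}

#' @export
print.flow_scenario <- function(x, ...) {
  cat("<flow_scenario>", x$label, "\n")
  cat(sprintf("  Q = %g ml/s (%s, ramp %g s) | rheology: %s\n",
              x$inflow$Q_ml_s, x$inflow$profile, x$inflow$ramp_s,
              x$rheology$mode))
  cat(sprintf("  grid %d x %d, t_end %g s\n", x$numerics$Nz,
              x$numerics$Nsigma, x$numerics$t_end_s))
  print(x$geometry)
  invisible(x)
}

#' The catheterized stenosed left-coronary reference case
#'
#' The single study case: artery radius 2 mm over a 10 mm segment, a
#' symmetric stenosis of length 2 mm and height 0.82 mm centered in the
#' segment (start a = 4 mm, shape factor n = 2), a 1 mm diameter catheter
#' (radius ratio c = 0.25) carrying a co-located balloon of height
#' 0.53 mm, and an inlet flow rate in the physiological range
#' 2.00-2.50 ml/s. The resulting throat gap is 0.15 mm at mid-stenosis.
#'
#' @param Q_ml_s inlet flow rate (ml/s); values outside [2.0, 2.5] are
#'   allowed with a warning.
#' @param rheology,numerics optional overrides of the blood-analog Casson
#'   defaults and solver configuration.
#' @return A `flow_scenario`.
#' @export
#' @examples
#' sc <- coronary_case(2.0)
#' throat_gap(sc$geometry)
coronary_case <- function(Q_ml_s = 2.0, rheology = casson_params(),
                          numerics = solver_config()) {
  if (Q_ml_s < 2.0 || Q_ml_s > 2.5)
    warning(sprintf(
      "flow rate %g ml/s is outside the reference range [2.0, 2.5] ml/s",
      Q_ml_s))
  geom <- channel_geometry(
    stenosis = stenosis_spec(R_mm = 2, delta_star_mm = 0.82, a_mm = 4,
                             b_mm = 2, n = 2, L_mm = 10),
    catheter = catheter_spec(c = 0.25, delta_b_mm = 0.53,
                             bump_profile = "sin2"))
  flow_scenario(geom, rheology, inflow_spec(Q_ml_s = Q_ml_s), numerics,
                label = sprintf("coronary stenosis + balloon, Q = %g ml/s",
                                Q_ml_s))
}

#' Straight annulus fixture (analytic-limit case)
#'
#' No stenosis, no balloon: a uniform annulus between the catheter and the
#' arterial wall. With `newtonian = TRUE` the yield stress is zeroed so the
#' steady solution is the closed-form annular Poiseuille flow - the
#' solver's Newtonian verification oracle.
#'
#' @param newtonian zero the yield stress (default TRUE).
#' @param Q_ml_s inlet flow rate (ml/s).
#' @param numerics a [solver_config()]; the default uses a modest uniform
#'   grid suited to the oracle comparison.
#' @return A `flow_scenario`.
#' @export
straight_annulus_case <- function(newtonian = TRUE, Q_ml_s = 2.0,
                                  numerics = solver_config(
                                    Nz = 48, Nsigma = 64, t_end_s = 10,
                                    cluster = FALSE)) {
  geom <- channel_geometry(
    stenosis = stenosis_spec(R_mm = 2, delta_star_mm = 0, a_mm = 4,
                             b_mm = 2, n = 2, L_mm = 10),
    catheter = catheter_spec(c = 0.25, delta_b_mm = 0))
  rheo <- if (newtonian) casson_params(tau_y = 0) else casson_params()
  flow_scenario(geom, rheo, inflow_spec(Q_ml_s = Q_ml_s), numerics,
                label = sprintf("straight annulus (%s), Q = %g ml/s",
                                if (newtonian) "Newtonian" else "Casson",
                                Q_ml_s))
}

#' Near-tube Casson fixture
#'
#' A hairline catheter (radius ratio c = 0.01) in an unstenosed artery:
#' the channel is a tube up to a thin wire on the axis, so the steady flow
#' rate at a given pressure gradient can be checked against the
#' Buckingham-Reiner Casson tube formula.
#'
#' @param Q_ml_s inlet flow rate (ml/s).
#' @param rheology a [casson_params()].
#' @param numerics a [solver_config()].
#' @return A `flow_scenario`.
#' @export
near_tube_case <- function(Q_ml_s = 1.0, rheology = casson_params(),
                           numerics = solver_config(
                             Nz = 48, Nsigma = 64, t_end_s = 10,
                             cluster = FALSE)) {
  geom <- channel_geometry(
    stenosis = stenosis_spec(R_mm = 2, delta_star_mm = 0, a_mm = 4,
                             b_mm = 2, n = 2, L_mm = 10),
    catheter = catheter_spec(c = 0.01, delta_b_mm = 0))
  flow_scenario(geom, rheology, inflow_spec(Q_ml_s = Q_ml_s), numerics,
                label = sprintf("near-tube Casson, Q = %g ml/s", Q_ml_s))
}

#' Open-tube Casson fixture
#'
#' No catheter at all (`c = 0`): the inner boundary is the symmetry axis,
#' so the channel is a plain circular tube and the steady Casson flow at a
#' measured pressure gradient can be compared directly with the
#' Buckingham-Reiner closed form (see [casson_tube_flow()]). The default
#' flow rate puts the plug radius near 10 percent of the tube radius,
#' where the yield-stress correction to the Newtonian flow rate is large
#' (about a factor 0.4).
#'
#' @param Q_ml_s inlet flow rate (ml/s).
#' @param rheology a [casson_params()].
#' @param numerics a [solver_config()].
#' @return A `flow_scenario`.
#' @export
tube_case <- function(Q_ml_s = 0.037, rheology = casson_params(),
                      numerics = solver_config(
                        Nz = 48, Nsigma = 64, t_end_s = 0.8,
                        stop_at_steady = FALSE, cluster = FALSE)) {
  geom <- channel_geometry(
    stenosis = stenosis_spec(R_mm = 2, delta_star_mm = 0, a_mm = 4,
                             b_mm = 2, n = 2, L_mm = 10),
    catheter = catheter_spec(c = 0, delta_b_mm = 0))
  flow_scenario(geom, rheology, inflow_spec(Q_ml_s = Q_ml_s), numerics,
                label = sprintf("open tube Casson, Q = %g ml/s", Q_ml_s))
}

#' Latin-hypercube scenario sweep
#'
#' Stratified sampling over stenosis height, balloon height and flow rate,
#' reproducible for a given seed. Every emitted scenario is validated
#' (positive throat gap); infeasible draws are rejected and redrawn, and
#' an entirely infeasible range is an error.
#'
#' @param delta_star_range,delta_b_range ranges in mm (length-2 vectors).
#' @param Q_range flow-rate range in ml/s.
#' @param n_samples number of scenarios.
#' @param seed integer RNG seed.
#' @param numerics a [solver_config()] shared by all samples.
#' @return A list of `flow_scenario` objects.
#' @export
scenario_sweep <- function(delta_star_range = c(0.4, 0.9),
                           delta_b_range = c(0.2, 0.6),
                           Q_range = c(2.0, 2.5),
                           n_samples = 5, seed = 1,
                           numerics = solver_config()) {
  rng <- function(r) sort(as.numeric(r))
  dsr <- rng(delta_star_range); dbr <- rng(delta_b_range); qr <- rng(Q_range)
  R <- 2; cc <- 0.25
  if (cc * R + dbr[1] >= R - dsr[1])
    stop(paste0("configuration error: infeasible sweep ranges ",
                "(throat gap closes for every sample)"), call. = FALSE)
  make_one <- function(ds, db, q) {
    geom <- tryCatch(
      channel_geometry(
        stenosis_spec(R_mm = R, delta_star_mm = ds, a_mm = 4, b_mm = 2,
                      n = 2, L_mm = 10),
        catheter_spec(c = cc, delta_b_mm = db)),
      error = function(e) NULL)
    if (is.null(geom)) return(NULL)
    flow_scenario(geom, casson_params(), inflow_spec(Q_ml_s = q), numerics,
                  label = sprintf(
                    "sweep: delta* = %.3g mm, delta_b = %.3g mm, Q = %.3g ml/s",
                    ds, db, q),
                  seed = seed)
  }
  out <- vector("list", n_samples)
  set.seed(seed)
  n_have <- 0L
  tries <- 0L
  while (n_have < n_samples && tries < 50L) {
    u <- lhs::randomLHS(n_samples, 3)
    for (k in seq_len(nrow(u))) {
      if (n_have >= n_samples) break
      sc <- make_one(dsr[1] + u[k, 1] * diff(dsr),
                     dbr[1] + u[k, 2] * diff(dbr),
                     qr[1] + u[k, 3] * diff(qr))
      if (!is.null(sc)) {
        n_have <- n_have + 1L
        out[[n_have]] <- sc
      }
    }
    tries <- tries + 1L
  }
  if (n_have < n_samples)
    stop("configuration error: could not draw enough feasible scenarios",
         call. = FALSE)
  out
}
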