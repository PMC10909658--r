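#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flow run: one row per snapshot
#'
#' @param x a `flow_run`.
#' @param ... unused.
#' @return A tibble with `t_s`, `Q_in_ml_s`, `Q_out_ml_s`, `dp_Pa`,
#'   `peak_speed_m_s` and `n_recirculation_zones`.
#' @export
tidy.flow_run <- function(x, ...) {
  rows <- lapply(x$snapshots, function(s) {
    q <- flow_rate(s)
    tibble::tibble(t_s = s$t,
                   Q_in_ml_s = q$Q_ml_s[1],
                   Q_out_ml_s = q$Q_ml_s[nrow(q)],
                   dp_Pa = pressure_drop(s)$dp_Pa,
                   peak_speed_m_s = peak_velocity(s)$speed,
                   n_recirculation_zones = nrow(detect_recirculation(s)))
  })
  do.call(rbind, rows)
}

#' One-row summary of a flow run
#'
#' @param x a `flow_run`.
#' @param ... unused.
#' @return A one-row tibble with the run audit: steps, final time, steady
#'   flag, maximum Courant number, final divergence norm, flow-rate
#'   conservation error and pressure drop.
#' @export
glance.flow_run <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_steps = as.integer(s$n_steps),
                 t_final_s = s$t_final,
                 steady = isTRUE(s$steady),
                 max_courant = s$max_courant,
                 final_divergence_linf = s$final_divergence_linf,
                 q_conservation_rel_err = s$q_conservation_rel_err,
                 dp_Pa = s$dp_Pa)
}

#' Field heat map of a snapshot
#'
#' Renders one cell-centered field over the physical (z, r) domain; the
#' tile heights follow the local gap so the stenosis and balloon shapes
#' are visible.
#'
#' @param object a `flow_snapshot`.
#' @param field one of `"speed"`, `"pressure"`, `"w"`, `"u"`,
#'   `"viscosity"`, `"shear_rate"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.flow_snapshot <- function(object,
                                   field = c("speed", "pressure", "w", "u",
                                             "viscosity", "shear_rate"),
                                   ...) {
  field <- match.arg(field)
  g <- object$grid
  ft <- field_table(object)
  ft$width_mm <- rep(g$dx * 1e3, g$Ns)
  ft$height_mm <- as.vector(outer(g$h_c, g$ds)) * 1e3
  col <- switch(field, speed = "speed", pressure = "p_Pa", w = "w", u = "u",
                viscosity = "mu_Pa_s", shear_rate = "gammadot")
  lab <- switch(field, speed = "|v| (m/s)", pressure = "p (Pa)",
                w = "w (m/s)", u = "u (m/s)", viscosity = "mu_eff (Pa s)",
                shear_rate = "shear rate (1/s)")
  ggplot2::ggplot(ft, ggplot2::aes(.data$z_mm, .data$r_mm)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[col]],
                                    width = .data$width_mm,
                                    height = .data$height_mm)) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (mm)", y = "r (mm)",
                  title = sprintf("t = %.3g s", object$t)) +
    ggplot2::theme_minimal()
}

#' Time-history plot of a run
#'
#' Inlet/outlet flow rate and pressure drop against snapshot time.
#'
#' @param object a `flow_run`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.flow_run <- function(object, ...) {
  td <- tidy(object)
  long <- rbind(
    data.frame(t_s = td$t_s, value = td$Q_in_ml_s, what = "Q inlet (ml/s)"),
    data.frame(t_s = td$t_s, value = td$Q_out_ml_s, what = "Q outlet (ml/s)"),
    data.frame(t_s = td$t_s, value = td$dp_Pa, what = "pressure drop (Pa)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "t (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Wall profile plot
#'
#' Outer (arterial) and inner (catheter + balloon) wall radii along the
#' segment.
#'
#' @param geom a [channel_geometry()].
#' @param n number of axial samples.
#' @return A ggplot object.
#' @export
plot_walls <- function(geom, n = 401) {
  wp <- wall_profiles(geom, n)
  long <- rbind(
    data.frame(z_mm = wp$z_mm, r_mm = wp$eta_mm, wall = "arterial wall"),
    data.frame(z_mm = wp$z_mm, r_mm = wp$eps_mm, wall = "catheter + balloon"))
  ggplot2::ggplot(long, ggplot2::aes(.data$z_mm, .data$r_mm,
                                     linetype = .data$wall)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (mm)", y = "r (mm)") +
    ggplot2::theme_minimal()
}
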