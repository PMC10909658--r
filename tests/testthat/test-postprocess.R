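test_that("stream function: zero flow, closed form, outer-wall value", {
  g <- build_grid(annulus_geometry(), 16, 24, cluster = FALSE)

  psi0 <- stream_function(make_snapshot(g))
  expect_equal(max(abs(psi0)), 0)

  # uniform w over a straight annulus: psi(r) = w (r^2 - R_i^2) / 2
  w0 <- 0.3
  snap <- make_snapshot(g, w_of_r = function(r) rep(w0, length(r)))
  psi <- stream_function(snap)
  for (i in c(1, 8, 17)) {
    expect_equal(psi[i, ], w0 * (g$rcorn[i, ]^2 - g$eps_f[i]^2) / 2,
                 tolerance = 1e-4)
  }
  expect_equal(psi[, 1], rep(0, g$Nz + 1))

  # outer-wall value equals Q / (2 pi) at every z, consistent with flow_rate
  q <- flow_rate(snap)
  expect_equal(psi[, g$Ns + 1], q$Q_ml_s * 1e-6 / (2 * pi),
               tolerance = 1e-12)
})

test_that("wall shear stress matches the annular Poiseuille gradient", {
  tau_err <- function(Ns) {
    g <- build_grid(annulus_geometry(), 16, Ns, cluster = FALSE)
    mu <- 3.45e-3
    G <- annulus_G_for_Q(2e-6, g$eps_f[1], g$eta_f[1], mu)
    ann <- annular_poiseuille(g$eps_f[1], g$eta_f[1], G, mu)
    snap <- make_snapshot(g, w_of_r = ann$w, mu = mu)
    tw <- wall_shear_stress(snap)
    c(abs(tw$tau_inner_Pa[8] - ann$tau(ann$R_i)) / abs(ann$tau(ann$R_i)),
      abs(tw$tau_outer_Pa[8] - (-ann$tau(ann$R_o))) / abs(ann$tau(ann$R_o)))
  }
  e32 <- tau_err(32)
  expect_lt(max(e32), 0.02)
  # refining the wall-normal grid shrinks the error order-consistently
  e64 <- tau_err(64)
  expect_lt(max(e64), max(e32) / 2)

  g <- build_grid(annulus_geometry(), 16, 24, cluster = FALSE)
  tw0 <- wall_shear_stress(make_snapshot(g))
  expect_equal(max(abs(tw0$tau_inner_Pa)), 0)
  expect_equal(max(abs(tw0$tau_outer_Pa)), 0)
})

test_that("pressure drop: zero flow and Poiseuille gradient", {
  g <- build_grid(annulus_geometry(), 24, 16, cluster = FALSE)
  expect_equal(pressure_drop(make_snapshot(g))$dp_Pa, 0)

  mu <- 3.45e-3
  G <- annulus_G_for_Q(2e-6, g$eps_f[1], g$eta_f[1], mu)
  p <- matrix(rep(G * (max(g$xf) - g$xc), g$Ns), g$Nz, g$Ns)
  pd <- pressure_drop(make_snapshot(g, p = p))
  expect_equal(pd$dp_Pa, G * (g$xc[g$Nz] - g$xc[1]), tolerance = 1e-10)
  expect_named(pd$profile, c("z_mm", "p_Pa"))
})

test_that("flow rate: constant profile closed form and interpolation", {
  g <- build_grid(annulus_geometry(), 16, 24, cluster = FALSE)
  w0 <- 0.25
  snap <- make_snapshot(g, w_of_r = function(r) rep(w0, length(r)))
  q <- flow_rate(snap)
  q_exact <- w0 * pi * (g$eta_f[1]^2 - g$eps_f[1]^2) * 1e6
  expect_equal(q$Q_ml_s, rep(q_exact, g$Nz + 1), tolerance = 1e-12)
  qi <- flow_rate(snap, z_mm = c(2.5, 7.5))
  expect_equal(qi$Q_ml_s, rep(q_exact, 2), tolerance = 1e-12)
  expect_error(flow_rate(snap, z_mm = 11), "domain")
})

test_that("recirculation detection: unidirectional, inserted blob, zones", {
  g <- build_grid(annulus_geometry(), 48, 24, cluster = FALSE)
  mu <- 3.45e-3
  G <- annulus_G_for_Q(2e-6, g$eps_f[1], g$eta_f[1], mu)
  ann <- annular_poiseuille(g$eps_f[1], g$eta_f[1], G, mu)
  base <- make_snapshot(g, w_of_r = ann$w, mu = mu)
  expect_equal(nrow(detect_recirculation(base)), 0)

  # insert a counter-rotating blob near the outer wall over z in [6, 8] mm
  blob <- base
  zf <- g$xf * 1e3
  for (i in seq_len(g$Nz + 1)) {
    bz <- exp(-((zf[i] - 7) / 0.5)^2)
    bs <- exp(-((g$sc - 0.8) / 0.12)^2)
    blob$w[i, ] <- blob$w[i, ] - 2.5 * max(ann$w(g$rw[i, ])) * bz * bs
  }
  zones <- detect_recirculation(blob)
  expect_equal(nrow(zones), 1)
  expect_gt(zones$z_start_mm, 5.5)
  expect_lt(zones$z_end_mm, 8.5)
  expect_true(zones$closed_streamlines)
  expect_gt(zones$strength_m3_s_rad, 0)

  # quiescent field: empty result with the documented columns
  empty <- detect_recirculation(make_snapshot(g))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("z_start_mm", "z_end_mm", "strength_m3_s_rad",
                        "closed_streamlines"))
})

test_that("field table and peak velocity locate the constriction jet", {
  run <- cached_run("coronary_tiny", {
    run_simulation(coronary_case(2.0, numerics = solver_config(
      Nz = 60, Nsigma = 16, t_end_s = 0.05, stop_at_steady = FALSE)))
  })
  snap <- final_snapshot(run)
  ft <- field_table(snap)
  expect_equal(nrow(ft), snap$grid$Nz * snap$grid$Ns)
  expect_true(all(is.finite(ft$speed)))
  pv <- peak_velocity(snap)
  expect_gte(pv$z_mm, 4)
  expect_lte(pv$z_mm, 6.5)
})
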