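test_that("boundary conditions: inlet flux, walls, zero inflow", {
  g <- build_grid(annulus_geometry(), 24, 16, cluster = FALSE)
  infl <- inflow_spec(Q_ml_s = 2.0, ramp_s = 0)
  st <- apply_boundary_conditions(flow_state(g), g, infl, t = 1)

  # discrete inlet flux matches the target exactly
  q_in <- 2 * pi * sum(st$w[1, ] * g$rw[1, ] * g$h_f[1] * g$ds) * 1e6
  expect_equal(q_in, 2.0, tolerance = 1e-10)

  wv <- wall_velocities(st, g)
  expect_equal(max(abs(wv$inner)), 0)
  expect_equal(max(abs(wv$outer)), 0)

  # zero target -> identically zero inlet profile
  st0 <- apply_boundary_conditions(flow_state(g), g,
                                   inflow_spec(Q_ml_s = 0, ramp_s = 0), t = 1)
  expect_equal(max(abs(st0$w[1, ])), 0)

  # smooth ramp: flux at half the ramp time is half the target
  str <- apply_boundary_conditions(flow_state(g), g,
                                   inflow_spec(Q_ml_s = 2, ramp_s = 0.1),
                                   t = 0.05)
  q_half <- 2 * pi * sum(str$w[1, ] * g$rw[1, ] * g$h_f[1] * g$ds) * 1e6
  expect_equal(q_half, 1.0, tolerance = 1e-10)
})

test_that("CFL time step honors the Courant bound", {
  g <- build_grid(annulus_geometry(), 24, 16, cluster = FALSE)
  cfg <- solver_config(Nz = 24, Nsigma = 16, courant_max = 0.5,
                       dt_init_s = 1e-3)
  st <- flow_state(g)
  expect_equal(cfl_timestep(st, g, cfg), 1e-3)   # quiescent: dt_init

  # uniform w such that w dt_init / dz = 1 per cell -> dt = 0.5 dz / w
  dz <- g$dx[1]
  st$w[] <- dz / 1e-3
  expect_equal(cfl_timestep(st, g, cfg), 0.5e-3, tolerance = 1e-12)

  # random velocity field: recomputed Courant at the returned dt <= bound
  set.seed(11)
  st$w[] <- stats::rnorm(length(st$w))
  st$u[] <- 0.1 * stats::rnorm(length(st$u))
  dt <- cfl_timestep(st, g, cfg)
  expect_lte(stenoflow:::cpp_courant_of(unclass(st), unclass(g), dt),
             0.5 + 1e-12)
})

test_that("momentum operators vanish on quiescent and exact steady fields", {
  g <- build_grid(annulus_geometry(), 24, 24, cluster = FALSE)
  rheo <- casson_params(tau_y = 0)

  # quiescent, no inflow: predictor is a fixed point
  st <- flow_state(g)
  pred <- momentum_predictor(st, g, rheo, dt = 1e-3)
  expect_equal(max(abs(pred$w)), 0)
  expect_equal(max(abs(pred$u)), 0)

  # exact annular Poiseuille + its driving pressure: discrete momentum
  # residual is small and shrinks at second order under refinement
  res_for <- function(Ns) {
    gg <- build_grid(annulus_geometry(), 24, Ns, cluster = FALSE)
    G <- annulus_G_for_Q(2e-6, gg$eps_f[1], gg$eta_f[1], rheo$mu_p)
    ann <- annular_poiseuille(gg$eps_f[1], gg$eta_f[1], G, rheo$mu_p)
    ss <- make_snapshot(gg, w_of_r = ann$w,
                        p = matrix(rep(G * (max(gg$xf) - gg$xc), gg$Ns),
                                   gg$Nz, gg$Ns))
    rhs <- stenoflow:::cpp_momentum_rhs(unclass(ss), unclass(gg),
                                        unclass(rheo))
    scale <- G / rheo$rho  # size of the pressure/viscous balance terms
    # fixed interior band: wall rows carry the one-sided closure error
    band <- which(gg$sc > 0.2 & gg$sc < 0.8)
    max(abs(rhs$rhs_w[2:gg$Nz, band])) / scale
  }
  r16 <- res_for(16); r32 <- res_for(32); r64 <- res_for(64)
  expect_lt(r64, 0.01)
  expect_gt(r16 / r32, 3)
  expect_gt(r32 / r64, 3)
})

test_that("divergence operator is second-order accurate on the mapped grid", {
  # wall-conforming Stokes stream function psi(z, sigma): the derived
  # velocity field is exactly solenoidal with zero wall-normal flux, so
  # the discrete curvilinear divergence (including the slope-induced
  # cross-flux terms) must vanish at the discretization order
  geom <- reference_geometry()
  L <- 0.01
  psi_z <- function(z, s) (pi / L) * cos(pi * z / L) * sin(pi * s)^2 * 1e-6
  psi_s <- function(z, s) sin(pi * z / L) * pi * sin(2 * pi * s) * 1e-6
  div_for <- function(N) {
    g <- build_grid(geom, 2 * N, N, cluster = TRUE)
    st <- flow_state(g)
    for (i in seq_len(g$Nz + 1))   # w = (1/(r h)) dpsi/ds at w-points
      st$w[i, ] <- psi_s(g$xf[i], g$sc) / (g$rw[i, ] * g$h_f[i])
    for (i in seq_len(g$Nz))       # u = -(1/r)(dpsi/dz - (r_z/h) dpsi/ds)
      st$u[i, ] <- -(psi_z(g$xc[i], g$sf) -
                       (g$rzu[i, ] / g$h_c[i]) * psi_s(g$xc[i], g$sf)) /
                    g$ru[i, ]
    out <- stenoflow:::cpp_div_field(unclass(st), unclass(g))
    # relative to the velocity-gradient scale of the field
    out$div_linf / (max(abs(st$w)) * pi / L)
  }
  # the normalization is a rough field scale (the sharp throat dominates
  # max |w|); the convergence ratios carry the order claim
  d12 <- div_for(12); d24 <- div_for(24); d48 <- div_for(48)
  expect_lt(d48, 0.3)
  expect_gt(d12 / d24, 2.5)
  expect_gt(d24 / d48, 2.5)
})

test_that("pressure correction drives the discrete divergence to tolerance", {
  g <- build_grid(annulus_geometry(), 24, 16, cluster = FALSE)
  rheo <- casson_params(tau_y = 0)
  cfg <- solver_config(Nz = 24, Nsigma = 16, poisson_rel_tol = 1e-10,
                       max_outer_iters = 10)
  infl <- inflow_spec(Q_ml_s = 2, ramp_s = 0)

  # axially modulated inflow profile: strongly divergent start field
  st <- apply_boundary_conditions(flow_state(g), g, infl, t = 1)
  mod <- 1 + 0.3 * sin(2 * pi * g$xf / max(g$xf))
  st$w[] <- st$w[rep(1, nrow(st$w)), ] * mod
  before <- stenoflow:::cpp_div_field(unclass(st), unclass(g))$div_linf
  expect_gt(before, 0)
  ref <- max(abs(st$w)) / min(g$h_f)
  out <- pressure_correction(st, g, rheo, dt = 1e-4, config = cfg,
                             div_ref = ref)
  expect_lt(out$div_linf, 1e-8 * ref)
  expect_lte(out$iters, 3)

  # an already divergence-free field is (numerically) untouched
  out2 <- pressure_correction(out$state, g, rheo, dt = 1e-4, config = cfg,
                              div_ref = ref)
  expect_equal(out2$state$w, out$state$w, tolerance = 1e-9)
  expect_equal(out2$iters, 0)
})

test_that("a zero-inflow state is a fixed point of the full step", {
  g <- build_grid(reference_geometry(), 32, 12)
  rheo <- casson_params()
  cfg <- solver_config(Nz = 32, Nsigma = 12)
  infl <- inflow_spec(Q_ml_s = 0, ramp_s = 0)
  ctx <- solver_context(g)
  out <- step_flow(flow_state(g), g, rheo, cfg, infl, context = ctx)
  expect_equal(max(abs(out$state$w)), 0)
  expect_equal(max(abs(out$state$u)), 0)
  expect_equal(out$dt, cfg$dt_init_s)
})

test_that("one step from rest keeps the Courant bound and conserves mass", {
  sc <- coronary_case(2.0, numerics = solver_config(Nz = 48, Nsigma = 16))
  g <- build_grid(sc$geometry, 48, 16)
  ctx <- solver_context(g)
  st <- flow_state(g)
  dt_prev <- -1
  for (k in 1:25) {
    out <- step_flow(st, g, sc$rheology, sc$numerics, sc$inflow,
                     context = ctx, dt_prev = dt_prev)
    st <- out$state
    dt_prev <- out$dt
    expect_lte(out$courant, 0.5 + 1e-12)
  }
  # flux uniform along z after the corrector (relative to inlet flux)
  snap <- structure(c(unclass(st), list(grid = g)), class = "flow_snapshot")
  q <- flow_rate(snap)
  expect_lt(max(abs(q$Q_ml_s - q$Q_ml_s[1])) / max(q$Q_ml_s[1], 1e-12),
            1e-3)
})

test_that("Newtonian annulus run converges to the closed-form solution", {
  run <- cached_run("annulus_32", {
    run_simulation(straight_annulus_case(
      newtonian = TRUE, Q_ml_s = 2.0,
      numerics = solver_config(Nz = 32, Nsigma = 32, t_end_s = 5,
                               cluster = FALSE)))
  })
  expect_true(run$summary$steady)
  snap <- final_snapshot(run)
  g <- run$grid
  G <- annulus_G_for_Q(2e-6, g$eps_f[1], g$eta_f[1], 3.45e-3)
  ann <- annular_poiseuille(g$eps_f[1], g$eta_f[1], G, 3.45e-3)
  i <- 16
  err <- max(abs(snap$w[i, ] - ann$w(g$rw[i, ]))) / max(ann$w(g$rw[i, ]))
  expect_lt(err, 0.02)

  # global conservation at steady state
  q <- flow_rate(snap)
  expect_lt(max(abs(q$Q_ml_s - q$Q_ml_s[1])) / q$Q_ml_s[1], 1e-3)
})

test_that("runs are deterministic: identical configs, identical fields", {
  num <- solver_config(Nz = 40, Nsigma = 12, t_end_s = 0.01,
                       stop_at_steady = FALSE)
  r1 <- run_simulation(coronary_case(2.0, numerics = num))
  r2 <- run_simulation(coronary_case(2.0, numerics = num))
  expect_identical(final_snapshot(r1)$w, final_snapshot(r2)$w)
  expect_identical(final_snapshot(r1)$p, final_snapshot(r2)$p)
  expect_identical(r1$summary$n_steps, r2$summary$n_steps)
})

test_that("hairline-wire annulus reproduces the classical flux deficit", {
  # a no-slip wire of radius 0.01 R removes ~22% of the tube flux (log
  # effect); the solver must agree with the independent 1-D annular
  # solution, and must NOT match the open-tube Buckingham-Reiner value
  rheo <- casson_params()
  run <- cached_run("near_tube_32", {
    run_simulation(near_tube_case(
      Q_ml_s = 0.012, rheology = rheo,
      numerics = solver_config(Nz = 32, Nsigma = 48, t_end_s = 0.8,
                               stop_at_steady = FALSE, cluster = FALSE)))
  })
  snap <- final_snapshot(run)
  G <- fitted_pressure_gradient(snap)
  q_sim <- flow_rate(snap)$Q_ml_s[17] * 1e-6
  oracle <- casson_annulus_1d(G, 0.01 * 2e-3, 2e-3, rheo)
  expect_equal(q_sim, oracle$Q, tolerance = 0.03)
  br <- casson_tube_flow(2e-3, G, rheo$mu_p, rheo$tau_y)
  expect_lt(q_sim / br$Q, 0.85)   # the wire deficit is real and large
})
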