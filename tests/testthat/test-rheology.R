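test_that("shear-rate invariant matches the tensor contraction", {
  expect_equal(shear_rate_invariant(dw_dr = 5), 5)
  expect_equal(shear_rate_invariant(dw_dr = -3), 3)
  expect_equal(shear_rate_invariant(0, 0, 0, 0, 0), 0)

  # brute-force oracle: gamma = sqrt(2 tr D^2) from the assembled tensor
  set.seed(42)
  for (k in 1:25) {
    v <- stats::rnorm(5, sd = 10)
    D <- matrix(0, 3, 3)
    D[1, 1] <- v[1]                    # D_rr
    D[2, 2] <- v[5]                    # D_theta_theta (u / r)
    D[3, 3] <- v[4]                    # D_zz
    D[1, 3] <- D[3, 1] <- (v[2] + v[3]) / 2
    expect_equal(shear_rate_invariant(v[1], v[2], v[3], v[4], v[5]),
                 sqrt(2 * sum(D * D)), tolerance = 1e-12)
  }
})

test_that("Casson effective viscosity: limits, value, monotonicity, cap", {
  p <- casson_params()
  expect_equal(effective_viscosity(100, casson_params(tau_y = 0)), 3.45e-3)
  expect_equal(effective_viscosity(100, p),
               (sqrt(3.45e-3) + sqrt(5e-5))^2, tolerance = 1e-12)
  expect_equal(effective_viscosity(100, p), 4.331e-3, tolerance = 1e-4)

  g <- 10^seq(-5, 6, length.out = 200)
  mu <- effective_viscosity(g, p)
  expect_true(all(diff(mu) <= 1e-18))            # non-increasing
  expect_true(all(is.finite(mu)))
  cap <- (sqrt(p$mu_p) + sqrt(p$tau_y / p$gammadot_floor))^2
  expect_equal(max(mu), cap)                      # bounded by the plug cap
  expect_lt(effective_viscosity(1e9, p) / p$mu_p, 1.001)  # high-shear limit
  expect_true(all(mu >= p$mu_p))

  expect_error(effective_viscosity(-1, p), "domain")
})

test_that("literal constant mode collapses to (sqrt(zeta)-sqrt(m))^2", {
  p <- casson_params(mode = "literal_constant", zeta = 4, m = 1)
  expect_equal(effective_viscosity(c(0, 1, 1e4), p), rep(1, 3))
  expect_equal(4 + 1 - 2 * sqrt(4 * 1), 1)  # zeta + m - 2 sqrt(zeta m)
  expect_error(casson_params(mode = "literal_constant", zeta = 1, m = 1),
               "literal")
})

test_that("stress components are linear and dissipation is non-negative", {
  mu <- 2.5e-3
  s0 <- stress_components(0, 0, 0, 0, 0, mu)
  expect_equal(unlist(s0), c(S_rr = 0, S_zz = 0, S_rz = 0, S_tt = 0))

  set.seed(7)
  for (k in 1:20) {
    v <- stats::rnorm(5, sd = 100)
    s1 <- stress_components(v[1], v[2], v[3], v[4], v[5], mu)
    s2 <- stress_components(2 * v[1], 2 * v[2], 2 * v[3], 2 * v[4],
                            2 * v[5], mu)
    expect_equal(unlist(s2), 2 * unlist(s1), tolerance = 1e-12)

    # dissipation sum S_ij D_ij >= 0
    d_rz <- (v[2] + v[3]) / 2
    diss <- s1$S_rr * v[1] + s1$S_tt * v[5] + s1$S_zz * v[4] +
      2 * s1$S_rz * d_rz
    expect_gte(diss, 0)
  }

  # Newtonian limit reduces to the standard viscous stresses
  pn <- casson_params(tau_y = 0, mu_p = mu)
  mu_eff <- effective_viscosity(123, pn)
  s <- stress_components(1, 2, 3, 4, 5, mu_eff)
  expect_equal(s$S_rr, 2 * mu * 1)
  expect_equal(s$S_zz, 2 * mu * 4)
  expect_equal(s$S_rz, mu * (2 + 3))
  expect_equal(s$S_tt, 2 * mu * 5)
})

test_that("parameter validation rejects unphysical rheology", {
  expect_error(casson_params(mu_p = 0), "mu_p")
  expect_error(casson_params(tau_y = -1), "tau_y")
  expect_error(casson_params(rho = -1), "rho")
  expect_error(casson_params(gammadot_floor = 0), "gammadot_floor")
})
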