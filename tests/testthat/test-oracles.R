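test_that("annular Poiseuille: no-slip walls, tube limit, Q consistency", {
  ann <- annular_poiseuille(5e-4, 2e-3, 100, 3.45e-3)
  expect_equal(ann$w(ann$R_i), 0, tolerance = 1e-15)
  expect_equal(ann$w(ann$R_o), 0, tolerance = 1e-15)

  # closed-form Q equals quadrature of 2 pi w r dr
  qnum <- stats::integrate(function(r) 2 * pi * ann$w(r) * r,
                           ann$R_i, ann$R_o, rel.tol = 1e-12)$value
  expect_equal(ann$Q, qnum, tolerance = 1e-10)

  # R_i -> 0: peak velocity approaches the Hagen-Poiseuille centerline
  # value G R_o^2 / (4 mu), though only logarithmically in R_i
  hp <- 100 * (2e-3)^2 / (4 * 3.45e-3)
  peak <- function(R_i) {
    tube <- annular_poiseuille(R_i, 2e-3, 100, 3.45e-3)
    max(tube$w(seq(R_i, 2e-3, length.out = 4001)))
  }
  expect_equal(peak(1e-12), hp, tolerance = 0.12)
  expect_lt(abs(peak(1e-12) - hp), abs(peak(1e-6) - hp))

  # wall shear consistent with a numerical derivative
  h <- 1e-9
  expect_equal(ann$tau(1e-3),
               3.45e-3 * (ann$w(1e-3 + h) - ann$w(1e-3 - h)) / (2 * h),
               tolerance = 1e-5)

  expect_error(annular_poiseuille(2e-3, 1e-3, 1, 1), "domain")
})

test_that("Casson tube flow: Newtonian limit, plug, Buckingham-Reiner", {
  R <- 2e-3; G <- 50; mu_p <- 3.45e-3

  newt <- casson_tube_flow(R, G, mu_p, 0)
  expect_equal(newt$Q, pi * G * R^4 / (8 * mu_p), tolerance = 1e-12)
  expect_equal(newt$r_p, 0)

  ct <- casson_tube_flow(R, G, mu_p, 5e-3)
  expect_equal(ct$r_p, 2 * 5e-3 / G)
  # flat plug
  rp <- seq(0, ct$r_p, length.out = 11)
  expect_equal(diff(range(ct$w(rp))), 0)
  expect_equal(ct$w(R), 0, tolerance = 1e-15)

  # piecewise profile quadrature (split at the plug edge) reproduces the
  # closed-form Buckingham-Reiner Q
  qnum <- stats::integrate(function(r) 2 * pi * ct$w(r) * r, 0, ct$r_p,
                           rel.tol = 1e-13)$value +
    stats::integrate(function(r) 2 * pi * ct$w(r) * r, ct$r_p, R,
                     rel.tol = 1e-13)$value
  expect_equal(ct$Q, qnum, tolerance = 1e-8)

  # full plug: no flow
  full <- casson_tube_flow(R, G, mu_p, tau_y = G * R / 2 * 1.01)
  expect_true(full$no_flow)
  expect_equal(full$Q, 0)
  # Q -> 0 continuously as r_p -> R
  near <- casson_tube_flow(R, G, mu_p, tau_y = G * R / 2 * 0.999)
  expect_lt(near$Q / newt$Q, 1e-8)
})
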