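test_that("severity coefficient pins the wall minimum at R - delta*", {
  st <- stenosis_spec(R_mm = 2, delta_star_mm = 0.82, a_mm = 4, b_mm = 2,
                      n = 2, L_mm = 10)
  expect_equal(stenosis_kappa(st), 0.41, tolerance = 1e-12)

  # brute-force minimization oracle across shape factors and heights
  for (n in c(2, 3, 4, 6)) {
    for (ds in c(0.2, 0.5, 0.82)) {
      st <- stenosis_spec(R_mm = 2, delta_star_mm = ds, a_mm = 4, b_mm = 2,
                          n = n, L_mm = 10)
      geom <- channel_geometry(st, catheter_spec(c = 0.1, delta_b_mm = 0))
      z <- seq(4, 6, length.out = 100001)
      expect_equal(min(eta_wall(geom, z)), 2 - ds, tolerance = 1e-9)
      expect_gt(stenosis_kappa(st), 0)
    }
  }
})

test_that("no stenosis means a uniform wall and zero kappa", {
  st <- stenosis_spec(delta_star_mm = 0)
  expect_equal(stenosis_kappa(st), 0)
  geom <- channel_geometry(st, catheter_spec())
  z <- seq(0, 10, length.out = 101)
  expect_equal(eta_wall(geom, z), rep(2, 101))
})

test_that("outer wall profile: branches, continuity, bounds, symmetry", {
  geom <- reference_geometry()
  expect_equal(eta_wall(geom, 1), 2)
  expect_equal(eta_wall(geom, 4), 2)
  expect_equal(eta_wall(geom, 5), 1.18, tolerance = 1e-12)

  # continuity at the stenosis ends
  e <- 1e-9
  expect_lt(abs(eta_wall(geom, 4 - e) - eta_wall(geom, 4 + e)), 1e-7)
  expect_lt(abs(eta_wall(geom, 6 - e) - eta_wall(geom, 6 + e)), 1e-7)

  z <- seq(0, 10, length.out = 5001)
  eta <- eta_wall(geom, z)
  expect_true(all(eta <= 2 + 1e-12 & eta >= 2 - 0.82 - 1e-12))

  # n = 2: symmetric about the midpoint
  s <- seq(0, 1, length.out = 257)
  expect_lt(max(abs(eta_wall(geom, 5 + s) - eta_wall(geom, 5 - s))), 1e-12)

  expect_error(eta_wall(geom, 10.5), "domain")
  expect_error(eta_wall(geom, -0.1), "domain")
})

test_that("inner wall: catheter radius, balloon peak, continuity", {
  geom <- reference_geometry()
  expect_equal(eps_wall(geom, 1), 0.5)
  expect_equal(eps_wall(geom, 4), 0.5, tolerance = 1e-12)
  expect_equal(eps_wall(geom, 5), 1.03, tolerance = 1e-12)

  z <- seq(0, 10, length.out = 5001)
  expect_equal(max(eps_wall(geom, z)), 0.5 + 0.53, tolerance = 1e-9)
  e <- 1e-9
  expect_lt(abs(eps_wall(geom, 4 - e) - eps_wall(geom, 4 + e)), 1e-7)
  expect_lt(abs(eps_wall(geom, 6 - e) - eps_wall(geom, 6 + e)), 1e-7)

  # the sin^4 alternative shares endpoints and peak location
  g4 <- channel_geometry(geom$stenosis,
                         catheter_spec(c = 0.25, delta_b_mm = 0.53,
                                       bump_profile = "sin4"))
  expect_equal(eps_wall(g4, 5), 1.03, tolerance = 1e-12)
  expect_equal(eps_wall(g4, 4), 0.5, tolerance = 1e-12)
})

test_that("wall slopes match numerical differentiation", {
  geom <- reference_geometry()
  z <- seq(4.05, 5.95, length.out = 41)
  h <- 1e-6
  expect_equal(deta_wall(geom, z),
               (eta_wall(geom, z + h) - eta_wall(geom, z - h)) / (2 * h),
               tolerance = 1e-5)
  expect_equal(deps_wall(geom, z),
               (eps_wall(geom, z + h) - eps_wall(geom, z - h)) / (2 * h),
               tolerance = 1e-5)
})

test_that("throat gap: reference value and dense-scan oracle", {
  geom <- reference_geometry()
  tg <- throat_gap(geom)
  expect_equal(tg$gap_mm, 0.15, tolerance = 1e-9)
  expect_equal(tg$z_mm, 5, tolerance = 1e-6)

  z <- seq(0, 10, length.out = 100001)
  gap_scan <- min(eta_wall(geom, z) - eps_wall(geom, z))
  expect_equal(tg$gap_mm, gap_scan, tolerance = 1e-6)

  ann <- annulus_geometry()
  expect_equal(throat_gap(ann)$gap_mm, 1.5, tolerance = 1e-12)
})

test_that("invalid geometry is rejected with informative errors", {
  expect_error(stenosis_spec(delta_star_mm = 2.5), "delta_star")
  expect_error(stenosis_spec(n = 1.5), "shape factor")
  expect_error(stenosis_spec(a_mm = 9, b_mm = 2), "inside")
  expect_error(catheter_spec(c = 1.2), "catheter ratio")
  expect_error(catheter_spec(c = 0, delta_b_mm = 0.5), "balloon")
  # channel closes: cR + delta_b exceeds R - delta*
  expect_error(
    channel_geometry(stenosis_spec(delta_star_mm = 0.9),
                     catheter_spec(c = 0.3, delta_b_mm = 0.6)),
    "gap|closes")
})

test_that("wall profile table and CSV export", {
  geom <- reference_geometry()
  wp <- wall_profiles(geom, n = 101)
  expect_named(wp, c("z_mm", "eta_mm", "eps_mm", "gap_mm"))
  expect_equal(wp$gap_mm, wp$eta_mm - wp$eps_mm)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wall_profiles_csv(geom, path, n = 51)
  hdr <- readLines(path, n = 1)
  expect_identical(hdr, "z_mm,eta_mm,eps_mm,gap_mm")
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 51)
  expect_equal(back$eta_mm, eta_wall(geom, back$z_mm), tolerance = 1e-6)
})
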