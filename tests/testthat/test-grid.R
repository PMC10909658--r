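test_that("uniform straight annulus gives uniform spacings", {
  g <- build_grid(annulus_geometry(), 16, 12, cluster = FALSE)
  expect_equal(diff(range(g$dx)), 0, tolerance = 1e-15)
  expect_equal(diff(range(g$ds)), 0, tolerance = 1e-15)
  # r spacing uniform in sigma at every z
  dr <- apply(g$rcorn, 1, function(r) diff(range(diff(r))))
  expect_lt(max(dr), 1e-18)
})

test_that("clustering concentrates axial nodes in the constriction", {
  geom <- reference_geometry()
  for (Nz in c(100, 200)) {
    g <- build_grid(geom, Nz, 16, cluster = TRUE)
    inside <- sum(g$xc * 1e3 > 4 & g$xc * 1e3 < 6)
    expect_gte(inside, ceiling(2 * (2 / 10) * Nz))
  }
  # wall-adjacent sigma spacing never exceeds interior spacing
  g <- build_grid(geom, 64, 24, cluster = TRUE)
  expect_lte(g$ds[1], min(g$ds[8:17]))
  expect_lte(g$ds[24], min(g$ds[8:17]))
})

test_that("grid invariants: monotone radii, positive volumes", {
  g <- build_grid(reference_geometry(), 64, 24)
  expect_true(all(apply(g$rcorn, 1, function(r) all(diff(r) > 0))))
  expect_true(all(g$rc > 0))
  expect_true(all(g$vol > 0))
})

test_that("cell volumes converge to the analytic annular volume", {
  geom <- reference_geometry()
  vol_exact <- pi * stats::integrate(
    function(z) (eta_wall(geom, z)^2 - eps_wall(geom, z)^2) * 1e-6,
    0, 10, rel.tol = 1e-12)$value * 1e-3
  g <- build_grid(geom, 200, 48)
  expect_equal(grid_volume(g), vol_exact, tolerance = 5e-3)

  # second-order decay of the volume error under axial refinement
  errs <- vapply(c(50, 100, 200), function(Nz) {
    abs(grid_volume(build_grid(geom, Nz, 16)) - vol_exact) / vol_exact
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("resolution guards reject unusable grids", {
  geom <- reference_geometry()
  expect_error(build_grid(geom, 6, 16), "Nz and Nsigma")
  expect_error(build_grid(geom, 16, 16, cluster = FALSE), "across")
  # no bump: coarse axial resolution is fine
  expect_s3_class(build_grid(annulus_geometry(), 16, 12, cluster = FALSE),
                  "mapped_grid")
})

test_that("open-tube grids expose the symmetry axis", {
  tube <- channel_geometry(stenosis_spec(delta_star_mm = 0),
                           catheter_spec(c = 0, delta_b_mm = 0))
  g <- build_grid(tube, 16, 12, cluster = FALSE)
  expect_true(g$axis)
  expect_equal(g$eps_f, rep(0, 17))
  expect_false(build_grid(annulus_geometry(), 16, 12)$axis)
})
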