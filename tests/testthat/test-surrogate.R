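test_that("surrogate energies hit their closed-form anchors", {
  spec <- surrogate_fixture()
  # the S0 minimum-energy construction returns exactly Delta_0 = 0
  p0 <- spec$states[["0"]]
  g0 <- make_scan_geometry(spec, p0$d0, sqrt(p0$s * (p0$d0 - p0$g)))
  expect_lt(abs(surrogate_energies(spec, g0)[["S0"]]), 1e-10)
  # r- symmetry of every state
  g <- make_scan_geometry(spec, 2.52, 0.35)
  gm <- make_scan_geometry(spec, 2.52, -0.35)
  expect_equal(surrogate_energies(spec, g), surrogate_energies(spec, gm),
               tolerance = 1e-10)
  # barrier at fixed d_OO equals B c^2 above gating and 0 below
  expect_equal(surrogate_barrier(spec, 2, 2.57),
               spec$states[["2"]]$B * (spec$states[["2"]]$s * 0.12)^2)
  expect_equal(surrogate_barrier(spec, 2, 2.40), 0)
  # numeric scan agrees with the closed form
  rs <- seq(-0.8, 0.8, by = 0.002)
  e <- vapply(rs, function(r)
    surrogate_energies(spec, make_scan_geometry(spec, 2.55, r))[["S2"]], 0)
  expect_equal(max(e[abs(rs) < 0.4]) - min(e), surrogate_barrier(spec, 2, 2.55),
               tolerance = 1e-4)
})

test_that("surrogate forces are exact gradients", {
  spec <- surrogate_fixture()
  # stationary point: zero force
  p0 <- spec$states[["0"]]
  g0 <- make_scan_geometry(spec, p0$d0, sqrt(p0$s * (p0$d0 - p0$g)))
  expect_lt(max(abs(surrogate_forces(spec, g0, 0))), 1e-9)
  # translation invariance: forces sum to zero
  g <- random_surrogate_geometries(spec, 1, seed = 3, sigma_xy = 0.06)[[1]]
  for (st in 0:2)
    expect_lt(max(abs(colSums(surrogate_forces(spec, g, st)))), 1e-10)
  # Richardson: central-difference error drops 4x when dx halves
  fa <- surrogate_forces(spec, g, 2)
  err <- vapply(c(0.004, 0.002), function(dx)
    max(abs(numerical_forces(function(gg)
      surrogate_energies(spec, gg)[[3]], g, dx) - fa)), 0)
  expect_equal(err[1] / err[2], 4, tolerance = 0.05)
})

test_that("surrogate densities integrate and difference correctly", {
  spec <- surrogate_fixture()
  grid <- default_grid(shape = c(26, 24, 16), spacing = 0.45)
  n0 <- surrogate_density(spec, spec$template, 0, grid)
  n1 <- surrogate_density(spec, spec$template, 1, grid)
  expect_equal(integrate_density(n0), spec$n_electrons, tolerance = 1e-3)
  # equal electron counts: the difference integrates to ~0
  expect_lt(abs(sum(n1$values - n0$values) * grid$spacing^3), 1e-6)
  expect_false(isTRUE(all.equal(n1$values, n0$values)))
  # pointwise brute-force Gaussian sum at a few grid points
  ax <- lapply(1:3, function(a) grid$origin[a] +
                 (seq_len(grid$shape[a]) - 1) * grid$spacing)
  w <- spec$states[["1"]]$w
  for (idx in list(c(5, 6, 7), c(13, 12, 8))) {
    r <- c(ax[[1]][idx[1]], ax[[2]][idx[2]], ax[[3]][idx[3]])
    val <- 0
    for (a in 1:9) {
      s <- spec$s_atom[a]
      val <- val + w[a] * (2 * pi * s^2)^-1.5 *
        exp(-sum((spec$template$xyz[a, ] - r)^2) / (2 * s^2))
    }
    expect_equal(array(n1$values, grid$shape)[idx[1], idx[2], idx[3]], val,
                 tolerance = 1e-12)
  }
})

test_that("fast coefficient path equals explicit projection", {
  spec <- surrogate_fixture()
  basis <- basis_spec(default_grid(shape = c(20, 18, 12), spacing = 0.5),
                      c(7, 7, 5))
  g <- random_surrogate_geometries(spec, 1, seed = 6, sigma_xy = 0.05)[[1]]
  fast <- surrogate_coefficient_matrix(spec, list(g), basis, states = 1)
  slow <- project_density(surrogate_density(spec, g, 1, basis$grid), basis)
  expect_equal(fast[["1"]][1, ], slow$coefficients, tolerance = 1e-10)
})

test_that("reference dataset generation is counted, seeded, and reactive", {
  spec <- surrogate_fixture()
  ds <- generate_reference_dataset(spec, n_gs_frames = 20L,
                                   n_es_trajectories = 2L, seed = 5L,
                                   es_steps = 120L)
  expect_length(ds$geometries, 20L + 2L * 120L)
  expect_equal(sum(ds$provenance$source == "es"), 240L)
  expect_equal(dim(ds$energies), c(260L, 3L))
  # bit-identical under the same seed
  ds2 <- generate_reference_dataset(spec, n_gs_frames = 20L,
                                    n_es_trajectories = 2L, seed = 5L,
                                    es_steps = 120L)
  expect_identical(ds$geometries[[137]]$xyz, ds2$geometries[[137]]$xyz)
  # the small fixture dataset shows proton-transfer events on S2
  big <- small_dataset()
  flips <- vapply(big$es_trajectories, function(tr)
    sum(diff(sign(traj_r_minus(tr))) != 0), 0)
  expect_gt(max(flips), 0)
})

test_that("crossing parameterization creates an S1/S2 seam", {
  spec <- surrogate_spec(crossing = TRUE)
  dvals <- seq(2.45, 2.9, by = 0.01)
  gaps <- vapply(dvals, function(d) {
    e <- surrogate_energies(spec, make_scan_geometry(spec, d, 0.4))
    e[["S2"]] - e[["S1"]]
  }, 0)
  expect_true(all(gaps >= 0))        # adiabatic ordering by construction
  expect_lt(min(gaps), 0.5)         # the seam is inside the scanned window
  expect_gt(max(gaps), 5)           # and the states separate away from it
})
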