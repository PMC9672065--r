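test_that("planarity restraint matches its closed form and units", {
  spec <- surrogate_fixture()
  restr <- restraint_spec()
  flat <- spec$template
  out <- restraint_energy_forces(flat, restr)
  expect_equal(out$energy, 0)
  expect_equal(out$forces, matrix(0, 9, 3))
  # an H displaced by 1 bohr: E = 1/2 * 9 kcal/mol, F_z = -9 kcal/(mol bohr)
  b <- 0.52917721067
  g <- geometry(1, matrix(c(0, 0, b), 1))
  out1 <- restraint_energy_forces(g, restr)
  expect_equal(out1$energy, 4.5, tolerance = 1e-12)
  expect_equal(out1$forces[1, 3] * b, -9, tolerance = 1e-12)
  expect_equal(out1$forces[1, 1:2], c(0, 0))
  # quadratic: doubling z quadruples the energy
  g2 <- geometry(1, matrix(c(0, 0, 2 * b), 1))
  expect_equal(restraint_energy_forces(g2, restr)$energy, 4 * out1$energy)
})

test_that("central differences recover analytic gradients at O(dx^2)", {
  flat <- function(g) 42
  g0 <- geometry(c(1, 1), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(numerical_forces(flat, g0, 0.001), matrix(0, 2, 3))
  # 1D harmonic: F = -kx with error < 1e-6 at k = 1, x = 0.5, dx = 0.001
  ho <- function(g) 0.5 * g$xyz[1, 1]^2
  gx <- geometry(1, matrix(c(0.5, 0, 0), 1))
  f <- numerical_forces(ho, gx, 0.001)
  expect_lt(abs(f[1, 1] + 0.5), 1e-6)
  expect_error(numerical_forces(function(g) NaN, gx, 0.001), "non-finite")
})

test_that("velocity Verlet integrates free and harmonic motion correctly", {
  free <- md_surface(function(g) 0, function(g) matrix(0, 1, 3))
  st <- md_state(geometry(1, matrix(0, 1, 3)),
                 matrix(c(0.02, -0.01, 0.005), 1), masses = 1)
  tr <- velocity_verlet_run(free, st, dt = 0.5, n_steps = 20)
  expect_equal(tr$frames[[21]]$xyz, matrix(c(0.02, -0.01, 0.005) * 10, 1),
               tolerance = 1e-12)
  # harmonic oscillator period = 2 pi sqrt(m_conv / k)
  k <- 100
  ho <- md_surface(function(g) 0.5 * k * g$xyz[1, 1]^2,
                   function(g) {
                     f <- matrix(0, 1, 3); f[1, 1] <- -k * g$xyz[1, 1]; f
                   })
  st2 <- md_state(geometry(1, matrix(c(1, 0, 0), 1)), matrix(0, 1, 3),
                  masses = 1)
  tr2 <- velocity_verlet_run(ho, st2, dt = 0.25, n_steps = 500)
  x <- vapply(tr2$frames, function(g) g$xyz[1, 1], 0)
  zc <- which(diff(sign(x)) != 0)
  period <- 2 * mean(diff(tr2$times[zc]))
  expect_equal(period, 2 * pi * sqrt((1e7 / 4184) / k), tolerance = 1e-3)
})

test_that("NVE conserves in-plane momentum under the z restraint", {
  spec <- surrogate_fixture()
  s2 <- surrogate_surface(spec, 2)
  set.seed(12)
  g0 <- make_scan_geometry(spec, 2.45, 0.1)
  m <- atomic_masses(g0$z)
  v0 <- matrix(rnorm(27, 0, 0.01), 9, 3)
  tr <- velocity_verlet_run(s2, md_state(g0, v0), dt = 0.25, n_steps = 40,
                            restraint = restraint_spec())
  p0 <- colSums(m * tr$velocities[[1]])
  p1 <- colSums(m * tr$velocities[[41]])
  expect_equal(p1[1:2], p0[1:2], tolerance = 1e-10)
  # trajectories are deterministic
  tr2 <- velocity_verlet_run(s2, md_state(g0, v0), dt = 0.25, n_steps = 40,
                             restraint = restraint_spec())
  expect_identical(tr$etot, tr2$etot)
})

test_that("vertical excitations copy phase-space points on a new surface", {
  free <- md_surface(function(g) 0, function(g) matrix(0, 1, 3))
  st <- md_state(geometry(1, matrix(0, 1, 3)), matrix(c(0.01, 0, 0), 1),
                 masses = 1)
  tr <- velocity_verlet_run(free, st, dt = 0.5, n_steps = 2000)
  inits <- vertical_excitation_initial_conditions(tr, 100, 2L)
  expect_length(inits, 10L)
  i3 <- which.min(abs(tr$times - 300))
  expect_identical(inits[[3]]$geometry$xyz, tr$frames[[i3]]$xyz)
  expect_identical(inits[[3]]$velocities, tr$velocities[[i3]])
  expect_equal(attr(inits[[3]], "target_state"), 2L)
  expect_equal(inits[[1]]$time, 0)
})

test_that("Langevin sampling equipartitions and is seed-reproducible", {
  k <- 50
  hw <- md_surface(function(g) 0.5 * k * sum(g$xyz^2),
                   function(g) -k * g$xyz)
  st <- md_state(geometry(1, matrix(0, 1, 3)), masses = 1)
  tr <- langevin_gs_sampler(hw, st, temperature = 300, friction = 0.3,
                            dt = 0.5, n_steps = 20000, seed = 4)
  kt2 <- 0.0019872041 * 300 / 2
  expect_equal(mean(tr$ekin[-(1:2000)]) / 3, kt2, tolerance = 0.05)
  tr2 <- langevin_gs_sampler(hw, st, temperature = 300, friction = 0.3,
                             dt = 0.5, n_steps = 100, seed = 9)
  tr3 <- langevin_gs_sampler(hw, st, temperature = 300, friction = 0.3,
                             dt = 0.5, n_steps = 100, seed = 9)
  expect_identical(tr2$frames[[101]]$xyz, tr3$frames[[101]]$xyz)
  # near-zero temperature relaxes toward the minimum
  stx <- md_state(geometry(1, matrix(c(1, 1, 1), 1)), masses = 1)
  trz <- langevin_gs_sampler(hw, stx, temperature = 1e-6, friction = 0.5,
                             dt = 0.5, n_steps = 2000, seed = 2)
  expect_lt(sqrt(sum(trz$frames[[2001]]$xyz^2)), 0.05)
})

test_that("trajectory energy logs and XYZ export are consistent", {
  spec <- surrogate_fixture()
  s0 <- surrogate_surface(spec, 0)
  tr <- velocity_verlet_run(s0, md_state(make_scan_geometry(spec, 2.57, 0.6)),
                            dt = 0.25, n_steps = 10,
                            restraint = restraint_spec())
  df <- as.data.frame(tr)
  expect_equal(df$etot, df$epot + df$ekin + df$erest)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory_xyz(tr, path)
  frames <- read_xyz(path)
  expect_length(frames, 11L)
  expect_match(attr(frames[[2]], "comment"), "etot=")
})
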