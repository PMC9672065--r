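test_that("S(t) encodes basin memory with the documented sign rules", {
  # all trajectories stay in the reactant basin
  stay <- replicate(4, traj_from_r(rep(0.5, 6)), simplify = FALSE)
  rf <- response_function(stay, bootstrap = FALSE)
  expect_equal(rf$s, rep(1, 6))
  expect_equal(rf$n, 4L)
  # exactly half transferred at the end
  half <- c(replicate(2, traj_from_r(c(0.5, 0.5, 0.5)), simplify = FALSE),
            replicate(2, traj_from_r(c(0.5, 0.5, -0.5)), simplify = FALSE))
  rf2 <- response_function(half, bootstrap = FALSE)
  expect_equal(rf2$s, c(1, 1, 0))
  # a single crossing steps from +1 to -1 at the crossing frame
  rf3 <- response_function(list(traj_from_r(c(0.4, 0.2, -0.1, -0.3))),
                           bootstrap = FALSE)
  expect_equal(rf3$s, c(1, 1, -1, -1))
  # an exact zero inherits the previous frame's sign
  rf4 <- response_function(list(traj_from_r(c(0.4, 0, -0.2))),
                           bootstrap = FALSE)
  expect_equal(rf4$s, c(1, 1, -1))
  # undefined initial basin is excluded with a warning
  expect_warning(
    rf5 <- response_function(list(traj_from_r(c(0, 0.3)),
                                  traj_from_r(c(0.5, 0.5))),
                             bootstrap = FALSE), "excluded")
  expect_equal(rf5$n, 1L)
})

test_that("S(t) averages consistently over ensemble partitions", {
  set.seed(21)
  trajs <- lapply(1:6, function(i)
    traj_from_r(cumsum(c(0.4, rnorm(5, 0, 0.3)))))
  full <- response_function(trajs, bootstrap = FALSE)
  a <- response_function(trajs[1:2], bootstrap = FALSE)
  b <- response_function(trajs[3:6], bootstrap = FALSE)
  expect_equal(full$s, (2 * a$s + 4 * b$s) / 6, tolerance = 1e-12)
})

test_that("bootstrap bands behave like percentile bootstrap bands", {
  smat <- matrix(rep(c(1, 1, 0, -1), 5), 5, 4, byrow = TRUE)
  ci <- bootstrap_ci(smat, n_resamples = 200, confidence = 0.95, seed = 1)
  expect_equal(ci$lower, colMeans(smat))   # identical rows: zero width
  expect_equal(ci$upper, colMeans(smat))
  set.seed(3)
  smat2 <- matrix(rnorm(30 * 8), 30, 8)
  ci2 <- bootstrap_ci(smat2, n_resamples = 999, seed = 2)
  expect_true(all(ci2$lower <= colMeans(smat2) + 1e-12))
  expect_true(all(ci2$upper >= colMeans(smat2) - 1e-12))
  # bands narrow roughly like 1/sqrt(n)
  wide <- mean(ci2$upper - ci2$lower)
  smat4 <- matrix(rnorm(120 * 8), 120, 8)
  ci4 <- bootstrap_ci(smat4, n_resamples = 999, seed = 2)
  expect_lt(mean(ci4$upper - ci4$lower), 0.75 * wide)
  expect_warning(bootstrap_ci(smat2, n_resamples = 50, seed = 1), "100")
})

test_that("mean distance series averages the ensemble", {
  spec <- surrogate_fixture()
  t1 <- traj_from_r(c(0.3, 0.3, 0.3))
  ser1 <- mean_distance_series(list(t1))
  expect_equal(ser1$mean_distance, rep(2.5, 3), tolerance = 1e-12)
  # two-trajectory ensemble = arithmetic mean of the two series
  frames2 <- lapply(c(2.4, 2.5, 2.6), function(d)
    make_scan_geometry(spec, d, 0.1))
  t2 <- structure(list(times = 0:2, frames = frames2), class = "trajectory")
  ser12 <- mean_distance_series(list(t1, t2))
  expect_equal(ser12$mean_distance, (rep(2.5, 3) + c(2.4, 2.5, 2.6)) / 2,
               tolerance = 1e-10)
})

test_that("surrogate excited-state ensembles contract the O-O distance", {
  ds <- small_dataset()
  ser <- mean_distance_series(ds$es_trajectories)
  i30 <- which.min(abs(ser$time - 30))
  expect_lt(ser$mean_distance[i30] - ser$mean_distance[1], 0)
})

test_that("profile scans and barrier extraction match the closed form", {
  spec <- surrogate_fixture()
  # exact surrogate S2 energies along a proton-transfer path
  for (d in c(2.55, 2.50, 2.42)) {
    rs <- seq(-0.75, 0.75, by = 0.005)
    sg <- lapply(rs, function(r) make_scan_geometry(spec, d, r))
    prof <- pes_scan(function(g) surrogate_energies(spec, g), sg)
    expect_equal(barrier_from_profile(rs, prof$S2),
                 surrogate_barrier(spec, 2, d), tolerance = 2e-4)
    # profiles are symmetric about r- = 0
    expect_equal(prof$S2, rev(prof$S2), tolerance = 1e-9)
  }
  # flat profile has zero barrier
  expect_equal(barrier_from_profile(seq(-1, 1, 0.1), rep(2, 21)), 0)
})
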