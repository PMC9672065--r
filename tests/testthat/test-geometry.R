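test_that("XYZ files round-trip geometries and labels", {
  g1 <- geometry(c(8, 6, 1), rbind(c(0, 0, 0), c(1.2, 0, 0), c(1.9, 0.8, -0.3)))
  g2 <- geometry(c(8, 6, 1), rbind(c(0.1, 0, 0), c(1.3, 0, 0), c(2.0, 0.8, 0.3)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(g1, g2), path, comments = c("frame a", "frame b"))
  back <- read_xyz(path, labels = c(O1 = 1, H = 3))
  expect_length(back, 2L)
  expect_equal(back[[1]]$z, g1$z)
  expect_equal(back[[2]]$xyz, g2$xyz, tolerance = 1e-9)
  expect_equal(attr(back[[1]], "comment"), "frame a")
  expect_equal(label_index(back[[1]], "O1"), 1L)
})

test_that("proton-transfer coordinate is the O-H distance difference", {
  g <- geometry(c(8, 8, 1),
                rbind(c(0, 0, 0), c(2.5, 0, 0), c(1.0, 0, 0)),
                labels = c(O1 = 1, O2 = 2, H = 3))
  expect_equal(proton_transfer_coordinate(g), 1.0 - 1.5)
  expect_equal(oo_distance(g), 2.5)
  g$xyz[3, 1] <- 1.25
  expect_equal(proton_transfer_coordinate(g), 0)
  expect_error(proton_transfer_coordinate(geometry(1, matrix(0, 1, 3))),
               "label")
})

test_that("Kabsch alignment recovers rigid transforms exactly", {
  spec <- surrogate_fixture()
  g <- spec$template
  expect_equal(rmsd(kabsch_align(g, g), g), 0, tolerance = 1e-12)
  # rotate + translate, then realign
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  gm <- g
  gm$xyz <- g$xyz %*% rot + matrix(c(1.5, -0.3, 0.8), n_atoms(g), 3,
                                   byrow = TRUE)
  aligned <- kabsch_align(gm, g)
  expect_lt(rmsd(aligned, g), 1e-12)
  expect_equal(det(attr(aligned, "rotation")), 1, tolerance = 1e-12)
  expect_error(kabsch_align(g, geometry(1, matrix(0, 1, 3))), "identical")
})

test_that("Kabsch beats a brute-force grid search over rotations", {
  spec <- surrogate_fixture()
  set.seed(4)
  g <- spec$template
  ref <- g
  ref$xyz <- ref$xyz + matrix(rnorm(27, 0, 0.15), 9, 3)
  aligned <- kabsch_align(g, ref)
  best <- attr(aligned, "rmsd")
  w <- as.numeric(g$z > 1); wn <- w / sum(w)
  cg <- colSums(g$xyz * wn); cr <- colSums(ref$xyz * wn)
  x0 <- sweep(g$xyz, 2, cg); y0 <- sweep(ref$xyz, 2, cr)
  grid_best <- Inf
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  half <- seq(0, pi, length.out = 7)
  for (a in angles) for (b in half) for (c in angles) {
    rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    rz2 <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    r <- rz1 %*% ry %*% rz2
    grid_best <- min(grid_best,
                     sqrt(sum(wn * rowSums((x0 %*% r - y0)^2))))
  }
  expect_lte(best, grid_best + 1e-12)   # analytic optimum dominates the grid
  expect_lt(grid_best - best, 0.1)      # and the 30-degree grid comes close
})

test_that("reflection is an involution that preserves distances and flips r-", {
  spec <- surrogate_fixture()
  g <- random_surrogate_geometries(spec, 1, seed = 5, sigma_xy = 0.08,
                                   sigma_z = 0.04)[[1]]
  gr <- reflect_geometry(g, spec$permutation)
  expect_equal(reflect_geometry(gr, spec$permutation)$xyz, g$xyz)
  # interatomic distances are preserved up to the atom relabelling
  expect_equal(unname(distance_matrix(gr)),
               unname(distance_matrix(g)[spec$permutation, spec$permutation]),
               tolerance = 1e-12)
  expect_equal(proton_transfer_coordinate(gr),
               -proton_transfer_coordinate(g), tolerance = 1e-12)
  # explicit r- example through the scan constructor
  gs <- make_scan_geometry(spec, 2.55, 0.3)
  expect_equal(proton_transfer_coordinate(gs), 0.3, tolerance = 1e-10)
  expect_equal(proton_transfer_coordinate(reflect_geometry(gs, spec$permutation)),
               -0.3, tolerance = 1e-10)
  # symmetric transition state is a fixed point
  ts <- make_scan_geometry(spec, 2.57, 0)
  expect_equal(reflect_geometry(ts, spec$permutation)$xyz, ts$xyz,
               tolerance = 1e-10)
  expect_error(reflect_geometry(g, c(2, 3, 1, 4:9)), "involution")
})
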