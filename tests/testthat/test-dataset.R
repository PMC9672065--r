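test_that("canonicalize aligns and enforces a non-negative transfer coordinate", {
  spec <- surrogate_fixture()
  g_pos <- make_scan_geometry(spec, 2.55, 0.4)
  g_neg <- reflect_geometry(g_pos, spec$permutation)
  out <- canonicalize(list(g_pos, g_neg), spec$template, spec$permutation)
  expect_equal(out$reflected, c(FALSE, TRUE))
  # the mirror pair collapses onto one canonical form
  expect_equal(out$geometries[[1]]$xyz, out$geometries[[2]]$xyz,
               tolerance = 1e-8)
  expect_true(all(vapply(out$geometries, proton_transfer_coordinate, 0) >= 0))
  # an already canonical geometry is returned unchanged (to tolerance)
  expect_equal(out$geometries[[1]]$xyz,
               kabsch_align(g_pos, spec$template)$xyz, tolerance = 1e-10)
  # exact r- = 0 is kept unreflected
  ts <- make_scan_geometry(spec, 2.57, 0)
  out0 <- canonicalize(list(ts), spec$template, spec$permutation)
  expect_false(out0$reflected)
})

test_that("kmeans_select handles the degenerate selection cases", {
  set.seed(8)
  x <- matrix(rnorm(12 * 2), 12)
  sel <- kmeans_select(x, 12, seed = 1)
  expect_setequal(as.integer(sel), 1:12)
  # k duplicates of k distinct points select those points
  base <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), 4, byrow = TRUE)
  xd <- base[rep(1:4, each = 3), ] + 0
  sel4 <- kmeans_select(xd, 4, seed = 2)
  expect_length(unique((as.integer(sel4) - 1) %/% 3), 4L)
  expect_error(kmeans_select(x, 13, seed = 1), "exceeds")
})

test_that("Lloyd iteration matches an independent naive implementation", {
  set.seed(9)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 4, 0.3), 20),
             matrix(rnorm(40, c(0, 8), 0.3), 20))
  sel <- kmeans_select(x, 3, seed = 5, nstart = 1, pca_tol = 0)
  init <- mshk:::with_local_seed(5, mshk:::kmeanspp_init(x, 3))
  # naive reference Lloyd loop, same starting centers
  centers <- init
  for (it in 1:100) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
      2 * x %*% t(centers)
    cl <- apply(d2, 1, which.min)
    newc <- t(vapply(1:3, function(j) colMeans(x[cl == j, , drop = FALSE]),
                     numeric(2)))
    if (max(abs(newc - centers)) < 1e-12) break
    centers <- newc
  }
  reps <- vapply(1:3, function(j) {
    m <- which(cl == j)
    m[which.min(rowSums(sweep(x[m, , drop = FALSE], 2, centers[j, ])^2))]
  }, 0L)
  expect_setequal(as.integer(sel), reps)
  # cross-check against stats::kmeans from the same initial centers
  km <- stats::kmeans(x, centers = init, algorithm = "Lloyd", iter.max = 100)
  expect_equal(sort(km$withinss), sort(vapply(1:3, function(j)
    sum(sweep(x[cl == j, , drop = FALSE], 2, centers[j, ])^2), 0)),
    tolerance = 1e-8)
})

test_that("selection is deterministic and PCA compression is harmless", {
  spec <- surrogate_fixture()
  ds <- small_dataset()
  gl <- canonicalize(ds$geometries[1:120], spec$template,
                     spec$permutation)$geometries
  x <- potential_matrix(gl, cluster_grid(), 0.2)
  s1 <- kmeans_select(x, 15, seed = 3)
  s2 <- kmeans_select(x, 15, seed = 3)
  expect_identical(as.integer(s1), as.integer(s2))
  s3 <- kmeans_select(x, 15, seed = 3, pca_tol = 0)
  expect_identical(as.integer(s1), as.integer(s3))
})

test_that("build_training_set doubles a clean selection by reflection", {
  spec <- surrogate_fixture()
  ds <- small_dataset()
  gs <- ds$geometries[ds$provenance$source == "gs"]
  es <- ds$geometries[ds$provenance$source == "es"][1:140]
  ts <- build_training_set(gs, es, spec$template, spec$permutation, k = 20,
                           seed = 4, clustering_grid = cluster_grid(),
                           nstart = 2)
  expect_length(ts$geometries, 40L)
  expect_equal(anyDuplicated(ts$selected), 0L)
  r <- vapply(ts$geometries, proton_transfer_coordinate, 0)
  expect_true(all(r[1:20] >= 0))
  expect_true(all(r[21:40] <= 0))
  # mirrored half maps 1-1 onto the canonical half
  for (i in c(1, 9, 20))
    expect_equal(ts$geometries[[20 + i]]$xyz,
                 reflect_geometry(ts$geometries[[i]],
                                  spec$permutation)$xyz)
  # pipeline is idempotent: re-canonicalizing the canonical half is a no-op
  re <- canonicalize(ts$geometries[1:20], spec$template, spec$permutation)
  expect_false(any(re$reflected))
  for (i in c(2, 13))
    expect_equal(re$geometries[[i]]$xyz, ts$geometries[[i]]$xyz,
                 tolerance = 1e-8)
  # k = 1 gives exactly two geometries
  ts1 <- build_training_set(gs[1:10], list(), spec$template,
                            spec$permutation, k = 1, seed = 1,
                            clustering_grid = cluster_grid())
  expect_length(ts1$geometries, 2L)
})
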