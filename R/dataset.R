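#' Canonicalize geometries into the aligned, positive-r- frame
#'
#' Aligns every geometry to the symmetric reference (Kabsch, heavy-atom
#' weights) and reflects any structure with a negative proton-transfer
#' coordinate in the sigma-v' mirror plane, so that every retained
#' geometry has r- >= 0.  Geometries with r- exactly 0 are kept
#' unreflected (reflection is a no-op there up to atom relabelling).
#'
#' @param geometries list of labelled [geometry()] objects.
#' @param reference the symmetric (C2v transition-state) reference frame.
#' @param permutation mirror-plane atom permutation for
#'   [reflect_geometry()].
#' @param weights alignment weights (default heavy atoms).
#' @param axis mirror-plane normal axis (default `"x"`).
#' @return list with `geometries` (aligned, r- >= 0) and `reflected`
#'   (logical vector recording which inputs were mirrored).
#' @export
canonicalize <- function(geometries, reference, permutation, weights = NULL,
                         axis = "x") {
  reflected <- logical(length(geometries))
  out <- vector("list", length(geometries))
  for (i in seq_along(geometries)) {
    g <- tryCatch(kabsch_align(geometries[[i]], reference, weights),
                  error = function(e)
                    stop("alignment failed for geometry ", i, ": ",
                         conditionMessage(e)))
    if (proton_transfer_coordinate(g) < 0) {
      g <- reflect_geometry(g, permutation, axis)
      ## mirroring is distance-preserving, but re-align so the frame is
      ## exactly the Kabsch optimum for the stored coordinates
      g <- kabsch_align(g, reference, weights)
      reflected[i] <- TRUE
    }
    out[[i]] <- g
  }
  list(geometries = out, reflected = reflected)
}

## k-means++ seeding (Arthur & Vassilvitskii): rows of x, RNG already set.
## Distances to the newest center via |x|^2 + |c|^2 - 2 x.c (one BLAS
## matrix-vector product per center).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  x2 <- rowSums(x^2)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  cvec <- x[centers[1], ]
  d2 <- pmax(x2 + sum(cvec^2) - 2 * as.numeric(x %*% cvec), 0)
  if (k > 1L) for (j in 2:k) {
    tot <- sum(d2)
    centers[j] <- if (tot <= 0) sample.int(n, 1L)
      else sample.int(n, 1L, prob = d2 / tot)
    cvec <- x[centers[j], ]
    nd <- pmax(x2 + sum(cvec^2) - 2 * as.numeric(x %*% cvec), 0)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

## Lloyd iteration with BLAS-based assignment (chunked so the n x k
## distance block stays modest) and reseeding of empty clusters to the
## currently worst-represented points.
lloyd_kmeans <- function(x, centers, iter_max = 100L, chunk = 2048L) {
  n <- nrow(x); k <- nrow(centers)
  x2 <- rowSums(x^2)
  cl_old <- integer(n)
  for (it in seq_len(iter_max)) {
    c2 <- rowSums(centers^2)
    cl <- integer(n)
    dmin <- numeric(n)
    for (lo in seq(1L, n, by = chunk)) {
      hi <- min(lo + chunk - 1L, n)
      d2 <- outer(x2[lo:hi], c2, "+") - 2 * tcrossprod(x[lo:hi, , drop = FALSE], centers)
      cl[lo:hi] <- max.col(-d2, ties.method = "first")
      dmin[lo:hi] <- d2[cbind(seq_len(hi - lo + 1L), cl[lo:hi])]
    }
    dmin[dmin < 0] <- 0
    counts <- tabulate(cl, nbins = k)
    empty <- which(counts == 0L)
    if (length(empty)) {
      far <- order(dmin, decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- x[far, , drop = FALSE]
      cl_old <- integer(n)  # force another pass
      next
    }
    if (all(cl == cl_old)) break
    cl_old <- cl
    centers <- rowsum(x, cl) / counts
  }
  list(cluster = cl, centers = centers, inertia = sum(dmin))
}

#' K-means training-sample selection under the L2 potential metric
#'
#' Clusters metric-scaled potential vectors with K-means (k-means++
#' seeding, Lloyd iteration, several restarts keeping the best inertia)
#' and returns one representative per cluster: the actual sample nearest
#' the centroid (centroids themselves are not valid molecules).
#' Representatives are drawn from within each cluster, so the `k`
#' returned indices are always distinct.
#'
#' Before iterating, the rows are losslessly compressed by principal
#' components retaining all but `pca_tol` of the total variance;
#' Euclidean distances (= the L2 potential metric for rows built by
#' [potential_matrix()]) are preserved to that tolerance.
#'
#' @param x n x d matrix of metric-scaled potential vectors, or a list of
#'   `potential_field`s sharing one grid.
#' @param k number of clusters/samples to retain (`k <= n`).
#' @param seed RNG seed (seeding and restarts are deterministic given it).
#' @param nstart number of k-means++ restarts (default 3).
#' @param iter_max Lloyd iteration cap per restart.
#' @param pca_tol variance fraction allowed to be discarded by the PCA
#'   compression (default 1e-6; set 0 to disable).
#' @return integer vector of `k` unique selected sample indices, with
#'   attributes `cluster` (assignments) and `inertia`.
#' @export
kmeans_select <- function(x, k, seed = 1L, nstart = 3L, iter_max = 100L,
                          pca_tol = 1e-6) {
  if (is.list(x) && inherits(x[[1]], "potential_field")) {
    grid <- x[[1]]$grid
    x <- t(vapply(x, function(f) {
      if (!same_grid(f$grid, grid)) stop("potential fields on different grids")
      f$values
    }, numeric(grid_size(grid)))) * grid$spacing^1.5
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k < 1L) stop("k must be positive")
  center <- colMeans(x)
  if (pca_tol > 0 && ncol(x) > 64L) {
    ## principal subspace via the Gram matrix of a row subsample: memory
    ## O(n_sub^2) instead of O(d^2), adequate because the potential
    ## manifold of a small molecule is low-rank.  Scores are computed as
    ## x v - (center' v) so the big matrix is never copied.
    n_sub <- min(n, 2000L)
    sub <- if (n_sub < n) with_local_seed(seed + 1L, sample.int(n, n_sub))
           else seq_len(n)
    xs <- sweep(x[sub, , drop = FALSE], 2, center)
    eg <- eigen(tcrossprod(xs), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    keep <- max(which(cumsum(ev) >= (1 - pca_tol) * sum(ev))[1], 1L)
    keep <- min(keep, 512L)   # the potential manifold is low-rank; cap defensively
    v <- crossprod(xs, sweep(eg$vectors[, seq_len(keep), drop = FALSE],
                             2, sqrt(ev[seq_len(keep)]), "/"))
    rm(xs)
    xr <- x %*% v
    xr <- sweep(xr, 2, as.numeric(center %*% v))
  } else {
    xr <- sweep(x, 2, center)
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(nstart)) {
      init <- kmeanspp_init(xr, k)
      km <- lloyd_kmeans(xr, init, iter_max)
      if (is.null(best) || km$inertia < best$inertia) best <- km
    }
  })
  groups <- split(seq_len(n), factor(best$cluster, levels = seq_len(k)))
  sel <- vapply(seq_len(k), function(j) {
    members <- groups[[j]]
    d2 <- rowSums(sweep(xr[members, , drop = FALSE], 2, best$centers[j, ])^2)
    members[which.min(d2)]
  }, 0L)
  structure(sel, cluster = best$cluster, inertia = best$inertia)
}

#' Build a symmetrized production training set
#'
#' The full recipe: pool ground-state and excited-state frames,
#' canonicalize (align + enforce r- >= 0 by mirror reflection), select
#' `k` representative samples by K-means under the L2 potential metric,
#' then double the set by applying the mirror reflection to every
#' selected geometry.  The output always has exactly `2 k` geometries and
#' is closed under the reflection operation.
#'
#' @param gs_frames,es_frames lists of labelled [geometry()]s (either may
#'   be empty).
#' @param reference symmetric reference frame geometry.
#' @param permutation mirror-plane atom permutation.
#' @param k cluster count (production value 2500).
#' @param seed RNG seed for the clustering.
#' @param clustering_grid [grid_spec()] on which clustering potentials
#'   are evaluated; default the stride-2 coarsening of [default_grid()]
#'   centred on the reference heavy-atom centroid.
#' @param sigma_pot Gaussian potential width.
#' @param nstart,pca_tol passed to [kmeans_select()].
#' @param weights,axis passed to [canonicalize()].
#' @return an object of class `"training_set"`: `geometries` (length
#'   `2 k`, canonical half first), `provenance` data.frame (`source`,
#'   `frame`, `canonicalized_reflection`, `doubled_reflection`), and the
#'   selection metadata (`k`, `seed`, selected indices).
#' @export
build_training_set <- function(gs_frames, es_frames, reference, permutation,
                               k, seed = 1L, clustering_grid = NULL,
                               sigma_pot = 0.2, nstart = 3L, pca_tol = 1e-6,
                               weights = NULL, axis = "x") {
  frames <- c(gs_frames, es_frames)
  if (length(frames) < 1L) stop("no input frames")
  source <- c(rep("gs", length(gs_frames)), rep("es", length(es_frames)))
  frame_id <- c(seq_along(gs_frames), seq_along(es_frames))
  canon <- canonicalize(frames, reference, permutation, weights, axis)
  if (is.null(clustering_grid)) {
    w <- alignment_weights(reference, weights)
    centroid <- colSums(reference$xyz * w / sum(w))
    clustering_grid <- coarsen_grid(default_grid(centroid), 2L)
  }
  x <- potential_matrix(canon$geometries, clustering_grid, sigma_pot)
  sel <- kmeans_select(x, k, seed = seed, nstart = nstart, pca_tol = pca_tol)
  chosen <- canon$geometries[sel]
  mirrored <- lapply(chosen, reflect_geometry, permutation = permutation,
                     axis = axis)
  prov <- data.frame(
    source = c(source[sel], source[sel]),
    frame = c(frame_id[sel], frame_id[sel]),
    canonicalized_reflection = c(canon$reflected[sel], canon$reflected[sel]),
    doubled_reflection = rep(c(FALSE, TRUE), each = k)
  )
  structure(list(geometries = c(chosen, mirrored), provenance = prov,
                 k = k, seed = seed, selected = as.integer(sel),
                 reference = reference, permutation = permutation,
                 clustering_grid = clustering_grid, sigma_pot = sigma_pot),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d geometries (%d selected x 2 by reflection)\n",
              length(x$geometries), x$k))
  invisible(x)
}
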