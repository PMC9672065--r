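#' Regular 3D grid specification
#'
#' An isotropically spaced rectangular grid on which external potentials
#' and electron densities are sampled.  Grid point `(i, j, k)` (1-based)
#' sits at `origin + (i-1, j-1, k-1) * spacing`; flattened vectors run
#' x-fastest (standard R array order for `dim = shape`).
#'
#' @param origin numeric length-3 vector, Angstrom.
#' @param spacing positive scalar, Angstrom.
#' @param shape integer length-3 vector of points per axis.
#' @return an object of class `"grid_spec"`.
#' @export
grid_spec <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("origin must be a finite length-3 vector")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar")
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  structure(list(origin = origin, spacing = as.numeric(spacing), shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d @ %.3f A, origin (%.3f, %.3f, %.3f)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_size <- function(grid) prod(grid$shape)

grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing)
}

#' Default potential grid centred on a point
#'
#' The production grid: 60 x 50 x 30 points at 0.2 Angstrom spacing,
#' centred so the molecular plane is xy and the long molecular axis is x.
#' The centred origin makes the grid symmetric under sign flips of each
#' axis, so mirror images of an aligned geometry see a permutation of the
#' same grid points.
#'
#' @param center length-3 centre of the box (typically the reference
#'   geometry's heavy-atom centroid); default the origin.
#' @param shape,spacing override the defaults.
#' @return a [grid_spec()].
#' @export
default_grid <- function(center = c(0, 0, 0), shape = c(60L, 50L, 30L),
                         spacing = 0.2) {
  origin <- center - (shape - 1) * spacing / 2
  grid_spec(origin, spacing, shape)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) && all(a$shape == b$shape)
}

#' Coarsen a grid by an integer stride
#'
#' Returns a grid with `stride`-times larger spacing sharing the fine
#' grid's centre; used to down-sample potential vectors for K-means
#' clustering and for coarse model descriptors.  The centre (rather than
#' the origin) is preserved so that a centred, mirror-symmetric grid
#' stays mirror-symmetric — reflection symmetry of trained models
#' depends on it.
#'
#' @param grid a [grid_spec()].
#' @param stride positive integer.
#' @return a [grid_spec()].
#' @export
coarsen_grid <- function(grid, stride) {
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be a positive integer")
  shape <- pmax(((grid$shape - 1L) %/% stride) + 1L, 1L)
  center <- grid$origin + (grid$shape - 1) * grid$spacing / 2
  spacing <- grid$spacing * stride
  grid_spec(center - (shape - 1) * spacing / 2, spacing, shape)
}

#' Gaussian-smeared external potential on a grid
#'
#' Replaces each nuclear Coulomb singularity by a Gaussian of width
#' `sigma_pot`: `v(r) = sum_a Z_a exp(-|R_a - r|^2 / (2 sigma_pot^2))`.
#' The separable Gaussian is evaluated as an outer product of per-axis
#' factors, so the cost is O(atoms x grid points).
#'
#' @param g a [geometry()].
#' @param grid a [grid_spec()]; warns if any atom lies more than
#'   `3 * sigma_pot` outside the box.
#' @param sigma_pot Gaussian width in Angstrom (default 0.2).
#' @return an object of class `"potential_field"` with fields `grid`,
#'   `values` (flattened, x-fastest) and `sigma_pot`.
#' @export
gaussian_potential <- function(g, grid, sigma_pot = 0.2) {
  if (!is.numeric(sigma_pot) || length(sigma_pot) != 1L || sigma_pot <= 0)
    stop("sigma_pot must be a positive scalar")
  if (n_atoms(g) < 1L) stop("empty geometry")
  ax <- grid_axes(grid)
  lo <- vapply(ax, min, 0) - 3 * sigma_pot
  hi <- vapply(ax, max, 0) + 3 * sigma_pot
  if (any(sweep(g$xyz, 2, lo) < 0) || any(sweep(g$xyz, 2, hi) > 0))
    warning("atom(s) more than 3*sigma_pot outside the grid box; ",
            "potential descriptor may truncate the molecule")
  s2 <- 2 * sigma_pot^2
  vals <- array(0, dim = grid$shape)
  for (a in seq_len(n_atoms(g))) {
    ex <- exp(-(ax[[1]] - g$xyz[a, 1])^2 / s2)
    ey <- exp(-(ax[[2]] - g$xyz[a, 2])^2 / s2)
    ez <- exp(-(ax[[3]] - g$xyz[a, 3])^2 / s2)
    vals <- vals + g$z[a] * ((ex %o% ey) %o% ez)
  }
  structure(list(grid = grid, values = as.numeric(vals), sigma_pot = sigma_pot),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> %d values, sigma_pot = %.3f A, max %.3f\n",
              length(x$values), x$sigma_pot, max(x$values)))
  invisible(x)
}

#' L2 distance between two potential fields
#'
#' Grid quadrature of `sqrt(integral (v - v')^2 dr)`, i.e.
#' `sqrt(sum_g (v_g - v'_g)^2 * spacing^3)` — the metric used both inside
#' the Gaussian potential kernel and for K-means clustering.
#'
#' @param a,b `potential_field`s on the same grid.
#' @return the distance (units potential x Angstrom^(3/2)).
#' @export
potential_l2_distance <- function(a, b) {
  if (!same_grid(a$grid, b$grid))
    stop("potential fields are on different grids")
  sqrt(sum((a$values - b$values)^2) * a$grid$spacing^3)
}

#' Metric-scaled potential descriptor matrix
#'
#' Evaluates [gaussian_potential()] for a list of geometries and stacks
#' the flattened fields as rows, scaled by `spacing^(3/2)` so that plain
#' Euclidean row distances equal [potential_l2_distance()].  This is the
#' descriptor format consumed by the KRR models and by [kmeans_select()].
#'
#' @param geometries list of [geometry()] objects.
#' @param grid a [grid_spec()].
#' @param sigma_pot Gaussian width in Angstrom.
#' @return an `n x prod(shape)` numeric matrix.
#' @export
potential_matrix <- function(geometries, grid, sigma_pot = 0.2) {
  scale <- grid$spacing^1.5
  n <- length(geometries)
  x <- matrix(0, n, grid_size(grid))
  for (i in seq_len(n))
    x[i, ] <- gaussian_potential(geometries[[i]], grid, sigma_pot)$values * scale
  x
}
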