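#' Train the potential-to-density map
#'
#' One Gaussian-kernel ridge regression over potential descriptors whose
#' targets are all Fourier density coefficients of all trained states:
#' every state j gets its own map `u_j[v]`, but all share one kernel
#' matrix and one (sigma, lambda) pair.  A single Cholesky solve covers
#' the full coefficient block.
#'
#' @param x_pot M x d matrix of metric-scaled potential descriptors
#'   (rows from [potential_matrix()]).
#' @param coef_list named list (names = state indices as characters, e.g.
#'   `"0"`, `"1"`, `"2"`); each element an M x L coefficient matrix.
#'   Every geometry must have coefficients for every trained state.
#' @param sigma,lambda kernel width and ridge strength of the potential
#'   kernel.
#' @param per_axis per-axis mode counts of the generating basis (kept for
#'   bookkeeping).
#' @return an object of class `"density_map"`.
#' @export
train_density_map <- function(x_pot, coef_list, sigma, lambda = 1e-10,
                              per_axis = NULL) {
  x_pot <- as.matrix(x_pot)
  m <- nrow(x_pot)
  if (is.null(names(coef_list)))
    stop("coef_list must be named by state index")
  l <- unique(vapply(coef_list, ncol, 0L))
  if (length(l) != 1L)
    stop("all states must share one coefficient length")
  if (!all(vapply(coef_list, nrow, 0L) == m))
    stop("every geometry needs coefficients for every trained state")
  fit <- krr_fit(x_pot, do.call(cbind, coef_list), sigma, lambda)
  structure(list(krr = fit, states = names(coef_list), n_coef = l,
                 per_axis = per_axis), class = "density_map")
}

#' Predict density coefficients from potential descriptors
#'
#' @param map a [train_density_map()] model.
#' @param x_query m x d matrix (or single vector) of potential descriptors.
#' @return named list of m x L coefficient matrices, one per state.
#' @export
predict_density_coefficients <- function(map, x_query) {
  pred <- predict(map$krr, x_query)
  l <- map$n_coef
  out <- lapply(seq_along(map$states), function(s)
    pred[, ((s - 1) * l + 1):(s * l), drop = FALSE])
  names(out) <- map$states
  out
}

#' Train the single multistate density-to-energy functional
#'
#' Every (geometry, state) pair contributes one training row: descriptor
#' = the state's density coefficient vector u, target = that state's
#' total energy.  The functional itself carries no state index — state
#' identity enters only through which density is fed in.  Energies are
#' shifted by a stored reference offset for conditioning and the offset
#' is re-added at prediction.
#'
#' @param coef_list named list of M x L coefficient matrices (states to
#'   pool, e.g. `"0"`, `"1"`, `"2"`; any subset is allowed).
#' @param energies M x S matrix (columns matching `coef_list` names) or
#'   named list of length-M vectors, kcal/mol.
#' @param sigma,lambda kernel width and ridge strength of the
#'   density-coefficient kernel (plain Euclidean distance in u-space).
#' @param standardize if `TRUE`, coefficients are centred/scaled by the
#'   pooled training moments before the kernel (off by default).
#' @return an object of class `"energy_functional"`.
#' @export
train_energy_functional <- function(coef_list, energies, sigma,
                                    lambda = 1e-10, standardize = FALSE) {
  if (is.list(energies)) energies <- do.call(cbind, energies[names(coef_list)])
  energies <- as.matrix(energies)
  if (is.null(colnames(energies))) colnames(energies) <- names(coef_list)
  l <- unique(vapply(coef_list, ncol, 0L))
  if (length(l) != 1L) stop("inconsistent coefficient lengths across states")
  u <- do.call(rbind, coef_list)
  y <- unlist(lapply(names(coef_list), function(s) energies[, s]), use.names = FALSE)
  if (length(y) != nrow(u)) stop("energy/coefficient row mismatch")
  center <- NULL; scale <- NULL
  if (standardize) {
    center <- colMeans(u)
    scale <- pmax(apply(u, 2, stats::sd), 1e-12)
    u <- scale(u, center = center, scale = scale)
  }
  offset <- mean(y)
  fit <- krr_fit(u, y - offset, sigma, lambda)
  structure(list(krr = fit, offset = offset, states = names(coef_list),
                 center = center, scale = scale), class = "energy_functional")
}

#' Evaluate the multistate energy functional on density coefficients
#' @param functional an [train_energy_functional()] model.
#' @param u m x L matrix (or single vector) of density coefficients.
#' @return numeric vector of energies, kcal/mol.
#' @export
predict_energy <- function(functional, u) {
  if (is.null(dim(u))) u <- matrix(u, 1)
  if (!is.null(functional$center))
    u <- scale(u, center = functional$center, scale = functional$scale)
  as.numeric(predict(functional$krr, u)) + functional$offset
}

#' Assemble a full ML-MSHK model
#'
#' Bundles the two maps with the shared geometric frame: the alignment
#' reference, the potential descriptor grid and Gaussian width, and the
#' density basis, so that prediction from a raw geometry is
#' self-contained.
#'
#' @param density_map a [train_density_map()] model.
#' @param energy_functional an [train_energy_functional()] model.
#' @param reference alignment reference [geometry()].
#' @param pot_grid [grid_spec()] of the potential descriptors.
#' @param basis [basis_spec()] of the density coefficients.
#' @param sigma_pot Gaussian potential width, Angstrom.
#' @param align_weights per-atom alignment weights (default heavy atoms).
#' @param provenance free-form list (seeds, dataset hash, ...).
#' @return an object of class `"mshk_model"`.
#' @export
mshk_model <- function(density_map, energy_functional, reference, pot_grid,
                       basis, sigma_pot = 0.2, align_weights = NULL,
                       provenance = list()) {
  structure(list(density_map = density_map,
                 energy_functional = energy_functional,
                 reference = reference, pot_grid = pot_grid, basis = basis,
                 sigma_pot = sigma_pot, align_weights = align_weights,
                 provenance = provenance),
            class = "mshk_model")
}

#' @export
print.mshk_model <- function(x, ...) {
  cat(sprintf(
    "<mshk_model> %d training potentials, states {%s}, %d coefficients/state\n",
    nrow(x$density_map$krr$x), paste(x$density_map$states, collapse = ","),
    x$density_map$n_coef))
  invisible(x)
}

#' Predict per-state energies and densities with ML-MSHK
#'
#' The full chain: align the geometry to the model frame, form the
#' Gaussian potential descriptor, predict each state's density
#' coefficients, then evaluate the single multistate energy functional on
#' each predicted density.
#'
#' @param model an [mshk_model()].
#' @param g a [geometry()] (alignable to the model reference).
#' @param align re-align to the model frame first (default `TRUE`).
#' @return a list: `energies` (named per-state vector, kcal/mol),
#'   `coefficients` (named list of [density_coefficients()]),
#'   `min_potential_distance` (L2 distance to the nearest training
#'   potential) and `extrapolated` (`TRUE` when that distance exceeds
#'   3x the potential kernel width — predictions decay to the training
#'   mean out there).
#' @export
predict_mshk <- function(model, g, align = TRUE) {
  xq <- mshk_descriptor(model, g, align)
  ulist <- predict_density_coefficients(model$density_map, xq$x)
  energies <- vapply(ulist, function(u)
    predict_energy(model$energy_functional, u[1, ]), 0)
  names(energies) <- paste0("S", model$density_map$states)
  coefs <- lapply(seq_along(ulist), function(i)
    density_coefficients(ulist[[i]][1, ], model$basis$per_axis,
                         as.integer(model$density_map$states[i])))
  names(coefs) <- names(energies)
  list(energies = energies, coefficients = coefs,
       min_potential_distance = xq$dmin, extrapolated = xq$extrapolated)
}

#' Batch ML-MSHK prediction for many geometries
#'
#' Vectorized equivalent of [predict_mshk()]: one potential-descriptor
#' matrix, one kernel block per stage.  Much faster than looping when
#' evaluating scans or trajectories.
#'
#' @param model an [mshk_model()].
#' @param geometries list of [geometry()]s.
#' @param align re-align each geometry to the model frame.
#' @return list with `energies` (n x states matrix, columns `S<j>`),
#'   `min_potential_distance` (length-n) and `extrapolated` (logical).
#' @export
predict_mshk_batch <- function(model, geometries, align = TRUE) {
  if (align)
    geometries <- lapply(geometries, kabsch_align, reference = model$reference,
                         weights = model$align_weights)
  xq <- potential_matrix(geometries, model$pot_grid, model$sigma_pot)
  d2 <- row_dist2(xq, model$density_map$krr$x)
  dmin <- sqrt(apply(d2, 1, min))
  kq <- exp(-d2 / model$density_map$krr$sigma^2)
  pred <- kq %*% model$density_map$krr$weights
  l <- model$density_map$n_coef
  states <- model$density_map$states
  energies <- vapply(seq_along(states), function(s) {
    u <- pred[, ((s - 1) * l + 1):(s * l), drop = FALSE]
    predict_energy(model$energy_functional, u)
  }, numeric(length(geometries)))
  energies <- matrix(energies, nrow = length(geometries),
                     dimnames = list(NULL, paste0("S", states)))
  list(energies = energies, min_potential_distance = dmin,
       extrapolated = dmin > 3 * model$density_map$krr$sigma)
}

## Shared descriptor construction for MSHK/MSKS prediction.
mshk_descriptor <- function(model, g, align = TRUE) {
  if (align) g <- kabsch_align(g, model$reference, model$align_weights)
  field <- gaussian_potential(g, model$pot_grid, model$sigma_pot)
  x <- matrix(field$values * model$pot_grid$spacing^1.5, 1)
  xtr <- if (inherits(model, "mshk_model")) model$density_map$krr$x else model$krr$x
  dmin <- sqrt(min(row_dist2(x, xtr)))
  sig <- if (inherits(model, "mshk_model")) model$density_map$krr$sigma else model$krr$sigma
  list(x = x, dmin = dmin, extrapolated = dmin > 3 * sig, geometry = g)
}

#' Train a direct multistate Kohn-Sham-style map (ML-MSKS)
#'
#' State-specific potential-to-energy regression with no density
#' intermediate: one weight column per state over a shared potential
#' kernel.
#'
#' @param x_pot M x d potential descriptor matrix.
#' @param energies M x S matrix of per-state energies (columns named by
#'   state index).
#' @param sigma,lambda potential-kernel hyperparameters.
#' @param reference,pot_grid,sigma_pot,align_weights frame bookkeeping as
#'   in [mshk_model()] (optional; required for [predict_msks()] from raw
#'   geometries).
#' @return an object of class `"msks_map"`.
#' @export
train_msks <- function(x_pot, energies, sigma, lambda = 1e-10,
                       reference = NULL, pot_grid = NULL, sigma_pot = 0.2,
                       align_weights = NULL) {
  energies <- as.matrix(energies)
  if (is.null(colnames(energies)))
    colnames(energies) <- as.character(seq_len(ncol(energies)) - 1L)
  offset <- mean(energies)
  fit <- krr_fit(as.matrix(x_pot), energies - offset, sigma, lambda)
  structure(list(krr = fit, offset = offset, states = colnames(energies),
                 reference = reference, pot_grid = pot_grid,
                 sigma_pot = sigma_pot, align_weights = align_weights),
            class = "msks_map")
}

#' Predict per-state energies with ML-MSKS
#' @param model a [train_msks()] map with frame bookkeeping.
#' @param g a [geometry()].
#' @param align re-align to the model frame first.
#' @return list with `energies` (named vector), `min_potential_distance`,
#'   `extrapolated`.
#' @export
predict_msks <- function(model, g, align = TRUE) {
  if (is.null(model$reference) || is.null(model$pot_grid))
    stop("msks map lacks frame bookkeeping; train with reference and pot_grid")
  xq <- mshk_descriptor(model, g, align)
  e <- as.numeric(predict(model$krr, xq$x)) + model$offset
  names(e) <- paste0("S", model$states)
  list(energies = e, min_potential_distance = xq$dmin,
       extrapolated = xq$extrapolated)
}

#' Save / load a trained model archive
#'
#' A single-file archive holding the weights, retained training
#' descriptors, hyperparameters and provenance; bit-stable across
#' save/load.
#'
#' @param model an `mshk_model` or `msks_map`.
#' @param path archive path (`.rds`).
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("mshk_model", "msks_map")))
  info <- list(package_version = as.character(utils::packageVersion("mshk")),
               saved = format(Sys.time(), tz = "UTC"))
  attr(model, "archive_info") <- info
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("mshk_model", "msks_map")))
    stop("file does not contain an mshk model archive")
  model
}
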