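#' Proton-transfer coordinate time series of a trajectory
#' @param traj a `trajectory` of labelled geometries.
#' @return numeric vector, r- per stored frame (Angstrom).
#' @export
traj_r_minus <- function(traj) {
  vapply(traj$frames, proton_transfer_coordinate, 0)
}

## Per-frame basin sign with the measure-zero tie rule: an exact zero
## inherits the previous frame's sign.
basin_signs <- function(r) {
  s <- sign(r)
  if (s[1] == 0) return(NULL)  # undefined initial basin
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  s
}

#' Non-equilibrium proton-location response function S(t)
#'
#' `S(t) = mean over trajectories of sign(r-(0) * r-(t))`: +1 while a
#' trajectory remembers its initial reaction basin, -1 after transfer,
#' and 0 on ensemble average once memory is lost (for the symmetric
#' donor/acceptor, S = 0 means the reaction is complete).  Trajectories
#' with r-(0) = 0 have an undefined initial basin and are excluded with
#' a warning.
#'
#' @param trajectories list of `trajectory` objects sharing timestep and
#'   length.
#' @param bootstrap compute 95% bootstrap confidence bands (resampling
#'   whole trajectories, the independent unit of the ensemble).
#' @param n_resamples bootstrap resamples (default 9999).
#' @param confidence band level (default 0.95).
#' @param seed bootstrap RNG seed.
#' @return an object of class `"response_function"`: `times`, `s`,
#'   `lower`/`upper` (or `NULL`), `n` (ensemble size used).
#' @export
response_function <- function(trajectories, bootstrap = TRUE,
                              n_resamples = 9999L, confidence = 0.95,
                              seed = 1L) {
  if (length(trajectories) < 1L) stop("empty trajectory ensemble")
  times <- trajectories[[1]]$times
  rs <- lapply(trajectories, function(tr) {
    if (length(tr$times) != length(times) ||
        max(abs(tr$times - times)) > 1e-9)
      stop("trajectories must share time base")
    basin_signs(traj_r_minus(tr))
  })
  drop <- vapply(rs, is.null, TRUE)
  if (any(drop)) {
    warning(sum(drop), " trajectory(ies) with r-(0) = 0 excluded ",
            "(undefined initial basin)")
    rs <- rs[!drop]
  }
  if (!length(rs)) stop("no trajectory with a defined initial basin")
  smat <- do.call(rbind, lapply(rs, function(s) s[1] * s))
  s <- colMeans(smat)
  lo <- up <- NULL
  if (bootstrap && nrow(smat) >= 2L) {
    ci <- bootstrap_ci(smat, n_resamples, confidence, seed)
    lo <- ci$lower; up <- ci$upper
  }
  structure(list(times = times, s = s, lower = lo, upper = up,
                 n = nrow(smat)), class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat(sprintf("<response_function> %d trajectories, %d frames, S(end) = %.3f\n",
              x$n, length(x$times), x$s[length(x$s)]))
  invisible(x)
}

#' Percentile bootstrap confidence band for an ensemble mean series
#'
#' Resamples whole rows (trajectories) with replacement, recomputes the
#' column means, and takes the percentile band.  Seed-reproducible.
#'
#' @param series_matrix n x T matrix: one row per trajectory.
#' @param n_resamples number of resamples (a warning is issued below
#'   100).
#' @param confidence band level.
#' @param seed RNG seed.
#' @return list with `lower` and `upper` length-T vectors.
#' @export
bootstrap_ci <- function(series_matrix, n_resamples = 9999L,
                         confidence = 0.95, seed = 1L) {
  smat <- as.matrix(series_matrix)
  n <- nrow(smat)
  if (n < 2L) stop("need at least 2 trajectories to bootstrap")
  if (n_resamples < 100L) warning("fewer than 100 bootstrap resamples")
  alpha <- (1 - confidence) / 2
  means <- with_local_seed(seed, {
    t(vapply(seq_len(n_resamples), function(b)
      colMeans(smat[sample.int(n, n, replace = TRUE), , drop = FALSE]),
      numeric(ncol(smat))))
  })
  list(lower = apply(means, 2, stats::quantile, probs = alpha, names = FALSE),
       upper = apply(means, 2, stats::quantile, probs = 1 - alpha,
                     names = FALSE))
}

#' Ensemble-mean interatomic distance time series
#'
#' E.g. the mean donor-acceptor oxygen-oxygen distance after
#' photoexcitation, whose initial contraction gates the proton transfer.
#'
#' @param trajectories list of `trajectory` objects on a shared time
#'   base.
#' @param a,b atom indices, or label names (e.g. `"O1"`, `"O2"`) resolved
#'   on each frame.
#' @return data.frame with columns `time` and `mean_distance` (Angstrom).
#' @export
mean_distance_series <- function(trajectories, a = "O1", b = "O2") {
  times <- trajectories[[1]]$times
  dser <- vapply(trajectories, function(tr) {
    if (length(tr$times) != length(times)) stop("shared time base required")
    vapply(tr$frames, function(g) {
      ia <- if (is.character(a)) label_index(g, a) else as.integer(a)
      ib <- if (is.character(b)) label_index(g, b) else as.integer(b)
      sqrt(sum((g$xyz[ia, ] - g$xyz[ib, ])^2))
    }, 0)
  }, numeric(length(times)))
  data.frame(time = times, mean_distance = rowMeans(as.matrix(dser)))
}

#' Potential-energy profile along a supplied geometry series
#'
#' Evaluates per-state energies for each geometry of a path (e.g. a
#' proton-transfer scan at fixed d_OO) on an ML model or any energy
#' evaluator.  Geometry optimization is out of scope: the profile is
#' taken on the geometries as given.
#'
#' @param surface an [mshk_model()], `msks_map`, or a function
#'   (geometry -> named per-state energy vector).
#' @param geometries list of [geometry()]s defining the path.
#' @return data.frame: one row per path point with one energy column per
#'   state plus `extrapolated` (model inputs only).
#' @export
pes_scan <- function(surface, geometries) {
  if (inherits(surface, "mshk_model")) {
    p <- predict_mshk_batch(surface, geometries)
    out <- as.data.frame(p$energies)
    out$extrapolated <- p$extrapolated
    return(out)
  }
  evalf <- if (inherits(surface, "msks_map")) {
    function(g) { p <- predict_msks(surface, g); c(p$energies, extrapolated = p$extrapolated) }
  } else {
    function(g) { e <- surface(g); c(e, extrapolated = NA) }
  }
  rows <- lapply(geometries, evalf)
  out <- as.data.frame(do.call(rbind, rows))
  out$extrapolated <- as.logical(out$extrapolated)
  out
}

#' Barrier height from a proton-transfer energy profile
#'
#' Reactant and product minima are located on the r- > 0 and r- < 0
#' sides; the barrier is the maximum between them minus the reactant-side
#' minimum.  When the profile has a single central minimum (no wells) the
#' construction returns (numerically) zero.
#'
#' @param r_minus r- value of each profile point (Angstrom), descending
#'   or ascending.
#' @param energy corresponding energies (kcal/mol).
#' @return barrier height in kcal/mol (>= 0).
#' @export
barrier_from_profile <- function(r_minus, energy) {
  if (length(r_minus) != length(energy)) stop("length mismatch")
  ord <- order(r_minus)
  r <- r_minus[ord]; e <- energy[ord]
  ipos <- which(r >= 0); ineg <- which(r <= 0)
  if (!length(ipos) || !length(ineg)) stop("profile must span r- = 0")
  i_react <- ipos[which.min(e[ipos])]
  i_prod <- ineg[which.min(e[ineg])]
  span <- min(i_react, i_prod):max(i_react, i_prod)
  max(0, max(e[span]) - e[i_react])
}
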