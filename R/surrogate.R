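#' Analytic multistate surrogate system
#'
#' An analytic stand-in for ab initio reference data: a planar
#' malonaldehyde-like 9-atom molecule (C3O2H4, labelled O1/O2/H) with a
#' closed-form multistate energy surface, analytic forces, and smooth
#' atom-centred Gaussian densities, so that every pipeline stage is
#' trainable and verifiable without any external data.
#'
#' Each electronic state j has
#' `E_j = A_j (d_OO - d_j)^2 + B_j (r-^2 - c_j(d_OO))^2 + proton-confinement
#'  + backbone harmonic network + Delta_j`,
#' with `c_j(d) = s_j (d - g_j)` a linear well-separation function that
#' crosses zero at the state's gating distance `g_j`: for `d_OO > g_j`
#' the proton sees a double well at `r- = +-sqrt(c_j)` with barrier
#' `B_j c_j^2`; below the gating distance the transfer is barrierless.
#' Default parameters put the ground-state equilibrium at
#' `d_OO = 2.57` A with a ~2 kcal/mol barrier, and the target excited
#' state (S2) minimum at 2.40 A with gating distance 2.45 A, so vertical
#' excitation drives an O-O contraction that unlocks the proton transfer.
#'
#' With `crossing = TRUE` the two excited surfaces are built from two
#' diabatic surfaces whose offsets make them intersect along a seam in
#' d_OO running through the thermally sampled region; the adiabatic
#' S1/S2 energies are their pointwise min/max and the densities follow
#' the corresponding diabat.
#'
#' @param crossing enable the S1/S2 crossing parameterization.
#' @param s_dens_heavy,s_dens_hydrogen widths of the atom-centred density
#'   Gaussians (Angstrom).  Hydrogens carry compact densities: a sharper
#'   width (and a transferring-proton weight of ~2 e, the proton plus the
#'   bonding density that follows it) keeps the proton visible in the
#'   density-coefficient metric next to the much heavier C/O clouds.
#' @return an object of class `"surrogate_spec"`.
#' @export
surrogate_spec <- function(crossing = FALSE, s_dens_heavy = 0.5,
                           s_dens_hydrogen = 0.3) {
  xyz <- rbind(
    c(-1.285,  0.910, 0),   # O1 (donor oxygen)
    c( 1.285,  0.910, 0),   # O2 (acceptor oxygen)
    c(-1.220, -0.330, 0),   # C1
    c( 0.000, -1.050, 0),   # C2 (central)
    c( 1.220, -0.330, 0),   # C3
    c( 0.000,  1.250, 0),   # H (transferring)
    c(-2.120, -0.950, 0),   # H1
    c( 0.000, -2.140, 0),   # H2
    c( 2.120, -0.950, 0)    # H3
  )
  template <- geometry(c(8, 8, 6, 6, 6, 1, 1, 1, 1), xyz,
                       labels = c(O1 = 1, O2 = 2, H = 6))
  permutation <- c(2L, 1L, 5L, 4L, 3L, 6L, 9L, 8L, 7L)
  pairs <- rbind(
    c(1, 3), c(3, 4), c(4, 5), c(5, 2),       # backbone bonds
    c(3, 7), c(4, 8), c(5, 9),                # C-H bonds
    c(1, 4), c(2, 4), c(3, 5),                # 1-3 backbone pairs
    c(7, 4), c(9, 4), c(8, 3), c(8, 5)        # C-H angle pairs
  )
  ref_d <- sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2))
  ## realistic bond-network stiffness for the heavy-atom skeleton keeps
  ## thermal strains near 0.05 A (so the external-potential metric is not
  ## swamped by backbone noise); pairs involving a hydrogen are softer,
  ## keeping the fastest modes integrable at the 0.25 fs timestep
  pair_k <- ifelse(pairs[, 1] >= 7L | pairs[, 2] >= 7L, 150, 250)
  z <- template$z
  ## base weights: transferring proton carries ~2 e (proton + bond density)
  w0 <- c(7.5, 7.5, 6, 6, 6, 2, 1, 1, 1)
  weights <- list(
    "0" = w0,
    ## n-pi*-like: deplete the oxygen lone pairs, fill the backbone pi*
    "1" = w0 + c(-0.75, -0.75, 0, 1.5, 0, 0, 0, 0, 0),
    ## pi-pi*-like: deplete the central carbon pi, spread onto ring
    "2" = w0 + c(0.3, 0.3, 0.6, -1.8, 0.6, 0, 0, 0, 0)
  )
  states <- list(
    "0" = list(A = 60, d0 = 2.57, B = 12, s = 1.5, g = 2.30, Delta = 0,
               w = weights[["0"]]),
    "1" = list(A = 60, d0 = 2.62, B = 18, s = 1.5, g = 2.25, Delta = 100,
               w = weights[["1"]]),
    "2" = list(A = 80, d0 = 2.40, B = 14, s = 3.2, g = 2.45, Delta = 122,
               w = weights[["2"]])
  )
  diabats <- NULL
  if (crossing) {
    ## lift the n-pi*-like diabat so the two excited surfaces intersect
    ## along a d_OO seam inside the thermally sampled region (~2.6 A)
    diabats <- list(A = states[["1"]], B = states[["2"]])
    diabats$A$Delta <- 127
  }
  structure(list(template = template, permutation = permutation,
                 states = states, diabats = diabats, crossing = crossing,
                 backbone_pairs = pairs, backbone_ref = ref_d,
                 backbone_k = pair_k, c_plus = 40, delta_plus = 0.09,
                 s_atom = ifelse(z == 1L, s_dens_hydrogen, s_dens_heavy),
                 n_electrons = sum(z)),
            class = "surrogate_spec")
}

#' @export
print.surrogate_spec <- function(x, ...) {
  cat(sprintf("<surrogate_spec> 9-atom planar C3O2H4 model, 3 states%s\n",
              if (x$crossing) " (S1/S2 crossing enabled)" else ""))
  invisible(x)
}

## Internal coordinates used by the analytic surface.
surrogate_internals <- function(spec, g) {
  i1 <- label_index(g, "O1"); i2 <- label_index(g, "O2")
  ih <- label_index(g, "H")
  u12 <- g$xyz[i1, ] - g$xyz[i2, ]
  d <- sqrt(sum(u12^2))
  v1 <- g$xyz[ih, ] - g$xyz[i1, ]; r1 <- sqrt(sum(v1^2))
  v2 <- g$xyz[ih, ] - g$xyz[i2, ]; r2 <- sqrt(sum(v2^2))
  list(i1 = i1, i2 = i2, ih = ih, d = d, r1 = r1, r2 = r2,
       rm = r1 - r2, rp = r1 + r2,
       u12 = u12 / d, e1 = v1 / r1, e2 = v2 / r2)
}

## Backbone harmonic network energy and per-pair strains.
backbone_terms <- function(spec, g) {
  p <- spec$backbone_pairs
  dd <- sqrt(rowSums((g$xyz[p[, 1], , drop = FALSE] -
                      g$xyz[p[, 2], , drop = FALSE])^2))
  list(d = dd, strain = dd - spec$backbone_ref,
       energy = 0.5 * sum(spec$backbone_k * (dd - spec$backbone_ref)^2))
}

## Energy of one diabatic parameter set.
diabat_energy <- function(spec, p, ic, bb) {
  cc <- p$s * (ic$d - p$g)
  p$A * (ic$d - p$d0)^2 + p$B * (ic$rm^2 - cc)^2 +
    0.5 * spec$c_plus * (ic$rp - ic$d - spec$delta_plus)^2 +
    bb$energy + p$Delta
}

## Force (-gradient) of one diabatic parameter set.
diabat_forces <- function(spec, p, g, ic, bb) {
  grad <- matrix(0, n_atoms(g), 3)
  cc <- p$s * (ic$d - p$g)
  q <- ic$rm^2
  gp <- spec$c_plus * (ic$rp - ic$d - spec$delta_plus)
  dE_dd <- 2 * p$A * (ic$d - p$d0) - 2 * p$B * (q - cc) * p$s - gp
  dE_dr1 <- 4 * p$B * (q - cc) * ic$rm + gp
  dE_dr2 <- -4 * p$B * (q - cc) * ic$rm + gp
  grad[ic$i1, ] <- grad[ic$i1, ] + dE_dd * ic$u12
  grad[ic$i2, ] <- grad[ic$i2, ] - dE_dd * ic$u12
  grad[ic$ih, ] <- grad[ic$ih, ] + dE_dr1 * ic$e1 + dE_dr2 * ic$e2
  grad[ic$i1, ] <- grad[ic$i1, ] - dE_dr1 * ic$e1
  grad[ic$i2, ] <- grad[ic$i2, ] - dE_dr2 * ic$e2
  pp <- spec$backbone_pairs
  dEdd <- spec$backbone_k * bb$strain
  for (k in seq_len(nrow(pp))) {
    i <- pp[k, 1]; j <- pp[k, 2]
    u <- (g$xyz[i, ] - g$xyz[j, ]) / bb$d[k]
    grad[i, ] <- grad[i, ] + dEdd[k] * u
    grad[j, ] <- grad[j, ] - dEdd[k] * u
  }
  -grad
}

## Resolve the parameter set backing adiabatic state j (crossing-aware).
active_diabat <- function(spec, state, ic, bb) {
  state <- as.integer(state)
  if (!spec$crossing || state == 0L)
    return(spec$states[[as.character(state)]])
  ea <- diabat_energy(spec, spec$diabats$A, ic, bb)
  eb <- diabat_energy(spec, spec$diabats$B, ic, bb)
  lower <- if (ea <= eb) spec$diabats$A else spec$diabats$B
  upper <- if (ea <= eb) spec$diabats$B else spec$diabats$A
  if (state == 1L) lower else upper
}

#' Surrogate per-state energies
#'
#' Closed-form, deterministic energies of all three electronic states at
#' a geometry (kcal/mol).
#'
#' @param spec a [surrogate_spec()].
#' @param g a labelled [geometry()].
#' @return named numeric vector `c(S0 = , S1 = , S2 = )`.
#' @export
surrogate_energies <- function(spec, g) {
  ic <- surrogate_internals(spec, g)
  bb <- backbone_terms(spec, g)
  if (!spec$crossing) {
    e <- vapply(spec$states, function(p) diabat_energy(spec, p, ic, bb), 0)
  } else {
    ea <- diabat_energy(spec, spec$diabats$A, ic, bb)
    eb <- diabat_energy(spec, spec$diabats$B, ic, bb)
    e <- c(diabat_energy(spec, spec$states[["0"]], ic, bb),
           min(ea, eb), max(ea, eb))
  }
  names(e) <- c("S0", "S1", "S2")
  e
}

#' Surrogate analytic forces
#'
#' Exact gradient of [surrogate_energies()] for one state.  For the
#' crossing parameterization the force of the active (lower/upper)
#' diabat is returned.
#'
#' @param spec a [surrogate_spec()].
#' @param g a labelled [geometry()].
#' @param state electronic state index (0, 1 or 2).
#' @return N x 3 force matrix, kcal/(mol Angstrom).
#' @export
surrogate_forces <- function(spec, g, state = 2L) {
  ic <- surrogate_internals(spec, g)
  bb <- backbone_terms(spec, g)
  p <- active_diabat(spec, state, ic, bb)
  diabat_forces(spec, p, g, ic, bb)
}

#' Surrogate surface for the MD engine
#' @param spec a [surrogate_spec()].
#' @param state electronic state index.
#' @return an [md_surface()] with analytic forces.
#' @export
surrogate_surface <- function(spec, state = 2L) {
  state <- as.integer(state)
  md_surface(function(g) surrogate_energies(spec, g)[[state + 1L]],
             function(g) surrogate_forces(spec, g, state),
             id = paste0("S", state))
}

## State-resolved density weights at a geometry (crossing-aware).
surrogate_weights <- function(spec, g, state) {
  ic <- surrogate_internals(spec, g)
  bb <- backbone_terms(spec, g)
  active_diabat(spec, state, ic, bb)$w
}

#' Surrogate electron density on a grid
#'
#' `n_j(r) = sum_a w_(a,j) G(r; R_a, s_dens)` with normalized Gaussians
#' and state-dependent weights summing to the electron count, so that
#' excited-state density differences are nonzero and state-specific.
#' Values are in e/Angstrom^3.
#'
#' @param spec a [surrogate_spec()].
#' @param g a labelled [geometry()].
#' @param state electronic state index.
#' @param grid a [grid_spec()]; warns when it captures less than 99% of
#'   the density mass.
#' @return a [density_field()].
#' @export
surrogate_density <- function(spec, g, state, grid) {
  w <- surrogate_weights(spec, g, state)
  ax <- grid_axes(grid)
  vals <- array(0, dim = grid$shape)
  for (a in seq_len(n_atoms(g))) {
    s2 <- 2 * spec$s_atom[a]^2
    norm <- (2 * pi * spec$s_atom[a]^2)^-1.5
    ex <- exp(-(ax[[1]] - g$xyz[a, 1])^2 / s2)
    ey <- exp(-(ax[[2]] - g$xyz[a, 2])^2 / s2)
    ez <- exp(-(ax[[3]] - g$xyz[a, 3])^2 / s2)
    vals <- vals + (w[a] * norm) * ((ex %o% ey) %o% ez)
  }
  out <- density_field(grid, as.numeric(vals), state)
  if (integrate_density(out) < 0.99 * sum(w))
    warning("grid captures less than 99% of the density mass")
  out
}

#' Fast surrogate density coefficients for many geometries
#'
#' Exploits the separability of atom-centred Gaussians: the Fourier
#' coefficients of each atom's density are an outer product of per-axis
#' 1D projections, so no grid density is ever materialized.  Numerically
#' identical to `project_density(surrogate_density(...))`.
#'
#' @param spec a [surrogate_spec()].
#' @param geometries list of labelled geometries.
#' @param basis a [basis_spec()].
#' @param states integer vector of states (default 0:2).
#' @return named list (per state) of n x [basis_size()] matrices.
#' @export
surrogate_coefficient_matrix <- function(spec, geometries, basis,
                                         states = 0:2) {
  f <- basis_factors(basis)
  ax <- grid_axes(basis$grid)
  h <- basis$grid$spacing
  l <- basis_size(basis)
  out <- lapply(states, function(st) matrix(0, length(geometries), l))
  names(out) <- as.character(states)
  for (i in seq_along(geometries)) {
    g <- geometries[[i]]
    ## per-atom separable projections (shared across states)
    px <- py <- pz <- vector("list", n_atoms(g))
    norms <- (2 * pi * spec$s_atom^2)^-1.5
    for (a in seq_len(n_atoms(g))) {
      s2 <- 2 * spec$s_atom[a]^2
      px[[a]] <- as.numeric(f[[1]] %*% exp(-(ax[[1]] - g$xyz[a, 1])^2 / s2)) * h
      py[[a]] <- as.numeric(f[[2]] %*% exp(-(ax[[2]] - g$xyz[a, 2])^2 / s2)) * h
      pz[[a]] <- as.numeric(f[[3]] %*% exp(-(ax[[3]] - g$xyz[a, 3])^2 / s2)) * h
    }
    for (st in states) {
      w <- surrogate_weights(spec, g, st)
      u <- array(0, basis$per_axis)
      for (a in seq_len(n_atoms(g)))
        u <- u + (w[a] * norms[a]) * ((px[[a]] %o% py[[a]]) %o% pz[[a]])
      out[[as.character(st)]][i, ] <- as.numeric(u)
    }
  }
  out
}

#' Closed-form surrogate proton-transfer barrier
#'
#' The definitive oracle for profile-recovery tests:
#' `b_j(d_OO) = B_j c_j(d_OO)^2` when `c_j > 0`, zero below the gating
#' distance.
#'
#' @param spec a [surrogate_spec()].
#' @param state electronic state index.
#' @param d_oo oxygen-oxygen distance(s), Angstrom.
#' @return barrier height(s), kcal/mol.
#' @export
surrogate_barrier <- function(spec, state, d_oo) {
  p <- spec$states[[as.character(as.integer(state))]]
  cc <- pmax(p$s * (d_oo - p$g), 0)
  p$B * cc^2
}

#' Construct a proton-transfer scan geometry
#'
#' Backbone at the template, oxygens placed symmetrically at the given
#' d_OO, and the transferring proton positioned (in-plane) to realize
#' the requested r- with the proton-confinement coordinate at its rest
#' value r+ = d_OO + delta.
#'
#' @param spec a [surrogate_spec()].
#' @param d_oo oxygen-oxygen distance, Angstrom.
#' @param r_minus proton-transfer coordinate, Angstrom.
#' @param r_plus optional override of r_HO1 + r_HO2.
#' @return a labelled [geometry()].
#' @export
make_scan_geometry <- function(spec, d_oo, r_minus,
                               r_plus = d_oo + spec$delta_plus) {
  g <- spec$template
  y_o <- g$xyz[1, 2]
  g$xyz[1, ] <- c(-d_oo / 2, y_o, 0)
  g$xyz[2, ] <- c(d_oo / 2, y_o, 0)
  r1 <- (r_plus + r_minus) / 2
  r2 <- (r_plus - r_minus) / 2
  x <- (r1^2 - r2^2) / (2 * d_oo)
  h2 <- r1^2 - (x + d_oo / 2)^2
  if (h2 < 0) stop("infeasible (d_oo, r_minus, r_plus) combination")
  g$xyz[6, ] <- c(x, y_o + sqrt(h2), 0)
  g
}

#' Randomly perturbed surrogate geometries
#'
#' Template plus independent Gaussian jitter (smaller out of plane);
#' cheap thermal-like configurations for symmetry and regression tests.
#'
#' @param spec a [surrogate_spec()].
#' @param n number of geometries.
#' @param seed RNG seed.
#' @param sigma_xy,sigma_z in-plane / out-of-plane jitter, Angstrom.
#' @param d_oo,r_minus optional base values passed to
#'   [make_scan_geometry()] (vectors are recycled over `n`).
#' @return list of labelled geometries.
#' @export
random_surrogate_geometries <- function(spec, n, seed = 1L, sigma_xy = 0.05,
                                        sigma_z = 0.02, d_oo = NULL,
                                        r_minus = NULL) {
  base <- if (is.null(d_oo)) rep(list(spec$template), n)
          else mapply(make_scan_geometry, rep_len(d_oo, n),
                      rep_len(r_minus, n), MoreArgs = list(spec = spec),
                      SIMPLIFY = FALSE)
  with_local_seed(seed, lapply(base, function(g) {
    g$xyz <- g$xyz + cbind(matrix(stats::rnorm(2 * n_atoms(g), 0, sigma_xy),
                                  n_atoms(g), 2),
                           stats::rnorm(n_atoms(g), 0, sigma_z))
    g
  }))
}

#' Generate a full surrogate reference dataset
#'
#' Emulates the reference data generation protocol: a canonical (300 K)
#' Langevin ground-state trajectory sampled every `gs_sample_fs`, from
#' which `n_gs_frames` ground-state frames are taken and vertical
#' excitations are launched every 100 fs to seed `n_es_trajectories`
#' restrained NVE trajectories on the target excited surface, recorded
#' every timestep (`es_steps` frames each, 0.25 fs).  Per-state energies
#' for all three states are attached to every frame.  The whole
#' construction is bit-reproducible for a fixed seed.
#'
#' @param spec a [surrogate_spec()].
#' @param n_gs_frames ground-state frames (default 2000).
#' @param n_es_trajectories excited-state trajectories (default 30).
#' @param seed RNG seed.
#' @param es_steps NVE steps (= recorded frames) per excited trajectory
#'   (default 480, i.e. 120 fs at 0.25 fs).
#' @param target_state excited surface for the NVE runs (default 2).
#' @param gs_sample_fs spacing of recorded ground-state frames, fs.
#' @param dt_gs,dt_es timesteps, fs.
#' @param temperature,friction Langevin parameters.
#' @param restraint planarity [restraint_spec()] applied to both
#'   samplers (the surrogate system, like the molecule it emulates, is
#'   intrinsically planar).
#' @param burn_in_steps discarded equilibration steps.
#' @return an object of class `"surrogate_dataset"`: `geometries`
#'   (gs frames then es frames), `energies` (n x 3, columns "0","1","2"),
#'   `provenance` (`source`, `traj`, `frame`), `es_trajectories` (the
#'   `trajectory` objects), `gs_trajectory`, `spec`, `seed`.
#' @export
generate_reference_dataset <- function(spec, n_gs_frames = 2000L,
                                       n_es_trajectories = 30L, seed = 7L,
                                       es_steps = 480L, target_state = 2L,
                                       gs_sample_fs = 10, dt_gs = 0.5,
                                       dt_es = 0.25, temperature = 300,
                                       friction = 0.01,
                                       restraint = restraint_spec(),
                                       burn_in_steps = 2000L) {
  s0 <- surrogate_surface(spec, 0L)
  start <- make_scan_geometry(spec, 2.57, 0.52)
  record_every <- max(1L, round(gs_sample_fs / dt_gs))
  burn <- langevin_gs_sampler(s0, md_state(start), temperature, friction,
                              dt_gs, burn_in_steps, seed = seed,
                              restraint = restraint,
                              record_every = burn_in_steps)
  nb <- length(burn$times)
  eq_state <- md_state(burn$frames[[nb]], burn$velocities[[nb]])
  n_steps <- max(n_gs_frames * record_every,
                 ceiling(n_es_trajectories * 100 / dt_gs))
  gs <- langevin_gs_sampler(s0, eq_state, temperature, friction, dt_gs,
                            n_steps, seed = seed + 1L,
                            restraint = restraint,
                            record_every = record_every)
  gs_frames <- gs$frames[-1][seq_len(n_gs_frames)]
  inits <- vertical_excitation_initial_conditions(gs, 100, target_state)
  inits <- inits[seq_len(n_es_trajectories)]
  s_es <- surrogate_surface(spec, target_state)
  es_traj <- lapply(inits, function(st)
    velocity_verlet_run(s_es, st, dt_es, es_steps, restraint = restraint))
  es_frames <- unlist(lapply(es_traj, function(tr) tr$frames[-1]),
                      recursive = FALSE)
  geometries <- c(gs_frames, es_frames)
  energies <- t(vapply(geometries, function(g) surrogate_energies(spec, g),
                       numeric(3)))
  colnames(energies) <- c("0", "1", "2")
  prov <- data.frame(
    source = c(rep("gs", n_gs_frames),
               rep("es", n_es_trajectories * es_steps)),
    traj = c(rep(0L, n_gs_frames),
             rep(seq_len(n_es_trajectories), each = es_steps)),
    frame = c(seq_len(n_gs_frames),
              rep(seq_len(es_steps), n_es_trajectories))
  )
  structure(list(geometries = geometries, energies = energies,
                 provenance = prov, es_trajectories = es_traj,
                 gs_trajectory = gs, spec = spec, seed = seed),
            class = "surrogate_dataset")
}

#' @export
print.surrogate_dataset <- function(x, ...) {
  cat(sprintf("<surrogate_dataset> %d frames (%d gs + %d es), seed %d\n",
              length(x$geometries), sum(x$provenance$source == "gs"),
              sum(x$provenance$source == "es"), x$seed))
  invisible(x)
}

#' Attach surrogate reference data to a training set
#'
#' Computes per-state surrogate energies and Fourier density
#' coefficients for the geometries of a [build_training_set()] result
#' (or any list of labelled geometries).
#'
#' @param x a `training_set` or list of geometries.
#' @param spec a [surrogate_spec()].
#' @param basis a [basis_spec()].
#' @param states integer vector of states (default 0:2).
#' @return list with `energies` (n x length(states), columns named by
#'   state) and `coefficients` (named list of n x L matrices).
#' @export
attach_reference_data <- function(x, spec, basis, states = 0:2) {
  geometries <- if (inherits(x, "training_set")) x$geometries else x
  energies <- t(vapply(geometries, function(g) surrogate_energies(spec, g),
                       numeric(3)))
  colnames(energies) <- c("0", "1", "2")
  list(energies = energies[, as.character(states), drop = FALSE],
       coefficients = surrogate_coefficient_matrix(spec, geometries, basis,
                                                   states))
}
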