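#' Planarity restraint specification
#'
#' Harmonic restraint `V = sum_a 1/2 k_a z_a^2` that keeps the molecule
#' in the xy plane of the aligned frame, suppressing the out-of-plane
#' torsions that would otherwise carry the system toward electronic
#' state crossings.  Force constants are given per element class in the
#' conventional kcal/(mol bohr^2) and converted to the internal
#' kcal/(mol Angstrom^2) at construction.
#'
#' @param k_hydrogen force constant for hydrogens, kcal/(mol bohr^2)
#'   (default 9).
#' @param k_heavy force constant for heavy atoms, kcal/(mol bohr^2)
#'   (default 40).
#' @return an object of class `"restraint_spec"`.
#' @export
restraint_spec <- function(k_hydrogen = 9, k_heavy = 40) {
  if (k_hydrogen < 0 || k_heavy < 0) stop("force constants must be >= 0")
  structure(list(k_hydrogen_bohr = k_hydrogen, k_heavy_bohr = k_heavy,
                 k_hydrogen = k_hydrogen / .bohr^2,
                 k_heavy = k_heavy / .bohr^2),
            class = "restraint_spec")
}

restraint_constants <- function(g, restraint) {
  ifelse(g$z == 1L, restraint$k_hydrogen, restraint$k_heavy)
}

#' Planarity restraint energy and forces
#'
#' @param g a [geometry()] in the aligned frame (z perpendicular to the
#'   molecular plane).
#' @param restraint a [restraint_spec()].
#' @return list with `energy` (kcal/mol) and `forces` (N x 3,
#'   kcal/(mol Angstrom); only the z column is nonzero).
#' @export
restraint_energy_forces <- function(g, restraint) {
  ka <- restraint_constants(g, restraint)
  z <- g$xyz[, 3]
  f <- matrix(0, n_atoms(g), 3)
  f[, 3] <- -ka * z
  list(energy = sum(0.5 * ka * z^2), forces = f)
}

#' Central-difference forces on an energy surface
#'
#' `F_i = -(E(x + dx e_i) - E(x - dx e_i)) / (2 dx)` for all 3N Cartesian
#' components (6N energy evaluations).
#'
#' @param energy_fun function taking a [geometry()] and returning a
#'   scalar energy in kcal/mol.
#' @param g the [geometry()] at which to differentiate.
#' @param dx displacement step in Angstrom (default 0.001).
#' @return N x 3 force matrix, kcal/(mol Angstrom).
#' @export
numerical_forces <- function(energy_fun, g, dx = 0.001) {
  if (dx <= 0) stop("dx must be positive")
  n <- n_atoms(g)
  f <- matrix(0, n, 3)
  for (a in seq_len(n)) for (c in 1:3) {
    gp <- g; gp$xyz[a, c] <- gp$xyz[a, c] + dx
    gm <- g; gm$xyz[a, c] <- gm$xyz[a, c] - dx
    ep <- energy_fun(gp); em <- energy_fun(gm)
    if (!is.finite(ep) || !is.finite(em))
      stop("non-finite energy at displacement of atom ", a, ", axis ", c)
    f[a, c] <- -(ep - em) / (2 * dx)
  }
  f
}

#' Construct a potential-energy surface for the MD engine
#'
#' A surface bundles an energy function with a force provider: analytic
#' forces when available, otherwise central differences at step `dx`.
#'
#' @param energy_fun function(geometry) -> energy (kcal/mol).
#' @param forces_fun optional function(geometry) -> N x 3 forces; when
#'   `NULL`, forces come from [numerical_forces()].
#' @param dx central-difference step (Angstrom) for numerical forces.
#' @param id free-form surface identifier (e.g. `"S2"`).
#' @return an object of class `"md_surface"`.
#' @export
md_surface <- function(energy_fun, forces_fun = NULL, dx = 0.001, id = NULL) {
  structure(list(energy = energy_fun, forces = forces_fun, dx = dx, id = id),
            class = "md_surface")
}

surface_eval <- function(surface, g, restraint = NULL) {
  e <- surface$energy(g)
  f <- if (is.null(surface$forces)) numerical_forces(surface$energy, g, surface$dx)
       else surface$forces(g)
  er <- 0
  if (!is.null(restraint)) {
    r <- restraint_energy_forces(g, restraint)
    er <- r$energy
    f <- f + r$forces
  }
  list(epot = e, erest = er, forces = f)
}

#' MD state (one snapshot)
#'
#' @param g a [geometry()].
#' @param velocities N x 3 matrix, Angstrom/fs.
#' @param masses per-atom masses in amu (default from atomic numbers).
#' @param time simulation time, fs.
#' @return an object of class `"md_state"`.
#' @export
md_state <- function(g, velocities = NULL, masses = atomic_masses(g$z),
                     time = 0) {
  if (is.null(velocities)) velocities <- matrix(0, n_atoms(g), 3)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == dim(g$xyz))) stop("velocity shape mismatch")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(geometry = g, velocities = velocities, masses = masses,
                 time = time), class = "md_state")
}

#' Kinetic energy of an MD state
#' @param state an [md_state()].
#' @return kcal/mol.
#' @export
kinetic_energy <- function(state) {
  0.5 * sum(state$masses * rowSums(state$velocities^2)) * .kcal_per_mass_vel2
}

new_trajectory <- function(dt, surface_id, restraint, seed = NULL) {
  structure(list(times = numeric(0), frames = list(), velocities = list(),
                 epot = numeric(0), ekin = numeric(0), erest = numeric(0),
                 etot = numeric(0), dt = dt, surface_id = surface_id,
                 restraint = restraint, seed = seed),
            class = "trajectory")
}

traj_append <- function(traj, state, ev) {
  i <- length(traj$times) + 1L
  traj$times[i] <- state$time
  traj$frames[[i]] <- state$geometry
  traj$velocities[[i]] <- state$velocities
  traj$epot[i] <- ev$epot
  traj$erest[i] <- ev$erest
  traj$ekin[i] <- kinetic_energy(state)
  traj$etot[i] <- ev$epot + ev$erest + traj$ekin[i]
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, dt = %g fs, surface %s\n",
              length(x$times), x$dt,
              if (is.null(x$surface_id)) "?" else x$surface_id))
  invisible(x)
}

#' Energy log of a trajectory
#' @param x a `trajectory`.
#' @param ... unused.
#' @return data.frame with columns time, epot, ekin, erest, etot.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, epot = x$epot, ekin = x$ekin,
             erest = x$erest, etot = x$etot)
}

#' Microcanonical (NVE) velocity Verlet propagation
#'
#' Standard velocity Verlet at a fixed timestep; the total energy
#' (surface + restraint + kinetic) is recorded every stored frame.
#' Internal units: Angstrom, fs, amu, kcal/mol.
#'
#' @param surface an [md_surface()].
#' @param initial an [md_state()].
#' @param dt timestep in fs (default 0.25).
#' @param n_steps number of steps.
#' @param restraint optional [restraint_spec()].
#' @param record_every store every this-many steps (default 1; the
#'   initial state is always frame 1).
#' @return a `"trajectory"` object.
#' @export
velocity_verlet_run <- function(surface, initial, dt = 0.25, n_steps,
                                restraint = NULL, record_every = 1L) {
  state <- initial
  ev <- surface_eval(surface, state$geometry, restraint)
  traj <- new_trajectory(dt, surface$id, restraint)
  traj <- traj_append(traj, state, ev)
  inv_m <- .kcal_per_mass_vel2^-1 / state$masses   # (kcal/mol/A) -> amu A/fs^2
  acc <- ev$forces * inv_m
  for (s in seq_len(n_steps)) {
    state$geometry$xyz <- state$geometry$xyz + dt * state$velocities +
      0.5 * dt^2 * acc
    ev <- surface_eval(surface, state$geometry, restraint)
    acc_new <- ev$forces * inv_m
    state$velocities <- state$velocities + 0.5 * dt * (acc + acc_new)
    acc <- acc_new
    state$time <- state$time + dt
    if (s %% record_every == 0L) traj <- traj_append(traj, state, ev)
  }
  traj
}

#' Energy-conservation diagnostics of an NVE trajectory
#'
#' Symplectic integrators such as velocity Verlet conserve a shadow
#' Hamiltonian: the recorded total energy shows a bounded O(dt^2)
#' oscillation but no systematic trend.  Two observables separate the
#' two effects: `energy_drift()` is the secular drift — the magnitude of
#' the linear trend of E_tot(t) accumulated over the run — and
#' `energy_fluctuation()` is the maximum deviation from the initial
#' total energy (dominated by the bounded shadow oscillation, which
#' shrinks by ~4x when the timestep is halved).  Both are in kcal/mol;
#' divide by the mean kinetic energy for a relative figure.
#'
#' @param traj a `trajectory` from [velocity_verlet_run()].
#' @return scalar, kcal/mol.
#' @export
energy_drift <- function(traj) {
  fit <- stats::lm.fit(cbind(1, traj$times), traj$etot)
  abs(fit$coefficients[2]) * diff(range(traj$times))
}

#' @rdname energy_drift
#' @export
energy_fluctuation <- function(traj) max(abs(traj$etot - traj$etot[1]))

#' Vertical-excitation initial conditions from a ground-state trajectory
#'
#' Takes snapshots (positions and velocities unchanged — a vertical
#' excitation) every `interval_fs`, starting at `interval_fs`, and tags
#' them with the target electronic surface.
#'
#' @param gs_trajectory a ground-state `trajectory`.
#' @param interval_fs spacing between excitations (default 100 fs).
#' @param target_state electronic state index the dynamics will run on
#'   (default 2).
#' @return list of [md_state()]s, each with attribute `"target_state"`.
#' @export
vertical_excitation_initial_conditions <- function(gs_trajectory,
                                                   interval_fs = 100,
                                                   target_state = 2L) {
  times <- gs_trajectory$times
  if (length(times) < 2L) stop("ground-state trajectory is empty or trivial")
  total <- max(times)
  if (total < interval_fs)
    stop("trajectory shorter than the excitation interval")
  picks <- seq(interval_fs, total, by = interval_fs)
  idx <- vapply(picks, function(t0) which.min(abs(times - t0)), 0L)
  lapply(idx, function(i) {
    st <- md_state(gs_trajectory$frames[[i]], gs_trajectory$velocities[[i]],
                   time = 0)
    attr(st, "target_state") <- as.integer(target_state)
    st
  })
}

#' Canonical (NVT) sampling by Langevin dynamics
#'
#' BAOAB-discretized Langevin dynamics: an inexpensive canonical sampler
#' used to emulate a thermostatted ground-state trajectory on the
#' surrogate surface.  Fully reproducible for a fixed seed.
#'
#' @param surface an [md_surface()].
#' @param initial an [md_state()]; zero velocities are resampled from the
#'   Maxwell-Boltzmann distribution at `temperature`.
#' @param temperature target temperature, K (default 300).
#' @param friction friction coefficient, 1/fs (default 0.01).
#' @param dt timestep, fs (default 0.5).
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param restraint optional [restraint_spec()].
#' @param record_every store every this-many steps.
#' @return a `"trajectory"`.
#' @export
langevin_gs_sampler <- function(surface, initial, temperature = 300,
                                friction = 0.01, dt = 0.5, n_steps,
                                seed = 1L, restraint = NULL,
                                record_every = 1L) {
  if (temperature <= 0) stop("temperature must be positive")
  kt <- .kb_kcal * temperature / .kcal_per_mass_vel2  # amu A^2/fs^2
  with_local_seed(seed, {
    state <- initial
    n <- n_atoms(state$geometry)
    if (all(state$velocities == 0))
      state$velocities <- matrix(stats::rnorm(3 * n), n, 3) *
        sqrt(kt / state$masses)
    ev <- surface_eval(surface, state$geometry, restraint)
    traj <- new_trajectory(dt, surface$id, restraint, seed)
    traj <- traj_append(traj, state, ev)
    inv_m <- .kcal_per_mass_vel2^-1 / state$masses
    acc <- ev$forces * inv_m
    c1 <- exp(-friction * dt)
    c2 <- sqrt(1 - c1^2)
    sig <- sqrt(kt / state$masses)
    for (s in seq_len(n_steps)) {
      state$velocities <- state$velocities + 0.5 * dt * acc          # B
      state$geometry$xyz <- state$geometry$xyz + 0.5 * dt * state$velocities  # A
      state$velocities <- c1 * state$velocities +
        c2 * sig * matrix(stats::rnorm(3 * n), n, 3)                 # O
      state$geometry$xyz <- state$geometry$xyz + 0.5 * dt * state$velocities  # A
      ev <- surface_eval(surface, state$geometry, restraint)
      acc <- ev$forces * inv_m
      state$velocities <- state$velocities + 0.5 * dt * acc          # B
      state$time <- state$time + dt
      if (s %% record_every == 0L) traj <- traj_append(traj, state, ev)
    }
    traj
  })
}

#' Write trajectory frames as extended XYZ
#'
#' One frame per stored step, with the per-frame energies in the comment
#' line (`time=.. epot=.. ekin=.. erest=.. etot=..`).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  comments <- sprintf("time=%.4f epot=%.8f ekin=%.8f erest=%.8f etot=%.8f",
                      traj$times, traj$epot, traj$ekin, traj$erest, traj$etot)
  write_xyz(traj$frames, path, comments)
}
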