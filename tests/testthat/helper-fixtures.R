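# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small centred grids used throughout
tiny_grid <- function() default_grid(shape = c(16, 14, 10), spacing = 0.5)
basis_grid <- function() default_grid(shape = c(40, 34, 20), spacing = 0.3)

# odd per-axis counts keep complete cos/sin pairs (mirror equivariance)
model_basis <- function() basis_spec(basis_grid(), c(13, 13, 13))

# descriptor grids: coarse for clustering, stride-2 for small models
cluster_grid <- function() coarsen_grid(default_grid(), 4L)
descriptor_grid <- function() coarsen_grid(default_grid(), 2L)

surrogate_fixture <- function() fixture("spec", surrogate_spec())

# a small reference dataset: 60 GS frames + 2 ES trajectories x 200 steps
small_dataset <- function() fixture("small_dataset",
  generate_reference_dataset(surrogate_fixture(), n_gs_frames = 60L,
                             n_es_trajectories = 2L, seed = 11L,
                             es_steps = 200L))

# 50 canonicalized geometries spanning the small dataset
small_geometries <- function() fixture("small_geometries", {
  spec <- surrogate_fixture()
  ds <- small_dataset()
  idx <- round(seq(1, length(ds$geometries), length.out = 50))
  canonicalize(ds$geometries[idx], spec$template, spec$permutation)$geometries
})

# a small end-to-end MSHK model trained on the 50 geometries (tiny ridge)
small_model <- function() fixture("small_model", {
  spec <- surrogate_fixture()
  geoms <- small_geometries()
  basis <- model_basis()
  ref <- attach_reference_data(geoms, spec, basis)
  x <- potential_matrix(geoms, descriptor_grid(), 0.2)
  sv <- median_heuristic(x)
  su <- median_heuristic(do.call(rbind, ref$coefficients)) / 2
  dmap <- train_density_map(x, ref$coefficients, sv, 1e-12)
  efun <- train_energy_functional(ref$coefficients, ref$energies, su, 1e-12)
  model <- mshk_model(dmap, efun, spec$template, descriptor_grid(), basis, 0.2)
  list(model = model, ref = ref, geometries = geoms, x = x)
})

# trajectory with a prescribed r-(t) series (for response-function tests)
traj_from_r <- function(r_series, dt = 1) {
  spec <- surrogate_fixture()
  frames <- lapply(r_series, function(r) make_scan_geometry(spec, 2.5, r))
  structure(list(times = (seq_along(r_series) - 1) * dt, frames = frames),
            class = "trajectory")
}
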