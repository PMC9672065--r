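#' Default run configuration
#'
#' All tunables with their production defaults: the 60 x 50 x 30 grid at
#' 0.2 Angstrom, sigma_pot = 0.2 Angstrom, 50 Fourier modes per axis,
#' 0.25 fs NVE timestep, dx = 0.001 Angstrom numerical forces, 9/40
#' kcal/(mol bohr^2) planarity restraints, K-means cluster count 2500,
#' and 95% bootstrap confidence level.
#'
#' @return a nested named list.
#' @export
default_run_config <- function() {
  list(
    grid = list(center = c(0, 0, 0), spacing = 0.2, shape = c(60L, 50L, 30L)),
    potential = list(sigma_pot = 0.2),
    basis = list(per_axis = c(50L, 50L, 50L)),
    kernel = list(sigma_pot_kernel = NULL, sigma_coef_kernel = NULL,
                  lambda = 1e-10),
    dataset = list(k = 2500L, nstart = 3L, clustering_stride = 2L,
                   pca_tol = 1e-6),
    md = list(dt = 0.25, dx = 0.001, steps = 240L,
              restraint_k_hydrogen = 9, restraint_k_heavy = 40),
    sampling = list(temperature = 300, friction = 0.01, dt_gs = 0.5,
                    excitation_interval_fs = 100),
    analysis = list(bootstrap_confidence = 0.95, n_resamples = 9999L),
    seed = 1L
  )
}

## Recursively overlay user values on the defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  for (nm in names(user))
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected by name; every omitted key takes its
#' documented default from [default_run_config()].
#'
#' @param path YAML file; `NULL` returns the pure defaults.
#' @return the resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge_config(defaults, user)
}

#' Write a dataset/model manifest
#'
#' Self-describing JSON provenance record (configuration, seeds, sizes,
#' package version) placed next to any artifact written to disk.
#'
#' @param path output JSON file.
#' @param ... named provenance fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  info <- list(package = "mshk",
               version = as.character(utils::packageVersion("mshk")),
               created = format(Sys.time(), tz = "UTC"), ...)
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
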