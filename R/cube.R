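#' Read a Gaussian cube file
#'
#' Standard cube layout: two comment lines; `natoms origin`; three axis
#' lines (`n_points axis_vector`); one line per atom (`Z charge x y z`);
#' then the volumetric data with the last (z) index fastest.  Positive
#' atom counts mean Bohr units (the common convention); a negative atom
#' count flags Angstrom coordinates.  Values read from Bohr-unit files
#' are converted from e/Bohr^3 to the package-internal e/Angstrom^3.
#'
#' Only isotropic, axis-aligned voxels are supported (the package's grids
#' are isotropic by construction).
#'
#' @param path cube file.
#' @param state_index state tag attached to the returned density.
#' @return a list with elements `density` (a [density_field()]) and
#'   `geometry` (a [geometry()]).
#' @export
read_cube <- function(path, state_index = 0L) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("malformed cube file: fewer than 7 lines")
  toks <- function(i) {
    tk <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(tk))
    if (anyNA(v)) stop("cube parse error at line ", i)
    v
  }
  hd <- toks(3)
  natoms <- as.integer(hd[1])
  angstrom <- natoms < 0L
  natoms <- abs(natoms)
  conv <- if (angstrom) 1 else .bohr
  origin <- hd[2:4] * conv
  axes <- lapply(4:6, toks)
  shape <- vapply(axes, function(a) as.integer(a[1]), 0L)
  vecs <- t(vapply(axes, function(a) a[2:4] * conv, numeric(3)))
  if (any(abs(vecs[row(vecs) != col(vecs)]) > 1e-10))
    stop("cube axes are not axis-aligned; unsupported")
  steps <- diag(vecs)
  if (max(abs(steps - steps[1])) > 1e-8)
    stop("cube voxels are anisotropic; unsupported")
  grid <- grid_spec(origin, steps[1], shape)
  at <- t(vapply(7:(6 + natoms), toks, numeric(5)))
  geom <- geometry(as.integer(at[, 1]), at[, 3:5, drop = FALSE] * conv)
  data_lines <- lines[(7 + natoms):length(lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines),
                                                      "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(shape))
    stop("cube data length ", length(vals), " does not match grid size ",
         prod(shape), " (file truncated after line ", 6 + natoms, "?)")
  if (!angstrom) vals <- vals / .bohr^3   # e/Bohr^3 -> e/A^3
  ## cube order is z-fastest; internal order is x-fastest
  arr <- aperm(array(vals, rev(shape)), c(3, 2, 1))
  list(density = density_field(grid, as.numeric(arr), state_index),
       geometry = geom)
}

#' Write a Gaussian cube file
#'
#' Writes in the standard Bohr convention (positive atom count) by
#' default, converting from the internal e/Angstrom^3 to e/Bohr^3.  With
#' `units = "angstrom"` the Angstrom-flagged convention (negative atom
#' count, no conversion) is used; full double precision is written, so an
#' Angstrom-unit write/read cycle round-trips bit-exactly.
#'
#' @param density a [density_field()].
#' @param geometry the molecular [geometry()] to embed.
#' @param path output file.
#' @param comment first header line.
#' @param units `"bohr"` (standard) or `"angstrom"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(density, geometry, path, comment = "mshk density",
                       units = c("bohr", "angstrom")) {
  units <- match.arg(units)
  conv <- if (units == "bohr") .bohr else 1
  nsign <- if (units == "bohr") 1L else -1L
  grid <- density$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, paste0("electron density, e/", units, "^3")), con)
  num <- function(x) sprintf(" %.17E", x)   # 18 significant digits: lossless
  writeLines(paste0(sprintf("%5d", nsign * n_atoms(geometry)),
                    paste(num(grid$origin / conv), collapse = "")), con)
  for (a in 1:3) {
    vec <- c(0, 0, 0)
    vec[a] <- grid$spacing / conv
    writeLines(paste0(sprintf("%5d", grid$shape[a]),
                      paste(num(vec), collapse = "")), con)
  }
  for (i in seq_len(n_atoms(geometry)))
    writeLines(paste0(sprintf("%5d", geometry$z[i]),
                      num(geometry$z[i]),
                      paste(num(geometry$xyz[i, ] / conv), collapse = "")), con)
  arr <- array(density$values * conv^3, grid$shape)
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # z fastest
  nper <- 6L
  idx <- split(seq_along(vals), (seq_along(vals) - 1L) %/% nper)
  writeLines(vapply(idx, function(ii) paste(num(vals[ii]), collapse = ""), ""), con)
  invisible(path)
}
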