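#' Read an (extended) XYZ file
#'
#' Standard XYZ: first line atom count, second line free-form comment,
#' then one `El x y z` line per atom (Angstrom).  Multi-frame files are
#' supported; each frame becomes one [geometry()].
#'
#' @param path file to read.
#' @param labels optional named integer label vector attached to every
#'   frame (e.g. `c(O1 = 1, O2 = 2, H = 6)`).
#' @return a list of [geometry()] objects; each carries its comment line
#'   as attribute `"comment"`.
#' @export
read_xyz <- function(path, labels = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L)
      stop("malformed XYZ at line ", i, ": expected an atom count")
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    el <- vapply(toks, `[[`, "", 1L)
    z <- match(el, .element_symbols)
    if (anyNA(z)) {
      zn <- suppressWarnings(as.integer(el))  # numeric Z also accepted
      z[is.na(z)] <- zn[is.na(z)]
    }
    if (anyNA(z)) stop("unknown element symbol in XYZ frame at line ", i)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    g <- geometry(z, xyz, labels = labels)
    attr(g, "comment") <- comment
    frames[[length(frames) + 1L]] <- g
    i <- i + 2L + n
  }
  frames
}

#' Write geometries to an (extended) XYZ file
#'
#' @param geometries a [geometry()] or list of them.
#' @param path output file.
#' @param comments character vector of per-frame comment lines (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometries, path, comments = "") {
  if (inherits(geometries, "geometry")) geometries <- list(geometries)
  comments <- rep_len(comments, length(geometries))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(geometries)) {
    g <- geometries[[i]]
    writeLines(as.character(n_atoms(g)), con)
    writeLines(comments[i], con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       .element_symbols[g$z],
                       g$xyz[, 1], g$xyz[, 2], g$xyz[, 3]), con)
  }
  invisible(path)
}
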