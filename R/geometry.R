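#' Molecular geometry
#'
#' A single molecular conformation: atomic numbers, Cartesian coordinates
#' in Angstrom, and optional per-atom role labels.  The labels `O1`, `O2`
#' and `H` mark the donor oxygen, acceptor oxygen and transferring proton
#' and are required by [proton_transfer_coordinate()].
#'
#' @param atomic_numbers integer vector of nuclear charges Z (one per atom).
#' @param coordinates N x 3 numeric matrix of positions in Angstrom.
#' @param labels optional named integer vector mapping role tags (e.g.
#'   `c(O1 = 1, O2 = 2, H = 6)`) to atom indices.
#' @return an object of class `"geometry"`.
#' @examples
#' g <- geometry(c(8, 1), rbind(c(0, 0, 0), c(0.97, 0, 0)))
#' @export
geometry <- function(atomic_numbers, coordinates, labels = NULL) {
  z <- as.integer(atomic_numbers)
  xyz <- as.matrix(coordinates)
  if (length(z) < 1L) stop("empty geometry: at least one atom required")
  if (any(z < 1L)) stop("atomic numbers must be positive integers")
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != length(z))
    stop("coordinates must be an N x 3 numeric matrix matching atomic_numbers")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  dimnames(xyz) <- NULL
  structure(
    list(z = z, xyz = xyz, labels = validate_labels(labels, length(z))),
    class = "geometry"
  )
}

validate_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  idx <- as.integer(labels)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a named integer vector of atom indices")
  if (any(idx < 1L | idx > n)) stop("label index out of range")
  names(idx) <- names(labels)
  idx
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atoms", length(x$z)))
  if (!is.null(x$labels))
    cat("  labels:", paste(names(x$labels), x$labels, sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}

n_atoms <- function(g) length(g$z)

#' Look up a labelled atom index
#' @param g a [geometry()].
#' @param label role tag, e.g. `"O1"`.
#' @return integer atom index.
#' @export
label_index <- function(g, label) {
  if (is.null(g$labels) || !label %in% names(g$labels))
    stop("geometry is missing required atom label '", label, "'")
  unname(g$labels[[label]])
}

#' Proton-transfer coordinate r- = r_HO1 - r_HO2
#'
#' Difference of the transferring proton's distances to the donor and
#' acceptor oxygens.  Its sign encodes the reaction basin (reactant vs
#' product); it is zero at the symmetric transition state.
#'
#' @param g a labelled [geometry()] with `O1`, `O2` and `H` tags.
#' @return the coordinate in Angstrom.
#' @export
proton_transfer_coordinate <- function(g) {
  h <- g$xyz[label_index(g, "H"), ]
  o1 <- g$xyz[label_index(g, "O1"), ]
  o2 <- g$xyz[label_index(g, "O2"), ]
  sqrt(sum((h - o1)^2)) - sqrt(sum((h - o2)^2))
}

#' Donor-acceptor oxygen-oxygen distance
#' @param g a labelled [geometry()].
#' @return d_OO in Angstrom.
#' @export
oo_distance <- function(g) {
  o1 <- g$xyz[label_index(g, "O1"), ]
  o2 <- g$xyz[label_index(g, "O2"), ]
  sqrt(sum((o1 - o2)^2))
}

#' Weighted RMSD between two geometries (no fitting)
#' @param g,reference geometries with matching atoms.
#' @param weights per-atom weights; defaults to heavy atoms only.
#' @return root-mean-square deviation in Angstrom.
#' @export
rmsd <- function(g, reference, weights = NULL) {
  w <- alignment_weights(g, weights)
  d2 <- rowSums((g$xyz - reference$xyz)^2)
  sqrt(sum(w * d2) / sum(w))
}

alignment_weights <- function(g, weights) {
  if (is.null(weights)) weights <- as.numeric(g$z > 1L)
  if (length(weights) != n_atoms(g) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum, one per atom")
  weights
}

#' Rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation (det = +1) and translation minimizing the
#' weighted RMSD of `g` onto `reference`, and returns the transformed
#' geometry.  The default weighting uses heavy atoms only, so the mobile
#' transferring proton cannot skew the molecular frame.
#'
#' @param g geometry to move.
#' @param reference target geometry; same atom count and element order.
#' @param weights optional per-atom weights.
#' @return the aligned [geometry()], with attributes `rotation`,
#'   `translation` (applied as `x %*% rotation + translation`) and `rmsd`.
#' @export
kabsch_align <- function(g, reference, weights = NULL) {
  if (n_atoms(g) != n_atoms(reference) || !all(g$z == reference$z))
    stop("geometry and reference must have identical atom counts and element order")
  w <- alignment_weights(g, weights)
  wn <- w / sum(w)
  cg <- colSums(g$xyz * wn)
  cr <- colSums(reference$xyz * wn)
  x <- sweep(g$xyz, 2, cg)
  y <- sweep(reference$xyz, 2, cr)
  h <- crossprod(x * wn, y)          # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  new_xyz <- x %*% rot
  new_xyz <- sweep(new_xyz, 2, cr, "+")
  out <- g
  out$xyz <- new_xyz
  attr(out, "rotation") <- rot
  attr(out, "translation") <- cr - as.numeric(cg %*% rot)
  attr(out, "rmsd") <- sqrt(sum(wn * rowSums((new_xyz - reference$xyz)^2)))
  out
}

#' Mirror a geometry in a symmetry plane
#'
#' Mirrors the coordinates across the plane through the aligned-frame
#' origin perpendicular to the given axis, then reapplies the atom
#' permutation pairing symmetry-equivalent atoms (e.g. O1 <-> O2 for the
#' sigma-v' plane of a planar C2v molecule).  Applying the operation twice
#' returns the input.
#'
#' @param g a [geometry()] already expressed in the aligned frame.
#' @param permutation integer vector: atom `i` of the output takes the
#'   (mirrored) coordinates of atom `permutation[i]`.  Must be an
#'   involution and preserve element identity.
#' @param axis which coordinate axis is perpendicular to the mirror plane
#'   (`"x"`, `"y"` or `"z"`).
#' @return the reflected [geometry()]; labels are retained.
#' @export
reflect_geometry <- function(g, permutation, axis = "x") {
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  p <- as.integer(permutation)
  n <- n_atoms(g)
  if (length(p) != n || !all(sort(p) == seq_len(n)))
    stop("permutation must be a permutation of 1..N")
  if (!all(p[p] == seq_len(n)))
    stop("permutation must be an involution (its own inverse)")
  if (!all(g$z[p] == g$z))
    stop("permutation must pair atoms of identical element")
  xyz <- g$xyz
  xyz[, ax] <- -xyz[, ax]
  out <- g
  out$xyz <- xyz[p, , drop = FALSE]
  out
}

#' All interatomic distances of a geometry
#' @param g a [geometry()].
#' @return an N x N symmetric distance matrix in Angstrom.
#' @export
distance_matrix <- function(g) as.matrix(stats::dist(g$xyz))
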