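#' Atom-table representation of a structure
#'
#' Throughout the package a conformer is a tibble of atoms with columns
#' `resno` (author residue number, 1-based), `elety` (atom name, e.g. "CA",
#' "N", "H") and Cartesian coordinates `x`, `y`, `z` in Angstrom. This
#' validator checks the contract and is called at module boundaries.
#'
#' @param x a data frame with columns resno, elety, x, y, z.
#' @return the input as a tibble, invisibly validated.
#' @export
as_structure <- function(x) {
  need <- c("resno", "elety", "x", "y", "z")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("structure table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!is.numeric(x$x) || !is.numeric(x$y) || !is.numeric(x$z)) {
    stop("coordinates must be numeric (Angstrom)", call. = FALSE)
  }
  if (anyNA(x[need])) stop("structure table contains NA", call. = FALSE)
  x
}

# n x 3 coordinate matrix for one atom type at given residues (pool-hot path)
atom_coords <- function(structure, elety = "CA", resno = NULL) {
  sel <- structure$elety == elety
  if (!is.null(resno)) sel <- sel & structure$resno %in% resno
  sub <- structure[sel, , drop = FALSE]
  m <- cbind(sub$x, sub$y, sub$z)
  rownames(m) <- sub$resno
  m
}

# replace coordinates of selected atoms (same order as selection)
set_coords <- function(structure, sel, m) {
  structure$x[sel] <- m[, 1]
  structure$y[sel] <- m[, 2]
  structure$z[sel] <- m[, 3]
  structure
}

coords_matrix <- function(structure) cbind(structure$x, structure$y, structure$z)

#' Inter-nuclear unit vectors for a set of coupling keys
#'
#' Resolves each (residue, atom pair) key to the two atoms in the structure
#' and returns the unit vector from the first to the second atom.
#'
#' @param structure an atom table (see [as_structure()]).
#' @param keys data frame with columns `resid`, `atom1`, `atom2`.
#' @return matrix with one unit row vector per key.
#' @keywords internal
bond_unit_vectors <- function(structure, keys) {
  structure <- as_structure(structure)
  idx <- paste(structure$resno, structure$elety)
  i1 <- match(paste(keys$resid, keys$atom1), idx)
  i2 <- match(paste(keys$resid, keys$atom2), idx)
  bad <- is.na(i1) | is.na(i2)
  if (any(bad)) {
    k <- which(bad)[1]
    stop("atom not found in structure: residue ", keys$resid[k], " (",
         keys$atom1[k], "-", keys$atom2[k], ")", call. = FALSE)
  }
  v <- cbind(structure$x[i2] - structure$x[i1],
             structure$y[i2] - structure$y[i1],
             structure$z[i2] - structure$z[i1])
  v / sqrt(rowSums(v^2))
}

#' Default coupling keys present in a structure
#'
#' @param structure atom table.
#' @param atom1,atom2 the bonded pair, default backbone amide N-H.
#' @param residues optional residue subset.
#' @return tibble with columns resid, atom1, atom2, one row per residue that
#'   carries both atoms.
#' @export
rdc_keys <- function(structure, atom1 = "N", atom2 = "H", residues = NULL) {
  structure <- as_structure(structure)
  r1 <- structure$resno[structure$elety == atom1]
  r2 <- structure$resno[structure$elety == atom2]
  res <- sort(intersect(r1, r2))
  if (!is.null(residues)) res <- intersect(res, residues)
  tibble::tibble(resid = as.integer(res), atom1 = atom1, atom2 = atom2)
}

# 3x3 rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

# uniformly random rotation matrix (for property tests)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# apply rigid transform to all atoms
transform_structure <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  m <- coords_matrix(structure) %*% t(rot)
  m <- sweep(m, 2, shift, "+")
  set_coords(structure, rep(TRUE, nrow(structure)), m)
}
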