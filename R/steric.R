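#' Coarse-grain a structure into a bead model
#'
#' For tensor prediction the molecule is represented as a set of spheres.
#' The residue-level scheme (default, used for large conformer pools) places
#' one bead of fixed effective radius on each C-alpha; the atom-level scheme
#' puts a smaller bead on every heavy atom and serves as the accuracy check.
#'
#' @param structure atom table.
#' @param scheme "residue" or "atom".
#' @param radius bead radius in Angstrom; defaults 3.8 (residue) / 1.7 (atom).
#' @return list of class `bead_model` with `centers` (n x 3, Angstrom),
#'   `radii` (length n) and `scheme`.
#' @export
coarse_grain <- function(structure, scheme = c("residue", "atom"),
                         radius = NULL) {
  scheme <- match.arg(scheme)
  structure <- as_structure(structure)
  if (scheme == "residue") {
    if (is.null(radius)) radius <- 3.8
    centers <- atom_coords(structure, "CA")
    res_with_ca <- unique(structure$resno[structure$elety == "CA"])
    missing <- setdiff(unique(structure$resno), res_with_ca)
    if (length(missing)) {
      stop("residue-level beads need a CA in every residue; missing for: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  } else {
    if (is.null(radius)) radius <- 1.7
    heavy <- structure[substr(structure$elety, 1, 1) != "H", , drop = FALSE]
    centers <- coords_matrix(heavy)
  }
  if (nrow(centers) < 1L) stop("empty bead model", call. = FALSE)
  structure(list(centers = centers, radii = rep(radius, nrow(centers)),
                 scheme = scheme),
            class = "bead_model")
}

#' Steric tensor prediction settings
#'
#' @param grid_deg angular grid resolution in degrees for the orientation
#'   average, in (0, 30].
#' @param spacing distance between the two obstructing planes in Angstrom, or
#'   "auto" for 4x the maximal molecular radius of the bead model.
#' @param bead_scheme "residue" or "atom".
#' @return list of class `steric_config`.
#' @export
steric_config <- function(grid_deg = 10, spacing = "auto",
                          bead_scheme = c("residue", "atom")) {
  if (!is.numeric(grid_deg) || grid_deg <= 0 || grid_deg > 30) {
    stop("grid_deg must be in (0, 30] degrees", call. = FALSE)
  }
  structure(list(grid_deg = grid_deg, spacing = spacing,
                 bead_scheme = match.arg(bead_scheme)),
            class = "steric_config")
}

# orientation grid over the sphere: unit vectors (3 x m) and quadrature
# weights. Gauss-Legendre nodes in cos(theta) (exact for the degree-2 Saupe
# integrand, so an isotropic shape gives a numerically zero tensor) crossed
# with a uniform midpoint rule in phi.
orientation_grid <- function(grid_deg) {
  n_theta <- max(2L, ceiling(180 / grid_deg))
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  theta <- acos(gl$x)
  phi <- seq(grid_deg * pi / 360, 2 * pi, by = grid_deg * pi / 180)
  g <- expand.grid(theta = theta, phi = phi)
  w <- expand.grid(wt = gl$w, phi = phi)$wt
  u <- rbind(sin(g$theta) * cos(g$phi),
             sin(g$theta) * sin(g$phi),
             cos(g$theta))
  list(u = u, w = w)
}

# extent of the bead model along each direction in u (3 x m) -> length m
bead_extent <- function(model, u) {
  p <- model$centers %*% u
  r <- model$radii
  hi <- apply(p + r, 2, max)
  lo <- apply(p - r, 2, min)
  hi - lo
}

resolve_spacing <- function(model, config) {
  if (identical(config$spacing, "auto")) {
    com <- colMeans(model$centers)
    rmax <- sqrt(max(rowSums(sweep(model$centers, 2, com)^2))) +
      max(model$radii)
    return(4 * rmax)
  }
  config$spacing
}

#' Predict a steric alignment tensor from molecular shape
#'
#' Implements the planar-barrier excluded-orientation mechanism of steric
#' alignment in a stretched gel: for each molecular orientation, the fraction
#' of translational positions between two parallel obstructing planes
#' (spacing L) that is not excluded by bead-plane overlap is
#' `max(0, 1 - h/L)`, with `h` the bead-model extent along the plane normal.
#' Orientations are weighted by that allowed fraction and the Saupe tensor is
#' the weighted orientational average
#' `S_ij = < (3 cos(phi_i) cos(phi_j) - delta_ij) / 2 >`,
#' expressed in the molecular frame (phi_i: angle between the plane normal
#' and molecular axis i). Elongated shapes are more often excluded when their
#' long axis crosses the planes, which is what makes the tensor report on
#' inter-domain arrangement.
#'
#' @param model a [coarse_grain()] bead model.
#' @param config a [steric_config()].
#' @return an [alignment_tensor()].
#' @export
predict_tensor <- function(model, config = steric_config()) {
  if (!inherits(model, "bead_model")) stop("need a bead_model", call. = FALSE)
  grid <- orientation_grid(config$grid_deg)
  spacing <- resolve_spacing(model, config)
  h <- bead_extent(model, grid$u)
  if (all(h >= spacing)) {
    stop("barrier spacing ", signif(spacing, 4),
         " A is degenerate: the molecule cannot fit between the planes",
         call. = FALSE)
  }
  f <- pmax(0, 1 - h / spacing)
  w <- f * grid$w
  w <- w / sum(w)
  m2 <- grid$u %*% (w * t(grid$u)) # <u u'>
  alignment_tensor((3 * m2 - diag(3)) / 2)
}
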