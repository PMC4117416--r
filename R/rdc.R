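#' Build an RDC table
#'
#' The package-wide container for residual dipolar couplings is a tibble with
#' columns `resid` (integer), `atom1`, `atom2` (atom names), `value` (Hz) and
#' `sigma` (uncertainty, Hz), plus an `origin` attribute
#' ("experimental", "calculated" or "synthetic"). Keys
#' (resid, atom1, atom2) must be unique. A missing uncertainty defaults to
#' 0.3 Hz, the typical precision of gel-aligned backbone amide measurements.
#'
#' @param resid integer residue numbers.
#' @param value couplings in Hz.
#' @param atom1,atom2 atom names of the bonded pair.
#' @param sigma per-coupling uncertainty in Hz (>= 0).
#' @param origin one of "experimental", "calculated", "synthetic".
#' @return a tibble of class `rdc_tbl`.
#' @export
rdc_table <- function(resid, value, atom1 = "N", atom2 = "H", sigma = 0.3,
                      origin = "experimental") {
  origin <- match.arg(origin, c("experimental", "calculated", "synthetic"))
  out <- tibble::tibble(
    resid = as.integer(resid),
    atom1 = as.character(atom1),
    atom2 = as.character(atom2),
    value = as.numeric(value),
    sigma = as.numeric(sigma)
  )
  if (any(out$sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(!nzchar(out$atom1)) || any(!nzchar(out$atom2))) {
    stop("atom names must be non-empty", call. = FALSE)
  }
  key <- paste(out$resid, out$atom1, out$atom2)
  if (anyDuplicated(key)) {
    stop("duplicate (residue, atom pair) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  attr(out, "origin") <- origin
  class(out) <- c("rdc_tbl", class(out))
  out
}

rdc_key <- function(x) paste(x$resid, x$atom1, x$atom2)

# join two rdc tables on their keys; errors if the intersection is empty
match_rdcs <- function(calc, exp) {
  i <- match(rdc_key(exp), rdc_key(calc))
  keep <- !is.na(i)
  if (!any(keep)) stop("no shared RDC keys between the two sets", call. = FALSE)
  list(calc = calc$value[i[keep]], exp = exp$value[keep], keep = keep)
}

#' Back-calculate RDCs from a structure and an alignment tensor
#'
#' Evaluates the Saupe contraction
#' `D = D_max(pair) * sum_ij S_ij cos(phi_i) cos(phi_j)`, where `phi_i` is
#' the angle between the inter-nuclear unit vector and molecular axis `i`
#' (the frame in which the tensor is expressed), equivalently
#' `D = D_max * v' S v`.
#'
#' @param structure atom table.
#' @param tensor an [alignment_tensor()].
#' @param keys tibble of (resid, atom1, atom2) keys; defaults to all backbone
#'   amide N-H pairs present.
#' @return an `rdc_tbl` with origin "calculated" and `sigma = 0`.
#' @export
back_calculate <- function(structure, tensor, keys = rdc_keys(structure)) {
  if (!inherits(tensor, "alignment_tensor")) tensor <- alignment_tensor(tensor)
  v <- bond_unit_vectors(structure, keys)
  pair <- paste(keys$atom1, keys$atom2, sep = "-")
  dm <- vapply(unique(pair), d_max, numeric(1))[pair]
  d <- dm * rowSums((v %*% unclass(tensor)) * v)
  rdc_table(keys$resid, d, keys$atom1, keys$atom2, sigma = 0,
            origin = "calculated")
}

#' Ensemble-average RDCs over conformers with per-conformer tensors
#'
#' Conformers in fast exchange contribute to the measured coupling with their
#' own, shape-dependent alignment tensor; the observable is the unweighted
#' arithmetic mean of per-conformer couplings (ensemble members are
#' equipopulated; unequal state populations arise from member multiplicity).
#'
#' @param members list of `list(structure =, tensor =)` entries.
#' @param keys coupling keys shared by all members.
#' @return an `rdc_tbl` of the averaged couplings.
#' @export
ensemble_average <- function(members, keys) {
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  vals <- vapply(
    members,
    function(m) back_calculate(m$structure, m$tensor, keys)$value,
    numeric(nrow(keys))
  )
  rdc_table(keys$resid, rowMeans(matrix(vals, nrow = nrow(keys))),
            keys$atom1, keys$atom2, sigma = 0, origin = "calculated")
}

# Q on bare numeric vectors (GA-hot path)
q_factor_vec <- function(calc, exp) {
  den <- sqrt(mean(exp^2))
  if (den == 0) stop("experimental RDCs are all zero; Q undefined", call. = FALSE)
  sqrt(mean((calc - exp)^2)) / den
}

#' Quality factor Q between calculated and experimental RDCs
#'
#' `Q = rms(D_calc - D_exp) / rms(D_exp)` over the shared keys
#' (the Cornilescu convention). 0 is a perfect fit.
#'
#' @param calc,exp `rdc_tbl` objects; keys are intersected.
#' @return Q, dimensionless.
#' @export
q_factor <- function(calc, exp) {
  m <- match_rdcs(calc, exp)
  q_factor_vec(m$calc, m$exp)
}

#' Optimal uniform scaling of calculated RDCs
#'
#' The degree of alignment (hence the absolute RDC scale) cannot be predicted
#' from the medium concentration, so calculated couplings are rescaled
#' after ensemble averaging by the least-squares factor
#' `s* = sum(Dcalc * Dexp) / sum(Dcalc^2)`, which minimizes Q.
#'
#' @param calc,exp `rdc_tbl` objects.
#' @return list with `scale` and `q` (the Q factor at the optimal scale).
#' @export
optimal_scale <- function(calc, exp) {
  m <- match_rdcs(calc, exp)
  ss <- sum(m$calc^2)
  if (ss == 0) stop("calculated RDCs are all zero; scale undefined", call. = FALSE)
  s <- sum(m$calc * m$exp) / ss
  list(scale = s, q = q_factor_vec(s * m$calc, m$exp))
}

# design matrix of the 5 independent tensor components for unit vectors v:
# D/Dmax = Sxx(x^2-z^2) + Syy(y^2-z^2) + 2Sxy xy + 2Sxz xz + 2Syz yz
saupe_design <- function(v) {
  cbind(
    v[, 1]^2 - v[, 3]^2,
    v[, 2]^2 - v[, 3]^2,
    2 * v[, 1] * v[, 2],
    2 * v[, 1] * v[, 3],
    2 * v[, 2] * v[, 3]
  )
}

saupe_from_params <- function(p) {
  alignment_tensor(matrix(c(
    p[1], p[3], p[4],
    p[3], p[2], p[5],
    p[4], p[5], -p[1] - p[2]
  ), 3, 3))
}

#' Fit an alignment tensor to RDCs by singular value decomposition
#'
#' Solves the linear least-squares problem for the five independent Saupe
#' elements given a structure's inter-nuclear vectors and measured couplings,
#' via the SVD pseudo-inverse of the direction-cosine design matrix. The
#' result is symmetric and traceless by construction.
#'
#' @param structure atom table.
#' @param exp experimental `rdc_tbl` (>= 5 couplings with non-degenerate
#'   directions).
#' @return list with `tensor` (an [alignment_tensor()]) and `q` (Q of the
#'   fit, unscaled: the fitted tensor already carries the magnitude).
#' @export
fit_tensor_svd <- function(structure, exp) {
  keys <- exp[c("resid", "atom1", "atom2")]
  if (nrow(keys) < 5L) {
    stop("tensor fit needs >= 5 RDCs; got ", nrow(keys), call. = FALSE)
  }
  v <- bond_unit_vectors(structure, keys)
  pair <- paste(keys$atom1, keys$atom2, sep = "-")
  dm <- vapply(unique(pair), d_max, numeric(1))[pair]
  a <- saupe_design(v) * dm
  sv <- svd(a)
  tol <- max(dim(a)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < 5L) {
    stop("direction matrix is rank-deficient (rank ", r,
         " < 5); inter-nuclear vectors are degenerate", call. = FALSE)
  }
  p <- sv$v %*% ((t(sv$u) %*% exp$value) / sv$d)
  tensor <- saupe_from_params(drop(p))
  calc <- back_calculate(structure, tensor, keys)
  list(tensor = tensor, q = q_factor(calc, exp))
}
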