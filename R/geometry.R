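#' Inter-domain opening-angle definitions
#'
#' Each opening angle is defined, following the Beckstein convention, by
#' three windows of residues whose C-alpha centers of mass form a vertex and
#' two arms: the angle is the one between vertex->arm1 and vertex->arm2.
#' Windows may be arbitrary residue sets (for the adenylate-kinase preset
#' they are the published contiguous ranges; note the hinge window 115-125
#' and the LID window 125-153 share residue 125, which is kept as published).
#'
#' @param ampbd,lid each a list with integer vectors `vertex`, `arm1`,
#'   `arm2` of residue numbers.
#' @return list of class `angle_definition`.
#' @export
angle_definition <- function(ampbd, lid) {
  chk <- function(a, nm) {
    if (!all(c("vertex", "arm1", "arm2") %in% names(a))) {
      stop(nm, " needs vertex, arm1 and arm2 residue windows", call. = FALSE)
    }
    lapply(a[c("vertex", "arm1", "arm2")], as.integer)
  }
  structure(list(ampbd = chk(ampbd, "ampbd"), lid = chk(lid, "lid")),
            class = "angle_definition")
}

#' Published angle windows for E. coli adenylate kinase
#'
#' theta_AMPbd: vertex at the CORE 90-100 center of mass, arms to the
#' CORE-LID hinge (115-125) and to AMPbd 35-55. theta_LID: vertex at the
#' hinge 115-125, arms to CORE 179-185 and LID 125-153.
#'
#' @return an [angle_definition()].
#' @export
ake_angle_definition <- function() {
  angle_definition(
    ampbd = list(vertex = 90:100, arm1 = 115:125, arm2 = 35:55),
    lid = list(vertex = 115:125, arm1 = 179:185, arm2 = 125:153)
  )
}

window_com <- function(structure, resnos, what) {
  m <- atom_coords(structure, "CA", resnos)
  if (nrow(m) == 0L) {
    stop("no CA atoms found for ", what, " window (residues ",
         paste(range(resnos), collapse = "-"), ")", call. = FALSE)
  }
  found <- as.integer(rownames(m))
  missing <- setdiff(resnos, found)
  if (length(missing)) {
    stop("missing CA for ", what, " window residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  colMeans(m)
}

angle_from_windows <- function(structure, w, label) {
  v0 <- window_com(structure, w$vertex, paste0(label, " vertex"))
  v1 <- window_com(structure, w$arm1, paste0(label, " arm1")) - v0
  v2 <- window_com(structure, w$arm2, paste0(label, " arm2")) - v0
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' AMP-binding-domain opening angle (degrees)
#'
#' @param structure atom table.
#' @param defn an [angle_definition()]; default the adenylate-kinase windows.
#' @return angle in degrees, in \[0, 180\].
#' @export
theta_ampbd <- function(structure, defn = ake_angle_definition()) {
  angle_from_windows(as_structure(structure), defn$ampbd, "theta_AMPbd")
}

#' LID-domain opening angle (degrees)
#'
#' @inheritParams theta_ampbd
#' @return angle in degrees, in \[0, 180\].
#' @export
theta_lid <- function(structure, defn = ake_angle_definition()) {
  angle_from_windows(as_structure(structure), defn$lid, "theta_LID")
}

#' Both opening angles as a one-row tibble
#'
#' @inheritParams theta_ampbd
#' @return tibble with columns `theta_ampbd`, `theta_lid` (degrees).
#' @export
interdomain_angles <- function(structure, defn = ake_angle_definition()) {
  structure <- as_structure(structure)
  tibble::tibble(
    theta_ampbd = theta_ampbd(structure, defn),
    theta_lid = theta_lid(structure, defn)
  )
}
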