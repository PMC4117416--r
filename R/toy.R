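#' Domain decomposition of a hinged three-domain protein
#'
#' Residue intervals for the stable core and the two mobile binding domains,
#' plus the hinge residue windows flanking each mobile domain. The hinge
#' axis of a domain runs through the centers of mass of its two flanking
#' windows.
#'
#' @param ampbd,lid integer residue vectors of the two mobile domains.
#' @param core list of integer residue vectors (core segments).
#' @param hinge_ampbd,hinge_lid each a list with residue vectors `a` and `b`,
#'   the two flanking anchor windows of that domain's hinge axis.
#' @return list of class `domain_definition`.
#' @export
domain_definition <- function(ampbd, lid, core, hinge_ampbd, hinge_lid) {
  all_mobile <- c(ampbd, lid)
  if (anyDuplicated(all_mobile)) {
    stop("AMPbd and LID residue ranges overlap", call. = FALSE)
  }
  structure(list(
    ampbd = as.integer(ampbd), lid = as.integer(lid),
    core = lapply(core, as.integer),
    hinge_ampbd = lapply(hinge_ampbd, as.integer),
    hinge_lid = lapply(hinge_lid, as.integer)
  ), class = "domain_definition")
}

#' Adenylate-kinase domain decomposition (as published)
#'
#' AMPbd 28-72, LID 113-176, CORE 1-27 / 73-112 / 176-214. Hinge anchors are
#' the two-residue windows flanking each mobile domain.
#'
#' @return a [domain_definition()].
#' @export
ake_domain_definition <- function() {
  domain_definition(
    ampbd = 28:72, lid = 113:176,
    core = list(1:27, 73:112, 177:214),
    hinge_ampbd = list(a = 26:27, b = 73:74),
    hinge_lid = list(a = 111:112, b = 177:178)
  )
}

# resample a polyline (waypoint matrix) into n points evenly spaced in
# arclength, endpoints included
polyline_points <- function(waypoints, n) {
  d <- sqrt(rowSums(diff(waypoints)^2))
  s <- c(0, cumsum(d))
  at <- seq(0, s[length(s)], length.out = n)
  t(vapply(at, function(si) {
    j <- max(which(s <= si + 1e-12))
    if (j == length(s)) return(waypoints[j, ])
    f <- (si - s[j]) / (s[j + 1] - s[j])
    waypoints[j, ] * (1 - f) + waypoints[j + 1, ] * f
  }, numeric(3)))
}

# deterministic quasi-uniform unit vectors (Fibonacci sphere), used for
# coordinate wobble and amide N-H directions
fib_dirs <- function(idx, n_total) {
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (idx - 0.5) / n_total
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- idx * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a synthetic hinged three-domain test protein
#'
#' Constructs a deterministic C-alpha / N / H backbone model of a protein
#' with a stable core and two mobile hairpin domains (an AMP-binding-domain
#' analogue hinged on one side of the core, a LID analogue on the other),
#' emulating the open/closed inter-domain motions of adenylate kinase at toy
#' scale. The two opening angles are geometrically independent: each mobile
#' domain rotates about its own hinge axis. Amide N-H vectors are spread
#' quasi-uniformly over orientations so that alignment tensors are
#' identifiable from the couplings.
#'
#' @param n_core,n_lid,n_ampbd residue counts (core is split into three
#'   segments); each domain needs >= 5 residues.
#' @param preset "open" (angles 80, 150 deg), "closed" (40, 100 deg), or a
#'   numeric `c(theta_ampbd, theta_lid)` target in degrees.
#' @return list with `structure` (atom tibble), `domains`
#'   (a [domain_definition()]) and `angle_def` (an [angle_definition()]
#'   using the toy's own residue windows).
#' @export
make_toy_structure <- function(n_core = 60, n_lid = 36, n_ampbd = 30,
                               preset = "open") {
  if (min(n_core, n_lid, n_ampbd) < 5) {
    stop("each domain needs at least 5 residues", call. = FALSE)
  }
  targets <- if (is.numeric(preset)) {
    if (length(preset) != 2) stop("numeric preset must be c(theta_ampbd, theta_lid)",
                                  call. = FALSE)
    preset
  } else {
    switch(match.arg(preset, c("open", "closed")),
           open = c(80, 150), closed = c(40, 100))
  }

  c1 <- max(5L, round(n_core * 0.25))
  c2 <- max(10L, round(n_core * 0.50))
  c3 <- n_core - c1 - c2
  if (c3 < 5L) stop("n_core too small to split into three segments", call. = FALSE)

  # canonical pose: AMPbd hairpin opens in the xy-plane about a z-axis hinge
  # at (8, 0, 0); LID opens in the xz-plane about a y-axis hinge at (-8, 0, 0)
  ga <- 70 * pi / 180          # canonical AMPbd hairpin direction
  la <- 18                     # AMPbd reach, Angstrom
  dl <- 100 * pi / 180         # canonical LID hairpin direction
  ll <- 16                     # LID reach, Angstrom

  tip_a <- c(8 + la * cos(ga), la * sin(ga), 0)
  perp_a <- c(-sin(ga), cos(ga), 0)
  tip_l <- c(-8 - ll * cos(dl), 0, ll * sin(dl))
  perp_l <- c(sin(dl), 0, cos(dl))

  seg <- list(
    core1 = polyline_points(rbind(
      c(2, -3, 6), c(6, -4, 7), c(8, -1, 5.5), c(8, 0, 4)), c1),
    ampbd = polyline_points(rbind(
      c(8, 0, 2.5), tip_a + 1.5 * perp_a + c(0, 0, 1),
      tip_a - 1.5 * perp_a + c(0, 0, -1), c(8, 0, -2.5)), n_ampbd),
    core2 = polyline_points(rbind(
      c(8, 0, -4), c(5, 1, -7.5), c(0, 0, -8), c(-4, 2, -5.5), c(-8, 4, 0)),
      c2),
    lid = polyline_points(rbind(
      c(-8, 2.5, 0), tip_l + 1.5 * perp_l + c(0, 1, 0),
      tip_l - 1.5 * perp_l + c(0, -1, 0), c(-8, -2.5, 0)), n_lid),
    core3 = polyline_points(rbind(
      c(-8, -4, 0), c(-4, -2.5, 3), c(0, -1, 5.5), c(3, -1, 6)), c3)
  )
  ca <- do.call(rbind, seg)
  n_res <- nrow(ca)
  ca <- ca + 0.8 * fib_dirs(seq_len(n_res), n_res)

  # residue numbering in chain order
  off <- cumsum(c(0, c1, n_ampbd, c2, n_lid))
  resno <- seq_len(n_res)
  ranges <- list(core1 = off[1] + 1:c1, ampbd = off[2] + 1:n_ampbd,
                 core2 = off[3] + 1:c2, lid = off[4] + 1:n_lid,
                 core3 = off[5] + 1:c3)

  n_dir <- fib_dirs(seq_len(n_res) * 7L + 3L, n_res * 7L)
  h_dir <- fib_dirs(seq_len(n_res) * 11L + 5L, n_res * 11L)
  npos <- ca + 1.46 * n_dir
  hpos <- npos + 1.02 * h_dir

  structure_tbl <- tibble::tibble(
    resno = rep(resno, each = 3L),
    elety = rep(c("N", "CA", "H"), n_res),
    x = as.vector(rbind(npos[, 1], ca[, 1], hpos[, 1])),
    y = as.vector(rbind(npos[, 2], ca[, 2], hpos[, 2])),
    z = as.vector(rbind(npos[, 3], ca[, 3], hpos[, 3]))
  )

  domains <- domain_definition(
    ampbd = ranges$ampbd, lid = ranges$lid,
    core = ranges[c("core1", "core2", "core3")],
    hinge_ampbd = list(a = utils::tail(ranges$core1, 2),
                       b = utils::head(ranges$core2, 2)),
    hinge_lid = list(a = utils::tail(ranges$core2, 2),
                     b = utils::head(ranges$core3, 2))
  )

  # angle windows: vertex / fixed arm windows sit in the core, the mobile arm
  # window is the hairpin tip region of each domain
  nearest_to_origin <- function(range, k = 5) {
    m <- ca[range, , drop = FALSE]
    range[order(rowSums(m^2))[seq_len(min(k, length(range)))]]
  }
  mid_window <- function(range) {
    c0 <- range[ceiling(length(range) / 2)]
    intersect((c0 - 3):(c0 + 3), range)
  }
  angle_def <- angle_definition(
    ampbd = list(
      vertex = nearest_to_origin(ranges$core2),
      arm1 = c(domains$hinge_ampbd$a, domains$hinge_ampbd$b),
      arm2 = mid_window(ranges$ampbd)
    ),
    lid = list(
      vertex = c(domains$hinge_lid$a, domains$hinge_lid$b),
      arm1 = nearest_to_origin(ranges$core3),
      arm2 = mid_window(ranges$lid)
    )
  )

  st <- rotate_domains_to(structure_tbl, domains, angle_def,
                          theta_ampbd = targets[1], theta_lid = targets[2])
  if (is.null(st)) {
    stop("preset angles (", targets[1], ", ", targets[2],
         ") deg unreachable for this topology", call. = FALSE)
  }
  list(structure = st, domains = domains, angle_def = angle_def)
}
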