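# --- rigid-body hinge rotations -------------------------------------------

hinge_axis <- function(structure, hinge) {
  a <- window_com(structure, hinge$a, "hinge anchor a")
  b <- window_com(structure, hinge$b, "hinge anchor b")
  dir <- b - a
  len <- sqrt(sum(dir^2))
  if (len < 1e-6) stop("degenerate hinge axis (coincident anchors)", call. = FALSE)
  list(point = (a + b) / 2, dir = dir / len)
}

# angle (deg) of the vertex/arm construction when the mobile-arm COM is
# rotated by alpha about the hinge axis; closed form on the COM only
angle_at_rotation <- function(alpha, arm2_com0, axis, vcom, arm1_com) {
  v1 <- arm1_com - vcom
  p <- arm2_com0 - axis$point
  vapply(alpha, function(a) {
    r <- rotation_about_axis(axis$dir, a)
    v2 <- drop(r %*% p) + axis$point - vcom
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))
}

# find every rotation (radians) about the hinge axis that brings the opening
# angle to `target` degrees: the target lies on a cone, so up to two branches
# exist. Coarse 1-degree scan for local minima of |theta - target|, then
# golden-section refinement of each; solutions are returned ordered by
# |alpha| (closest to the seed pose first). NULL if none reaches the target
# within `tol` degrees.
solve_hinge_rotation <- function(structure, window, hinge, target, tol = 2) {
  axis <- hinge_axis(structure, hinge)
  vcom <- window_com(structure, window$vertex, "vertex")
  a1 <- window_com(structure, window$arm1, "arm1")
  a2 <- window_com(structure, window$arm2, "arm2")
  grid <- seq(-pi, pi - pi / 180, by = pi / 180)
  f <- abs(angle_at_rotation(grid, a2, axis, vcom, a1) - target)
  m <- length(grid)
  is_min <- f <= f[c(m, 1:(m - 1))] & f <= f[c(2:m, 1)] & f < 15
  alphas <- numeric(0)
  for (i in which(is_min)) {
    opt <- stats::optimize(
      function(a) abs(angle_at_rotation(a, a2, axis, vcom, a1) - target),
      lower = grid[i] - 2 * pi / 180, upper = grid[i] + 2 * pi / 180,
      tol = 1e-8
    )
    if (opt$objective <= tol) alphas <- c(alphas, opt$minimum)
  }
  if (!length(alphas)) return(NULL)
  list(alphas = alphas[order(abs(alphas))], axis = axis)
}

rotate_residues <- function(structure, resnos, axis, alpha) {
  sel <- structure$resno %in% resnos
  m <- coords_matrix(structure)[sel, , drop = FALSE]
  m <- sweep(m, 2, axis$point)
  m <- m %*% t(rotation_about_axis(axis$dir, alpha))
  m <- sweep(m, 2, axis$point, "+")
  set_coords(structure, sel, m)
}

# rotate both mobile domains so the measured opening angles hit the targets
# (within tol degrees). The two angles are solved independently (each
# domain's windows are unaffected by the other domain's rotation); among the
# branch combinations the first without an inter-domain clash is taken,
# falling back to the least-clashing one (the caller's clash filter decides
# its fate). NULL if either target is unreachable.
rotate_domains_to <- function(structure, domains, angle_def,
                              theta_ampbd, theta_lid, tol = 2,
                              clash_cutoff = 3.0) {
  sa <- solve_hinge_rotation(structure, angle_def$ampbd, domains$hinge_ampbd,
                             theta_ampbd, tol)
  sl <- solve_hinge_rotation(structure, angle_def$lid, domains$hinge_lid,
                             theta_lid, tol)
  if (is.null(sa) || is.null(sl)) return(NULL)
  combos <- expand.grid(a = sa$alphas, l = sl$alphas)
  combos <- combos[order(abs(combos$a) + abs(combos$l)), , drop = FALSE]
  best <- NULL
  best_d <- -Inf
  for (k in seq_len(nrow(combos))) {
    st <- rotate_residues(structure, domains$ampbd, sa$axis, combos$a[k])
    st <- rotate_residues(st, domains$lid, sl$axis, combos$l[k])
    d <- min_interdomain_distance(st, domains)
    if (d >= clash_cutoff) return(st)
    if (d > best_d) {
      best_d <- d
      best <- st
    }
  }
  best
}

# minimum inter-domain CA-CA distance; pairs within 6 residues along the
# chain are ignored (hinge-proximal proximity is covalent geometry, not an
# inter-domain collision)
min_interdomain_distance <- function(structure, domains) {
  ca <- structure[structure$elety == "CA", , drop = FALSE]
  grp <- rep("core", nrow(ca))
  grp[ca$resno %in% domains$ampbd] <- "ampbd"
  grp[ca$resno %in% domains$lid] <- "lid"
  m <- cbind(ca$x, ca$y, ca$z)
  dmin <- Inf
  pairs <- list(c("ampbd", "core"), c("lid", "core"), c("ampbd", "lid"))
  for (p in pairs) {
    i <- which(grp == p[1]); j <- which(grp == p[2])
    if (!length(i) || !length(j)) next
    d2 <- outer(rowSums(m[i, , drop = FALSE]^2), rowSums(m[j, , drop = FALSE]^2), "+") -
      2 * m[i, , drop = FALSE] %*% t(m[j, , drop = FALSE])
    near_chain <- abs(outer(ca$resno[i], ca$resno[j], "-")) <= 6
    d2[near_chain] <- Inf
    dmin <- min(dmin, min(d2))
  }
  sqrt(max(dmin, 0))
}

# --- conformer pool --------------------------------------------------------

new_conformer_pool <- function(atoms, coords, angles, domains, angle_def,
                               seed = NA_integer_, discarded = NULL) {
  structure(list(
    atoms = atoms, coords = coords, angles = angles,
    domains = domains, angle_def = angle_def, seed = seed,
    discarded = discarded %||% tibble::tibble(
      theta_ampbd = numeric(), theta_lid = numeric(), reason = character()),
    keys = NULL, rdc = NULL, tensors = NULL, steric = NULL
  ), class = "conformer_pool")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.conformer_pool <- function(x, ...) {
  cat("<conformer_pool> ", length(x$coords), " conformers, ",
      nrow(x$atoms), " atoms each\n", sep = "")
  cat("  theta_AMPbd range: ",
      paste(round(range(x$angles$theta_ampbd), 1), collapse = " - "),
      " deg; theta_LID range: ",
      paste(round(range(x$angles$theta_lid), 1), collapse = " - "), " deg\n",
      sep = "")
  if (nrow(x$discarded)) cat("  discarded: ", nrow(x$discarded), "\n", sep = "")
  if (!is.null(x$rdc)) cat("  cached RDCs: ", ncol(x$rdc), " keys\n", sep = "")
  invisible(x)
}

#' Number of conformers in a pool
#' @param pool a `conformer_pool`.
#' @return integer count.
#' @export
pool_size <- function(pool) length(pool$coords)

#' Extract one conformer as an atom tibble
#' @param pool a `conformer_pool`.
#' @param i conformer index.
#' @return atom tibble.
#' @export
pool_conformer <- function(pool, i) {
  m <- pool$coords[[i]]
  tibble::tibble(resno = pool$atoms$resno, elety = pool$atoms$elety,
                 x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Tidy a conformer pool into its angle table
#' @param x a `conformer_pool`.
#' @param ... unused.
#' @return tibble with conf, theta_ampbd, theta_lid.
#' @method tidy conformer_pool
#' @export
tidy.conformer_pool <- function(x, ...) x$angles

#' Default target-angle grid for pool generation
#'
#' A regular grid over the opening ranges sampled for adenylate kinase:
#' theta_AMPbd 30-90 deg, theta_LID 90-160 deg.
#'
#' @param n points per axis (n^2 targets); the default 45 gives a pool of
#'   about 2000 conformers.
#' @param ampbd_range,lid_range angle ranges in degrees.
#' @return tibble of target angle pairs.
#' @export
default_angle_grid <- function(n = 45, ampbd_range = c(30, 90),
                               lid_range = c(90, 160)) {
  g <- expand.grid(
    theta_ampbd = seq(ampbd_range[1], ampbd_range[2], length.out = n),
    theta_lid = seq(lid_range[1], lid_range[2], length.out = n)
  )
  tibble::as_tibble(g)
}

#' Generate a conformer pool by rigid-body hinge rotation
#'
#' For each target angle pair the two mobile domains of the seed structure
#' are rigidly rotated about their hinge axes until the measured opening
#' angles match the targets within 2 degrees (intra-domain geometry is
#' untouched). Conformers with inter-domain CA-CA contacts closer than
#' `clash_cutoff` are discarded and reported in the pool's `discarded`
#' table, as are unreachable targets. This replaces biased all-atom
#' simulation as a pool source: ensemble selection only needs broad, even
#' coverage of the angle space, not a physical Boltzmann sample. Pools from
#' any simulation engine can be imported instead via multi-model PDB files
#' (see [read_pool_pdb()]).
#'
#' @param seed_structure atom tibble (canonical conformer).
#' @param domains a [domain_definition()].
#' @param angle_def an [angle_definition()] whose windows live on the seed.
#' @param targets tibble of target angles (theta_ampbd, theta_lid), degrees;
#'   default the [default_angle_grid()].
#' @param jitter s.d. (degrees) of Gaussian jitter added to targets.
#' @param rng_seed integer seed controlling the jitter.
#' @param clash_cutoff minimum allowed inter-domain CA-CA distance, Angstrom.
#' @return a `conformer_pool`.
#' @export
generate_hinge_pool <- function(seed_structure, domains, angle_def,
                                targets = default_angle_grid(),
                                jitter = 0.5, rng_seed = 1L,
                                clash_cutoff = 3.0) {
  seed_structure <- as_structure(seed_structure)
  n <- nrow(targets)
  tgt <- targets
  if (jitter > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(rng_seed)
    tgt$theta_ampbd <- tgt$theta_ampbd + stats::rnorm(n, 0, jitter)
    tgt$theta_lid <- tgt$theta_lid + stats::rnorm(n, 0, jitter)
  }
  atoms <- seed_structure[c("resno", "elety")]
  coords <- vector("list", n)
  ang <- matrix(NA_real_, n, 2)
  disc <- list()
  kept <- 0L
  for (i in seq_len(n)) {
    st <- rotate_domains_to(seed_structure, domains, angle_def,
                            tgt$theta_ampbd[i], tgt$theta_lid[i])
    if (is.null(st)) {
      disc[[length(disc) + 1L]] <- tibble::tibble(
        theta_ampbd = tgt$theta_ampbd[i], theta_lid = tgt$theta_lid[i],
        reason = "unreachable target angle")
      next
    }
    if (min_interdomain_distance(st, domains) < clash_cutoff) {
      disc[[length(disc) + 1L]] <- tibble::tibble(
        theta_ampbd = tgt$theta_ampbd[i], theta_lid = tgt$theta_lid[i],
        reason = "inter-domain clash")
      next
    }
    kept <- kept + 1L
    coords[[kept]] <- coords_matrix(st)
    a <- interdomain_angles(st, angle_def)
    ang[kept, ] <- c(a$theta_ampbd, a$theta_lid)
  }
  if (kept == 0L) stop("no conformer survived generation", call. = FALSE)
  discarded <- if (length(disc)) dplyr::bind_rows(disc) else NULL
  if (!is.null(discarded) && nrow(discarded)) {
    message("discarded ", nrow(discarded), " of ", n, " target conformers (",
            sum(discarded$reason == "inter-domain clash"), " clash, ",
            sum(discarded$reason == "unreachable target angle"),
            " unreachable)")
  }
  new_conformer_pool(
    atoms = atoms, coords = coords[seq_len(kept)],
    angles = tibble::tibble(conf = seq_len(kept),
                            theta_ampbd = ang[seq_len(kept), 1],
                            theta_lid = ang[seq_len(kept), 2]),
    domains = domains, angle_def = angle_def, seed = rng_seed,
    discarded = discarded
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cache per-conformer alignment tensors and calculated RDCs
#'
#' Runs steric tensor prediction and RDC back-calculation once per
#' conformer and stores the results on the pool (an `n_conformers` x
#' `n_keys` coupling matrix plus the tensor list). Idempotent: re-running
#' with the same keys and configuration reuses the cache.
#'
#' @param pool a `conformer_pool`.
#' @param keys coupling keys; default all backbone N-H pairs.
#' @param config a [steric_config()].
#' @return the pool with `rdc`, `tensors`, `keys` and `steric` filled in.
#' @export
precompute_pool_rdcs <- function(pool, keys = NULL, config = steric_config()) {
  if (is.null(keys)) keys <- rdc_keys(pool_conformer(pool, 1L))
  hash <- paste(nrow(keys), paste(rdc_key(keys), collapse = "|"),
                config$grid_deg, paste(config$spacing, collapse = ","),
                config$bead_scheme, sep = "@")
  if (!is.null(pool$rdc) && identical(attr(pool$rdc, "hash"), hash)) {
    message("pool RDC cache hit (", pool_size(pool), " conformers); ",
            "no recomputation")
    return(pool)
  }
  atoms <- pool$atoms
  template <- pool_conformer(pool, 1L)
  idx <- paste(atoms$resno, atoms$elety)
  i1 <- match(paste(keys$resid, keys$atom1), idx)
  i2 <- match(paste(keys$resid, keys$atom2), idx)
  if (anyNA(i1) || anyNA(i2)) {
    k <- which(is.na(i1) | is.na(i2))[1]
    stop("key not resolvable on pool conformers: residue ", keys$resid[k],
         " ", keys$atom1[k], "-", keys$atom2[k], call. = FALSE)
  }
  pair <- paste(keys$atom1, keys$atom2, sep = "-")
  dm <- vapply(unique(pair), d_max, numeric(1))[pair]
  ca_sel <- atoms$elety == "CA"
  grid <- orientation_grid(config$grid_deg)
  n <- pool_size(pool)
  rdc <- matrix(NA_real_, n, nrow(keys))
  tensors <- vector("list", n)
  for (c in seq_len(n)) {
    m <- pool$coords[[c]]
    model <- structure(list(centers = m[ca_sel, , drop = FALSE],
                            radii = rep(3.8, sum(ca_sel)),
                            scheme = "residue"), class = "bead_model")
    if (config$bead_scheme == "atom") {
      heavy <- substr(atoms$elety, 1, 1) != "H"
      model <- structure(list(centers = m[heavy, , drop = FALSE],
                              radii = rep(1.7, sum(heavy)),
                              scheme = "atom"), class = "bead_model")
    }
    s <- predict_tensor(model, config)
    tensors[[c]] <- s
    v <- m[i2, , drop = FALSE] - m[i1, , drop = FALSE]
    v <- v / sqrt(rowSums(v^2))
    rdc[c, ] <- dm * rowSums((v %*% unclass(s)) * v)
  }
  attr(rdc, "hash") <- hash
  pool$rdc <- rdc
  pool$tensors <- tensors
  pool$keys <- keys
  pool$steric <- config
  pool
}
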