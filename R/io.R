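#' Read a structure (or conformer pool) from a PDB file
#'
#' Single-model files give an atom tibble; multi-model files give a
#' `conformer_pool` (all models must share atom identity). Coordinates are
#' Angstrom; author residue numbering is preserved.
#'
#' @param path PDB file.
#' @param domains,angle_def optional [domain_definition()] /
#'   [angle_definition()] attached to a multi-model pool (defaults to the
#'   adenylate-kinase presets; pool angles are computed with `angle_def`).
#' @return atom tibble, or `conformer_pool` for multi-model files.
#' @export
read_structure <- function(path, domains = ake_domain_definition(),
                           angle_def = ake_angle_definition()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  base <- tibble::tibble(
    resno = as.integer(at$resno), elety = as.character(at$elety),
    x = at$x, y = at$y, z = at$z
  )
  if (is.null(n_models) || n_models <= 1L) return(base)
  coords <- lapply(seq_len(n_models), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  angles <- lapply(coords, function(co) {
    st <- base
    st$x <- co[, 1]; st$y <- co[, 2]; st$z <- co[, 3]
    interdomain_angles(st, angle_def)
  })
  angles <- dplyr::bind_rows(angles)
  new_conformer_pool(
    atoms = base[c("resno", "elety")], coords = coords,
    angles = tibble::tibble(conf = seq_len(n_models),
                            theta_ampbd = angles$theta_ampbd,
                            theta_lid = angles$theta_lid),
    domains = domains, angle_def = angle_def
  )
}

#' @rdname read_structure
#' @export
read_pool_pdb <- function(path, domains = ake_domain_definition(),
                          angle_def = ake_angle_definition()) {
  out <- read_structure(path, domains, angle_def)
  if (!inherits(out, "conformer_pool")) {
    stop(path, " holds a single model, not a pool", call. = FALSE)
  }
  out
}

#' Write a structure or conformer pool as (multi-model) PDB
#'
#' @param x atom tibble or `conformer_pool`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "conformer_pool")) {
    xyz <- do.call(rbind, lapply(x$coords, function(m) as.vector(t(m))))
    at <- x$atoms
  } else {
    x <- as_structure(x)
    xyz <- matrix(as.vector(t(coords_matrix(x))), nrow = 1)
    at <- x
  }
  n_atom <- nrow(at)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nrow(xyz) > 1L
  for (m in seq_len(nrow(xyz))) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    el <- substr(trimws(at$elety), 1, 1)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n_atom),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      "ALA", "A", at$resno, co[, 1], co[, 2], co[, 3], 1, 0, el
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an RDC table from a whitespace-delimited text file
#'
#' Expected columns: residue number, first atom name, second atom name,
#' coupling (Hz) and, optionally, uncertainty (Hz; defaults to 0.3). Lines
#' starting with `#` are ignored.
#'
#' @param path text file.
#' @return an `rdc_tbl` (origin "experimental").
#' @export
read_rdc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  nf <- lengths(rows)
  if (any(nf < 4L)) {
    stop("line ", which(keep)[which(nf < 4L)[1]],
         ": expected residue, atom1, atom2, value[, sigma]", call. = FALSE)
  }
  num <- function(v, what, col) {
    x <- suppressWarnings(as.numeric(v))
    if (anyNA(x)) {
      stop("line ", which(keep)[which(is.na(x))[1]], ": non-numeric ", what,
           call. = FALSE)
    }
    x
  }
  resid <- num(vapply(rows, `[[`, "", 1L), "residue number")
  value <- num(vapply(rows, `[[`, "", 4L), "coupling value")
  sigma <- ifelse(nf >= 5L, vapply(rows, function(r) r[5], ""), NA)
  sigma <- suppressWarnings(as.numeric(sigma))
  sigma[is.na(sigma)] <- 0.3
  rdc_table(resid, value,
            atom1 = vapply(rows, `[[`, "", 2L),
            atom2 = vapply(rows, `[[`, "", 3L),
            sigma = sigma, origin = "experimental")
}

#' Write an RDC table
#' @param x an `rdc_tbl`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rdc_table <- function(x, path) {
  lines <- c(
    "# resid atom1 atom2 value_Hz sigma_Hz",
    sprintf("%d %s %s %.6g %.6g", x$resid, x$atom1, x$atom2, x$value, x$sigma)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Reconstruct amide hydrogens from backbone geometry
#'
#' X-ray structures usually lack hydrogens; the amide H is placed 1.02
#' Angstrom from N along the bisector-based ideal geometry (opposite the
#' mean of the N->CA and N->C(i-1) directions). Residues whose previous-
#' residue carbonyl C is missing fall back to the N->CA direction alone and
#' are reported.
#'
#' @param structure atom tibble with N, CA (and ideally C) atoms.
#' @return the structure with H atoms appended for residues that lacked one.
#' @export
add_amide_hydrogens <- function(structure) {
  structure <- as_structure(structure)
  res <- sort(unique(structure$resno))
  have_h <- unique(structure$resno[structure$elety == "H"])
  todo <- setdiff(intersect(res, structure$resno[structure$elety == "N"]),
                  have_h)
  if (!length(todo)) return(structure)
  get1 <- function(r, ety) {
    i <- which(structure$resno == r & structure$elety == ety)[1]
    if (is.na(i)) return(NULL)
    c(structure$x[i], structure$y[i], structure$z[i])
  }
  fallback <- integer(0)
  new_rows <- list()
  for (r in todo) {
    n <- get1(r, "N"); ca <- get1(r, "CA")
    if (is.null(n) || is.null(ca)) next
    cprev <- get1(r - 1L, "C")
    u1 <- (n - ca) / sqrt(sum((n - ca)^2))
    if (!is.null(cprev)) {
      u2 <- (n - cprev) / sqrt(sum((n - cprev)^2))
      u <- u1 + u2
    } else {
      fallback <- c(fallback, r)
      u <- u1
    }
    u <- u / sqrt(sum(u^2))
    h <- n + 1.02 * u
    new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
      resno = r, elety = "H", x = h[1], y = h[2], z = h[3])
  }
  if (length(fallback)) {
    message("amide H placed from N->CA direction only (missing C(i-1)) ",
            "for residue(s): ", paste(fallback, collapse = ", "))
  }
  out <- dplyr::bind_rows(structure, dplyr::bind_rows(new_rows))
  dplyr::arrange(out, .data$resno)
}

#' Residues in regular secondary structure (loop filter)
#'
#' A light geometric classifier used to exclude loop residues from fits:
#' a residue is "structured" when its CA(i)-CA(i+4) distance matches a
#' helical pitch (< 7 Angstrom) or its CA(i)-CA(i+2) distance an extended
#' strand (> 6 Angstrom), in a window of two consecutive hits. Explicit
#' `include` / `exclude` residue lists override the classifier.
#'
#' @param structure atom tibble.
#' @param include,exclude optional residue vectors that override the
#'   geometric call.
#' @return integer vector of structured residue numbers.
#' @export
structured_residues <- function(structure, include = NULL, exclude = NULL) {
  ca <- atom_coords(as_structure(structure), "CA")
  res <- as.integer(rownames(ca))
  n <- nrow(ca)
  hit <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d4 <- if (i + 4 <= n) sqrt(sum((ca[i, ] - ca[i + 4, ])^2)) else NA
    d2 <- if (i + 2 <= n) sqrt(sum((ca[i, ] - ca[i + 2, ])^2)) else NA
    hit[i] <- isTRUE(d4 < 7) || isTRUE(d2 > 6)
  }
  ok <- hit & (c(hit[-1], FALSE) | c(FALSE, hit[-n]))
  out <- res[ok]
  out <- union(out, include)
  sort(setdiff(out, exclude))
}

#' Write a selection run's results to a directory
#'
#' Writes `result.json` (ensemble members, Q values, scale, seeds and the
#' resolved GA configuration), `dist.csv` (the binned angle distribution)
#' and `populations.json` so a run can be replayed and audited from its
#' output directory alone.
#'
#' @param ga a `ga_result`.
#' @param pool the `conformer_pool`.
#' @param dir output directory (created if needed).
#' @param basins optional [basin_set()] for the population summary.
#' @param bin_width histogram bin width, degrees.
#' @return `dir`, invisibly.
#' @export
write_results <- function(ga, pool, dir, basins = ake_default_basins(),
                          bin_width = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dist <- build_distribution(ga, pool, bin_width)
  pops <- basin_populations(dist, basins)
  jsonlite::write_json(
    list(
      n = ga$n,
      config = unclass(ga$config),
      repeats = lapply(seq_len(nrow(ga$repeats)), function(i) {
        list(members = ga$repeats$members[[i]],
             q_work = ga$repeats$q_work[i],
             q_free = ga$repeats$q_free[i],
             scale = ga$repeats$scale[i])
      })
    ),
    file.path(dir, "result.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(as.data.frame(dist), file.path(dir, "dist.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(pops$fraction), pops$label),
    file.path(dir, "populations.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
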