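#' Rectangular basins in inter-domain angle space
#'
#' A basin is a rectangle in (theta_AMPbd, theta_LID) space identified with
#' a conformational state; its integrated distribution weight is the state
#' population. `ake_default_basins()` gives the package defaults for
#' adenylate kinase, centred on the reported basin angles: closed-like
#' (60, 105) and open (74, 146).
#'
#' @param label basin names.
#' @param ampbd_lo,ampbd_hi,lid_lo,lid_hi rectangle bounds in degrees,
#'   inside \[0, 180\].
#' @param population optional target population (for synthetic targets).
#' @return tibble of class `basin_set`.
#' @export
basin_set <- function(label, ampbd_lo, ampbd_hi, lid_lo, lid_hi,
                      population = NULL) {
  b <- tibble::tibble(
    label = as.character(label),
    ampbd_lo = as.numeric(ampbd_lo), ampbd_hi = as.numeric(ampbd_hi),
    lid_lo = as.numeric(lid_lo), lid_hi = as.numeric(lid_hi)
  )
  if (any(b$ampbd_lo > b$ampbd_hi) || any(b$lid_lo > b$lid_hi)) {
    stop("basin bounds must satisfy lo <= hi", call. = FALSE)
  }
  if (any(c(b$ampbd_lo, b$lid_lo) < 0) || any(c(b$ampbd_hi, b$lid_hi) > 180)) {
    stop("basins must lie within [0, 180] degrees", call. = FALSE)
  }
  if (!is.null(population)) {
    if (any(population < 0)) stop("populations must be >= 0", call. = FALSE)
    b$population <- as.numeric(population)
  }
  # warn on pairwise overlap
  if (nrow(b) > 1) {
    for (i in seq_len(nrow(b) - 1)) {
      for (j in seq(i + 1, nrow(b))) {
        if (b$ampbd_lo[i] < b$ampbd_hi[j] && b$ampbd_lo[j] < b$ampbd_hi[i] &&
            b$lid_lo[i] < b$lid_hi[j] && b$lid_lo[j] < b$lid_hi[i]) {
          warning("basins '", b$label[i], "' and '", b$label[j],
                  "' overlap", call. = FALSE)
        }
      }
    }
  }
  class(b) <- c("basin_set", class(b))
  b
}

#' @rdname basin_set
#' @export
ake_default_basins <- function() {
  basin_set(
    label = c("closed-like", "open"),
    ampbd_lo = c(45, 65), ampbd_hi = c(70, 85),
    lid_lo = c(95, 135), lid_hi = c(120, 160)
  )
}

# resolve selected members: ga_result, list of index vectors, or a vector
pooled_members <- function(x) {
  if (inherits(x, "ga_result")) return(x$pooled)
  if (inherits(x, "rdc_error_replicas")) return(unlist(x$replicas$members))
  if (is.list(x)) return(unlist(x))
  as.integer(x)
}

#' Inter-domain angle distribution of selected ensembles
#'
#' Every selected ensemble member contributes equal weight
#' 1 / (members x repeats) to a 2D histogram over
#' (theta_AMPbd, theta_LID), using the angles cached on the pool.
#'
#' @param x a `ga_result`, a list of member-index vectors, or an integer
#'   vector of pool indices.
#' @param pool the `conformer_pool` the indices refer to.
#' @param bin_width histogram bin width in degrees (bins tile \[0, 180\]).
#' @return object of class `angle_distribution`: tibble with bin lower
#'   edges (`theta_ampbd_bin`, `theta_lid_bin`, degrees) and normalized
#'   `weight` (sparse: only occupied bins), with the bin width as attribute.
#' @export
build_distribution <- function(x, pool, bin_width = 2) {
  members <- pooled_members(x)
  if (length(members) == 0L) stop("no ensemble members given", call. = FALSE)
  if (any(members < 1L | members > pool_size(pool))) {
    stop("member index outside the pool", call. = FALSE)
  }
  a <- pool$angles$theta_ampbd[members]
  l <- pool$angles$theta_lid[members]
  ia <- pmin(floor(a / bin_width), ceiling(180 / bin_width) - 1)
  il <- pmin(floor(l / bin_width), ceiling(180 / bin_width) - 1)
  tab <- dplyr::count(tibble::tibble(ia = ia, il = il), ia, il)
  out <- tibble::tibble(
    theta_ampbd_bin = tab$ia * bin_width,
    theta_lid_bin = tab$il * bin_width,
    weight = tab$n / length(members)
  )
  attr(out, "bin_width") <- bin_width
  attr(out, "n_members") <- length(members)
  class(out) <- c("angle_distribution", class(out))
  out
}

# does bin (lower edge) fall inside rectangle? membership by bin centre
bin_in_basin <- function(dist, basin) {
  bw <- attr(dist, "bin_width")
  ca <- dist$theta_ampbd_bin + bw / 2
  cl <- dist$theta_lid_bin + bw / 2
  ca >= basin$ampbd_lo & ca <= basin$ampbd_hi &
    cl >= basin$lid_lo & cl <= basin$lid_hi
}

#' Basin populations of an angle distribution
#'
#' Sums the distribution weight inside each basin rectangle (bin membership
#' by bin centre); weight outside every basin is reported as "unassigned".
#'
#' @param dist an [build_distribution()] result.
#' @param basins a [basin_set()].
#' @return tibble with `label` and `fraction`; fractions sum to 1.
#' @export
basin_populations <- function(dist, basins) {
  fr <- vapply(seq_len(nrow(basins)), function(i) {
    sum(dist$weight[bin_in_basin(dist, basins[i, ])])
  }, numeric(1))
  tibble::tibble(
    label = c(basins$label, "unassigned"),
    fraction = c(fr, max(0, 1 - sum(fr)))
  )
}

#' Basin-population uncertainty across noise replicas
#'
#' Builds the angle distribution of each replica separately and reports the
#' mean and standard deviation of every basin population across replicas —
#' the package's estimate of how experimental RDC uncertainty propagates
#' into state populations.
#'
#' @param replicas an [propagate_rdc_error()] result.
#' @param pool the `conformer_pool`.
#' @param basins a [basin_set()].
#' @param bin_width histogram bin width in degrees.
#' @return tibble with `label`, `mean`, `sd` over replicas.
#' @export
population_uncertainty <- function(replicas, pool, basins, bin_width = 2) {
  if (nrow(replicas$replicas) < 2L) {
    stop("need at least 2 replicas", call. = FALSE)
  }
  per <- lapply(replicas$replicas$members, function(m) {
    basin_populations(build_distribution(m, pool, bin_width), basins)$fraction
  })
  fm <- do.call(rbind, per)
  tibble::tibble(
    label = c(basins$label, "unassigned"),
    mean = colMeans(fm),
    sd = apply(fm, 2, stats::sd)
  )
}

#' Open-state fraction along a FRET-like distance coordinate
#'
#' Projects the selected ensemble onto the CA-CA distance between a donor
#' and acceptor residue (an smFRET-style reaction coordinate) and returns
#' the fraction of ensemble weight with distance greater than the cutoff
#' (the "open" fraction in the Beckstein-style distance mapping).
#'
#' @param x a `ga_result`, list of member vectors, or integer indices.
#' @param pool the `conformer_pool`.
#' @param residue_pair length-2 integer vector of residue numbers.
#' @param open_cutoff distance threshold in Angstrom (> 0).
#' @return list with `open_fraction` and the per-member `distances` tibble.
#' @export
fret_projection <- function(x, pool, residue_pair, open_cutoff) {
  stopifnot(length(residue_pair) == 2, open_cutoff > 0)
  members <- pooled_members(x)
  ca_sel <- pool$atoms$elety == "CA"
  res_ca <- pool$atoms$resno[ca_sel]
  i1 <- match(residue_pair[1], res_ca)
  i2 <- match(residue_pair[2], res_ca)
  if (is.na(i1) || is.na(i2)) {
    stop("residue ", residue_pair[which(c(is.na(i1), is.na(i2)))[1]],
         " has no CA in the pool", call. = FALSE)
  }
  dists <- vapply(members, function(m) {
    co <- pool$coords[[m]][ca_sel, , drop = FALSE]
    sqrt(sum((co[i1, ] - co[i2, ])^2))
  }, numeric(1))
  list(open_fraction = mean(dists > open_cutoff),
       distances = tibble::tibble(member = members, distance = dists))
}

#' Plot an inter-domain angle distribution
#'
#' @param object an `angle_distribution`.
#' @param ... unused.
#' @return a ggplot2 heat map over (theta_AMPbd, theta_LID).
#' @method autoplot angle_distribution
#' @export
autoplot.angle_distribution <- function(object, ...) {
  bw <- attr(object, "bin_width")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$theta_ampbd_bin + bw / 2,
    y = .data$theta_lid_bin + bw / 2,
    fill = .data$weight
  )) +
    ggplot2::geom_tile(width = bw, height = bw) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_cartesian(xlim = c(0, 180), ylim = c(0, 180)) +
    ggplot2::labs(x = expression(theta["AMPbd"] * " (deg)"),
                  y = expression(theta["LID"] * " (deg)"),
                  fill = "weight") +
    ggplot2::theme_minimal()
}

#' Plot GA convergence traces
#'
#' @param object a `ga_result`.
#' @param ... unused.
#' @return a ggplot2 line plot of best Q_work (and Q_free when available)
#'   per step, one line per repeat.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    object$trace, c("q_work", "q_free"),
    names_to = "set", values_to = "q"
  )
  tr <- tr[!is.na(tr$q), , drop = FALSE]
  ggplot2::ggplot(tr, ggplot2::aes(
    x = .data$step, y = .data$q,
    group = interaction(.data$repeat_id, .data$set),
    colour = .data$set
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "GA step", y = "quality factor Q") +
    ggplot2::theme_minimal()
}
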