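#' Alignment (Saupe) tensor
#'
#' A 3x3 symmetric traceless matrix of orientational order parameters. The
#' constructor validates symmetry and tracelessness and symmetrizes /
#' re-centers within tight tolerance so downstream code can rely on the
#' invariants exactly.
#'
#' @param m numeric 3x3 matrix, symmetric within 1e-12 and traceless within
#'   1e-10.
#' @return an object of class `alignment_tensor` (a 3x3 matrix).
#' @examples
#' s <- alignment_tensor(diag(c(-0.5, -0.5, 1)) * 1e-3)
#' tensor_eigen(s)
#' @export
alignment_tensor <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L)) || !is.numeric(m)) {
    stop("an alignment tensor is a numeric 3x3 matrix", call. = FALSE)
  }
  scale <- max(abs(m), 1e-30)
  if (max(abs(m - t(m))) > 1e-12 * max(1, scale)) {
    stop("alignment tensor must be symmetric", call. = FALSE)
  }
  if (abs(sum(diag(m))) > 1e-10 * max(1, scale)) {
    stop("alignment tensor must be traceless", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- diag(m) - sum(diag(m)) / 3
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(m, class = c("alignment_tensor", "matrix", "array"))
}

#' @export
print.alignment_tensor <- function(x, digits = 4, ...) {
  cat("<alignment_tensor>\n")
  print(signif(unclass(x), digits))
  ev <- tensor_eigen(x)
  cat("principal values (|Szz| >= |Syy| >= |Sxx|):\n")
  print(signif(stats::setNames(ev$values, c("Szz", "Syy", "Sxx")), digits))
  invisible(x)
}

#' Eigen-decomposition of an alignment tensor
#'
#' Orders eigenvalues by decreasing magnitude (the `|Szz| >= |Syy| >= |Sxx|`
#' convention), so `values[1]` is the principal order parameter and
#' `vectors[, 1]` the principal alignment axis.
#'
#' @param s an [alignment_tensor()].
#' @return list with `values` (length 3, sum ~0) and `vectors` (3x3, columns
#'   are unit eigenvectors matching `values`).
#' @export
tensor_eigen <- function(s) {
  e <- eigen(unclass(s), symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

#' Tidy an alignment tensor into its principal frame
#'
#' @param x an [alignment_tensor()].
#' @param ... unused.
#' @return a tibble with one row per principal axis: eigenvalue and the axis
#'   direction cosines, ordered by eigenvalue magnitude.
#' @method tidy alignment_tensor
#' @export
tidy.alignment_tensor <- function(x, ...) {
  e <- tensor_eigen(x)
  tibble::tibble(
    axis = c("zz", "yy", "xx"),
    value = e$values,
    ex = e$vectors[1, ],
    ey = e$vectors[2, ],
    ez = e$vectors[3, ]
  )
}

# random valid tensor, for tests and examples
random_tensor <- function(magnitude = 1e-3) {
  a <- matrix(stats::rnorm(9), 3, 3)
  m <- (a + t(a)) / 2
  diag(m) <- diag(m) - sum(diag(m)) / 3
  alignment_tensor(m * magnitude / max(abs(m)))
}
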