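#' Physical constants for dipolar coupling calculations
#'
#' SI values used to form the maximal (static) dipolar coupling for a bonded
#' nucleus pair. Gyromagnetic ratios are signed; 15N is negative.
#'
#' @format A list with vacuum permeability `mu0` (T m/A), Planck's constant
#'   `h` (J s), gyromagnetic ratios `gamma` (rad/s/T, named by nucleus), and
#'   default effective bond lengths `r_pq` (Angstrom, named by atom pair).
#' @export
physical_constants <- list(
  mu0 = 4 * pi * 1e-7,
  h = 6.62607015e-34,
  gamma = c(
    H = 2.6752218744e8,
    N = -2.7126180400e7,
    C = 6.7282840000e7
  ),
  r_pq = c("N-H" = 1.02, "C-H" = 1.09, "C-N" = 1.329)
)

#' Maximal dipolar coupling for a bonded atom pair
#'
#' Returns the prefactor `D_max` (Hz) of the Saupe contraction
#' `D = D_max * sum_ij S_ij cos(phi_i) cos(phi_j)`:
#' `D_max = -mu0 * h * gamma_P * gamma_Q / (16 * pi^3 * r^3)`.
#' For N-H (negative gamma of 15N, r = 1.02 Angstrom) the value is positive.
#' The absolute magnitude does not affect ensemble selection because the
#' ensemble-averaged couplings are rescaled against experiment (see
#' [optimal_scale()]), which also absorbs the unknown degree of alignment of
#' the medium.
#'
#' @param pair atom-pair label, e.g. `"N-H"`; the two nucleus letters select
#'   the gyromagnetic ratios.
#' @param r_angstrom bond length in Angstrom; defaults to the stored value
#'   for the pair.
#' @param constants a list shaped like [physical_constants].
#' @return maximal coupling in Hz (signed).
#' @examples
#' d_max("N-H") # about 1.1e4 Hz
#' @export
d_max <- function(pair = "N-H", r_angstrom = NULL,
                  constants = physical_constants) {
  nuclei <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(nuclei) != 2L) {
    stop("`pair` must be of the form \"P-Q\", e.g. \"N-H\"", call. = FALSE)
  }
  gam <- constants$gamma[substr(nuclei, 1L, 1L)]
  if (anyNA(gam)) {
    stop("no gyromagnetic ratio stored for pair ", pair, call. = FALSE)
  }
  if (is.null(r_angstrom)) r_angstrom <- unname(constants$r_pq[pair])
  if (is.null(r_angstrom) || is.na(r_angstrom)) {
    stop("no default bond length for pair ", pair,
         "; supply `r_angstrom`", call. = FALSE)
  }
  r <- r_angstrom * 1e-10
  -constants$mu0 * constants$h * prod(gam) / (16 * pi^3 * r^3)
}
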