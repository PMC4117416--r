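# fixtures shared across test files, built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

toy_fixture <- function() cached("toy", function() make_toy_structure())

# ~140-conformer pool with cached couplings, for unit tests
small_pool <- function() {
  cached("small_pool", function() {
    toy <- toy_fixture()
    p <- suppressMessages(generate_hinge_pool(
      toy$structure, toy$domains, toy$angle_def,
      targets = default_angle_grid(12), jitter = 0.5, rng_seed = 3
    ))
    suppressMessages(precompute_pool_rdcs(p))
  })
}

# the full desk-scale pool (~2000 conformers), for acceptance tests
desk_pool <- function() {
  cached("desk_pool", function() {
    toy <- toy_fixture()
    p <- suppressMessages(generate_hinge_pool(
      toy$structure, toy$domains, toy$angle_def, rng_seed = 7
    ))
    suppressMessages(precompute_pool_rdcs(p))
  })
}

# structure whose amide N-H vectors are exactly the given unit row vectors
structure_from_vectors <- function(v) {
  n <- nrow(v)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    npos <- c(10 * i, 0, 0)
    tibble::tibble(
      resno = i, elety = c("N", "CA", "H"),
      x = c(npos[1], npos[1], npos[1] + v[i, 1]),
      y = c(0, 2, v[i, 2]),
      z = c(0, 0, v[i, 3])
    )
  }))
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# independent brute-force Saupe contraction: explicit double loop over i, j
brute_force_rdc <- function(v, s, dmax) {
  vapply(seq_len(nrow(v)), function(k) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) acc <- acc + s[i, j] * v[k, i] * v[k, j]
    dmax * acc
  }, numeric(1))
}

# independent random symmetric traceless matrix
random_saupe <- function(mag = 1e-3) {
  a <- matrix(stats::rnorm(9), 3, 3)
  m <- (a + t(a)) / 2
  diag(m) <- diag(m) - sum(diag(m)) / 3
  m * mag / max(abs(m))
}
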