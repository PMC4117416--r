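test_that("alignment tensor constructor enforces symmetry and tracelessness", {
  expect_error(alignment_tensor(matrix(1:9, 3)), "symmetric")
  m <- diag(c(1, 1, 1)) * 1e-3
  expect_error(alignment_tensor(m), "traceless")
  s <- alignment_tensor(diag(c(-0.5, -0.5, 1)) * 1e-3)
  e <- tensor_eigen(s)
  expect_true(all(diff(abs(e$values)) <= 1e-15))
  expect_lt(abs(sum(e$values)), 1e-12)
})

test_that("d_max reproduces the dipolar prefactor from stored constants", {
  k <- physical_constants
  r <- 1.02e-10
  expected <- -k$mu0 * k$h * k$gamma[["H"]] * k$gamma[["N"]] / (16 * pi^3 * r^3)
  expect_equal(d_max("N-H"), expected)
  expect_gt(d_max("N-H"), 0) # negative gamma of 15N flips the sign
  expect_lt(d_max("C-H"), 0)
  expect_error(d_max("N-X"), "gyromagnetic")
})

test_that("back-calculation matches closed forms of the Saupe contraction", {
  s_mag <- 1e-3
  axial <- alignment_tensor(diag(c(-s_mag / 2, -s_mag / 2, s_mag)))
  magic <- sqrt(c(1, 1, 1) / 3)
  st <- structure_from_vectors(rbind(c(0, 0, 1), magic))
  zero <- back_calculate(st, alignment_tensor(matrix(0, 3, 3)))
  expect_equal(zero$value, c(0, 0))
  d <- back_calculate(st, axial)
  expect_equal(d$value[1], d_max("N-H") * s_mag)
  expect_equal(d$value[2], 0, tolerance = 1e-12)
})

test_that("back-calculation agrees with a brute-force double-loop oracle", {
  withr::with_seed(11, {
    v <- random_unit_vectors(20)
    s <- random_saupe()
  })
  st <- structure_from_vectors(v)
  got <- back_calculate(st, alignment_tensor(s))$value
  want <- brute_force_rdc(v, s, d_max("N-H"))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("back-calculation is linear in the tensor and frame-covariant", {
  withr::with_seed(4, {
    v <- random_unit_vectors(15)
    s1 <- random_saupe()
    s2 <- random_saupe()
    r <- rdcens:::random_rotation()
  })
  st <- structure_from_vectors(v)
  d1 <- back_calculate(st, alignment_tensor(s1))$value
  d2 <- back_calculate(st, alignment_tensor(s2))$value
  d12 <- back_calculate(st, alignment_tensor(2 * s1 + 0.3 * s2))$value
  expect_equal(d12, 2 * d1 + 0.3 * d2, tolerance = 1e-10)
  # rotating the structure and the tensor frame together changes nothing
  st_rot <- rdcens:::transform_structure(st, rot = r)
  d_rot <- back_calculate(st_rot, alignment_tensor(r %*% s1 %*% t(r)))$value
  expect_equal(d_rot, d1, tolerance = 1e-10)
})

test_that("ensemble averaging is the plain mean over members", {
  withr::with_seed(7, {
    v <- random_unit_vectors(12)
    tensors <- lapply(1:4, function(i) alignment_tensor(random_saupe()))
  })
  st <- structure_from_vectors(v)
  keys <- rdc_keys(st)
  members <- lapply(tensors, function(s) list(structure = st, tensor = s))

  one <- ensemble_average(members[1], keys)
  expect_equal(one$value, back_calculate(st, tensors[[1]], keys)$value)

  flip <- list(members[[1]],
               list(structure = st,
                    tensor = alignment_tensor(-unclass(tensors[[1]]))))
  expect_equal(ensemble_average(flip, keys)$value, rep(0, 12),
               tolerance = 1e-15)

  per_member <- vapply(members,
                       function(m) back_calculate(st, m$tensor, keys)$value,
                       numeric(12))
  expect_equal(ensemble_average(members, keys)$value, rowMeans(per_member),
               tolerance = 1e-12)
  expect_error(ensemble_average(list(), keys), "empty")
})

test_that("Q factor satisfies its analytic identities", {
  exp <- rdc_table(1:3, c(1, 2, 3))
  expect_equal(q_factor(rdc_table(1:3, c(1, 2, 3), origin = "calculated"), exp), 0)
  expect_equal(q_factor(rdc_table(1:3, c(-1, -2, -3), origin = "calculated"), exp), 2)
  expect_equal(
    q_factor(rdc_table(1:3, c(1, 2, 4), origin = "calculated"), exp),
    sqrt(1 / 14)
  )
  expect_error(q_factor(rdc_table(7:9, 1:3, origin = "calculated"), exp),
               "shared")
  expect_error(q_factor(rdc_table(1:3, 1:3, origin = "calculated"),
                        rdc_table(1:3, c(0, 0, 0))), "zero")
})

test_that("optimal scaling minimizes Q and matches a grid-search oracle", {
  exp <- rdc_table(1:8, c(3, -1, 4, 1, -5, 9, 2, -6))
  calc2 <- rdc_table(1:8, 2 * exp$value, origin = "calculated")
  os <- optimal_scale(calc2, exp)
  expect_equal(os$scale, 0.5)
  expect_equal(os$q, 0)

  orth <- rdc_table(1:2, c(1, 1), origin = "calculated")
  expect_equal(optimal_scale(orth, rdc_table(1:2, c(1, -1)))$scale, 0)

  withr::with_seed(21, {
    calc <- rdc_table(1:30, rnorm(30), origin = "calculated")
    expv <- rdc_table(1:30, rnorm(30))
  })
  os <- optimal_scale(calc, expv)
  grid <- seq(-3, 3, by = 1e-4)
  qs <- vapply(grid, function(s) {
    sqrt(mean((s * calc$value - expv$value)^2)) / sqrt(mean(expv$value^2))
  }, numeric(1))
  expect_equal(os$scale, grid[which.min(qs)], tolerance = 1e-3)
  expect_lte(os$q, min(qs) + 1e-12)
  expect_lte(os$q, q_factor(calc, expv))
})

test_that("SVD tensor fit recovers a generating tensor exactly", {
  withr::with_seed(31, {
    v <- random_unit_vectors(10)
    s <- random_saupe()
  })
  st <- structure_from_vectors(v)
  truth <- back_calculate(st, alignment_tensor(s))
  exp <- rdc_table(truth$resid, truth$value)
  fit <- fit_tensor_svd(st, exp)
  expect_equal(unclass(fit$tensor), unclass(alignment_tensor(s)),
               tolerance = 1e-8)
  expect_lt(fit$q, 1e-10)
  # round trip: refitted tensor reproduces the couplings
  expect_equal(back_calculate(st, fit$tensor)$value, truth$value,
               tolerance = 1e-8)
})

test_that("SVD tensor fit rejects under-determined or degenerate input", {
  withr::with_seed(5, v <- random_unit_vectors(4))
  st <- structure_from_vectors(v)
  expect_error(fit_tensor_svd(st, rdc_table(1:4, rnorm(4))), ">= 5")
  same <- structure_from_vectors(matrix(rep(c(0, 0, 1), 8), 8, 3,
                                        byrow = TRUE))
  expect_error(fit_tensor_svd(same, rdc_table(1:8, rnorm(8))),
               "rank-deficient")
})

test_that("SVD fit equals the normal-equations least-squares oracle on noisy data", {
  withr::with_seed(43, {
    v <- random_unit_vectors(25)
    s <- random_saupe()
    noise <- rnorm(25, 0, 0.5)
  })
  st <- structure_from_vectors(v)
  y <- back_calculate(st, alignment_tensor(s))$value + noise
  fit <- fit_tensor_svd(st, rdc_table(1:25, y))
  a <- rdcens:::saupe_design(v) * d_max("N-H")
  p <- solve(t(a) %*% a, t(a) %*% y)
  want <- rdcens:::saupe_from_params(drop(p))
  expect_equal(unclass(fit$tensor), unclass(want), tolerance = 1e-8)
})

test_that("rdc_table enforces its key and uncertainty contract", {
  expect_error(rdc_table(c(1, 1), c(2, 3)), "duplicate")
  expect_error(rdc_table(1, 2, sigma = -1), "sigma")
  expect_error(rdc_table(1, 2, atom1 = ""), "non-empty")
  t <- rdc_table(1:3, 1:3)
  expect_equal(t$sigma, rep(0.3, 3)) # default experimental uncertainty
  expect_identical(attr(t, "origin"), "experimental")
})
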