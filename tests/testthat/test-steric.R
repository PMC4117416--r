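make_rod <- function(n = 20, spacing = 4, radius = 3.8) {
  structure(list(centers = cbind(0, 0, seq(0, by = spacing, length.out = n)),
                 radii = rep(radius, n), scheme = "residue"),
            class = "bead_model")
}

test_that("coarse graining preserves counts and is translation-equivariant", {
  toy <- toy_fixture()
  chain <- toy$structure[toy$structure$resno <= 10, ]
  res_model <- coarse_grain(chain, "residue")
  expect_equal(nrow(res_model$centers), 10)
  atom_model <- coarse_grain(chain, "atom")
  heavy <- sum(substr(chain$elety, 1, 1) != "H")
  expect_equal(nrow(atom_model$centers), heavy)
  shifted <- chain
  shifted$x <- chain$x + 5; shifted$y <- chain$y - 3; shifted$z <- chain$z + 1
  m2 <- coarse_grain(shifted, "residue")
  expect_equal(m2$centers, res_model$centers + rep(c(5, -3, 1), each = 10))
  expect_equal(m2$radii, res_model$radii)
  no_ca <- chain[chain$elety != "CA", ]
  expect_error(coarse_grain(no_ca, "residue"), "CA")
})

test_that("steric tensors are symmetric and traceless for arbitrary shapes", {
  withr::with_seed(2, {
    for (i in 1:5) {
      centers <- matrix(rnorm(3 * 30, sd = 10), ncol = 3)
      model <- structure(list(centers = centers, radii = rep(3, 30),
                              scheme = "residue"), class = "bead_model")
      s <- unclass(predict_tensor(model))
      expect_lt(max(abs(s - t(s))), 1e-12)
      expect_lt(abs(sum(diag(s))), 1e-10)
    }
  })
})

test_that("a spherical bead shell has no orientational preference", {
  # 100 beads give a smooth shell; fewer leave genuine surface bumps
  n <- 100
  u <- rdcens:::fib_dirs(1:n, n) * 15
  sphere <- structure(list(centers = u, radii = rep(3.8, n),
                           scheme = "residue"), class = "bead_model")
  s_sphere <- tensor_eigen(predict_tensor(sphere))$values
  s_rod <- tensor_eigen(predict_tensor(make_rod(n)))$values
  expect_lt(max(abs(s_sphere)), 1e-3 * max(abs(s_rod)))
})

test_that("rod tensor matches a 1e6-sample Monte-Carlo excluded-orientation oracle", {
  model <- make_rod(20, spacing = 4)
  cfg <- steric_config(grid_deg = 10)
  s <- predict_tensor(model, cfg)
  ev <- tensor_eigen(s)
  # axially symmetric with the principal axis on the rod axis
  expect_lt(abs(ev$values[2] - ev$values[3]) / abs(ev$values[1]), 0.05)
  expect_lt(acos(abs(ev$vectors[3, 1])) * 180 / pi, 2)

  # oracle: random orientations and positions with an explicit per-bead
  # plane-overlap test
  withr::with_seed(42, {
    nmc <- 1e6
    u <- matrix(rnorm(3 * nmc), 3)
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
    com <- colMeans(model$centers)
    l <- 4 * (sqrt(max(rowSums(sweep(model$centers, 2, com)^2))) +
                max(model$radii))
    p <- model$centers %*% u
    r <- model$radii[1]
    shift <- runif(nmc, 0, l) - (Reduce(pmin, asplit(p, 1)) - r)
    ok <- rep(TRUE, nmc)
    for (k in seq_len(nrow(p))) {
      z <- p[k, ] + shift
      ok <- ok & (z - r >= -1e-9) & (z + r <= l + 1e-9)
    }
  })
  ua <- u[, ok]
  m2 <- ua %*% t(ua) / ncol(ua)
  s_mc <- (3 * m2 - diag(3)) / 2
  ev_mc <- eigen((s_mc + t(s_mc)) / 2, symmetric = TRUE)
  vals_mc <- ev_mc$values[order(abs(ev_mc$values), decreasing = TRUE)]
  expect_equal(ev$values, vals_mc, tolerance = 0.05)
})

test_that("steric prediction is rotation-equivariant and translation-invariant", {
  toy <- toy_fixture()
  model <- coarse_grain(toy$structure)
  cfg <- steric_config()
  s <- unclass(predict_tensor(model, cfg))
  withr::with_seed(9, rots <- replicate(3, rdcens:::random_rotation(),
                                        simplify = FALSE))
  for (r in rots) {
    m2 <- model
    m2$centers <- model$centers %*% t(r)
    s2 <- unclass(predict_tensor(m2, cfg))
    # tolerance set by the 10-degree orientation grid
    expect_lt(norm(s2 - r %*% s %*% t(r), "F") / norm(s, "F"), 0.12)
  }
  m3 <- model
  m3$centers <- sweep(model$centers, 2, c(13, -7, 22), "+")
  expect_equal(unclass(predict_tensor(m3, cfg)), s, tolerance = 1e-12)
})

test_that("tighter confinement strengthens alignment monotonically", {
  model <- coarse_grain(toy_fixture()$structure)
  com <- colMeans(model$centers)
  rmax <- sqrt(max(rowSums(sweep(model$centers, 2, com)^2))) +
    max(model$radii)
  szz <- vapply(c(8, 4, 2) * rmax, function(l) {
    abs(tensor_eigen(predict_tensor(model, steric_config(spacing = l)))$values[1])
  }, numeric(1))
  expect_true(all(diff(szz) > 0))
})

test_that("degenerate barrier spacing and invalid grids are rejected", {
  model <- make_rod(10)
  expect_error(predict_tensor(model, steric_config(spacing = 1)),
               "cannot fit")
  expect_error(steric_config(grid_deg = 0), "grid_deg")
  expect_error(steric_config(grid_deg = 45), "grid_deg")
})

test_that("open and closed conformations give distinct tensors", {
  open <- make_toy_structure(preset = "open")
  closed <- make_toy_structure(preset = "closed")
  e_open <- tensor_eigen(predict_tensor(coarse_grain(open$structure)))$values[1]
  e_closed <- tensor_eigen(predict_tensor(coarse_grain(closed$structure)))$values[1]
  expect_gt(abs(e_open - e_closed) / max(abs(c(e_open, e_closed))), 0.10)
})
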