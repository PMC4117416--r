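# synthetic couplings equal to one pool conformer's, for exact-recovery tests
conformer_target <- function(pool, i) {
  rdc_table(pool$keys$resid, pool$rdc[i, ], pool$keys$atom1,
            pool$keys$atom2, sigma = 0, origin = "synthetic")
}

test_that("the GA finds the generating conformer of a noise-free target", {
  p <- small_pool()
  exp <- conformer_target(p, 37)
  res <- run_ga(p, exp, 1, ga_config_scaled(rng_seed = 5, n_repeats = 2))
  expect_true(all(vapply(res$repeats$members, identical, TRUE, 37L)))
  expect_lt(min(res$repeats$q_work), 1e-8)
})

test_that("the GA attains the exhaustive-search optimum for small pools", {
  p <- small_pool()
  idx <- round(seq(1, pool_size(p), length.out = 20))
  sub <- p
  sub$coords <- p$coords[idx]
  sub$angles <- p$angles[idx, ]
  sub$rdc <- p$rdc[idx, ]
  attr(sub$rdc, "hash") <- attr(p$rdc, "hash")
  sub$tensors <- p$tensors[idx]
  withr::with_seed(99, {
    y <- colMeans(sub$rdc[c(3, 14), ]) +
      rnorm(ncol(sub$rdc), 0, 0.01 * max(abs(sub$rdc)))
  })
  exp <- rdc_table(sub$keys$resid, y, sigma = 0, origin = "synthetic")
  # oracle: enumerate all unordered pairs with repetition
  best_q <- Inf
  for (i in 1:20) {
    for (j in i:20) {
      cm <- (sub$rdc[i, ] + sub$rdc[j, ]) / 2
      s <- sum(cm * y) / sum(cm^2)
      q <- sqrt(mean((s * cm - y)^2)) / sqrt(mean(y^2))
      best_q <- min(best_q, q)
    }
  }
  hits <- 0
  for (sd in 1:10) {
    g <- run_ga(sub, exp, 2, ga_config_scaled(rng_seed = sd, n_repeats = 1,
                                              n_ensembles = 100,
                                              n_steps = 150))
    q <- g$repeats$q_work[1]
    expect_lte(q, best_q * 1.01)
    if (q <= best_q + 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("GA runs are elitist and deterministic under a seed", {
  p <- small_pool()
  exp <- conformer_target(p, 80)
  cfg <- ga_config_scaled(rng_seed = 12, n_repeats = 2, n_steps = 100)
  a <- run_ga(p, exp, 4, cfg, free = 1:15)
  b <- run_ga(p, exp, 4, cfg, free = 1:15)
  expect_identical(a$repeats, b$repeats)
  expect_identical(a$trace, b$trace)
  for (r in unique(a$trace$repeat_id)) {
    tr <- a$trace[a$trace$repeat_id == r, ]
    expect_true(all(diff(tr$q_work) <= 1e-15))
    expect_true(all(tr$mutation_rate >= 0.001 & tr$mutation_rate <= 1))
    expect_true(all(diff(tr$mutation_rate) <= 0))
    expect_true(all(diff(tr$crossing_rate) >= 0))
  }
})

test_that("GA input contracts are enforced", {
  p <- small_pool()
  exp <- conformer_target(p, 5)
  expect_error(run_ga(p, exp, pool_size(p) + 1, ga_config_scaled()),
               "exceeds pool size")
  alien <- rdc_table(900:905, rnorm(6))
  expect_error(run_ga(p, alien, 2, ga_config_scaled()), "shared")
  raw <- small_pool()
  raw$rdc <- NULL
  expect_error(run_ga(raw, exp, 2, ga_config_scaled()), "precompute")
})

test_that("scaled-preset GA traces plateau within the run", {
  p <- small_pool()
  withr::with_seed(6, {
    y <- colMeans(p$rdc[sample(pool_size(p), 12), ]) +
      rnorm(ncol(p$rdc), 0, 0.01 * max(abs(p$rdc)))
  })
  exp <- rdc_table(p$keys$resid, y, sigma = 0, origin = "synthetic")
  res <- run_ga(p, exp, 8, ga_config_scaled(rng_seed = 3, n_repeats = 1))
  tr <- res$trace
  last <- tr$q_work[nrow(tr)]
  at200 <- tr$q_work[nrow(tr) - 100]
  expect_lt((at200 - last) / last, 0.01) # < 1% change over the last 100 steps
})

test_that("ensemble-size selection picks N = 1 for a single-conformer target", {
  p <- small_pool()
  exp <- conformer_target(p, 60)
  sel <- select_ensemble_size(
    p, exp, ga_config_scaled(rng_seed = 2, sizes = c(1, 2, 4)),
    n_holdout_sets = 2, runs_per_set = 2
  )
  expect_equal(sel$best_n, 1)
})

test_that("error propagation reproduces its noise model", {
  p <- small_pool()
  exp <- conformer_target(p, 21)
  reps <- propagate_rdc_error(p, exp, 2, sigma = 1.0, n_replicas = 6,
                              config = ga_config_scaled(rng_seed = 9,
                                                        n_steps = 60,
                                                        n_ensembles = 60))
  expect_equal(nrow(reps$replicas), 6)
  # noise realizations are Gaussian with the requested spread (126 couplings)
  sds <- vapply(reps$replicas$noise, sd, numeric(1))
  expect_true(all(abs(sds - 1.0) < 0.1 * 3)) # 3 sigma of sd estimate at n=126
  expect_lt(abs(mean(sds) - 1.0), 0.1)
  # sigma = 0 replicas all see the unperturbed couplings
  reps0 <- propagate_rdc_error(p, exp, 2, sigma = 0, n_replicas = 3,
                               config = ga_config_scaled(rng_seed = 9,
                                                         n_steps = 60,
                                                         n_ensembles = 60))
  expect_true(all(vapply(reps0$replicas$noise,
                         function(x) all(x == 0), TRUE)))
  reps0b <- propagate_rdc_error(p, exp, 2, sigma = 0, n_replicas = 3,
                                config = ga_config_scaled(rng_seed = 9,
                                                          n_steps = 60,
                                                          n_ensembles = 60))
  expect_identical(reps0$replicas, reps0b$replicas)
})
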