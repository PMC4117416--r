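test_that("scrambling permutes values but preserves the multiset", {
  exp <- rdc_table(1:20, seq(-10, 9) + 0.5)
  scr <- scramble_rdcs(exp, rng_seed = 3)
  expect_equal(sort(scr$value), sort(exp$value))
  expect_equal(scr$resid, exp$resid)
  expect_false(identical(scr$value, exp$value))
  expect_identical(scramble_rdcs(exp, rng_seed = 3), scr)
  # an identity permutation is seedable for tiny sets
  two <- rdc_table(1:2, c(1, 2))
  id_seed <- NULL
  for (s in 1:50) {
    if (identical(scramble_rdcs(two, s)$value, two$value)) {
      id_seed <- s
      break
    }
  }
  expect_false(is.null(id_seed))
  expect_identical(scramble_rdcs(two, id_seed)$value, two$value)
  expect_error(scramble_rdcs(rdc_table(1, 5), 1), ">= 2")
})

test_that("synthetic couplings from one conformer reproduce it exactly", {
  p <- small_pool()
  i <- 42L
  a <- p$angles$theta_ampbd[i]
  l <- p$angles$theta_lid[i]
  box <- basin_set("point", a - 0.01, a + 0.01, l - 0.01, l + 0.01,
                   population = 1)
  expect_length(rdcens:::conformers_in_basin(p, box), 1)
  synth <- make_synthetic_rdcs(p, box, noise_pct = 0)
  expect_equal(synth$value, unname(p$rdc[i, ]))
  expect_identical(attr(synth, "origin"), "synthetic")
})

test_that("two-box synthetic couplings equal the weighted mean of box means", {
  p <- small_pool()
  boxes <- basin_set(c("lo", "hi"),
                     ampbd_lo = c(35, 70), ampbd_hi = c(50, 85),
                     lid_lo = c(95, 140), lid_hi = c(110, 155),
                     population = c(0.5, 0.5))
  synth <- make_synthetic_rdcs(p, boxes, noise_pct = 0)
  g <- attr(synth, "generating_conformers")
  want <- 0.5 * colMeans(p$rdc[g$lo, , drop = FALSE]) +
    0.5 * colMeans(p$rdc[g$hi, , drop = FALSE])
  expect_equal(synth$value, unname(want), tolerance = 1e-12)
  # noise magnitude follows the percent-of-maximum convention
  noisy <- make_synthetic_rdcs(p, boxes, noise_pct = 3, rng_seed = 8)
  expect_equal(attr(noisy, "noise_sd"), 0.03 * max(abs(want)))
  empty <- basin_set("void", 0, 5, 0, 5, population = 1)
  expect_error(make_synthetic_rdcs(p, empty), "no pool conformer")
})

test_that("tensor-error scales follow the closed-form exponential profile", {
  p <- small_pool()
  expect_equal(tensor_error_scales(p, 1), rep(1, pool_size(p)))
  for (fold in c(2, 10)) {
    sc <- tensor_error_scales(p, fold)
    a <- p$angles$theta_ampbd
    l <- p$angles$theta_lid
    d <- sqrt(((a - mean(range(a))) / (diff(range(a)) / 2))^2 +
                ((l - mean(range(l))) / (diff(range(l)) / 2))^2)
    d <- d / max(d)
    expect_equal(sc, fold^d, tolerance = 1e-12)
    # endpoint conformer carries exactly the requested fold
    expect_equal(max(sc), fold, tolerance = 1e-9)
    expect_gte(min(sc), 1)
  }
})

test_that("tensor-error robustness reports per-fold population shifts", {
  p <- small_pool()
  basins <- ake_default_basins()
  boxes <- basins
  boxes$population <- c(0.5, 0.5)
  synth <- make_synthetic_rdcs(p, boxes, noise_pct = 0)
  cfg <- ga_config_scaled(rng_seed = 21, n_repeats = 2, n_steps = 80,
                          n_ensembles = 80)
  out <- tensor_error_robustness(p, synth, 8, basins, folds = c(3, 20),
                                 config = cfg)
  expect_setequal(unique(out$fold), c(1, 3, 20))
  expect_true(all(out$shift[out$fold == 1] == 0))
  base <- run_ga(p, synth, 8, cfg)
  want <- basin_populations(build_distribution(base, p), basins)$fraction
  expect_equal(out$fraction[out$fold == 1], want)
})

test_that("noise-free reconstruction recovers every generating basin", {
  p <- small_pool()
  i <- c(20L, 110L)
  boxes <- basin_set(
    c("g1", "g2"),
    ampbd_lo = p$angles$theta_ampbd[i] - 0.01,
    ampbd_hi = p$angles$theta_ampbd[i] + 0.01,
    lid_lo = p$angles$theta_lid[i] - 0.01,
    lid_hi = p$angles$theta_lid[i] + 0.01,
    population = c(0.5, 0.5)
  )
  synth <- make_synthetic_rdcs(p, boxes, noise_pct = 0)
  g <- run_ga(p, synth, 2, ga_config_scaled(rng_seed = 30, n_repeats = 2))
  expect_lt(min(g$repeats$q_work), 1e-6)
  # every generating basin is occupied by the selected members (scored with
  # a 3-degree pad so bin centres can fall inside the point-like boxes)
  padded <- boxes
  padded$ampbd_lo <- padded$ampbd_lo - 3; padded$ampbd_hi <- padded$ampbd_hi + 3
  padded$lid_lo <- padded$lid_lo - 3; padded$lid_hi <- padded$lid_hi + 3
  pops <- basin_populations(build_distribution(g, p), padded)
  expect_gt(pops$fraction[1], 0)
  expect_gt(pops$fraction[2], 0)
})

test_that("population sweep recovers pure states at zero tensor error", {
  p <- small_pool()
  sw <- population_recovery_sweep(
    p, ake_default_basins(), p_step = 0.5, folds = numeric(0), n = 4,
    n_runs = 2, config = ga_config_scaled(rng_seed = 41, n_steps = 100,
                                          n_ensembles = 100)
  )
  det <- tidy(sw)
  expect_equal(det$p_true, c(0, 0.5, 1))
  expect_lt(det$deviation[det$p_true == 0], 0.05)
  expect_lt(det$deviation[det$p_true == 1], 0.05)
  expect_true(all(det$p_recovered >= 0 & det$p_recovered <= 1))
})
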