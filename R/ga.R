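#' Genetic-algorithm configuration
#'
#' The published schedule: 1000 ensembles evolved for 1000 steps; at each
#' step every ensemble produces one mutated and one crossed copy (3000
#' candidates) and the best 1000 by Q are retained; the mutation rate starts
#' at 100% and is divided by 1.001 each step while the crossing rate starts
#' at 2% and is multiplied by 1.001; the best ensemble after the final step
#' is saved and the whole procedure repeated 200 times. `ga_config_scaled()`
#' is the desk-scale preset used by the package's tests and validation runs
#' (200 ensembles, 300 steps, 20 repeats).
#'
#' @param n_ensembles population size.
#' @param n_steps evolution steps per run.
#' @param n_repeats independent repeats whose best ensembles are pooled.
#' @param sizes ensemble sizes N considered by size selection.
#' @param mutation_rate0,crossing_rate0 initial per-ensemble operator
#'   probabilities.
#' @param rate_factor per-step factor (mutation divided, crossing
#'   multiplied); rates are clamped to \[0.001, 1\].
#' @param rng_seed integer master seed; every repeat draws an independent
#'   sub-seed from it.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(n_ensembles = 1000, n_steps = 1000, n_repeats = 200,
                      sizes = c(1, 2, 4, 8, 16, 32, 64),
                      mutation_rate0 = 1.0, crossing_rate0 = 0.02,
                      rate_factor = 1.001, rng_seed = 1L) {
  stopifnot(n_ensembles >= 1, n_steps >= 1, n_repeats >= 1,
            mutation_rate0 >= 0, mutation_rate0 <= 1,
            crossing_rate0 >= 0, crossing_rate0 <= 1, rate_factor >= 1)
  structure(list(
    n_ensembles = as.integer(n_ensembles), n_steps = as.integer(n_steps),
    n_repeats = as.integer(n_repeats), sizes = as.integer(sizes),
    mutation_rate0 = mutation_rate0, crossing_rate0 = crossing_rate0,
    rate_factor = rate_factor, rng_seed = as.integer(rng_seed)
  ), class = "ga_config")
}

#' @rdname ga_config
#' @export
ga_config_scaled <- function(rng_seed = 1L, n_ensembles = 200, n_steps = 300,
                             n_repeats = 20,
                             sizes = c(1, 2, 4, 8, 16, 32)) {
  ga_config(n_ensembles = n_ensembles, n_steps = n_steps,
            n_repeats = n_repeats, sizes = sizes, rng_seed = rng_seed)
}

# Q of each candidate at its optimal scale, from member-sum matrix S
# (rows = candidates): min_s ||s*S/N - y||^2 = yy - (S.y)^2/(S.S)
q_from_sums <- function(s_mat, y) {
  yy <- sum(y^2)
  cy <- drop(s_mat %*% y)
  cc <- rowSums(s_mat^2)
  q2 <- ifelse(cc > 0, pmax(0, yy - cy^2 / cc) / yy, 1)
  sqrt(q2)
}

scale_from_sums <- function(s_vec, y, n) {
  cc <- sum(s_vec^2)
  if (cc == 0) return(0)
  n * sum(s_vec * y) / cc
}

# one GA run (a single repeat) on the precomputed coupling matrix.
# d: n_pool x n_keys; y: work couplings; y_free optional held-out couplings
# (d_free their columns). Returns best ensemble, traces, scale.
ga_single_run <- function(d, y, n, config, seed, d_free = NULL,
                          y_free = NULL) {
  set.seed(seed)
  n_pool <- nrow(d)
  n_ens <- config$n_ensembles
  pop <- matrix(sample.int(n_pool, n_ens * n, replace = TRUE), n_ens, n)
  s <- matrix(0, n_ens, length(y))
  for (j in seq_len(n)) s <- s + d[pop[, j], , drop = FALSE]
  mrate <- config$mutation_rate0
  crate <- config$crossing_rate0
  trace_q <- numeric(config$n_steps)
  trace_qf <- rep(NA_real_, config$n_steps)
  trace_m <- numeric(config$n_steps)
  trace_c <- numeric(config$n_steps)
  q <- q_from_sums(s, y)

  for (step in seq_len(config$n_steps)) {
    # mutated copies: replace one uniformly chosen member by a pool draw
    mut <- stats::runif(n_ens) < mrate
    slot <- sample.int(n, n_ens, replace = TRUE)
    repl <- sample.int(n_pool, n_ens, replace = TRUE)
    pop_m <- pop
    s_m <- s
    if (any(mut)) {
      i <- which(mut)
      old <- pop[cbind(i, slot[i])]
      pop_m[cbind(i, slot[i])] <- repl[i]
      s_m[i, ] <- s[i, , drop = FALSE] +
        d[repl[i], , drop = FALSE] - d[old, , drop = FALSE]
    }
    # crossed copies: randomly pair ensembles, swap one member per pair
    perm <- sample.int(n_ens)
    half <- n_ens %/% 2L
    a <- perm[seq_len(half)]
    b <- perm[half + seq_len(half)]
    cross <- stats::runif(half) < crate
    pop_c <- pop
    s_c <- s
    if (any(cross)) {
      k <- which(cross)
      ja <- sample.int(n, length(k), replace = TRUE)
      jb <- sample.int(n, length(k), replace = TRUE)
      xa <- pop[cbind(a[k], ja)]
      xb <- pop[cbind(b[k], jb)]
      pop_c[cbind(a[k], ja)] <- xb
      pop_c[cbind(b[k], jb)] <- xa
      s_c[a[k], ] <- s_c[a[k], , drop = FALSE] +
        d[xb, , drop = FALSE] - d[xa, , drop = FALSE]
      s_c[b[k], ] <- s_c[b[k], , drop = FALSE] +
        d[xa, , drop = FALSE] - d[xb, , drop = FALSE]
    }
    # truncation selection of the best n_ens among the 3 * n_ens candidates
    q_all <- c(q, q_from_sums(s_m, y), q_from_sums(s_c, y))
    keep <- order(q_all, method = "radix")[seq_len(n_ens)]
    pop_all <- rbind(pop, pop_m, pop_c)
    s_all <- rbind(s, s_m, s_c)
    pop <- pop_all[keep, , drop = FALSE]
    s <- s_all[keep, , drop = FALSE]
    q <- q_all[keep]

    trace_q[step] <- q[1]
    trace_m[step] <- mrate
    trace_c[step] <- crate
    if (!is.null(y_free)) {
      sc <- scale_from_sums(s[1, ], y, n)
      calc_free <- colSums(d_free[pop[1, ], , drop = FALSE]) / n
      trace_qf[step] <- q_factor_vec(sc * calc_free, y_free)
    }
    mrate <- min(1, max(0.001, mrate / config$rate_factor))
    crate <- min(1, max(0.001, crate * config$rate_factor))
  }
  best <- sort(pop[1, ])
  sc <- scale_from_sums(s[1, ], y, n)
  q_free <- if (!is.null(y_free)) {
    calc_free <- colSums(d_free[best, , drop = FALSE]) / n
    q_factor_vec(sc * calc_free, y_free)
  } else NA_real_
  list(members = best, q_work = q[1], q_free = q_free, scale = sc,
       trace = tibble::tibble(step = seq_len(config$n_steps),
                              q_work = trace_q, q_free = trace_qf,
                              mutation_rate = trace_m,
                              crossing_rate = trace_c))
}

# match an rdc table to the pool's cached key/coupling matrix
pool_match_exp <- function(pool, exp) {
  if (is.null(pool$rdc)) {
    stop("pool has no cached RDCs; run precompute_pool_rdcs() first",
         call. = FALSE)
  }
  i <- match(rdc_key(exp), rdc_key(pool$keys))
  keep <- !is.na(i)
  if (!any(keep)) stop("no shared RDC keys between pool and data", call. = FALSE)
  list(d = pool$rdc[, i[keep], drop = FALSE], y = exp$value[keep],
       keys = exp[keep, c("resid", "atom1", "atom2")])
}

#' Select conformer ensembles that fit RDCs with a genetic algorithm
#'
#' Searches the pool for size-`n` multisets of conformers whose
#' ensemble-averaged, optimally rescaled couplings minimize the quality
#' factor Q against `exp`. Each repeat is an independent evolution from a
#' random population; the best ensemble of every repeat is kept and their
#' members pooled for distribution analysis. Repeats are seeded from the
#' config's master seed, so results are fully reproducible.
#'
#' @param pool a `conformer_pool` with cached RDCs
#'   (see [precompute_pool_rdcs()]).
#' @param exp experimental (or synthetic) `rdc_tbl`.
#' @param n ensemble size (members are drawn with replacement, so repeated
#'   members can express unequal state populations).
#' @param config a [ga_config()].
#' @param free optional integer indices into `exp` rows to withhold from the
#'   search and score as free (cross-validation) couplings.
#' @return object of class `ga_result`: tibble `repeats` (one row per
#'   repeat: members, q_work, q_free, scale), `trace` (per-step best Q and
#'   operator rates), `pooled` (all best-ensemble members across repeats).
#' @export
run_ga <- function(pool, exp, n, config = ga_config_scaled(), free = NULL) {
  m <- pool_match_exp(pool, exp)
  if (n > pool_size(pool)) {
    stop("ensemble size ", n, " exceeds pool size ", pool_size(pool),
         call. = FALSE)
  }
  work_cols <- seq_along(m$y)
  d_free <- NULL
  y_free <- NULL
  if (!is.null(free)) {
    free <- sort(unique(as.integer(free)))
    work_cols <- setdiff(work_cols, free)
    if (length(work_cols) < 1L) stop("all RDCs withheld", call. = FALSE)
    d_free <- m$d[, free, drop = FALSE]
    y_free <- m$y[free]
  }
  d <- m$d[, work_cols, drop = FALSE]
  y <- m$y[work_cols]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)

  runs <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    runs[[r]] <- ga_single_run(d, y, n, config, seeds[r],
                               d_free = d_free, y_free = y_free)
  }
  repeats <- tibble::tibble(
    repeat_id = seq_len(config$n_repeats),
    members = lapply(runs, `[[`, "members"),
    q_work = vapply(runs, `[[`, numeric(1), "q_work"),
    q_free = vapply(runs, `[[`, numeric(1), "q_free"),
    scale = vapply(runs, `[[`, numeric(1), "scale")
  )
  trace <- dplyr::bind_rows(
    lapply(seq_along(runs), function(r) {
      dplyr::mutate(runs[[r]]$trace, repeat_id = r, .before = 1)
    })
  )
  structure(list(
    repeats = repeats, trace = trace,
    pooled = unlist(repeats$members), n = as.integer(n),
    config = config, keys_work = m$keys[work_cols, ],
    keys_free = if (!is.null(free)) m$keys[free, ] else NULL
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> N = ", x$n, ", ", nrow(x$repeats), " repeat(s)\n", sep = "")
  cat("  best Q_work: ", signif(min(x$repeats$q_work), 4),
      "; median Q_work: ", signif(stats::median(x$repeats$q_work), 4), "\n",
      sep = "")
  if (!all(is.na(x$repeats$q_free))) {
    cat("  median Q_free: ", signif(stats::median(x$repeats$q_free), 4),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a GA result into its per-repeat table
#' @param x a `ga_result`.
#' @param ... unused.
#' @return the per-repeat tibble (members as a list column).
#' @method tidy ga_result
#' @export
tidy.ga_result <- function(x, ...) x$repeats

#' One-row summary of a GA result
#' @param x a `ga_result`.
#' @param ... unused.
#' @return tibble with n, repeats and Q summaries.
#' @method glance ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_repeats = nrow(x$repeats),
    q_work_best = min(x$repeats$q_work),
    q_work_median = stats::median(x$repeats$q_work),
    q_free_median = stats::median(x$repeats$q_free),
    n_rdc_work = nrow(x$keys_work),
    n_rdc_free = if (is.null(x$keys_free)) 0L else nrow(x$keys_free)
  )
}

#' Choose the minimal adequate ensemble size by free-RDC cross-validation
#'
#' For each candidate size N, random holdout sets (20% of the couplings by
#' default) are withheld, the GA is run on the remainder, and the fit to
#' withheld couplings (Q_free) is recorded. The adequate size is the
#' smallest N whose median Q_free lies within `tolerance` (relative) of the
#' minimum median over all sizes: larger ensembles fit the data equally
#' well, so the smallest such N is kept.
#'
#' @param pool `conformer_pool` with cached RDCs.
#' @param exp `rdc_tbl`.
#' @param config a [ga_config()]; its `sizes` are the candidate N values and
#'   its `rng_seed` controls holdout draws and run seeds. Each calculation is
#'   a single GA run (the config's `n_repeats` is not used here).
#' @param holdout_fraction fraction of couplings withheld per set.
#' @param n_holdout_sets number of random holdout sets.
#' @param runs_per_set independent GA runs per holdout set.
#' @param tolerance relative tolerance on the median Q_free plateau.
#' @return object of class `size_selection`: `best_n`, per-size `summary`
#'   tibble and the full `runs` tibble.
#' @export
select_ensemble_size <- function(pool, exp, config = ga_config_scaled(),
                                 holdout_fraction = 0.2,
                                 n_holdout_sets = 10, runs_per_set = 20,
                                 tolerance = 0.05) {
  m <- pool_match_exp(pool, exp)
  n_rdc <- length(m$y)
  n_hold <- max(1L, round(holdout_fraction * n_rdc))
  if (n_rdc - n_hold < 5L) {
    stop("holdout would leave fewer than 5 working RDCs", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  holdouts <- lapply(seq_len(n_holdout_sets),
                     function(i) sort(sample.int(n_rdc, n_hold)))
  run_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L,
               n_holdout_sets * runs_per_set * length(config$sizes)),
    nrow = length(config$sizes)
  )
  rows <- list()
  cfg1 <- config
  cfg1$n_repeats <- 1L
  for (si in seq_along(config$sizes)) {
    nn <- config$sizes[si]
    col <- 0L
    for (h in seq_len(n_holdout_sets)) {
      for (r in seq_len(runs_per_set)) {
        col <- col + 1L
        cfg1$rng_seed <- run_seeds[si, col]
        res <- run_ga(pool, exp, nn, cfg1, free = holdouts[[h]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          n = nn, holdout_set = h, run = r,
          q_work = res$repeats$q_work[1], q_free = res$repeats$q_free[1],
          members = res$repeats$members[1]
        )
      }
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- runs |>
    dplyr::group_by(n) |>
    dplyr::summarise(
      q_work_median = stats::median(q_work),
      q_free_median = stats::median(q_free),
      q_free_iqr = stats::IQR(q_free),
      .groups = "drop"
    )
  qmin <- min(summary$q_free_median)
  ok <- summary$q_free_median <= qmin * (1 + tolerance)
  best_n <- min(summary$n[ok])
  structure(list(best_n = best_n, summary = summary, runs = runs,
                 tolerance = tolerance, holdouts = holdouts),
            class = "size_selection")
}

#' @export
print.size_selection <- function(x, ...) {
  cat("<size_selection> adequate ensemble size N* =", x$best_n, "\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy size_selection
#' @export
tidy.size_selection <- function(x, ...) x$runs

#' @method glance size_selection
#' @export
glance.size_selection <- function(x, ...) {
  tibble::tibble(best_n = x$best_n,
                 q_free_min_median = min(x$summary$q_free_median))
}

#' Propagate experimental RDC uncertainty into ensemble replicas
#'
#' Repeats the GA selection on noise-perturbed copies of the experimental
#' couplings: each replica adds independent Gaussian noise of standard
#' deviation `sigma` (default 1.0 Hz, three times the typical 0.3 Hz
#' measurement error) and runs one GA optimization. The scatter of basin
#' populations across replicas estimates the population uncertainty.
#'
#' @param pool `conformer_pool` with cached RDCs.
#' @param exp `rdc_tbl`.
#' @param n ensemble size.
#' @param sigma noise standard deviation in Hz.
#' @param n_replicas number of noise replicas.
#' @param config a [ga_config()] (one GA run per replica).
#' @return object of class `rdc_error_replicas`: tibble with one row per
#'   replica (noise seed, members, q_work, scale).
#' @export
propagate_rdc_error <- function(pool, exp, n, sigma = 1.0, n_replicas = 200,
                                config = ga_config_scaled()) {
  stopifnot(sigma >= 0, n_replicas >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  cfg1 <- config
  cfg1$n_repeats <- 1L
  rows <- lapply(seq_len(n_replicas), function(k) {
    set.seed(noise_seeds[k])
    noise <- stats::rnorm(nrow(exp), 0, sigma)
    noisy <- exp
    noisy$value <- exp$value + noise
    cfg1$rng_seed <- run_seeds[k]
    res <- run_ga(pool, noisy, n, cfg1)
    tibble::tibble(replica = k, noise_seed = noise_seeds[k],
                   members = res$repeats$members[1],
                   q_work = res$repeats$q_work[1],
                   scale = res$repeats$scale[1],
                   noise = list(noise))
  })
  structure(list(replicas = dplyr::bind_rows(rows), n = as.integer(n),
                 sigma = sigma), class = "rdc_error_replicas")
}

#' @export
print.rdc_error_replicas <- function(x, ...) {
  cat("<rdc_error_replicas> ", nrow(x$replicas), " replicas, sigma = ",
      x$sigma, " Hz, N = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @method tidy rdc_error_replicas
#' @export
tidy.rdc_error_replicas <- function(x, ...) x$replicas
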