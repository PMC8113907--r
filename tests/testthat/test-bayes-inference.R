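test_that("effective sample size behaves on reference series", {
  with_test_seed(301, {
    wn <- rnorm(4000)
    ess_wn <- effective_sample_size(wn)
    expect_gt(ess_wn, 4000 * 0.85)
    expect_lte(ess_wn, 4000)

    # AR(1), phi = 0.5: ESS -> n (1 - phi) / (1 + phi) = n / 3
    n <- 20000
    phi <- 0.5
    ar <- numeric(n)
    innov <- rnorm(n, sd = sqrt(1 - phi^2))
    for (i in 2:n) ar[i] <- phi * ar[i - 1] + innov[i]
    ess_ar <- effective_sample_size(ar)
    expect_gt(ess_ar, n / 3 * 0.75)
    expect_lt(ess_ar, n / 3 * 1.25)
  })
  expect_warning(ess_const <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(ess_const, 1)
  expect_error(effective_sample_size(1:5), "too short")
})

test_that("trace bookkeeping follows chain length, burn-in and thinning", {
  tr <- simulate_bd_tree(12, seed = 81)
  sim <- simulate_traits(tr, random_pagel_Q(82), root = "00", seed = 83)
  x <- setNames(sim$brush_organ, rownames(sim))
  y <- setNames(sim$scent_pad, rownames(sim))
  cfg <- bayes_config(chain_length = 3000, burnin = 500, thinning = 7,
                      seed = 84)
  trace <- rjmcmc_run(tr, x, y, "dependent", cfg)
  expect_equal(nrow(trace$samples), floor((3000 - 500) / 7))
  expect_true(all(trace$ess <= nrow(trace$samples) + 1e-9))
  # determinism under the config seed
  trace2 <- rjmcmc_run(tr, x, y, "dependent", cfg)
  expect_identical(trace$samples, trace2$samples)
})

test_that("prior-only sampling reproduces the exponential hyperprior", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x <- named_states(A = 0, B = 1, C = 0, D = 1)
  y <- named_states(A = 1, B = 0, C = 1, D = 0)
  cfg <- bayes_config(chain_length = 60000, burnin = 5000, thinning = 5,
                      hyper_max = 30, seed = 85)
  trace <- rjmcmc_run(tr, x, y, "dependent", cfg, rj = FALSE,
                      prior_only = TRUE)
  # oracle: mu ~ U(0, 30), rate ~ Exp(mean mu) => E = 15.  The eight rate
  # columns share one hyper-mean, so pool them per iteration and treat the
  # pooled mean as a single autocorrelated series for the MC error.
  oracle_mean <- 15
  pooled <- rowMeans(trace$samples[, pagelion:::rate_names("dependent")])
  mc_se <- stats::sd(pooled) /
    sqrt(max(effective_sample_size(pooled, warn = FALSE), 10))
  expect_lt(abs(mean(pooled) - oracle_mean), 3 * mc_se + 0.2)
  # mu itself is marginally uniform on (0, 30)
  expect_lt(abs(mean(trace$samples$mu) - 15),
            3 * stats::sd(trace$samples$mu) /
              sqrt(max(trace$ess[["mu"]], 10)))
})

test_that("posterior of a one-rate toy matches quadrature (detailed balance)", {
  tr <- read_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  x <- named_states(A = 0, B = 1, C = 1, D = 0, E = 1)
  loglik <- pagelion:::make_loglik(tr, x, NULL, "ER",
                                   pagelion:::as_root_prior("equal"))
  post_kernel <- function(q) {
    vapply(q, function(v) exp(loglik(v)) * dexp(v, 1), 0)
  }
  z <- integrate(post_kernel, 0, Inf, rel.tol = 1e-10)$value
  breaks <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, Inf)
  p_bins <- vapply(seq_len(length(breaks) - 1L), function(i) {
    integrate(post_kernel, breaks[i], breaks[i + 1L],
              rel.tol = 1e-10)$value / z
  }, 0)
  cfg <- bayes_config(chain_length = 120000, burnin = 5000, thinning = 1,
                      hyper = FALSE, prior_mean = 1, seed = 86)
  trace <- rjmcmc_run(tr, x, NULL, "ER", cfg, rj = FALSE)
  q_draws <- trace$samples$q
  p_hat <- as.numeric(table(cut(q_draws, breaks)) / length(q_draws))
  tv <- 0.5 * sum(abs(p_hat - p_bins))
  expect_lt(tv, 0.02)
})

test_that("stepping-stone logML matches quadrature on a one-rate toy", {
  tr <- read_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
  x <- named_states(A = 0, B = 1, C = 1, D = 0, E = 1)
  loglik <- pagelion:::make_loglik(tr, x, NULL, "ER",
                                   pagelion:::as_root_prior("equal"))
  marg <- integrate(function(q) vapply(q, function(v) exp(loglik(v)) *
                                         dexp(v, 1), 0),
                    0, Inf, rel.tol = 1e-10)$value
  cfg <- bayes_config(n_stones = 30, stone_iters = 1500, hyper = FALSE,
                      prior_mean = 1, seed = 87)
  ss <- stepping_stone(tr, x, NULL, "ER", cfg)
  expect_lt(abs(ss$log_marginal - log(marg)), 0.1)

  # doubling the stone budget moves the estimate by less than the MC error
  cfg2 <- bayes_config(n_stones = 60, stone_iters = 3000, hyper = FALSE,
                       prior_mean = 1, seed = 88)
  ss2 <- stepping_stone(tr, x, NULL, "ER", cfg2)
  expect_lt(abs(ss2$log_marginal - ss$log_marginal),
            3 * sqrt(ss$mc_se^2 + ss2$mc_se^2) + 0.05)
})

test_that("a fully fixed model has logML equal to its log-likelihood", {
  tr <- fixture_tree_5()
  sim <- simulate_traits(tr, random_pagel_Q(91), root = "00", seed = 92)
  x <- setNames(sim$brush_organ, rownames(sim))
  y <- setNames(sim$scent_pad, rownames(sim))
  rates <- setNames(rep(0.1, 8), pagelion:::rate_names("dependent"))
  ss <- stepping_stone(tr, x, y, "dependent", bayes_config(seed = 1),
                       fixed_rates = rates)
  expect_equal(ss$log_marginal,
               prune_loglik(tr, pagelion:::pair_partials(tr, x, y),
                            build_rate_matrix(rates, "dependent")),
               tolerance = 1e-12)
})

test_that("Bayes factors follow the 2-delta-log convention", {
  mk_ss <- function(lml) {
    structure(list(log_marginal = lml, data_id = "toy", mode = "dependent"),
              class = "stepping_stone")
  }
  dep <- mk_ss(-100)
  ind <- mk_ss(-104.2905)
  bf <- bayes_factor(dep, ind)
  expect_equal(bf$bf, 8.581, tolerance = 1e-10)
  expect_equal(bf$interpretation, "strong")
  swapped <- bayes_factor(ind, dep)
  expect_equal(swapped$bf, -bf$bf)
  expect_equal(bayes_factor(dep, mk_ss(-100))$bf, 0)
  expect_equal(bayes_factor(mk_ss(-101), mk_ss(-102.5))$bf, 3,
               tolerance = 1e-12)
  expect_equal(bayes_factor(mk_ss(-101), mk_ss(-102.5))$interpretation,
               "positive")
  bad <- mk_ss(-100)
  bad$data_id <- "other"
  expect_error(bayes_factor(dep, bad), "different data")
})

test_that("RJ moves find the zero bin under a trade-off regime", {
  Qdep <- build_rate_matrix(c(q12 = 0.1, q13 = 0.1, q21 = 0.05, q24 = 0,
                              q31 = 0.05, q34 = 0, q42 = 0.05, q43 = 0.05),
                            "dependent")
  tr <- simulate_bd_tree(60, seed = 95)
  sim <- simulate_traits(tr, Qdep, root = "10", seed = 96)
  x <- setNames(sim$brush_organ, rownames(sim))
  y <- setNames(sim$scent_pad, rownames(sim))
  cfg <- bayes_config(chain_length = 30000, burnin = 5000, thinning = 10,
                      seed = 97)
  trace <- rjmcmc_run(tr, x, y, "dependent", cfg, rj = TRUE)
  # the unidentifiable-forbidden transitions should sit in the zero bin or
  # near zero most of the time
  q24 <- trace$samples$q24
  q34 <- trace$samples$q34
  expect_gt(mean(q24 < 0.02), 0.5)
  expect_gt(mean(q34 < 0.02), 0.5)
  expect_gt(mean(trace$samples$n_zero > 0), 0.3)
})
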