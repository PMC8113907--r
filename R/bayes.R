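#' MCMC configuration
#'
#' Bundles chain-length, burn-in, thinning, hyperprior and stepping-stone
#' settings.  The defaults are desk-scale (1e5 generations, 30 stones of
#' 1000 iterations) so a full analysis runs in seconds-to-minutes; the large
#' production settings used with BayesTraits-style runs (1e8 generations,
#' 1e6 burn-in, thinning 5000, 2000 stones of 50 000 iterations) are
#' available by argument.
#'
#' @param chain_length Total MCMC generations.
#' @param burnin Generations discarded before sampling.
#' @param thinning Keep every `thinning`-th generation.
#' @param hyper_max Upper bound of the uniform hyperprior on the exponential
#'   prior mean: class rates are iid Exponential(mean `mu`) with
#'   `mu ~ Uniform(0, hyper_max)`.
#' @param prior_mean Fixed exponential prior mean used when
#'   `hyper = FALSE` (e.g. for quadrature-checkable toys).
#' @param hyper Sample the exponential mean under the uniform hyperprior?
#' @param n_stones Number of stepping stones.
#' @param stone_iters MCMC iterations per stone.
#' @param seed Integer seed.
#' @return An object of class `bayes_config`.
#' @export
bayes_config <- function(chain_length = 1e5, burnin = 1e4, thinning = 10,
                         hyper_max = 30, prior_mean = 1, hyper = TRUE,
                         n_stones = 30, stone_iters = 1000, seed = NULL) {
  stopifnot(burnin < chain_length, thinning >= 1, n_stones >= 1,
            stone_iters >= 10, hyper_max > 0, prior_mean > 0)
  structure(list(chain_length = as.integer(chain_length),
                 burnin = as.integer(burnin),
                 thinning = as.integer(thinning),
                 hyper_max = hyper_max, prior_mean = prior_mean,
                 hyper = hyper, n_stones = as.integer(n_stones),
                 stone_iters = as.integer(stone_iters), seed = seed),
            class = "bayes_config")
}

# Rate prior density (log) for class values given current hyper mean.
log_rate_prior <- function(values, mu) sum(dexp(values, rate = 1 / mu, log = TRUE))

# --- sampler state ---------------------------------------------------------
# assignment: integer vector over the model's free rates; 0 = zero bin,
# j >= 1 = index into `values` (shared rate classes).  Non-RJ runs pin the
# assignment at the identity (each rate its own class, none zeroed).

rates_from_state <- function(state) {
  r <- ifelse(state$assignment == 0L, 0, state$values[pmax(state$assignment, 1L)])
  setNames(r, names(state$assignment))
}

make_loglik <- function(tree, x, y, mode, prior) {
  plan <- tree_plan(tree)
  if (mode %in% c("ER", "ARD")) {
    v <- align_binary(x, tree$tip.label, "x")
    partials <- tip_partials(tree, setNames(as.character(v), tree$tip.label),
                             c("0", "1"))
    if (mode == "ER") {
      return(function(rates) {
        q <- max(rates[1L], 0)
        loglik_given_plan(plan, partials, fast_binary_Q(q, q), prior)
      })
    }
    return(function(rates) {
      r <- pmax(rates, 0)
      loglik_given_plan(plan, partials, fast_binary_Q(r[1L], r[2L]), prior)
    })
  }
  partials <- unname(pair_partials(tree, x, y)[tree$tip.label, , drop = FALSE])
  expand_idx <- pair_expand_index(mode)
  function(rates) {
    loglik_given_plan(plan, partials,
                      fast_pair_Q(pmax(rates, 0), expand_idx), prior)
  }
}

BAYES_MODES <- c("dependent", "independent", "x_dep", "y_dep", "ER", "ARD")

#' Reversible-jump MCMC over discrete-trait rate models
#'
#' Samples the posterior of the transition rates of a Pagel pair model
#' (independent or dependent) under an exponential prior whose mean carries
#' a uniform hyperprior, with reversible-jump moves over rate-class
#' structures: rates may share a class value, and any rate may be pinned to
#' the zero bin — the mechanism by which conditional gain rates such as
#' `q24`/`q34` can vanish.  New class values are proposed from the
#' exponential prior, so the acceptance probability of structure moves
#' reduces to the likelihood ratio under the uniform structure prior.
#' Proposal widths are tuned during burn-in only.
#'
#' @param tree,x,y Data as in [fit_pagel()]; for the single-trait modes
#'   `"ER"`/`"ARD"` only `x` is used.
#' @param mode `"independent"` or `"dependent"` (or a conditional model tag,
#'   or a single-trait Mk tag).
#' @param config A [bayes_config()].
#' @param root Root prior over joint states.
#' @param rj Enable reversible-jump structure moves?  With `rj = FALSE`
#'   every rate keeps its own class (a plain Metropolis sampler).
#' @param prior_only Ignore the likelihood (prior sampling; used to validate
#'   the sampler against direct draws from the hyperprior).
#' @return An object of class `mcmc_trace`: data frame `samples` (iteration,
#'   logL, mu, one column per rate, n_zero, n_classes, class string),
#'   `ess` per numeric column, `acceptance` rates by move type, `config`,
#'   `mode`, `data_id`.
#' @export
rjmcmc_run <- function(tree, x, y = NULL, mode = "dependent",
                       config = bayes_config(), root = "equal",
                       rj = TRUE, prior_only = FALSE) {
  mode <- match.arg(mode, BAYES_MODES)
  prior <- as_root_prior(root)
  nms <- rate_names(mode)
  kq <- length(nms)
  loglik <- if (prior_only) function(rates) 0 else make_loglik(tree, x, y, mode, prior)

  with_seed(config$seed, {
    state <- list(assignment = setNames(seq_len(kq), nms),
                  values = rexp(kq, 1),
                  mu = if (config$hyper) runif(1, 1e-3, config$hyper_max)
                       else config$prior_mean)
    state$ll <- loglik(rates_from_state(state))
    step <- 1.0   # log-scale proposal sd, tuned in burn-in
    acc <- c(value = 0, value_n = 0, mu = 0, mu_n = 0, move = 0, move_n = 0)
    keep_at <- seq(config$burnin + config$thinning, config$chain_length,
                   by = config$thinning)
    out <- vector("list", length(keep_at))
    ki <- 0L

    for (it in seq_len(config$chain_length)) {
      u <- runif(1)
      if (config$hyper && u < 0.1) {
        # hyper mean: uniform independence proposal
        mu_new <- runif(1, 1e-3, config$hyper_max)
        lr <- log_rate_prior(state$values, mu_new) -
              log_rate_prior(state$values, state$mu)
        acc["mu_n"] <- acc["mu_n"] + 1
        if (log(runif(1)) < lr) {
          state$mu <- mu_new
          acc["mu"] <- acc["mu"] + 1
        }
      } else if (rj && u < 0.35) {
        res <- rj_reassign_move(state, loglik, config)
        acc["move_n"] <- acc["move_n"] + 1
        if (res$accepted) {
          state <- res$state
          acc["move"] <- acc["move"] + 1
        }
      } else {
        # log-scale sliding update of one class value
        if (length(state$values) > 0L) {
          j <- sample.int(length(state$values), 1L)
          prop <- state
          prop$values[j] <- state$values[j] * exp(rnorm(1, 0, step))
          prop$ll <- loglik(rates_from_state(prop))
          lr <- prop$ll - state$ll +
            dexp(prop$values[j], 1 / state$mu, log = TRUE) -
            dexp(state$values[j], 1 / state$mu, log = TRUE) +
            log(prop$values[j]) - log(state$values[j])
          acc["value_n"] <- acc["value_n"] + 1
          if (is.finite(lr) && log(runif(1)) < lr) {
            state <- prop
            acc["value"] <- acc["value"] + 1
          }
        }
        if (it <= config$burnin && acc["value_n"] > 0 &&
            acc["value_n"] %% 100 == 0) {
          rate_acc <- acc["value"] / acc["value_n"]
          step <- max(0.05, min(5, step * exp(rate_acc - 0.3)))
        }
      }
      if (ki < length(keep_at) && it == keep_at[ki + 1L]) {
        ki <- ki + 1L
        rates <- rates_from_state(state)
        out[[ki]] <- c(list(iteration = it, logL = state$ll, mu = state$mu),
                       as.list(rates),
                       list(n_zero = sum(state$assignment == 0L),
                            n_classes = length(unique(
                              state$assignment[state$assignment > 0L])),
                            classes = paste(state$assignment, collapse = "")))
      }
    }
    samples <- do.call(rbind, lapply(out[seq_len(ki)], as.data.frame))
    num_cols <- c("logL", "mu", nms)
    ess <- vapply(num_cols, function(cn) {
      effective_sample_size(samples[[cn]], warn = FALSE)
    }, 0)
    structure(list(samples = samples, ess = ess,
                   acceptance = c(value = unname(acc["value"] / max(acc["value_n"], 1)),
                                  mu = unname(acc["mu"] / max(acc["mu_n"], 1)),
                                  move = unname(acc["move"] / max(acc["move_n"], 1))),
                   config = config, mode = mode, rj = rj,
                   prior_only = prior_only,
                   data_id = data_id(tree, x, y)),
              class = "mcmc_trace")
  })
}

# One reversible-jump reassignment: pick a rate, remove it from its current
# class, and propose a new location among {each surviving class, a fresh
# class with a prior-drawn value, the zero bin}.  The candidate-set size is
# identical in both directions and new values are drawn from their prior, so
# the Hastings ratio is the likelihood ratio.
rj_reassign_move <- function(state, loglik, config) {
  kq <- length(state$assignment)
  i <- sample.int(kq, 1L)
  old_class <- state$assignment[i]
  base <- state
  # remove rate i; drop its class value if it was a singleton
  if (old_class > 0L && sum(state$assignment == old_class) == 1L) {
    base$values <- base$values[-old_class]
    base$assignment <- ifelse(base$assignment > old_class,
                              base$assignment - 1L, base$assignment)
  }
  base$assignment[i] <- NA_integer_
  n_class <- length(base$values)
  # targets: 1..n_class existing, n_class+1 = new singleton, n_class+2 = zero
  target <- sample.int(n_class + 2L, 1L)
  prop <- base
  if (target <= n_class) {
    prop$assignment[i] <- target
  } else if (target == n_class + 1L) {
    prop$values <- c(prop$values, rexp(1, 1 / state$mu))
    prop$assignment[i] <- n_class + 1L
  } else {
    prop$assignment[i] <- 0L
  }
  prop$ll <- loglik(rates_from_state(prop))
  lr <- prop$ll - state$ll
  if (is.finite(lr) && log(runif(1)) < lr) {
    list(accepted = TRUE, state = prop)
  } else {
    list(accepted = FALSE, state = state)
  }
}

data_id <- function(tree, x, y = NULL) {
  paste(paste(tree$tip.label, collapse = ","),
        paste(x, collapse = ""),
        if (is.null(y)) "" else paste(y, collapse = ""), sep = ";")
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("MCMC trace (%s%s): %d samples, min ESS = %.0f\n",
              x$mode, if (x$rj) ", RJ" else "", nrow(x$samples), min(x$ess)))
  cat("acceptance:", paste(sprintf("%s %.2f", names(x$acceptance),
                                   x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' Stepping-stone marginal likelihood
#'
#' Estimates the log marginal likelihood of a pair model by power-posterior
#' stepping-stone sampling: a ladder of powers `beta` in (0, 1] from
#' quantiles of Beta(0.3, 1) (concentrating stones near the prior), a
#' Metropolis chain per stone warm-started from the previous one, and the
#' standard log-sum-exp stone estimator.  Rates keep their own classes (no
#' RJ) so the marginal likelihood refers to the named model.
#'
#' @param tree,x,y,mode,root As in [rjmcmc_run()].
#' @param config A [bayes_config()]; `n_stones`, `stone_iters`, the prior
#'   settings and `seed` are used.
#' @param fixed_rates Optional named vector fixing every rate (a point-mass
#'   "model" whose log marginal likelihood is exactly the log-likelihood).
#' @return An object of class `stepping_stone`: `log_marginal`, per-stone
#'   data frame `stones` (beta_from, beta_to, log_contribution, mc_se),
#'   `mode`, `data_id`.
#' @export
stepping_stone <- function(tree, x, y = NULL, mode = "dependent",
                           config = bayes_config(), root = "equal",
                           fixed_rates = NULL) {
  mode <- match.arg(mode, BAYES_MODES)
  prior <- as_root_prior(root)
  loglik <- make_loglik(tree, x, y, mode, prior)
  nms <- rate_names(mode)
  kq <- length(nms)

  if (!is.null(fixed_rates)) {
    ll <- loglik(fixed_rates[nms])
    return(structure(list(log_marginal = ll,
                          stones = data.frame(), mode = mode,
                          fixed = TRUE, data_id = data_id(tree, x, y)),
                     class = "stepping_stone"))
  }

  K <- config$n_stones
  beta <- (seq(0, K) / K)^(1 / 0.3)   # quantiles of Beta(0.3, 1)

  with_seed(config$seed, {
    state <- list(values = rexp(kq, 1),
                  mu = if (config$hyper) runif(1, 1e-3, config$hyper_max)
                       else config$prior_mean)
    state$ll <- loglik(state$values)
    step <- 1.0
    stones <- vector("list", K)
    for (s in seq_len(K)) {
      b_from <- beta[s]
      b_to <- beta[s + 1L]
      lls <- numeric(config$stone_iters)
      n_acc <- 0
      for (it in seq_len(config$stone_iters)) {
        if (config$hyper && runif(1) < 0.1) {
          mu_new <- runif(1, 1e-3, config$hyper_max)
          lr <- log_rate_prior(state$values, mu_new) -
                log_rate_prior(state$values, state$mu)
          if (log(runif(1)) < lr) state$mu <- mu_new
        } else {
          j <- sample.int(kq, 1L)
          vals <- state$values
          vals[j] <- vals[j] * exp(rnorm(1, 0, step))
          ll_new <- loglik(vals)
          lr <- b_from * (ll_new - state$ll) +
            dexp(vals[j], 1 / state$mu, log = TRUE) -
            dexp(state$values[j], 1 / state$mu, log = TRUE) +
            log(vals[j]) - log(state$values[j])
          if (is.finite(lr) && log(runif(1)) < lr) {
            state$values <- vals
            state$ll <- ll_new
            n_acc <- n_acc + 1
          }
        }
        lls[it] <- state$ll
      }
      # samples from power beta[s] weight the step to beta[s+1]
      w <- (b_to - b_from) * lls
      wmax <- max(w)
      contrib <- wmax + log(mean(exp(w - wmax)))
      ess_w <- effective_sample_size(w, warn = FALSE)
      mc_se <- stats::sd(exp(w - wmax)) / exp(log(mean(exp(w - wmax)))) /
        sqrt(max(ess_w, 1))
      stones[[s]] <- data.frame(beta_from = b_from, beta_to = b_to,
                                log_contribution = contrib, mc_se = mc_se,
                                acceptance = n_acc / config$stone_iters)
      # light adaptation between stones (kernel fixed within a stone)
      arate <- n_acc / config$stone_iters
      step <- max(0.05, min(5, step * exp(arate - 0.3)))
    }
    stones <- do.call(rbind, stones)
    structure(list(log_marginal = sum(stones$log_contribution),
                   stones = stones, mode = mode, fixed = FALSE,
                   mc_se = sqrt(sum(stones$mc_se^2)),
                   data_id = data_id(tree, x, y)),
              class = "stepping_stone")
  })
}

#' @export
print.stepping_stone <- function(x, ...) {
  cat(sprintf("Stepping-stone logML (%s): %.4f", x$mode, x$log_marginal))
  if (!isTRUE(x$fixed)) cat(sprintf(" (%d stones, MC se %.3f)",
                                    nrow(x$stones), x$mc_se))
  cat("\n")
  invisible(x)
}

#' Bayes factor between dependent and independent models
#'
#' `BF = 2 (logML_dependent - logML_independent)`, the 2-delta-log
#' convention under which BF > 2 is read as positive and BF > 5 as strong
#' evidence for correlated evolution.
#'
#' @param dep,indep `stepping_stone` results for the two models on the same
#'   data (checked).
#' @param scale `"2log"` (default) or `"ratio"` for the plain marginal
#'   likelihood ratio.
#' @return An object of class `bayes_factor`: `bf`, `scale`,
#'   `interpretation` (one of "negative", "weak", "positive", "strong").
#' @export
bayes_factor <- function(dep, indep, scale = c("2log", "ratio")) {
  scale <- match.arg(scale)
  stopifnot(inherits(dep, "stepping_stone"), inherits(indep, "stepping_stone"))
  if (!identical(dep$data_id, indep$data_id)) {
    stop("the two marginal likelihoods were computed on different data")
  }
  d <- dep$log_marginal - indep$log_marginal
  bf <- if (scale == "2log") 2 * d else exp(d)
  band <- if (scale == "2log") {
    if (bf > 5) "strong" else if (bf > 2) "positive"
    else if (bf > 0) "weak" else "negative"
  } else {
    if (bf > exp(2.5)) "strong" else if (bf > exp(1)) "positive"
    else if (bf > 1) "weak" else "negative"
  }
  structure(list(bf = bf, scale = scale, interpretation = band,
                 logml_dep = dep$log_marginal,
                 logml_indep = indep$log_marginal),
            class = "bayes_factor")
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("Bayes factor (%s scale) = %.4f [%s evidence for dependence]\n",
              x$scale, x$bf, x$interpretation))
  invisible(x)
}

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence: the
#' integrated autocorrelation time sums consecutive lag pairs until the
#' first negative pair.  A constant series has ESS 1 (with a warning); the
#' estimate is clamped to `[1, length(series)]`.
#'
#' @param series Numeric trace of length >= 10.
#' @param warn Warn on constant input?
#' @return The ESS (a single number).
#' @export
effective_sample_size <- function(series, warn = TRUE) {
  n <- length(series)
  if (n < 10L) stop("series too short for an ESS estimate")
  if (var(series) == 0 || !all(is.finite(series))) {
    if (warn) warning("constant or non-finite series; ESS set to 1")
    return(1)
  }
  rho <- as.numeric(acf(series, lag.max = min(n - 1L, 2000L),
                        plot = FALSE)$acf)
  tau <- -1
  m <- 0L
  repeat {
    i1 <- 2L * m + 1L
    i2 <- 2L * m + 2L
    if (i1 > length(rho)) break
    gam <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (gam <= 0) break
    tau <- tau + 2 * gam
    m <- m + 1L
  }
  tau <- max(tau, 1 / n)
  min(max(n / tau, 1), n)
}
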