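# Optimisation happens in log-rate space within fixed bounds; multi-start
# guards against the multimodality known for dependent-model surfaces.
RATE_LOWER <- 1e-8
RATE_UPPER <- 1e3

# Hot-path generator constructors bypassing build_rate_matrix validation.
# Column-major positions of (1,2),(1,3),(2,1),(2,4),(3,1),(3,4),(4,2),(4,3)
PAIR_Q_SLOTS <- c(5L, 9L, 2L, 14L, 3L, 15L, 8L, 12L)

# index expanding each mode's free rates into the eight q_ij in the order
# q12, q13, q21, q24, q31, q34, q42, q43
pair_expand_index <- function(mode) {
  switch(mode,
    dependent = 1:8,
    independent = c(3L, 1L, 4L, 1L, 2L, 3L, 2L, 4L),
    x_dep = c(1L, 2L, 3L, 4L, 5L, 1L, 6L, 3L),
    y_dep = c(1L, 2L, 3L, 2L, 4L, 5L, 4L, 6L))
}

fast_pair_Q <- function(free_rates, expand_idx) {
  m <- matrix(0, 4L, 4L)
  m[PAIR_Q_SLOTS] <- free_rates[expand_idx]
  diag(m) <- -rowSums(m)
  m
}

fast_binary_Q <- function(q01, q10) {
  matrix(c(-q01, q10, q01, -q10), 2L, 2L)
}

new_fit_result <- function(model, rates, loglik, k, converged, root,
                           trace = NULL) {
  structure(list(model = model, rates = rates, loglik = loglik,
                 n_params = k, aic = 2 * k - 2 * loglik,
                 converged = converged, root = root, trace = trace),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit: logL = %.4f, k = %d, AIC = %.4f%s\n",
              x$model, x$loglik, x$n_params, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(x$rates, digits))
  invisible(x)
}

# Shared multi-start optimiser over log-rates.  `start_list` entries are
# rate vectors on the natural scale; further random starts are drawn
# log-uniformly over [0.01, 10] scaled by a data-informed magnitude.
optimise_rates <- function(nll, n_rates, rate_scale, starts, seed,
                           start_list = list()) {
  seeds <- spawn_seeds(if (is.null(seed)) 7L else seed, starts)
  best <- NULL
  trace <- data.frame(start = integer(), loglik = numeric(),
                      converged = logical())
  for (i in seq_len(starts)) {
    init <- if (i <= length(start_list)) {
      log(pmin(pmax(start_list[[i]], RATE_LOWER), RATE_UPPER))
    } else {
      with_seed(seeds[[i]],
                log(rate_scale) + runif(n_rates, log(0.05), log(20)))
    }
    fit <- tryCatch(
      nlminb(init, nll, lower = log(RATE_LOWER), upper = log(RATE_UPPER),
             control = list(iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    trace <- rbind(trace, data.frame(start = i, loglik = -fit$objective,
                                     converged = fit$convergence == 0))
    # ties broken by lowest start index: strict improvement required
    if (is.null(best) || fit$objective < best$objective - 1e-9) {
      best <- fit
      best$start <- i
    }
  }
  if (is.null(best)) stop("all optimiser starts failed")
  list(par = exp(best$par), loglik = -best$objective,
       converged = isTRUE(best$convergence == 0), trace = trace)
}

# Crude per-trait rate scale: parsimony-style changes per unit tree length.
guess_rate_scale <- function(tree, n_states_changing = 1) {
  tl <- sum(tree$edge.length)
  if (tl <= 0) return(1)
  max(1 / tl, min(10 / tl * n_states_changing, 1))
}

#' Fit an Mk model to one binary character
#'
#' Maximum-likelihood estimation of the transition rates of a single binary
#' character under the equal-rates (ER, one parameter) or all-rates-different
#' (ARD, two parameters) Mk model, using the pruning likelihood and
#' multi-start box-constrained optimisation in log-rate space.
#'
#' @param tree A `phylo` with branch lengths.
#' @param states Named vector of 0/1 tip states (`NA` = missing).
#' @param model `"ER"` or `"ARD"`.
#' @param root Root prior (see [root_prior()]); `"equal"` by default.
#' @param starts Number of optimiser starts (first from a data-informed
#'   guess, the rest log-uniform with per-start seeds).
#' @param seed Integer seed making the random restarts reproducible.
#' @return An object of class `mk_fit` with elements `model`, `rates`,
#'   `loglik`, `n_params`, `aic`, `converged`, `root` and the per-start
#'   `trace`.
#' @examples
#' tr <- simulate_bd_tree(30, seed = 1)
#' x <- simulate_traits(tr, build_rate_matrix(c(q = 0.05), "ER"), seed = 2)
#' fit_mk(tr, setNames(x$trait, rownames(x)), "ER", starts = 3, seed = 3)
#' @export
fit_mk <- function(tree, states, model = c("ER", "ARD"), root = "equal",
                   starts = 10, seed = NULL) {
  model <- match.arg(model)
  prior <- as_root_prior(root)
  v <- align_binary(states, tree$tip.label, "states")
  if (sum(!is.na(v)) < 2L) stop("need at least two tips with observed states")
  plan <- tree_plan(tree)
  partials <- tip_partials(tree, setNames(as.character(v), tree$tip.label),
                           c("0", "1"))
  n_rates <- n_free_rates(model)
  nll <- if (model == "ER") {
    function(logq) {
      q <- exp(logq)
      -loglik_given_plan(plan, partials, fast_binary_Q(q, q), prior)
    }
  } else {
    function(logq) {
      q <- exp(logq)
      -loglik_given_plan(plan, partials, fast_binary_Q(q[1L], q[2L]), prior)
    }
  }
  scale0 <- guess_rate_scale(tree)
  n_changes <- max(1, min(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE)))
  start1 <- rep(n_changes / max(sum(tree$edge.length), 1e-6), n_rates)
  opt <- optimise_rates(nll, n_rates, scale0, starts, seed,
                        start_list = list(start1))
  rates <- setNames(opt$par, rate_names(model))
  new_fit_result(model, rates, opt$loglik, n_rates, opt$converged,
                 prior$kind, opt$trace)
}

#' Fit Pagel's independent or dependent model to a trait pair
#'
#' Fits the 4-state CTMC over joint states of two binary traits, either with
#' the 8 free rates of the dependent model, the 4 rates of the independent
#' model, or the 6-rate one-way conditional models (`"x_dep"`: X's gain/loss
#' rates depend on Y; `"y_dep"`: the converse).  Because the independent
#' model factorises exactly into two single-trait chains, its rates are
#' optimised trait-by-trait and the joint log-likelihood is then recomputed
#' through the 4-state pruning engine.  The dependent fit always includes a
#' start at the mapped independent estimate, which guarantees the nesting
#' inequality up to optimiser tolerance.
#'
#' @param tree A `phylo`.
#' @param x,y Named 0/1 vectors for the two traits (`NA` = missing).
#' @param mode `"independent"`, `"dependent"`, `"x_dep"` or `"y_dep"`.
#' @param root Root prior over the four joint states.
#' @param starts,seed Multi-start controls as in [fit_mk()].
#' @return An `mk_fit` whose `rates` are the model's free parameters; the
#'   full 4x4 generator is available as `build_rate_matrix(fit$rates, mode)`.
#' @export
fit_pagel <- function(tree, x, y,
                      mode = c("dependent", "independent", "x_dep", "y_dep"),
                      root = "equal", starts = 10, seed = NULL) {
  mode <- match.arg(mode)
  prior <- as_root_prior(root)
  plan <- tree_plan(tree)
  partials <- pair_partials(tree, x, y)
  partials <- partials[tree$tip.label, , drop = FALSE]

  if (mode == "independent") {
    return(fit_pagel_independent(tree, plan, partials, x, y, prior,
                                 starts, seed))
  }

  n_rates <- n_free_rates(mode)
  nms <- rate_names(mode)
  expand_idx <- pair_expand_index(mode)
  partials <- unname(partials)
  nll <- function(logq) {
    -loglik_given_plan(plan, partials, fast_pair_Q(exp(logq), expand_idx),
                       prior)
  }
  # seed the search from the independent fit mapped into this model's space
  indep <- fit_pagel_independent(tree, plan, partials, x, y, prior,
                                 starts = 1, seed = seed)
  start1 <- map_independent_start(indep$rates, mode)
  opt <- optimise_rates(nll, n_rates, guess_rate_scale(tree), starts, seed,
                        start_list = list(start1))
  rates <- setNames(opt$par, nms)
  new_fit_result(mode, rates, opt$loglik, n_rates, opt$converged,
                 prior$kind, opt$trace)
}

fit_pagel_independent <- function(tree, plan, partials, x, y, prior,
                                  starts, seed) {
  seeds <- spawn_seeds(if (is.null(seed)) 11L else seed, 2)
  fx <- fit_mk(tree, x, "ARD", root = marginal_prior(prior), starts = starts,
               seed = seeds[[1]])
  fy <- fit_mk(tree, y, "ARD", root = marginal_prior(prior), starts = starts,
               seed = seeds[[2]])
  rates <- c(qx01 = unname(fx$rates["q01"]), qx10 = unname(fx$rates["q10"]),
             qy01 = unname(fy$rates["q01"]), qy10 = unname(fy$rates["q10"]))
  Q <- build_rate_matrix(rates, "independent")
  ll <- loglik_given_plan(plan, unname(partials), Q, prior)
  new_fit_result("independent", rates, ll, 4L,
                 fx$converged && fy$converged, prior$kind)
}

# The equal/fitzjohn/stationary pair prior corresponds to the same kind on
# each binary margin; fixed pair priors fall back to equal margins.
marginal_prior <- function(prior) {
  if (prior$kind %in% c("equal", "stationary", "fitzjohn")) prior$kind
  else "equal"
}

map_independent_start <- function(ir, mode) {
  full <- c(q12 = unname(ir["qy01"]), q34 = unname(ir["qy01"]),
            q21 = unname(ir["qy10"]), q43 = unname(ir["qy10"]),
            q13 = unname(ir["qx01"]), q24 = unname(ir["qx01"]),
            q31 = unname(ir["qx10"]), q42 = unname(ir["qx10"]))
  full[rate_names(mode)]
}

#' Likelihood-ratio test between nested model fits
#'
#' The statistic is `2 (logL_alt - logL_null)`, floored at zero to absorb
#' optimiser tolerance, with degrees of freedom equal to the difference in
#' free parameters and the p-value from the chi-square upper tail.  The
#' independent-vs-dependent comparison of Pagel's test has df = 8 - 4 = 4,
#' whose 0.05 threshold is 9.49.
#'
#' @param null,alt `mk_fit` objects with the null nested in the alternative.
#' @return An object of class `lrt_result`: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null, alt) {
  nesting <- list(ER = c("ARD"), independent = c("dependent", "x_dep", "y_dep"),
                  x_dep = "dependent", y_dep = "dependent")
  allowed <- nesting[[null$model]]
  if (is.null(allowed) || !alt$model %in% allowed) {
    stop("model ", dQuote(null$model), " is not nested in ", dQuote(alt$model))
  }
  stat <- max(0, 2 * (alt$loglik - null$loglik))
  df <- alt$n_params - null$n_params
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Significance threshold of the likelihood-ratio statistic
#'
#' Upper `alpha` chi-square quantile at the given degrees of freedom; with
#' the default `df = 4` of the independent-vs-dependent comparison this is
#' the 9.49 line drawn through likelihood-ratio distributions.
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom.
#' @return The quantile (unrounded).
#' @export
lrt_significance_threshold <- function(alpha = 0.05, df = 4) {
  qchisq(1 - alpha, df)
}

#' Akaike weights of competing fits
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with `Delta` the AIC
#' difference to the best model.
#'
#' @param fits List of `mk_fit` objects (or a numeric vector of AICs).
#' @return Named numeric weights summing to 1.
#' @export
aic_weights <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  aics <- if (is.numeric(fits)) fits else vapply(fits, `[[`, 0, "aic")
  if (is.null(names(aics)) && !is.numeric(fits)) {
    names(aics) <- vapply(fits, `[[`, "", "model")
  }
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Replicate Pagel's test across a tree set
#'
#' Runs the independent-vs-dependent comparison for one trait pair on every
#' tree of a (bootstrap) tree set, recording per-tree log-likelihoods, rates,
#' likelihood-ratio statistics and p-values, and summarising the fraction of
#' trees significant at `alpha` — the quantity plotted as a likelihood-ratio
#' distribution with its chi-square significance line.
#'
#' @param trees A `multiPhylo` (e.g. from [sample_tree_set()] or
#'   [perturb_tree_set()]).
#' @param x,y Named 0/1 trait vectors shared by all trees.
#' @param alpha Significance level for the per-tree LRT.
#' @param root,starts,seed As in [fit_pagel()]; each tree gets its own
#'   deterministic sub-seed.
#' @return An object of class `pagel_treeset`: data frame `per_tree`
#'   (tree, logL_indep, logL_dep, statistic, p_value, converged, and the
#'   eight dependent rates), `fraction_significant`, `mean_statistic`,
#'   `mean_p`, `alpha`, `threshold`.
#' @export
fit_over_tree_set <- function(trees, x, y, alpha = 0.05, root = "equal",
                              starts = 3, seed = NULL) {
  trees <- as_tree_list(trees)
  if (length(trees) == 0L) stop("empty tree set")
  seeds <- spawn_seeds(if (is.null(seed)) 23L else seed, length(trees))
  rows <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    row <- tryCatch({
      fi <- fit_pagel(trees[[i]], x, y, "independent", root = root,
                      starts = starts, seed = seeds[[i]])
      fd <- fit_pagel(trees[[i]], x, y, "dependent", root = root,
                      starts = starts, seed = seeds[[i]])
      lrt <- likelihood_ratio_test(fi, fd)
      c(list(tree = i, logL_indep = fi$loglik, logL_dep = fd$loglik,
             statistic = lrt$statistic, p_value = lrt$p_value,
             converged = fi$converged && fd$converged),
        as.list(fd$rates))
    }, error = function(e) {
      warning("tree ", i, " failed: ", conditionMessage(e))
      c(list(tree = i, logL_indep = NA_real_, logL_dep = NA_real_,
             statistic = NA_real_, p_value = NA_real_, converged = FALSE),
        as.list(setNames(rep(NA_real_, 8), rate_names("dependent"))))
    })
    rows[[i]] <- as.data.frame(row)
  }
  per_tree <- do.call(rbind, rows)
  ok <- !is.na(per_tree$p_value)
  structure(list(
    per_tree = per_tree,
    fraction_significant = sum(per_tree$p_value[ok] < alpha) / sum(ok),
    mean_statistic = mean(per_tree$statistic[ok]),
    mean_p = mean(per_tree$p_value[ok]),
    n_failed = sum(!ok),
    alpha = alpha,
    threshold = lrt_significance_threshold(alpha, 4),
    root = root), class = "pagel_treeset")
}

#' @export
print.pagel_treeset <- function(x, ...) {
  cat(sprintf(
    "Pagel test over %d trees: %.1f%% significant at alpha = %g (LRT > %.2f)\n",
    nrow(x$per_tree), 100 * x$fraction_significant, x$alpha, x$threshold))
  cat(sprintf("mean LRT = %.3f, mean p = %.3f, failures = %d\n",
              x$mean_statistic, x$mean_p, x$n_failed))
  invisible(x)
}
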