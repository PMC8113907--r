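#' Sample stochastic character maps
#'
#' Draws full character histories on the tree conditional on the tip data and
#' a fixed rate matrix (empirical-Q stochastic mapping, the convention of
#' summarising 1000 maps under the ML estimate).  Node states are drawn by
#' backward filtering / forward sampling; each branch history conditional on
#' its endpoint states is drawn by rejection sampling, falling back to exact
#' uniformization sampling after `max_rejects` failed attempts (endpoint
#' combinations that rejection reaches too rarely).
#'
#' @param tree A `phylo`.
#' @param tip_states Tip data as in [prune_loglik()]; missing states are
#'   integrated during filtering and sampled like internal nodes.
#' @param Q A `rate_matrix` or generator (typically the ML fit).
#' @param root Root prior.
#' @param n Number of maps.
#' @param seed Integer seed; the same seed reproduces the same histories.
#' @param max_rejects Rejection attempts per branch before switching to
#'   uniformization.
#' @return A list of `simmap_history` objects.  Each has `node_states`
#'   (named vector over all nodes incl. tips), and `maps`: one named numeric
#'   vector per edge (in `tree$edge` order) of dwell times whose names are
#'   the visited states and whose sum is the branch length.
#' @seealso [simmap_summarize()], [ancestral_marginal()]
#' @export
simmap_sample <- function(tree, tip_states, Q, root = "equal", n = 100,
                          seed = NULL, max_rejects = 1000) {
  m <- as_generator(Q)
  plan <- tree_plan(tree)
  partials <- tip_partials(tree, tip_states, rownames(m))
  prior <- as_root_prior(root)
  res <- prune_engine(plan, partials, m, prior, keep = TRUE)
  if (!is.finite(res$loglik)) stop("data have zero likelihood under this model")
  states <- rownames(m)
  k <- length(states)
  edge <- plan$edge
  n_tip <- plan$n_tip
  unif <- uniformization_setup(m)

  with_seed(seed, {
    lapply(seq_len(n), function(rep) {
      node_states <- integer(n_tip + plan$n_node)
      rw <- res$root_weights * res$lik[plan$root, ]
      node_states[plan$root] <- sample.int(k, 1L, prob = rw)
      # preorder: reverse postorder visits parents before children
      for (e in rev(seq_len(nrow(edge)))) {
        p <- edge[e, 1L]; ch <- edge[e, 2L]
        w <- res$pm[node_states[p], , e] * res$lik[ch, ]
        node_states[ch] <- sample.int(k, 1L, prob = w)
      }
      maps <- vector("list", nrow(edge))
      for (e in seq_len(nrow(edge))) {
        maps[[e]] <- sample_branch_history(
          m, unif, res$pm[, , e], node_states[edge[e, 1L]],
          node_states[edge[e, 2L]], plan$lengths[e], states, max_rejects)
      }
      structure(list(
        node_states = setNames(states[node_states],
                               c(tree$tip.label,
                                 (n_tip + 1L):(n_tip + plan$n_node))),
        maps = maps, edge = edge, states = states,
        tip_hash = paste(tree$tip.label, collapse = "|")),
        class = "simmap_history")
    })
  })
}

# --- branch-level endpoint-conditioned path sampling -----------------------

# Forward CTMC path from state a over time t; returns states and dwell times.
forward_path <- function(m, a, t) {
  states <- a
  dwell <- numeric(0)
  cur <- a
  left <- t
  repeat {
    rate <- -m[cur, cur]
    if (rate <= 0) {
      dwell <- c(dwell, left)
      return(list(states = states, dwell = dwell))
    }
    wait <- rexp(1, rate)
    if (wait >= left) {
      dwell <- c(dwell, left)
      return(list(states = states, dwell = dwell))
    }
    dwell <- c(dwell, wait)
    left <- left - wait
    nxt <- m[cur, ]
    nxt[cur] <- 0
    cur <- sample.int(length(nxt), 1L, prob = nxt)
    states <- c(states, cur)
  }
}

# Rejection sampler after Nielsen: when a != b the first jump is forced by
# drawing its time from the exponential truncated to [0, t).
conditioned_first_jump_path <- function(m, a, t) {
  rate <- -m[a, a]
  u <- runif(1)
  wait <- -log(1 - u * (1 - exp(-rate * t))) / rate
  nxt <- m[a, ]
  nxt[a] <- 0
  cur <- sample.int(length(nxt), 1L, prob = nxt)
  rest <- forward_path(m, cur, t - wait)
  list(states = c(a, rest$states), dwell = c(wait, rest$dwell))
}

sample_branch_history <- function(m, unif, pmat, a, b, t, states,
                                  max_rejects) {
  if (t == 0 || all(m == 0)) {
    return(setNames(t, states[b]))
  }
  for (try in seq_len(max_rejects)) {
    path <- if (a == b) forward_path(m, a, t)
            else if (-m[a, a] > 0) conditioned_first_jump_path(m, a, t)
            else break
    if (tail(path$states, 1L) == b) {
      return(collapse_path(path, states))
    }
  }
  path <- uniformization_path(m, unif, pmat, a, b, t)
  collapse_path(path, states)
}

collapse_path <- function(path, states) {
  st <- path$states
  dw <- path$dwell
  keep <- c(TRUE, st[-1L] != st[-length(st)])
  grp <- cumsum(keep)
  setNames(as.numeric(tapply(dw, grp, sum)), states[st[keep]])
}

uniformization_setup <- function(m) {
  mu <- max(-diag(m))
  if (mu <= 0) return(list(mu = 0))
  R <- diag(nrow(m)) + m / mu
  # powers of R up to a generous truncation for endpoint bridging
  list(mu = mu, R = R)
}

# Exact endpoint-conditioned path via uniformization: draw the number of
# (possibly virtual) jumps from P(N = n | a -> b in t), then the embedded
# chain as a discrete bridge, then jump times as uniform order statistics.
uniformization_path <- function(m, unif, pmat, a, b, t) {
  mu <- unif$mu
  R <- unif$R
  k <- nrow(R)
  pab <- pmat[a, b]
  # build R powers lazily until the posterior mass on N is exhausted
  nmax <- max(20, ceiling(mu * t + 10 * sqrt(mu * t) + 10))
  Rpow <- vector("list", nmax + 1L)
  Rpow[[1L]] <- diag(k)
  for (i in seq_len(nmax)) Rpow[[i + 1L]] <- Rpow[[i]] %*% R
  wts <- vapply(0:nmax, function(n) {
    dpois(n, mu * t) * Rpow[[n + 1L]][a, b]
  }, 0)
  tot <- sum(wts)
  if (tot <= 0) stop("uniformization failed: endpoint pair has zero probability")
  n_jump <- sample.int(nmax + 1L, 1L, prob = wts) - 1L
  if (n_jump == 0L) return(list(states = a, dwell = t))
  # discrete bridge over the embedded chain
  st <- integer(n_jump + 1L)
  st[1L] <- a
  st[n_jump + 1L] <- b
  if (n_jump > 1L) {
    for (i in 2L:n_jump) {
      rem <- n_jump + 1L - i   # steps remaining after this one
      w <- R[st[i - 1L], ] * Rpow[[rem + 1L]][, b]
      st[i] <- sample.int(k, 1L, prob = w)
    }
  }
  times <- sort(runif(n_jump, 0, t))
  dwell <- diff(c(0, times, t))
  list(states = st, dwell = dwell)
}

#' @export
print.simmap_history <- function(x, ...) {
  n_changes <- sum(vapply(x$maps, length, 1L) - 1L)
  cat("Stochastic map:", length(x$maps), "branches,", n_changes,
      "state changes\n")
  invisible(x)
}

#' Summarise a set of stochastic maps
#'
#' Aggregates sampled histories into per-node state frequencies (the
#' pie-chart currency of ancestral-state figures), expected transition counts
#' by type, and expected dwell-time fractions per state.
#'
#' @param maps List of `simmap_history` objects over the same tree.
#' @return An object of class `simmap_summary`: `node_freq` (nodes x states,
#'   rows sum to 1), `transitions` (expected count matrix, from-state rows),
#'   `dwell` (expected dwell fraction per state, sums to 1), `n_maps`.
#' @export
simmap_summarize <- function(maps) {
  if (length(maps) == 0L) stop("no maps supplied")
  hashes <- vapply(maps, `[[`, "", "tip_hash")
  if (length(unique(hashes)) != 1L) {
    stop("maps were sampled on different trees")
  }
  states <- maps[[1L]]$states
  k <- length(states)
  nodes <- names(maps[[1L]]$node_states)
  freq <- matrix(0, length(nodes), k, dimnames = list(nodes, states))
  trans <- matrix(0, k, k, dimnames = list(states, states))
  dwell <- setNames(numeric(k), states)
  for (h in maps) {
    idx <- cbind(seq_along(nodes), match(h$node_states, states))
    freq[idx] <- freq[idx] + 1
    for (seg in h$maps) {
      sts <- match(names(seg), states)
      dwell[sts] <- dwell[sts] + seg
      if (length(sts) > 1L) {
        for (i in seq_len(length(sts) - 1L)) {
          trans[sts[i], sts[i + 1L]] <- trans[sts[i], sts[i + 1L]] + 1
        }
      }
    }
  }
  n <- length(maps)
  structure(list(node_freq = freq / n, transitions = trans / n,
                 dwell = dwell / sum(dwell), n_maps = n, states = states),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, digits = 3, ...) {
  cat("Summary of", x$n_maps, "stochastic maps\n")
  cat("Expected transitions:\n")
  print(round(x$transitions, digits))
  cat("Dwell fractions:\n")
  print(round(x$dwell, digits))
  invisible(x)
}
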