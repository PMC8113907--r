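# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: the matrix exponential is a truncated
# Taylor series, and tree likelihoods / marginals come from brute-force
# enumeration over internal-node state assignments.

# exp(Q t) by direct series summation (adequate for the small ||Qt|| used in
# tests; terms are added until they vanish at double precision).
expm_series <- function(Q, t) {
  k <- nrow(Q)
  acc <- diag(k)
  term <- diag(k)
  for (n in 1:200) {
    term <- term %*% Q * (t / n)
    acc <- acc + term
    if (max(abs(term)) < 1e-18) break
  }
  acc
}

# Full enumeration of the tree likelihood: sum over all assignments of states
# to internal nodes of prod(edge transition probabilities) * root prior.
# tips: named vector of state labels; missing (NA) tips are summed over.
enum_loglik <- function(tree, tips, Q, root_weights = NULL) {
  m <- if (inherits(Q, "rate_matrix")) Q$matrix else Q
  states <- rownames(m)
  k <- nrow(m)
  if (is.null(root_weights)) root_weights <- rep(1 / k, k)
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  pm <- lapply(seq_len(nrow(edge)), function(e) expm_series(m, elen[e]))

  tip_sets <- lapply(tree$tip.label, function(lb) {
    s <- tips[[lb]]
    if (is.null(s) || is.na(s)) seq_len(k) else match(s, states)
  })
  node_ids <- (n_tip + 1L):(n_tip + n_node)
  grid_nodes <- expand.grid(rep(list(seq_len(k)), n_node))
  grid_tips <- expand.grid(tip_sets)
  total <- 0
  for (gi in seq_len(nrow(grid_nodes))) {
    assign_node <- as.integer(grid_nodes[gi, ])
    state_of <- function(id) {
      if (id <= n_tip) NA_integer_ else assign_node[id - n_tip]
    }
    for (ti in seq_len(nrow(grid_tips))) {
      assign_tip <- as.integer(grid_tips[ti, ])
      p <- root_weights[assign_node[1L]]
      for (e in seq_len(nrow(edge))) {
        a <- state_of(edge[e, 1L])
        b <- if (edge[e, 2L] <= n_tip) assign_tip[edge[e, 2L]]
             else assign_node[edge[e, 2L] - n_tip]
        p <- p * pm[[e]][a, b]
      }
      total <- total + p
    }
  }
  as.numeric(log(total))
}

# Marginal node probabilities by the same enumeration.
enum_marginals <- function(tree, tips, Q, root_weights = NULL) {
  m <- if (inherits(Q, "rate_matrix")) Q$matrix else Q
  states <- rownames(m)
  k <- nrow(m)
  if (is.null(root_weights)) root_weights <- rep(1 / k, k)
  n_tip <- ape::Ntip(tree)
  n_node <- tree$Nnode
  edge <- tree$edge
  pm <- lapply(seq_len(nrow(edge)), function(e) expm_series(m, tree$edge.length[e]))
  tip_idx <- vapply(tree$tip.label, function(lb) match(tips[[lb]], states), 1L)
  grid <- expand.grid(rep(list(seq_len(k)), n_node))
  probs <- matrix(0, n_node, k)
  for (gi in seq_len(nrow(grid))) {
    assign_node <- as.integer(grid[gi, ])
    p <- root_weights[assign_node[1L]]
    for (e in seq_len(nrow(edge))) {
      a <- assign_node[edge[e, 1L] - n_tip]
      b <- if (edge[e, 2L] <= n_tip) tip_idx[edge[e, 2L]]
           else assign_node[edge[e, 2L] - n_tip]
      p <- p * pm[[e]][a, b]
    }
    for (j in seq_len(n_node)) {
      probs[j, assign_node[j]] <- probs[j, assign_node[j]] + p
    }
  }
  probs / rowSums(probs)
}

# Random generators for property-style loops.
random_pagel_Q <- function(seed, lo = 0.02, hi = 0.5) {
  with_test_seed(seed, {
    q <- stats::runif(8, lo, hi)
    build_rate_matrix(stats::setNames(q, c("q12", "q13", "q21", "q24",
                                           "q31", "q34", "q42", "q43")),
                      "dependent")
  })
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# A small fixed ultrametric fixture shared by several files.
fixture_tree_5 <- function() {
  read_newick("(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
}

named_states <- function(...) {
  v <- c(...)
  stats::setNames(as.character(v), names(v))
}
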