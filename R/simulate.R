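#' Simulate an ultrametric birth-death tree
#'
#' Generates a rooted ultrametric phylogeny with exactly `n_tips` extant
#' species under a constant-rate birth-death process (via [ape::rphylo]) and
#' rescales it to a fixed root height, by default 30 time units — matching
#' the ~30 Ma crown age typical of the clades these analyses target, so that
#' simulated transition rates are interpretable on the same per-Ma scale.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Speciation and extinction rates.
#' @param root_height Height the tree is rescaled to (`NULL` = no rescale).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return A `phylo`, ultrametric with root height `root_height`.
#' @export
simulate_bd_tree <- function(n_tips, birth = 0.2, death = 0.05,
                             root_height = 30, seed = NULL) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0, death < birth)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  if (!is.null(root_height)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * root_height / h
  }
  tr
}

#' Simulate binary traits down a tree
#'
#' Forward simulation of a continuous-time Markov chain from the root to the
#' tips.  With a 2-state generator this yields one binary trait; with a
#' 4-state pair generator the joint states are split back into the two
#' binary columns, so that e.g. a trade-off regime (`q24 = q34 = 0`, root
#' without both traits) can never produce a tip carrying both.
#'
#' @param tree A `phylo`.
#' @param Q A `rate_matrix` (2- or 4-state) or generator matrix.
#' @param root Root state label (e.g. `"0"`, `"10"`), or a probability
#'   vector over states to draw it from, or `"stationary"`.
#' @param traits Column name(s) for the output: one name for a binary trait,
#'   two for a pair (default `c("brush_organ", "scent_pad")`).
#' @param seed Integer seed.
#' @return A data frame with species rownames and 0/1 trait columns.
#' @export
simulate_traits <- function(tree, Q, root = "stationary", traits = NULL,
                            seed = NULL) {
  m <- as_generator(Q)
  states <- rownames(m)
  k <- nrow(m)
  if (is.null(traits)) {
    traits <- if (k == 2L) "trait" else c("brush_organ", "scent_pad")
  }
  stopifnot((k == 2L && length(traits) == 1L) ||
            (k == 4L && length(traits) == 2L))
  plan <- tree_plan(tree)
  edge <- plan$edge
  n_tip <- plan$n_tip

  with_seed(seed, {
    root_state <- resolve_root_state(root, m, states)
    node_state <- integer(n_tip + plan$n_node)
    node_state[plan$root] <- root_state
    for (e in rev(seq_len(nrow(edge)))) {
      path <- forward_path(m, node_state[edge[e, 1L]], plan$lengths[e])
      node_state[edge[e, 2L]] <- tail(path$states, 1L)
    }
    tip_labels <- states[node_state[seq_len(n_tip)]]
    out <- if (k == 2L) {
      data.frame(as.integer(tip_labels))
    } else {
      data.frame(as.integer(substr(tip_labels, 1, 1)),
                 as.integer(substr(tip_labels, 2, 2)))
    }
    names(out) <- traits
    rownames(out) <- tree$tip.label
    out
  })
}

resolve_root_state <- function(root, m, states) {
  if (is.character(root) && length(root) == 1L) {
    if (root == "stationary") {
      return(sample.int(length(states), 1L, prob = stationary_distribution(m)))
    }
    j <- match(root, states)
    if (is.na(j)) stop("root state ", dQuote(root), " not among ",
                       paste(states, collapse = ", "))
    return(j)
  }
  if (is.numeric(root) && length(root) == length(states)) {
    return(sample.int(length(states), 1L, prob = root))
  }
  stop("cannot interpret `root` as a state or state distribution")
}

#' Perturb a tree into a bootstrap-style tree set
#'
#' Emulates the topological and branch-length heterogeneity of a bootstrap
#' tree cloud: each replicate multiplies every branch by an independent
#' lognormal factor with unit mean and coefficient of variation `jitter_cv`,
#' and optionally applies `nni_moves` random nearest-neighbour interchanges
#' (via [phangorn::rNNI]).  Tip sets are preserved.
#'
#' @param tree Source `phylo`.
#' @param n Number of replicate trees.
#' @param jitter_cv Branch-length jitter CV (0 = lengths untouched).
#' @param nni_moves NNI moves per replicate (0 = topology untouched).
#' @param seed Integer seed.
#' @return A `multiPhylo` of `n` trees with `"provenance" = "perturbation"`.
#' @export
perturb_tree_set <- function(tree, n, jitter_cv = 0.1, nni_moves = 0,
                             seed = NULL) {
  stopifnot(n >= 1, jitter_cv >= 0, nni_moves >= 0)
  sdlog <- sqrt(log(1 + jitter_cv^2))
  out <- with_seed(seed, lapply(seq_len(n), function(i) {
    tr <- tree
    if (nni_moves > 0) tr <- phangorn::rNNI(tr, moves = nni_moves)
    if (jitter_cv > 0) {
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), -sdlog^2 / 2, sdlog)
    }
    tr
  }))
  class(out) <- "multiPhylo"
  attr(out, "provenance") <- "perturbation"
  out
}
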