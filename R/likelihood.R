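#' Root state prior
#'
#' The weight placed on each state at the root when the conditional
#' likelihoods are combined into the tree likelihood.  `"equal"` (flat)
#' is the default throughout the package; `"stationary"` uses the stationary
#' distribution of the fitted generator; `"fitzjohn"` weights states by their
#' own conditional likelihood; `"fixed"` takes user weights.  Every fit and
#' reconstruction records the prior used, since root-state probabilities can
#' depend on it.
#'
#' @param kind One of `"equal"`, `"stationary"`, `"fitzjohn"`, `"fixed"`.
#' @param weights Probability vector over states, required for `"fixed"`.
#' @return An object of class `root_prior`.
#' @export
root_prior <- function(kind = c("equal", "stationary", "fitzjohn", "fixed"),
                       weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(weights) || any(weights < 0)) {
      stop("fixed root prior needs non-negative weights")
    }
    weights <- weights / sum(weights)
  }
  structure(list(kind = kind, weights = weights), class = "root_prior")
}

as_root_prior <- function(root) {
  if (inherits(root, "root_prior")) return(root)
  if (is.character(root)) return(root_prior(root))
  if (is.numeric(root)) return(root_prior("fixed", weights = root))
  stop("cannot interpret `root` as a root prior")
}

root_weights <- function(prior, Q, root_partial) {
  k <- length(root_partial)
  switch(prior$kind,
    equal = rep(1 / k, k),
    stationary = stationary_distribution(Q),
    fitzjohn = {
      s <- sum(root_partial)
      if (s <= 0) rep(1 / k, k) else root_partial / s
    },
    fixed = {
      if (length(prior$weights) != k) stop("fixed root prior has wrong length")
      prior$weights
    })
}

# --- tip partial likelihoods ----------------------------------------------

# Build the n_tip x k matrix of tip conditional likelihoods.
# `tip_states` may be:
#   * a named vector of state labels (or 0/1 integers for binary traits),
#     with NA meaning missing (all-ones partial);
#   * a matrix of partial likelihoods with rownames = tip labels.
tip_partials <- function(tree, tip_states, states) {
  k <- length(states)
  tips <- tree$tip.label
  if (is.matrix(tip_states)) {
    if (is.null(rownames(tip_states))) stop("partial matrix needs rownames")
    missing <- setdiff(tips, rownames(tip_states))
    if (length(missing)) stop("no states for tips: ", paste(missing, collapse = ", "))
    m <- tip_states[tips, , drop = FALSE]
    if (ncol(m) != k) stop("partial matrix has wrong number of states")
    return(unname(m))
  }
  if (is.null(names(tip_states))) {
    if (length(tip_states) != length(tips)) {
      stop("unnamed tip states must match the number of tips")
    }
    names(tip_states) <- tips
  }
  missing <- setdiff(tips, names(tip_states))
  if (length(missing)) stop("no states for tips: ", paste(missing, collapse = ", "))
  vals <- as.character(tip_states[tips])
  m <- matrix(0, length(tips), k)
  for (i in seq_along(vals)) {
    if (is.na(vals[i])) {
      m[i, ] <- 1
    } else {
      j <- match(vals[i], states)
      if (is.na(j)) {
        stop("tip state ", dQuote(vals[i]), " not among model states (",
             paste(states, collapse = ", "), ")")
      }
      m[i, j] <- 1
    }
  }
  m
}

# Combine two binary trait vectors into pair-state partials over states 1-4.
# Missingness in one trait leaves the corresponding margin ambiguous.
pair_partials <- function(tree, x, y) {
  tips <- tree$tip.label
  x <- align_binary(x, tips, "x")
  y <- align_binary(y, tips, "y")
  px <- cbind(ifelse(is.na(x), 1, 1 - x), ifelse(is.na(x), 1, x))
  py <- cbind(ifelse(is.na(y), 1, 1 - y), ifelse(is.na(y), 1, y))
  # state order 00, 01, 10, 11 = (x0y0, x0y1, x1y0, x1y1)
  m <- cbind(px[, 1] * py[, 1], px[, 1] * py[, 2],
             px[, 2] * py[, 1], px[, 2] * py[, 2])
  rownames(m) <- tips
  m
}

align_binary <- function(v, tips, what) {
  if (is.null(names(v))) {
    if (length(v) != length(tips)) stop("unnamed `", what,
                                        "` must match the number of tips")
    names(v) <- tips
  }
  missing <- setdiff(tips, names(v))
  if (length(missing)) stop("no `", what, "` states for tips: ",
                            paste(missing, collapse = ", "))
  v <- v[tips]
  v <- suppressWarnings(as.integer(as.character(v)))
  if (any(!v %in% c(0L, 1L) & !is.na(v))) stop("`", what, "` must be binary 0/1 or NA")
  v
}

# --- pruning ---------------------------------------------------------------

# Precompute traversal order and edge bookkeeping for a tree; reused across
# likelihood evaluations during optimisation.
tree_plan <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = po$edge, lengths = po$edge.length,
       n_tip = ape::Ntip(tree), n_node = tree$Nnode,
       root = ape::Ntip(tree) + 1L)
}

# Felsenstein pruning with per-node rescaling (compiled core).  Returns the
# log-likelihood and, when `keep`, the bookkeeping reused by ancestral-state
# reconstruction and stochastic mapping: scaled partials `lik`, per-edge
# transition matrices `pm` and per-edge upward messages `up_msg`.
prune_engine <- function(plan, partials, Q, prior, keep = FALSE) {
  m <- if (inherits(Q, "rate_matrix")) Q$matrix else Q
  res <- .prune_core(plan$edge, plan$lengths, unname(partials), unname(m),
                     plan$n_tip, plan$n_node, keep)
  if (isTRUE(res$zero)) {
    return(list(loglik = -Inf, lik = res$lik, pm = res$pm,
                up_msg = res$up_msg, root_weights = NULL))
  }
  root_partial <- as.numeric(res$root_partial)
  w <- root_weights(prior, m, root_partial)
  total <- sum(w * root_partial)
  ll <- if (total <= 0) -Inf else log(total) + res$logscale
  list(loglik = ll, lik = res$lik, pm = res$pm, up_msg = res$up_msg,
       root_weights = w)
}

#' Pruning log-likelihood of discrete tip data
#'
#' Computes the log-likelihood of observed (possibly partially missing) tip
#' states under a CTMC rate matrix by Felsenstein's pruning algorithm, with
#' per-node rescaling for numerical stability.  Multifurcating trees and
#' zero-length branches are handled natively; missing tip states contribute a
#' partial likelihood of 1 for every state.
#'
#' @param tree A `phylo`.
#' @param tip_states Named state vector (labels drawn from the rate matrix's
#'   states; `NA` = missing) or a tip-by-state matrix of partial likelihoods.
#'   For pair models built from two binary vectors see [fit_pagel()].
#' @param Q A `rate_matrix` or generator matrix.
#' @param root Root prior: a [root_prior()], its kind as a string, or a fixed
#'   weight vector.
#' @return The log-likelihood (possibly `-Inf` for impossible data, e.g. a
#'   both-traits tip under a trade-off model with no mass on state 4).
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' Q <- build_rate_matrix(c(q = 0.5), "ER")
#' prune_loglik(tr, c(A = "0", B = "0"), Q)
#' @export
prune_loglik <- function(tree, tip_states, Q, root = "equal") {
  m <- as_generator(Q)
  plan <- tree_plan(tree)
  partials <- tip_partials(tree, tip_states, rownames(m))
  prune_engine(plan, partials, m, as_root_prior(root))$loglik
}

# Internal fast path used by optimisers: plan and partials precomputed.
loglik_given_plan <- function(plan, partials, Q, prior) {
  prune_engine(plan, partials, Q, prior)$loglik
}
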