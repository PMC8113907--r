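#' Marginal ancestral-state probabilities
#'
#' Computes, for every internal node, the marginal posterior probability of
#' each state given the tip data and a fixed rate matrix (typically the ML
#' fit), by the standard two-pass (downward pruning + upward message)
#' algorithm — equivalent to re-rooting at each node.
#'
#' @param tree A `phylo`.
#' @param tip_states Tip data as in [prune_loglik()].
#' @param Q A `rate_matrix` or generator.
#' @param root Root prior; recorded in the result since root-state
#'   probabilities can depend on it.
#' @return An object of class `ancestral_states`: matrix `prob`
#'   (`Nnode` rows, one per internal node in ape numbering order
#'   `Ntip+1 ... Ntip+Nnode`, columns = states, rows sum to 1), plus
#'   `loglik` and `root` (the prior kind).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' Q <- build_rate_matrix(c(q = 0.3), "ER")
#' ancestral_marginal(tr, c(A = "0", B = "0", C = "1", D = "1"), Q)$prob
#' @export
ancestral_marginal <- function(tree, tip_states, Q, root = "equal") {
  m <- as_generator(Q)
  plan <- tree_plan(tree)
  partials <- tip_partials(tree, tip_states, rownames(m))
  prior <- as_root_prior(root)
  res <- prune_engine(plan, partials, m, prior, keep = TRUE)
  if (!is.finite(res$loglik)) stop("data have zero likelihood under this model")

  k <- nrow(m)
  n_tip <- plan$n_tip
  n_tot <- n_tip + plan$n_node
  edge <- plan$edge
  # upward (root-side) messages, preorder = reverse postorder
  up <- matrix(NA_real_, n_tot, k)
  up[plan$root, ] <- res$root_weights
  edges_of_parent <- split(seq_len(nrow(edge)), edge[, 1L])
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    if (ch <= n_tip) next
    sib <- setdiff(edges_of_parent[[as.character(p)]], e)
    # parent-side partial excluding this child's subtree
    excl <- up[p, ]
    for (se in sib) excl <- excl * res$up_msg[se, ]
    up[ch, ] <- crossprod(res$pm[, , e], excl)[, 1L]
    s <- sum(up[ch, ])
    if (s > 0) up[ch, ] <- up[ch, ] / s
  }
  prob <- res$lik[(n_tip + 1L):n_tot, , drop = FALSE] *
    up[(n_tip + 1L):n_tot, , drop = FALSE]
  prob <- prob / rowSums(prob)
  dimnames(prob) <- list((n_tip + 1L):n_tot, rownames(m))
  structure(list(prob = prob, loglik = res$loglik, root = prior$kind,
                 states = rownames(m)),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, digits = 3, ...) {
  cat("Marginal ancestral states (", nrow(x$prob), " nodes, root prior ",
      x$root, ")\n", sep = "")
  print(round(head(x$prob, 10), digits))
  if (nrow(x$prob) > 10) cat("...\n")
  invisible(x)
}
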