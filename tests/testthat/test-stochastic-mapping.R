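test_that("marginal reconstruction matches enumeration on a 4-tip tree", {
  tr <- read_newick("((A:1,B:2):0.5,(C:1.5,D:0.7):1);")
  with_test_seed(9, {
    Q <- build_rate_matrix(c(q01 = runif(1, 0.2, 0.6),
                             q10 = runif(1, 0.2, 0.6)), "ARD")
  })
  tips <- named_states(A = 0, B = 1, C = 1, D = 0)
  am <- ancestral_marginal(tr, tips, Q)
  oracle <- enum_marginals(tr, tips, Q)
  expect_lt(max(abs(am$prob - oracle)), 1e-10)
  expect_equal(rowSums(am$prob), rep(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)

  # 4-state pair model against the same oracle
  Qp <- random_pagel_Q(71)
  ptips <- named_states(A = "00", B = "01", C = "11", D = "10")
  amp <- ancestral_marginal(tr, ptips, Qp)
  expect_lt(max(abs(amp$prob - enum_marginals(tr, ptips, Qp))), 1e-10)
})

test_that("marginal reconstruction respects symmetry and uniform data", {
  two <- read_newick("(A:1,B:1);")
  Q <- build_rate_matrix(c(q = 0.4), "ER")
  am <- ancestral_marginal(two, named_states(A = 0, B = 1), Q)
  expect_equal(unname(am$prob[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  tr <- simulate_bd_tree(20, seed = 5)
  zeros <- setNames(rep("0", 20), tr$tip.label)
  amz <- ancestral_marginal(tr, zeros, build_rate_matrix(c(q = 1e-6), "ER"))
  expect_true(all(amz$prob[, "0"] > 0.999))
})

test_that("stochastic maps honour tip data, seeds and branch lengths", {
  tr <- fixture_tree_5()
  Q <- build_rate_matrix(c(q01 = 0.3, q10 = 0.2), "ARD")
  tips <- named_states(A = 0, B = 1, C = 1, D = 0, E = 1)
  maps <- simmap_sample(tr, tips, Q, n = 25, seed = 17)
  expect_length(maps, 25L)
  for (h in maps[1:5]) {
    expect_identical(h$node_states[names(tips)],
                     setNames(as.character(tips), names(tips)))
    lens <- vapply(h$maps, sum, 0)
    expect_equal(lens, pagelion:::tree_plan(tr)$lengths, tolerance = 1e-12)
    # branch start state equals the parent node state
    for (e in seq_len(nrow(h$edge))) {
      expect_identical(names(h$maps[[e]])[1L],
                       unname(h$node_states[h$edge[e, 1L]]))
      expect_identical(names(h$maps[[e]])[length(h$maps[[e]])],
                       unname(h$node_states[h$edge[e, 2L]]))
    }
  }
  again <- simmap_sample(tr, tips, Q, n = 25, seed = 17)
  expect_identical(maps, again)
})

test_that("map frequencies converge to the marginal probabilities", {
  tr <- read_newick("((A:1,B:2):0.5,(C:1.5,D:0.7):1);")
  Q <- build_rate_matrix(c(q01 = 0.4, q10 = 0.5), "ARD")
  tips <- named_states(A = 0, B = 1, C = 1, D = 0)
  n <- 4000
  sm <- simmap_summarize(simmap_sample(tr, tips, Q, n = n, seed = 23))
  am <- ancestral_marginal(tr, tips, Q)
  p <- am$prob
  mc_se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(sm$node_freq[5:7, ] - p) <= 3 * mc_se + 1e-9))
})

test_that("expected transition counts dominate the parsimony minimum", {
  tr <- simulate_bd_tree(25, seed = 33)
  Q <- build_rate_matrix(c(q = 0.03), "ER")
  sim <- simulate_traits(tr, Q, seed = 34)
  s <- setNames(as.character(sim$trait), rownames(sim))
  pd <- phangorn::phyDat(matrix(as.character(sim$trait), ncol = 1,
                                dimnames = list(rownames(sim), NULL)),
                         type = "USER", levels = c("0", "1"))
  parsimony_min <- phangorn::parsimony(tr, pd)
  sm <- simmap_summarize(simmap_sample(tr, s, Q, n = 200, seed = 35))
  expect_gte(sum(sm$transitions), parsimony_min)
  expect_equal(sum(sm$dwell), 1, tolerance = 1e-12)

  single <- simmap_summarize(simmap_sample(tr, s, Q, n = 1, seed = 36))
  expect_true(all(single$node_freq %in% c(0, 1)))
})

test_that("branch sampler matches the uniformization law for jump counts", {
  # single-branch endpoint-conditioned problem: distribution of the number
  # of realised jumps under rejection sampling vs the uniformization weights
  Q <- as.matrix(build_rate_matrix(c(q01 = 0.8, q10 = 0.5), "ARD"))
  t_len <- 1.3
  a <- 1L; b <- 2L
  mu <- max(-diag(Q))
  R <- diag(2) + Q / mu
  pmat <- transition_probabilities(Q, t_len)
  # P(N_total = n | a -> b): Poisson(mu t) x R^n, including virtual jumps;
  # realised-jump distribution obtained by Monte Carlo from the exact
  # uniformization path sampler is compared against rejection sampling.
  unif <- pagelion:::uniformization_setup(Q)
  draw_changes <- function(sampler_seed, use_rejection) {
    with_test_seed(sampler_seed, {
      vapply(1:3000, function(i) {
        seg <- if (use_rejection) {
          pagelion:::sample_branch_history(Q, unif, pmat, a, b, t_len,
                                           c("0", "1"), 1e6)
        } else {
          pagelion:::sample_branch_history(Q, unif, pmat, a, b, t_len,
                                           c("0", "1"), 0L)
        }
        length(seg) - 1L
      }, 1L)
    })
  }
  rej <- draw_changes(101, TRUE)
  uni <- draw_changes(102, FALSE)
  tab <- function(v) tabulate(pmin(v, 5L) + 1L, nbins = 6L)
  counts <- rbind(rej = tab(rej), uni = tab(uni))
  keep <- colSums(counts) > 10
  gof <- suppressWarnings(stats::chisq.test(counts[, keep]))
  expect_gt(gof$p.value, 0.01)
})

test_that("mismatched maps are rejected by the summariser", {
  tr <- fixture_tree_5()
  Q <- build_rate_matrix(c(q = 0.2), "ER")
  tips <- named_states(A = 0, B = 1, C = 1, D = 0, E = 1)
  m1 <- simmap_sample(tr, tips, Q, n = 2, seed = 1)
  tr2 <- simulate_bd_tree(5, seed = 2)
  tips2 <- setNames(c("0", "1", "0", "1", "0"), tr2$tip.label)
  m2 <- simmap_sample(tr2, tips2, Q, n = 1, seed = 3)
  expect_error(simmap_summarize(c(m1, m2)), "different trees")
})
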