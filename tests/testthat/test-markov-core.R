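test_that("rate matrices satisfy their structural constraints", {
  er <- build_rate_matrix(c(q = 0.3), "ER")
  expect_equal(as.matrix(er), matrix(c(-0.3, 0.3, 0.3, -0.3), 2, 2,
                                     byrow = TRUE), ignore_attr = TRUE)

  dep <- build_rate_matrix(setNames(rep(1, 8), c("q12", "q13", "q21", "q24",
                                                 "q31", "q34", "q42", "q43")),
                           "dependent")
  m <- as.matrix(dep)
  expect_equal(diag(m), rep(-2, 4), ignore_attr = TRUE)
  expect_equal(m[cbind(c(1, 4, 2, 3), c(4, 1, 3, 2))], rep(0, 4))
  expect_equal(rowSums(m), rep(0, 4), ignore_attr = TRUE)

  ind <- build_rate_matrix(c(qx01 = 0.1, qx10 = 0.2, qy01 = 0.3, qy10 = 0.4),
                           "independent")
  mi <- as.matrix(ind)
  expect_equal(mi[1, 2], 0.3)  # q12 = qy01
  expect_equal(mi[3, 4], 0.3)  # q34 = qy01
  expect_equal(mi[1, 3], 0.1)  # q13 = qx01
  expect_equal(mi[2, 4], 0.1)  # q24 = qx01
  expect_equal(mi[2, 1], 0.4)  # q21 = qy10
  expect_equal(mi[4, 3], 0.4)  # q43 = qy10
  expect_equal(mi[3, 1], 0.2)  # q31 = qx10
  expect_equal(mi[4, 2], 0.2)  # q42 = qx10

  expect_error(build_rate_matrix(c(q = -1), "ER"), "non-negative")
})

test_that("transition probabilities match closed forms and a series oracle", {
  Q <- build_rate_matrix(c(q = 0.5), "ER")
  expect_equal(transition_probabilities(Q, 0), diag(2), ignore_attr = TRUE)
  expect_equal(transition_probabilities(Q, 1)[1, 1],
               0.5 + 0.5 * exp(-2 * 0.5), tolerance = 1e-12)

  for (seed in c(11, 12, 13)) {
    Qp <- random_pagel_Q(seed)
    p <- transition_probabilities(Qp, 0.7)
    expect_lt(max(abs(p - expm_series(as.matrix(Qp), 0.7))), 1e-10)
    expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(transition_probabilities(Q, -1), "t must")
})

test_that("pruning log-likelihood agrees with closed forms", {
  Q <- build_rate_matrix(c(q = 0.5), "ER")
  star <- read_newick("(A:0,B:0,C:0);")
  expect_equal(prune_loglik(star, named_states(A = 0, B = 0, C = 0), Q),
               -log(2))

  cherry <- read_newick("(A:1,B:1);")
  p00 <- 0.5 + 0.5 * exp(-1)
  p10 <- 0.5 - 0.5 * exp(-1)
  expect_equal(prune_loglik(cherry, named_states(A = 0, B = 0), Q),
               log(0.5 * (p00^2 + p10^2)), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small trees", {
  tr <- fixture_tree_5()
  with_test_seed(21, {
    Qa <- build_rate_matrix(c(q01 = runif(1, 0.1, 0.6),
                              q10 = runif(1, 0.1, 0.6)), "ARD")
  })
  tips <- named_states(A = 0, B = 1, C = 1, D = 0, E = 1)
  expect_equal(prune_loglik(tr, tips, Qa), enum_loglik(tr, tips, Qa),
               tolerance = 1e-10)

  # with a missing tip, and on a multifurcating tree
  tips_na <- tips
  tips_na["C"] <- NA
  expect_equal(prune_loglik(tr, tips_na, Qa), enum_loglik(tr, tips_na, Qa),
               tolerance = 1e-10)
  multi <- read_newick("((A:1,B:1,C:1):1,(D:1.5,E:1.5):0.5);")
  expect_equal(prune_loglik(multi, tips, Qa), enum_loglik(multi, tips, Qa),
               tolerance = 1e-10)

  # 4-state pair model
  Qp <- random_pagel_Q(31)
  ptips <- named_states(A = "00", B = "01", C = "11", D = "10", E = "00")
  expect_equal(prune_loglik(tr, ptips, Qp), enum_loglik(tr, ptips, Qp),
               tolerance = 1e-10)
})

test_that("ER likelihood is invariant under relabeling 0 <-> 1", {
  Q <- build_rate_matrix(c(q = 0.2), "ER")
  for (seed in 1:4) {
    tr <- simulate_bd_tree(15, seed = seed)
    sim <- simulate_traits(tr, Q, seed = seed + 100)
    s <- setNames(as.character(sim$trait), rownames(sim))
    flipped <- setNames(as.character(1L - sim$trait), rownames(sim))
    expect_equal(prune_loglik(tr, s, Q), prune_loglik(tr, flipped, Q),
                 tolerance = 1e-12)
  }
})

test_that("independent-model pair likelihood factorises into the margins", {
  for (seed in 1:4) {
    tr <- simulate_bd_tree(25, seed = seed)
    with_test_seed(seed + 50, {
      r <- runif(4, 0.02, 0.4)
    })
    Qi <- build_rate_matrix(setNames(r, c("qx01", "qx10", "qy01", "qy10")),
                            "independent")
    Qx <- build_rate_matrix(c(q01 = r[1], q10 = r[2]), "ARD")
    Qy <- build_rate_matrix(c(q01 = r[3], q10 = r[4]), "ARD")
    simx <- simulate_traits(tr, Qx, seed = seed + 60)
    simy <- simulate_traits(tr, Qy, seed = seed + 70)
    x <- setNames(simx$trait, rownames(simx))
    y <- setNames(simy$trait, rownames(simy))
    pp <- pagelion:::pair_partials(tr, x, y)
    ll_pair <- prune_loglik(tr, pp, Qi)
    ll_sum <- prune_loglik(tr, setNames(as.character(x), names(x)), Qx) +
      prune_loglik(tr, setNames(as.character(y), names(y)), Qy)
    expect_equal(ll_pair, ll_sum, tolerance = 1e-8)
  }
})

test_that("rescaling branch lengths and rates inversely leaves logL fixed", {
  tr <- simulate_bd_tree(20, seed = 8)
  Qp <- random_pagel_Q(41)
  sim <- simulate_traits(tr, Qp, root = "00", seed = 9)
  pp <- pagelion:::pair_partials(tr, setNames(sim$brush_organ, rownames(sim)),
                                 setNames(sim$scent_pad, rownames(sim)))
  ll1 <- prune_loglik(tr, pp, Qp)
  for (c_scale in c(0.1, 3, 42)) {
    tr2 <- tr
    tr2$edge.length <- tr2$edge.length * c_scale
    Q2 <- as.matrix(Qp) / c_scale
    dimnames(Q2) <- dimnames(as.matrix(Qp))
    expect_equal(prune_loglik(tr2, pp, Q2), ll1, tolerance = 1e-8)
  }
})

test_that("trade-off model assigns zero likelihood to both-traits tips", {
  Qt <- build_rate_matrix(c(q12 = 0.1, q13 = 0.1, q21 = 0.1, q24 = 0,
                            q31 = 0.1, q34 = 0, q42 = 0.1, q43 = 0.1),
                          "dependent")
  tr <- fixture_tree_5()
  tips <- named_states(A = "11", B = "00", C = "00", D = "00", E = "10")
  expect_identical(prune_loglik(tr, tips, Qt, root = c(1, 1, 1, 0) / 3),
                   -Inf)
  # without a both-traits tip the likelihood is positive
  tips_ok <- named_states(A = "10", B = "00", C = "00", D = "00", E = "10")
  expect_true(is.finite(prune_loglik(tr, tips_ok, Qt,
                                     root = c(1, 1, 1, 0) / 3)))
})

test_that("stationary distribution solves pi Q = 0", {
  Qp <- random_pagel_Q(55)
  pi_hat <- stationary_distribution(Qp)
  expect_equal(sum(pi_hat), 1)
  expect_lt(max(abs(pi_hat %*% as.matrix(Qp))), 1e-10)
})
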