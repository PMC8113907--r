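#' Build a CTMC rate matrix for one binary trait or a trait pair
#'
#' Constructs the generator of a continuous-time Markov chain over either a
#' single binary character (`ER`, `ARD`) or an ordered pair of binary
#' characters (`independent`, `dependent`, and the one-way conditional models
#' `x_dep`, `y_dep`).  Pair states are ordered 1 = (0,0), 2 = (0,1),
#' 3 = (1,0), 4 = (1,1); double transitions (1<->4, 2<->3) are structural
#' zeros, so the dependent model has eight free rates `q12, q13, q21, q24,
#' q31, q34, q42, q43`.  Under independence the pair rates collapse onto the
#' four marginal rates: `q13 = q24 = qx01`, `q31 = q42 = qx10`,
#' `q12 = q34 = qy01`, `q21 = q43 = qy10`.
#'
#' @param params Named (or positional) non-negative rates.
#'   * `ER`: `q` (one rate).
#'   * `ARD`: `q01`, `q10`.
#'   * `independent`: `qx01`, `qx10`, `qy01`, `qy10`.
#'   * `dependent`: `q12`, `q13`, `q21`, `q24`, `q31`, `q34`, `q42`, `q43`.
#'   * `x_dep` (X's rates depend on Y; 6 parameters): as `dependent` but with
#'     `q12 = q34`, `q21 = q43` (Y evolves independently of X).
#'   * `y_dep` (Y's rates depend on X): `q13 = q24`, `q31 = q42`.
#' @param mode Model tag, one of `"ER"`, `"ARD"`, `"independent"`,
#'   `"dependent"`, `"x_dep"`, `"y_dep"`.
#' @return An object of class `rate_matrix`: a list with the generator
#'   `$matrix` (zero row sums), `$mode`, `$rates` (the free parameters),
#'   `$states` and `$k`.
#' @examples
#' build_rate_matrix(c(q = 0.3), "ER")
#' build_rate_matrix(c(q12 = 1, q13 = 1, q21 = 1, q24 = 1,
#'                     q31 = 1, q34 = 1, q42 = 1, q43 = 1), "dependent")
#' @export
build_rate_matrix <- function(params, mode = c("ER", "ARD", "independent",
                                               "dependent", "x_dep", "y_dep")) {
  mode <- match.arg(mode)
  params <- unlist(params)
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("rates must be finite and non-negative")
  }
  expected <- rate_names(mode)
  if (is.null(names(params)) || !any(nzchar(names(params)))) {
    if (length(params) != length(expected)) {
      stop(mode, " model needs ", length(expected), " rates (",
           paste(expected, collapse = ", "), ")")
    }
    names(params) <- expected
  }
  if (!setequal(names(params), expected)) {
    stop(mode, " model needs rates named ", paste(expected, collapse = ", "))
  }
  params <- params[expected]

  if (mode %in% c("ER", "ARD")) {
    q01 <- if (mode == "ER") params[["q"]] else params[["q01"]]
    q10 <- if (mode == "ER") params[["q"]] else params[["q10"]]
    m <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE,
                dimnames = list(c("0", "1"), c("0", "1")))
    return(new_rate_matrix(m, mode, params))
  }

  q <- pair_rates(params, mode)
  m <- matrix(0, 4, 4, dimnames = list(pagel_states(), pagel_states()))
  m[1, 2] <- q[["q12"]]; m[1, 3] <- q[["q13"]]
  m[2, 1] <- q[["q21"]]; m[2, 4] <- q[["q24"]]
  m[3, 1] <- q[["q31"]]; m[3, 4] <- q[["q34"]]
  m[4, 2] <- q[["q42"]]; m[4, 3] <- q[["q43"]]
  diag(m) <- -rowSums(m)
  new_rate_matrix(m, mode, params)
}

rate_names <- function(mode) {
  switch(mode,
    ER = "q",
    ARD = c("q01", "q10"),
    independent = c("qx01", "qx10", "qy01", "qy10"),
    dependent = c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43"),
    x_dep = c("q12", "q13", "q21", "q24", "q31", "q42"),
    y_dep = c("q12", "q13", "q21", "q31", "q34", "q43"))
}

# Expand the free parameters of each pair model into the eight q_ij entries.
pair_rates <- function(params, mode) {
  p <- as.list(params)
  switch(mode,
    independent = list(
      q12 = p$qy01, q34 = p$qy01, q21 = p$qy10, q43 = p$qy10,
      q13 = p$qx01, q24 = p$qx01, q31 = p$qx10, q42 = p$qx10),
    dependent = p,
    # X conditional on Y, Y independent of X: Y's rates shared across X states
    x_dep = list(q12 = p$q12, q34 = p$q12, q21 = p$q21, q43 = p$q21,
                 q13 = p$q13, q24 = p$q24, q31 = p$q31, q42 = p$q42),
    # Y conditional on X, X independent of Y
    y_dep = list(q13 = p$q13, q24 = p$q13, q31 = p$q31, q42 = p$q31,
                 q12 = p$q12, q21 = p$q21, q34 = p$q34, q43 = p$q43))
}

#' Joint state labels for a trait pair
#' @return `c("00", "01", "10", "11")`, i.e. states 1-4.
#' @export
pagel_states <- function() c("00", "01", "10", "11")

new_rate_matrix <- function(m, mode, rates) {
  structure(list(matrix = m, mode = mode, rates = rates,
                 states = rownames(m), k = nrow(m)),
            class = "rate_matrix")
}

#' @export
as.matrix.rate_matrix <- function(x, ...) x$matrix

#' @export
print.rate_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("%s rate matrix (%d states, %d free rates)\n",
              x$mode, x$k, length(x$rates)))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Number of free rate parameters of a model tag
#' @param mode Model tag as in [build_rate_matrix()].
#' @return Integer count.
#' @export
n_free_rates <- function(mode) length(rate_names(mode))

as_generator <- function(Q) {
  if (inherits(Q, "rate_matrix")) return(Q$matrix)
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (is.null(rownames(Q))) {
    dimnames(Q) <- list(as.character(seq_len(nrow(Q)) - 1L),
                        as.character(seq_len(nrow(Q)) - 1L))
  }
  Q
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi Q = 0` with `sum(pi) = 1`.  For reducible generators (e.g. the
#' trade-off regime where state 4 is unreachable) the returned vector is the
#' stationary distribution of the chain restricted to its recurrent classes.
#'
#' @param Q A `rate_matrix` or plain generator matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(Q) {
  m <- as_generator(Q)
  k <- nrow(m)
  a <- rbind(t(m), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- qr.solve(a, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- rownames(m)
  pi_hat
}

# --- matrix exponential ----------------------------------------------------

# Eigendecomposition cache for repeated P(t) evaluation with a fixed Q.
# Falls back to Matrix::expm (scaling and squaring) when the eigenvector
# matrix is ill-conditioned (defective or nearly-defective Q).
decompose_generator <- function(Q) {
  m <- as_generator(Q)
  dec <- tryCatch({
    e <- eigen(m)
    vinv <- solve(e$vectors)
    cond <- max(abs(e$vectors)) * max(abs(vinv))
    if (!all(is.finite(vinv)) || cond > 1e8) NULL
    else list(values = e$values, vectors = e$vectors, vinv = vinv)
  }, error = function(e) NULL)
  list(matrix = m, eig = dec, k = nrow(m))
}

pmat_from_decomposition <- function(dec, t) {
  if (t == 0) return(diag(dec$k))
  if (is.null(dec$eig)) {
    p <- as.matrix(Matrix::expm(dec$matrix * t))
  } else {
    e <- dec$eig
    p <- Re(e$vectors %*% (exp(e$values * t) * e$vinv))
  }
  p[p < 0] <- 0
  p / rowSums(p)
}

#' Transition probabilities over an elapsed time
#'
#' Computes `expm(Q t)`, the state-to-state transition probability matrix of
#' the CTMC after time `t`, by eigendecomposition with a scaling-and-squaring
#' fallback for (near-)defective generators.
#'
#' @param Q A `rate_matrix` or generator matrix.
#' @param t Non-negative elapsed time.
#' @return A stochastic matrix (rows sum to 1).
#' @examples
#' Q <- build_rate_matrix(c(q = 0.5), "ER")
#' transition_probabilities(Q, 1)[1, 1]  # 1/2 + exp(-2*0.5)/2
#' @export
transition_probabilities <- function(Q, t) {
  m <- as_generator(Q)
  if (!all(is.finite(m))) stop("non-finite rate matrix")
  if (!is.finite(t) || t < 0) stop("t must be finite and >= 0")
  p <- pmat_from_decomposition(decompose_generator(m), t)
  dimnames(p) <- dimnames(m)
  p
}
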