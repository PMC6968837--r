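#' @useDynLib moranamp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

check_params <- function(r, delta) {
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r), r > 0,
            is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1)
  invisible(NULL)
}

# One-step flip probabilities of the delta-dB Moran process, evaluated
# simultaneously for a batch of mutant configurations.
#
# `Mut` is an S x N 0/1 matrix (one configuration per row). Returns UP and
# DOWN, S x N matrices: UP[s, v] is the probability that one step turns
# vertex v from resident to mutant (0 at mutant vertices), DOWN[s, v] the
# reverse. Both update rules change at most one vertex per step, so these
# flips and the complementary "stay" probability describe the kernel fully.
#
# dB (weight w_{u,v} = strength of u placing offspring on v):
#   die v uniform 1/N; filler u among in-neighbors, prob f(u) w_{u,v} / sum.
# Bd:
#   reproducer u prob f(u)/F; target v prob w_{u,v} / sum_v' w_{u,v'}.
kernel_flip_probs <- function(W, Mut, r, delta) {
  N <- ncol(W)
  Mut <- matrix(as.numeric(Mut), ncol = N)
  k <- rowSums(Mut)
  res <- 1 - Mut
  up <- matrix(0, nrow(Mut), N)
  down <- matrix(0, nrow(Mut), N)
  if (delta > 0) {
    num_mut <- (r * Mut) %*% W          # sum_{u mutant} f(u) w_{u,v}
    den <- num_mut + res %*% W          # sum_{all u} f(u) w_{u,v}
    up <- up + delta / N * (num_mut / den) * res
    down <- down + delta / N * ((den - num_mut) / den) * Mut
  }
  if (delta < 1) {
    Wn <- W / rowSums(W)                # Bd placement probabilities
    Ftot <- N + (r - 1) * k             # total fitness per configuration
    up <- up + (1 - delta) * ((r * Mut) %*% Wn) / Ftot * res
    down <- down + (1 - delta) * (res %*% Wn) / Ftot * Mut
  }
  list(up = up, down = down)
}

state_bits <- function(states, n) {
  # states: 0-based bitmasks; returns length(states) x n 0/1 matrix
  m <- vapply(seq_len(n) - 1L, function(b) bitwAnd(states %/% 2^b, 1L),
              numeric(length(states)))
  matrix(m, nrow = length(states), ncol = n)
}

#' Convert between vertex sets and configuration bitmasks
#'
#' Mutant configurations are encoded as bitmasks: bit `i - 1` set means
#' vertex `i` is occupied by a mutant (so the all-resident state is 0 and
#' the all-mutant state is `2^N - 1`).
#'
#' @param vertices Integer vector of mutant vertex ids (1-based).
#' @param state A single bitmask (numeric, `< 2^N`).
#' @param n Number of vertices.
#' @return `vertices_to_state()` a bitmask; `state_to_vertices()` an
#'   integer vector of vertex ids.
#' @export
vertices_to_state <- function(vertices, n) {
  stopifnot(all(vertices >= 1), all(vertices <= n),
            !anyDuplicated(vertices))
  sum(2^(vertices - 1))
}

#' @rdname vertices_to_state
#' @export
state_to_vertices <- function(state, n) {
  which(state_bits(state, n)[1, ] == 1)
}

#' One-step transition distribution of the delta-dB Moran process
#'
#' With probability `delta` a step is a death-Birth (dB) update: a vertex
#' `v` dies uniformly at random and its in-neighbors `u` compete to fill
#' the vacancy with probability proportional to `f(u) * w[u, v]`, where
#' `f(u) = r` for mutants and 1 for residents. With probability
#' `1 - delta` it is a Birth-death (Bd) update: a reproducer `u` is chosen
#' proportionally to fitness and places offspring on an out-neighbor `v`
#' with probability proportional to `w[u, v]`. Successors that coincide
#' are merged; probabilities sum to 1.
#'
#' @param g A validated [weighted_digraph()].
#' @param state Mutant configuration: bitmask (see [vertices_to_state()])
#'   or integer vector of mutant vertices if `as_vertices = TRUE`.
#' @param r Mutant relative fitness (`> 0`).
#' @param delta Fraction of dB updates, in `[0, 1]` (`delta = 1` pure dB,
#'   `delta = 0` pure Bd).
#' @param as_vertices Interpret/return states as vertex vectors.
#' @return A data frame with columns `state` (successor bitmask) and
#'   `prob`, or with a list-column `mutants` if `as_vertices = TRUE`.
#' @examples
#' g <- make_family("complete", n = 2)
#' step_distribution(g, state = 1, r = 2, delta = 0.5)
#' @export
step_distribution <- function(g, state, r, delta, as_vertices = FALSE) {
  check_params(r, delta)
  assert_valid_graph(g)
  if (as_vertices) state <- vertices_to_state(state, g$n)
  stopifnot(state >= 0, state < 2^g$n)
  mut <- state_bits(state, g$n)
  fl <- kernel_flip_probs(weight_matrix(g), mut, r, delta)
  v <- seq_len(g$n)
  succ <- c(state + 2^(v - 1), state - 2^(v - 1), state)
  prob <- c(fl$up[1, ], fl$down[1, ], 1 - sum(fl$up) - sum(fl$down))
  prob[abs(prob) < 1e-14] <- 0   # zap roundoff dust in the self-transition
  keep <- prob > 0
  out <- stats::aggregate(prob ~ succ, data.frame(succ = succ[keep],
                                                  prob = prob[keep]), sum)
  names(out) <- c("state", "prob")
  out <- out[order(out$state), ]
  rownames(out) <- NULL
  if (as_vertices)
    out$mutants <- lapply(out$state, state_to_vertices, n = g$n)
  out
}

new_fixation_result <- function(per_start, average, method, residual = NA_real_,
                                r, delta, graph_label = NULL, extra = list()) {
  structure(c(list(per_start = per_start, average = average, method = method,
                   residual = residual, r = r, delta = delta,
                   graph = graph_label), extra),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  cat(sprintf("Fixation probability (%s)%s\n", x$method,
              if (!is.null(x$graph)) paste0(" on ", x$graph) else ""))
  cat(sprintf("  r = %g, delta = %g\n", x$r, x$delta))
  cat(sprintf("  average rho = %.10g\n", x$average))
  if (!is.na(x$residual))
    cat(sprintf("  solver residual = %.3g\n", x$residual))
  if (!is.null(x$std_error))
    cat(sprintf("  replicates = %d, SE = %.3g, 95%% CI [%.6g, %.6g]\n",
                x$replicates, x$std_error, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Exact fixation probability by solving the full configuration chain
#'
#' Builds the absorbing Markov chain over all `2^N` mutant configurations
#' under delta-dB updating and solves the linear system
#' `x(S) = sum_T P(S -> T) x(T)` with `x(all-mutant) = 1`,
#' `x(all-resident) = 0` by a sparse direct solve. The reported fixation
#' probability averages the single-mutant states `x({v})` over a uniform
#' initial vertex, the convention for a randomly placed invader.
#'
#' @inheritParams step_distribution
#' @param max_n State-space guard: refuse `N > max_n` (default 14, i.e.
#'   16384 configurations); use [fixation_lumped()] or
#'   [estimate_fixation_mc()] beyond it.
#' @return A `fixation_result` with `per_start` (length-`N` vector of
#'   per-initial-vertex fixation probabilities), `average`, `method =
#'   "full-solve"`, and the max-norm `residual` of the solved system.
#' @examples
#' fixation_exact(make_family("star", n = 10), r = 2, delta = 0.2)
#' @export
fixation_exact <- function(g, r, delta = 1, max_n = 14) {
  check_params(r, delta)
  assert_valid_graph(g)
  N <- g$n
  if (N > max_n)
    stop("N = ", N, " exceeds max_n = ", max_n,
         "; use fixation_lumped() or estimate_fixation_mc()")
  S <- 2^N
  states <- 0:(S - 1)
  Mut <- state_bits(states, N)
  fl <- kernel_flip_probs(weight_matrix(g), Mut, r, delta)
  # transitions: state s -> s +/- 2^(v-1)
  i_up <- rep(states, N)
  j_up <- i_up + rep(2^(0:(N - 1)), each = S)
  x_up <- as.vector(fl$up)
  j_dn <- i_up - rep(2^(0:(N - 1)), each = S)
  x_dn <- as.vector(fl$down)
  keep_u <- x_up > 0
  keep_d <- x_dn > 0
  ii <- c(i_up[keep_u], i_up[keep_d])
  jj <- c(j_up[keep_u], j_dn[keep_d])
  xx <- c(x_up[keep_u], x_dn[keep_d])
  # transient states are 1 .. S-2 (bitmasks); absorbing 0 and S-1
  trans <- ii > 0 & ii < S - 1
  ii <- ii[trans]; jj <- jj[trans]; xx <- xx[trans]
  to_fix <- jj == S - 1
  b <- rep(0, S - 2)
  if (any(to_fix)) {
    agg <- rowsum(xx[to_fix], ii[to_fix])
    b[as.numeric(rownames(agg))] <- agg[, 1]
  }
  inner <- !to_fix & jj != 0
  flip_total <- rowSums(fl$up) + rowSums(fl$down)
  Q <- Matrix::sparseMatrix(i = ii[inner], j = jj[inner], x = xx[inner],
                            dims = c(S - 2, S - 2))
  Matrix::diag(Q) <- Matrix::diag(Q) + 1 - flip_total[2:(S - 1)]
  sol <- solve_absorbing(Q, b)
  x <- sol$x
  residual <- sol$residual
  per_start <- x[2^(0:(N - 1))]
  new_fixation_result(per_start, mean(per_start), "full-solve",
                      residual, r, delta, graph_label = graph_label(g))
}

# Solve x = Q x + b for a substochastic transient kernel Q. Small systems
# go through a sparse direct LU; larger ones (the hypercube chain causes
# severe LU fill-in) use the monotone fixed-point iteration
# x_{k+1} = Q x_k + b from x_0 = b, whose error decays at the chain's
# absorption-tail rate. Falls back to the direct solve if the iteration
# has not reached tolerance within max_iter sweeps.
solve_absorbing <- function(Q, b, direct_limit = 2048, tol = 1e-13,
                            max_iter = 2e5) {
  residual_of <- function(x) max(abs(x - as.vector(Q %*% x) - b))
  direct <- function() {
    A <- -Q
    Matrix::diag(A) <- Matrix::diag(A) + 1
    x <- as.vector(Matrix::solve(A, b))
    list(x = x, residual = residual_of(x))
  }
  if (length(b) <= direct_limit) return(direct())
  x <- b
  for (i in seq_len(max_iter)) {
    xn <- as.vector(Q %*% x) + b
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  if (residual_of(x) > 1e-10) return(direct())  # iteration stalled
  list(x = x, residual = residual_of(x))
}

graph_label <- function(g) {
  if (identical(g$family, "custom")) sprintf("custom graph (N=%d)", g$n)
  else sprintf("%s (N=%d)", g$family, g$n)
}

#' Closed-form fixation probability on the complete graph
#'
#' The well-mixed baselines: under Birth-death updating
#' `rho^Bd(K_N, r) = (1 - 1/r) / (1 - 1/r^N)`, and under death-Birth
#' updating `rho^dB(K_N, r) = (1 - 1/N) (1 - 1/r) / (1 - 1/r^(N-1))`.
#' Both are evaluated through the equivalent geometric-sum forms
#' `1 / sum_{k=0}^{N-1} r^-k` and `(1 - 1/N) / sum_{k=0}^{N-2} r^-k`,
#' which are stable for every `r > 0` and give the analytic limit `1/N`
#' at `r = 1` without a special case.
#'
#' @param n Population size (`>= 2`).
#' @param r Mutant relative fitness (`> 0`).
#' @param update `"Bd"` or `"dB"`.
#' @return Fixation probability in `[0, 1]`.
#' @examples
#' rho_complete_closed(10, 2, "Bd") # 512/1023
#' rho_complete_closed(2, 7, "dB")  # exactly 1/2 for every r
#' @export
rho_complete_closed <- function(n, r, update = c("Bd", "dB")) {
  update <- match.arg(update)
  stopifnot(n >= 2, r > 0)
  if (update == "Bd") 1 / sum(r^-(0:(n - 1)))
  else (1 - 1 / n) / sum(r^-(0:(n - 2)))
}

#' Linear-interpolation baseline for mixed updating
#'
#' The convex combination `delta * rho^dB(K_N, r) +
#' (1 - delta) * rho^Bd(K_N, r)` of the two closed forms, used as the
#' well-mixed baseline for delta-dB amplification. It tracks the exact
#' complete-graph value [rho_delta_complete_exact()] to within about 1%
#' (exactly at `N = 2` and at the endpoints `delta = 0, 1`).
#'
#' @inheritParams rho_complete_closed
#' @param delta Fraction of dB updates, in `[0, 1]`.
#' @return Baseline fixation probability.
#' @export
rho_hat_interpolation <- function(n, r, delta) {
  check_params(r, delta)
  delta * rho_complete_closed(n, r, "dB") +
    (1 - delta) * rho_complete_closed(n, r, "Bd")
}

# Per-count step probabilities of the delta-dB process on K_n with k
# mutants: returns p_up = P(k -> k+1) and p_down = P(k -> k-1).
complete_count_steps <- function(n, r, delta, k) {
  Ftot <- n + (r - 1) * k
  up_db <- (n - k) / n * (r * k) / (r * k + n - 1 - k)
  dn_db <- k / n * (n - k) / (r * (k - 1) + n - k)
  up_bd <- (r * k) / Ftot * (n - k) / (n - 1)
  dn_bd <- (n - k) / Ftot * k / (n - 1)
  list(up = delta * up_db + (1 - delta) * up_bd,
       down = delta * dn_db + (1 - delta) * dn_bd)
}

#' Exact fixation probability on the complete graph under mixed updating
#'
#' Exploits the vertex-transitivity of `K_N`: the mutant count is a
#' one-dimensional birth-death chain, so
#' `rho = 1 / (1 + sum_{k=1}^{N-1} prod_{i=1}^{k} gamma_i)` with
#' `gamma_i = P(i -> i-1) / P(i -> i+1)` the per-count bias toward losing
#' a mutant. The step probabilities are derived from the delta-dB rule on
#' `K_N` (and cross-checked against the full `2^N` solver in the test
#' suite). Scales to `N` in the thousands.
#'
#' @inheritParams rho_hat_interpolation
#' @return Fixation probability; matches [rho_complete_closed()] exactly
#'   at `delta = 0` and `delta = 1`.
#' @export
rho_delta_complete_exact <- function(n, r, delta) {
  check_params(r, delta)
  stopifnot(n >= 2)
  k <- seq_len(n - 1)
  st <- complete_count_steps(n, r, delta, k)
  gam <- st$down / st$up
  1 / (1 + sum(cumprod(gam)))
}
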