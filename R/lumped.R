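# Symmetry-lumped exact chains for the named graph families.
#
# Each family's automorphism group makes whole orbits of mutant
# configurations dynamically equivalent, so the 2^N configuration chain
# collapses to a small exact chain over orbit descriptors:
#   complete : mutant count k = 0..N                     (N+1 states)
#   ring     : length of the mutant arc k = 0..N         (N+1 states)
#   star     : (center occupant, mutant leaf count)      (2N states)
#   bipartite: (mutants in part 1, in part 2)            ((m+1)(n+1))
#   fan      : (center occupant, #blades with 1 mutant leaf, #with 2)
#              (2 (B+1)(B+2)/2 states)
# Transition rows are computed by evaluating the exact one-step flip
# probabilities (the same kernel as the full solver) at one representative
# configuration per state; successor states follow by index arithmetic.
# The ring reduction additionally uses the fact that a mutant set that
# starts as a single contiguous arc stays a contiguous arc under both
# update rules (flips have positive probability only at the arc ends).

# Per-family lumping layout: representatives, flip successors, absorbing
# and initial states. Vertex numbering follows make_family().
lumped_layout <- function(g) {
  fam <- g$family
  N <- g$n
  if (fam == "complete" || fam == "ring") {
    S <- N + 1
    k <- 0:N
    Rep <- outer(k, seq_len(N), ">=")
    succ_up <- matrix(rep(k + 2, N), S, N)
    succ_dn <- matrix(rep(k, N), S, N)
    states <- data.frame(k = k)
    init <- data.frame(state = 2, weight = 1, orbit = "vertex",
                       stringsAsFactors = FALSE)
    list(S = S, Rep = Rep, succ_up = succ_up, succ_dn = succ_dn,
         ext = 1L, fix = S, init = init, states = states)
  } else if (fam == "star") {
    L <- N - 1
    id <- function(c, j) c * (L + 1) + j + 1
    grid <- expand.grid(j = 0:L, c = 0:1)
    S <- nrow(grid)
    Rep <- matrix(FALSE, S, N)
    Rep[, 1] <- grid$c == 1
    for (s in seq_len(S))
      if (grid$j[s] > 0) Rep[s, 1 + seq_len(grid$j[s])] <- TRUE
    succ_up <- cbind(id(1, grid$j),
                     matrix(rep(pmin(id(grid$c, grid$j + 1), S), L), S, L))
    succ_dn <- cbind(id(0, grid$j),
                     matrix(rep(pmax(id(grid$c, grid$j - 1), 1), L), S, L))
    init <- data.frame(state = c(id(1, 0), id(0, 1)),
                       weight = c(1 / N, (N - 1) / N),
                       orbit = c("center", "leaf"), stringsAsFactors = FALSE)
    list(S = S, Rep = Rep, succ_up = succ_up, succ_dn = succ_dn,
         ext = id(0, 0), fix = id(1, L), init = init,
         states = data.frame(center = grid$c, leaves = grid$j))
  } else if (fam == "bipartite") {
    m <- g$family_params$m
    n2 <- g$family_params$n
    id <- function(i, j) i * (n2 + 1) + j + 1
    grid <- expand.grid(j = 0:n2, i = 0:m)
    S <- nrow(grid)
    Rep <- matrix(FALSE, S, N)
    for (s in seq_len(S)) {
      if (grid$i[s] > 0) Rep[s, seq_len(grid$i[s])] <- TRUE
      if (grid$j[s] > 0) Rep[s, m + seq_len(grid$j[s])] <- TRUE
    }
    succ_up <- cbind(matrix(rep(id(grid$i + 1, grid$j), m), S, m),
                     matrix(rep(id(grid$i, grid$j + 1), n2), S, n2))
    succ_dn <- cbind(matrix(rep(id(grid$i - 1, grid$j), m), S, m),
                     matrix(rep(id(grid$i, grid$j - 1), n2), S, n2))
    init <- data.frame(state = c(id(1, 0), id(0, 1)),
                       weight = c(m / N, n2 / N),
                       orbit = c("part1", "part2"), stringsAsFactors = FALSE)
    list(S = S, Rep = Rep, succ_up = succ_up, succ_dn = succ_dn,
         ext = id(0, 0), fix = id(m, n2), init = init,
         states = data.frame(part1 = grid$i, part2 = grid$j))
  } else if (fam == "fan") {
    B <- g$family_params$blades
    Tn <- (B + 1) * (B + 2) / 2
    off <- function(j, k2) k2 * (B + 1) - k2 * (k2 - 1) / 2 + j
    id <- function(c, j, k2) c * Tn + off(j, k2) + 1
    desc <- do.call(rbind, lapply(0:1, function(c)
      do.call(rbind, lapply(0:B, function(k2)
        data.frame(c = c, j = 0:(B - k2), k2 = k2)))))
    desc <- desc[order(id(desc$c, desc$j, desc$k2)), ]
    S <- nrow(desc)
    Rep <- matrix(FALSE, S, N)
    Rep[, 1] <- desc$c == 1
    blade_of <- c(NA, rep(seq_len(B), each = 2))   # vertex -> blade
    first_leaf <- c(NA, rep(c(TRUE, FALSE), B))    # vertex is blade's 1st leaf
    for (s in seq_len(S)) {
      k2 <- desc$k2[s]; j <- desc$j[s]
      mut_blades_full <- seq_len(k2)
      mut_blades_one <- if (j > 0) k2 + seq_len(j) else integer(0)
      v <- 2:N
      Rep[s, v] <- (blade_of[v] %in% mut_blades_full) |
        (blade_of[v] %in% mut_blades_one & first_leaf[v])
    }
    succ_up <- matrix(1L, S, N)
    succ_dn <- matrix(1L, S, N)
    for (s in seq_len(S)) {
      c0 <- desc$c[s]; j <- desc$j[s]; k2 <- desc$k2[s]
      v <- 2:N
      b <- blade_of[v]
      full <- b <= k2
      single <- b > k2 & b <= k2 + j
      empty <- b > k2 + j
      su <- integer(N - 1)
      su[empty] <- id(c0, j + 1, k2)                       # 0 -> 1 blade
      su[single & !first_leaf[v]] <- id(c0, j - 1, k2 + 1) # 1 -> 2 blade
      sd <- integer(N - 1)
      sd[full] <- id(c0, j + 1, k2 - 1)                    # 2 -> 1 blade
      sd[single & first_leaf[v]] <- id(c0, j - 1, k2)      # 1 -> 0 blade
      succ_up[s, ] <- c(id(1, j, k2), pmax(su, 1L))
      succ_dn[s, ] <- c(id(0, j, k2), pmax(sd, 1L))
    }
    init <- data.frame(state = c(id(1, 0, 0), id(0, 1, 0)),
                       weight = c(1 / N, (N - 1) / N),
                       orbit = c("center", "leaf"), stringsAsFactors = FALSE)
    list(S = S, Rep = Rep, succ_up = succ_up, succ_dn = succ_dn,
         ext = id(0, 0, 0), fix = id(1, 0, B), init = init,
         states = desc)
  } else {
    stop("no lumping available for family '", fam,
         "'; only complete, ring, star, bipartite, fan are lumped")
  }
}

#' Build the symmetry-lumped transition chain for a named family
#'
#' Collapses the `2^N` configuration chain of the delta-dB Moran process
#' to its exact orbit chain (see the family state descriptors in the
#' package documentation), enabling exact fixation probabilities at
#' population sizes in the hundreds. Transition probabilities are
#' computed by evaluating the exact one-step kernel at one representative
#' configuration per orbit.
#'
#' @param g A graph built by [make_family()] (families `complete`,
#'   `ring`, `star`, `bipartite`, `fan`).
#' @param r Mutant relative fitness (`> 0`).
#' @param delta Fraction of dB updates, in `[0, 1]`.
#' @param max_states State-budget guard (default `1e5`).
#' @return A `lumped_chain`: list with the state descriptor table
#'   `states`, sparse row-stochastic transition matrix `P`, absorbing
#'   indices `ext`/`fix`, and the uniform-single-mutant initial
#'   distribution `init` (one row per starting orbit).
#' @export
build_lumped_chain <- function(g, r, delta = 1, max_states = 1e5) {
  check_params(r, delta)
  lay <- lumped_layout(g)
  if (lay$S > max_states)
    stop("lumped state count ", lay$S, " exceeds max_states = ", max_states)
  fl <- kernel_flip_probs(weight_matrix(g), lay$Rep, r, delta)
  iu <- which(fl$up > 0, arr.ind = TRUE)
  idn <- which(fl$down > 0, arr.ind = TRUE)
  flip_total <- rowSums(fl$up) + rowSums(fl$down)
  P <- Matrix::sparseMatrix(
    i = c(iu[, 1], idn[, 1], seq_len(lay$S)),
    j = c(lay$succ_up[iu], lay$succ_dn[idn], seq_len(lay$S)),
    x = c(fl$up[iu], fl$down[idn], 1 - flip_total),
    dims = c(lay$S, lay$S)
  )
  structure(list(family = g$family, family_params = g$family_params,
                 n = g$n, r = r, delta = delta, states = lay$states,
                 P = P, ext = lay$ext, fix = lay$fix, init = lay$init),
            class = "lumped_chain")
}

#' @export
print.lumped_chain <- function(x, ...) {
  cat(sprintf("lumped_chain: %s (N=%d), %d states, r = %g, delta = %g\n",
              x$family, x$n, nrow(x$states), x$r, x$delta))
  invisible(x)
}

#' Exact fixation probability via the lumped chain
#'
#' Solves the absorbing linear system of [build_lumped_chain()] and
#' averages over the uniform single-mutant initial distribution. The
#' per-orbit starting values (e.g. star center-start vs leaf-start) are
#' retained in `per_start`.
#'
#' @inheritParams build_lumped_chain
#' @return A `fixation_result` with `per_start` a named vector of
#'   per-starting-orbit fixation probabilities, `orbit_weights`, the
#'   uniform `average`, `method = "lumped"`, and the solver residual.
#' @examples
#' fixation_lumped(make_family("star", n = 10), r = 2, delta = 0.2)
#' @export
fixation_lumped <- function(g, r, delta = 1, max_states = 1e5) {
  ch <- build_lumped_chain(g, r, delta, max_states)
  trans <- setdiff(seq_len(nrow(ch$states)), c(ch$ext, ch$fix))
  A <- -ch$P[trans, trans, drop = FALSE]
  Matrix::diag(A) <- Matrix::diag(A) + 1
  b <- as.vector(ch$P[trans, ch$fix])
  x <- as.vector(Matrix::solve(A, b))
  residual <- max(abs(A %*% x - b))
  xf <- numeric(nrow(ch$states))
  xf[trans] <- x
  xf[ch$fix] <- 1
  per_start <- stats::setNames(xf[ch$init$state], ch$init$orbit)
  avg <- sum(ch$init$weight * per_start)
  new_fixation_result(per_start, avg, "lumped", residual, r, delta,
                      graph_label = graph_label(g),
                      extra = list(orbit_weights =
                                     stats::setNames(ch$init$weight,
                                                     ch$init$orbit)))
}

# Map a full mutant configuration to its lumped state index (validation
# helper; used by tests to check that lumping commutes with the kernel).
lump_state <- function(g, mutants) {
  fam <- g$family
  N <- g$n
  mut <- logical(N)
  mut[mutants] <- TRUE
  k <- sum(mut)
  if (fam == "complete") {
    k + 1L
  } else if (fam == "ring") {
    if (k > 0 && k < N) {
      # contiguous cyclic arc check
      runs <- rle(mut[c(which.min(mut):N, seq_len(which.min(mut) - 1))])
      if (sum(runs$values) > 1)
        stop("mutant set is not a contiguous arc; ring lumping undefined")
    }
    k + 1L
  } else if (fam == "star") {
    L <- N - 1
    (mut[1]) * (L + 1) + sum(mut[-1]) + 1L
  } else if (fam == "bipartite") {
    m <- g$family_params$m
    i <- sum(mut[seq_len(m)])
    j <- sum(mut[(m + 1):N])
    i * (g$family_params$n + 1) + j + 1L
  } else if (fam == "fan") {
    B <- g$family_params$blades
    per_blade <- vapply(seq_len(B),
                        function(b) sum(mut[c(2 * b, 2 * b + 1)]), numeric(1))
    j <- sum(per_blade == 1)
    k2 <- sum(per_blade == 2)
    Tn <- (B + 1) * (B + 2) / 2
    (mut[1]) * Tn + k2 * (B + 1) - k2 * (k2 - 1) / 2 + j + 1L
  } else stop("no lumping for family '", fam, "'")
}
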