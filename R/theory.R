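# Bounds, baselines, and amplifier-classification machinery.

#' Upper bounds on death-Birth fixation probability
#'
#' `lemma1_bound(d, r)` is the general upper bound
#' `d * r / (d * r + d + r - 1)` on the dB fixation probability of any
#' (possibly directed/weighted) graph with average out-degree `d`: the
#' initial mutant goes extinct immediately if it is selected for death
#' before any of its neighbors reproduces onto it.
#' `theorem2_bound(r) = 1 - 1/(r + 1)` is its supremum over `d` — no dB
#' amplifier can exceed it, so dB amplification is bounded and the
#' implied scale of fitness of any graph is at most `r + 1`.
#' `theorem4_bound(r, delta) = 1 - 1/((r/delta) + 1)` is the mixed-update
#' analogue: delta-dB amplifiers are at most linear. At `delta = 1` it
#' coincides with `theorem2_bound()`; as `delta -> 0` it tends to 1
#' (vacuous, consistent with unbounded Bd amplification), and `delta = 0`
#' itself is rejected.
#' `theorem1_threshold(n) = 2 n^2` is a fitness threshold beyond which no
#' non-complete graph on `n` vertices amplifies under dB updating
#' (amplification is transient).
#'
#' @param d Average out-degree (`> 0`), see [average_out_degree()].
#' @param r Mutant relative fitness (`> 0`).
#' @param delta Fraction of dB updates, in `(0, 1]`.
#' @param n Population size (`>= 2`).
#' @return A single numeric bound (probability, or threshold for
#'   `theorem1_threshold()`).
#' @examples
#' lemma1_bound(d = 1.8, r = 2)   # star S_10: 0.5625
#' theorem2_bound(2)              # 2/3
#' theorem4_bound(2, 0.5)         # 0.8
#' theorem1_threshold(10)         # 200
#' @export
lemma1_bound <- function(d, r) {
  stopifnot(d > 0, r > 0)
  d * r / (d * r + d + r - 1)
}

#' @rdname lemma1_bound
#' @export
theorem2_bound <- function(r) {
  stopifnot(r > 0)
  1 - 1 / (r + 1)
}

#' @rdname lemma1_bound
#' @export
theorem4_bound <- function(r, delta) {
  stopifnot(r > 0)
  if (delta <= 0 || delta > 1)
    stop("theorem4_bound requires delta in (0, 1]; at delta = 0 the bound is vacuous")
  1 - 1 / ((r / delta) + 1)
}

#' @rdname lemma1_bound
#' @export
theorem1_threshold <- function(n) {
  stopifnot(n >= 2)
  2 * n^2
}

#' Implied scale of fitness
#'
#' The effective fitness a well-mixed population would need for the same
#' (limiting) fixation probability: `isf = 1 / (1 - rho)`. For complete
#' graphs `isf(r) = r`; Bd Star graphs approach `r^2` (quadratic
#' amplification); under dB updating no graph exceeds `r + 1`.
#'
#' @param rho Fixation probability in `[0, 1]`; `rho = 1` maps to `Inf`.
#' @return The implied fitness scale (`>= 1`).
#' @export
implied_scale_of_fitness <- function(rho) {
  stopifnot(all(rho >= 0), all(rho <= 1))
  ifelse(rho == 1, Inf, 1 / (1 - rho))
}

# Best exact route to the average fixation probability of a graph.
rho_exact_route <- function(g, r, delta, max_n = 14) {
  if (identical(g$family, "complete")) {
    list(rho = rho_delta_complete_exact(g$n, r, delta), method = "closed-form")
  } else if (g$family %in% c("ring", "star", "bipartite", "fan")) {
    res <- fixation_lumped(g, r, delta)
    list(rho = res$average, method = "lumped")
  } else if (g$n <= max_n) {
    res <- fixation_exact(g, r, delta, max_n = max_n)
    list(rho = res$average, method = "full-solve")
  } else {
    stop("no exact route: graph is custom with N = ", g$n, " > ", max_n)
  }
}

# The well-mixed baseline rho^delta(K_N, r): closed forms at the pure
# endpoints; for 0 < delta < 1 either the linear interpolation (the
# field-convention default) or the exact complete-graph count chain.
baseline_rho <- function(n, r, delta, baseline = c("interpolation",
                                                   "exact-complete")) {
  baseline <- match.arg(baseline)
  if (delta == 0) list(value = rho_complete_closed(n, r, "Bd"), kind = "Bd closed form")
  else if (delta == 1) list(value = rho_complete_closed(n, r, "dB"), kind = "dB closed form")
  else if (baseline == "interpolation")
    list(value = rho_hat_interpolation(n, r, delta), kind = "interpolation")
  else list(value = rho_delta_complete_exact(n, r, delta), kind = "exact-complete")
}

#' Classify a graph as amplifier or suppressor of selection
#'
#' Computes the graph's fixation probability by the best exact route
#' (closed form for complete graphs, lumped chain for named families,
#' full `2^N` solve for small custom graphs; Monte Carlo only if
#' `method = "mc"`) and compares it to the well-mixed baseline
#' `rho^delta(K_N, r)`. A graph amplifies selection at `(r, delta)` if
#' its fixation probability exceeds the baseline.
#'
#' @inheritParams fixation_exact
#' @param baseline For `0 < delta < 1`: `"interpolation"` (the
#'   convention; see [rho_hat_interpolation()]) or `"exact-complete"`
#'   (the exact count chain, [rho_delta_complete_exact()]). The pure
#'   endpoints always use the closed forms.
#' @param tolerance Exact-route neutrality tolerance on `|ratio - 1|`
#'   (default `1e-9`, the solver-residual scale).
#' @param method `"auto"` (exact routes) or `"mc"`; for `"mc"` supply
#'   `replicates` and `seed`, and the verdict is only `"amplifier"` /
#'   `"suppressor"` when the 95% CI excludes the baseline.
#' @param replicates,seed Monte Carlo controls (`method = "mc"`).
#' @return An `amplification_report`: `rho`, `baseline` (value and kind),
#'   `ratio`, `verdict` (`"amplifier"`, `"suppressor"`,
#'   `"neutral-within-tolerance"`, or `"inconclusive"` for a CI
#'   straddling the baseline), and `isf` (implied scale of fitness).
#' @examples
#' classify_amplifier(make_family("star", n = 10), r = 2, delta = 0.2)
#' @export
classify_amplifier <- function(g, r, delta = 1,
                               baseline = c("interpolation", "exact-complete"),
                               tolerance = 1e-9, method = c("auto", "mc"),
                               replicates = 1e5, seed = NULL, max_n = 14) {
  check_params(r, delta)
  method <- match.arg(method)
  base <- baseline_rho(g$n, r, delta, baseline)
  if (method == "mc") {
    batch <- estimate_fixation_mc(g, r, delta, replicates, seed)
    rho <- batch$estimate
    verdict <- if (batch$conf_int[1] > base$value) "amplifier"
    else if (batch$conf_int[2] < base$value) "suppressor"
    else "inconclusive"
    route <- "monte-carlo"
    extra <- list(conf_int = batch$conf_int, std_error = batch$std_error)
  } else {
    sol <- rho_exact_route(g, r, delta, max_n)
    rho <- sol$rho
    route <- sol$method
    ratio <- rho / base$value
    verdict <- if (ratio > 1 + tolerance) "amplifier"
    else if (ratio < 1 - tolerance) "suppressor"
    else "neutral-within-tolerance"
    extra <- list()
  }
  structure(c(list(graph = graph_label(g), n = g$n, r = r, delta = delta,
                   rho = rho, baseline = base$value,
                   baseline_kind = base$kind, ratio = rho / base$value,
                   verdict = verdict, isf = implied_scale_of_fitness(rho),
                   method = route, tolerance = tolerance), extra),
            class = "amplification_report")
}

#' @export
print.amplification_report <- function(x, ...) {
  cat(sprintf("Amplification report: %s at r = %g, delta = %g\n",
              x$graph, x$r, x$delta))
  cat(sprintf("  rho = %.8g (%s), baseline = %.8g (%s)\n",
              x$rho, x$method, x$baseline, x$baseline_kind))
  cat(sprintf("  ratio = %.8g -> %s; isf = %.6g\n", x$ratio, x$verdict, x$isf))
  invisible(x)
}

#' Full bound report for a graph
#'
#' Evaluates the dB/delta-dB amplification bounds for a graph at given
#' `(r, delta)` together with the exact fixation probability, and flags
#' whether each applicable bound is satisfied.
#'
#' @inheritParams classify_amplifier
#' @return A list: average out-degree `d`, `lemma1`, `theorem2`,
#'   `theorem4` (`NA` at `delta = 0`), `r_star = 2 N^2`, observed `rho`,
#'   and logical `satisfied` flags. Lemma 1 and Theorem 2 apply to pure
#'   dB updating, so their flags are `NA` unless `delta = 1`.
#' @export
bound_report <- function(g, r, delta = 1, max_n = 14) {
  check_params(r, delta)
  d <- average_out_degree(g)
  rho <- rho_exact_route(g, r, delta, max_n)$rho
  l1 <- lemma1_bound(d, r)
  t2 <- theorem2_bound(r)
  t4 <- if (delta > 0) theorem4_bound(r, delta) else NA_real_
  list(d = d, lemma1 = l1, theorem2 = t2, theorem4 = t4,
       r_star = theorem1_threshold(g$n), rho = rho,
       satisfied = list(
         lemma1 = if (delta == 1) rho <= l1 else NA,
         theorem2 = if (delta == 1) rho <= t2 else NA,
         theorem4 = if (delta > 0) rho <= t4 else NA))
}

#' Scan a fitness grid for transient amplification
#'
#' Evaluates amplification at every grid value of `r` and reports the
#' largest grid point at which the graph still amplifies and the smallest
#' grid point beyond which it never amplifies again *within the grid*.
#' The verdict is grid-relative: in principle a graph could alternate
#' between amplifying and suppressing between or beyond grid points.
#'
#' @inheritParams classify_amplifier
#' @param r_grid Increasing vector of fitness values to scan; for a
#'   guaranteed finite threshold on non-complete graphs with `delta > 0`,
#'   extend it to `2 N^2` (see [theorem1_threshold()]).
#' @return A list with `table` (data frame: `r`, `rho`, `baseline`,
#'   `ratio`, `amplifies`), `last_amplifying` (largest amplifying grid
#'   `r`, `NA` if none), `first_non_amplifying_tail` (smallest grid point
#'   from which no later grid point amplifies), and `grid_relative =
#'   TRUE`.
#' @export
transient_threshold_scan <- function(g, delta = 1, r_grid,
                                     baseline = c("interpolation",
                                                  "exact-complete"),
                                     tolerance = 1e-9, max_n = 14) {
  stopifnot(length(r_grid) > 0, !is.unsorted(r_grid, strictly = TRUE))
  rows <- lapply(r_grid, function(r) {
    rep_ <- classify_amplifier(g, r, delta, baseline, tolerance,
                               max_n = max_n)
    data.frame(r = r, rho = rep_$rho, baseline = rep_$baseline,
               ratio = rep_$ratio,
               amplifies = rep_$verdict == "amplifier")
  })
  tab <- do.call(rbind, rows)
  amp <- which(tab$amplifies)
  last_amp <- if (length(amp)) tab$r[max(amp)] else NA_real_
  first_tail <- if (length(amp) == 0) tab$r[1]
  else if (max(amp) < nrow(tab)) tab$r[max(amp) + 1] else NA_real_
  list(table = tab, last_amplifying = last_amp,
       first_non_amplifying_tail = first_tail, grid_relative = TRUE)
}

#' Compare Bd and dB fixation probabilities on the same graph
#'
#' For fitness advantages beyond the transience threshold, Bd updating
#' always favors fixation more than dB updating; at `r = 1` both equal
#' `1/N`.
#'
#' @inheritParams classify_amplifier
#' @return A list with `rho_bd`, `rho_db`, `difference`
#'   (`rho_bd - rho_db`), and `bd_larger`.
#' @export
compare_bd_db <- function(g, r, max_n = 14) {
  bd <- rho_exact_route(g, r, delta = 0, max_n)$rho
  db <- rho_exact_route(g, r, delta = 1, max_n)$rho
  list(rho_bd = bd, rho_db = db, difference = bd - db, bd_larger = bd > db)
}

# All permutations of 1..n as an n! x n integer matrix.
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- matrix(ifelse(sub >= i, sub + 1L, sub), nrow(sub))
    cbind(rep(i, nrow(sub)), rest)
  }))
}

#' Enumerate all connected unweighted graphs up to isomorphism
#'
#' Exhaustively generates the connected undirected unweighted graphs on
#' `n` vertices, one representative per isomorphism class, by canonical-
#' form filtering: each of the `2^(n(n-1)/2)` edge sets is assigned the
#' minimum of its adjacency bitcode over all `n!` vertex relabelings, and
#' the self-canonical connected codes are kept. Sizes: 1, 2, 6, 21, 112
#' classes for `n = 2..6`. Intended for the exhaustive bound- and
#' transience-verification suites; capped at `n <= 6`.
#'
#' @param n Number of vertices, `2 <= n <= 6`.
#' @return A list of [weighted_digraph()] objects (mirrored arcs,
#'   weight 1).
#' @export
all_connected_graphs <- function(n) {
  stopifnot(n >= 2, n <= 6)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ns <- nrow(pairs)
  nmask <- 2^ns
  B <- state_bits(0:(nmask - 1), ns)
  slot <- matrix(0L, n, n)
  slot[pairs] <- seq_len(ns)
  slot <- slot + t(slot)
  perms <- perm_matrix(n)
  code <- rep(Inf, nmask)
  for (p in seq_len(nrow(perms))) {
    pi <- perms[p, ]
    newslot <- slot[cbind(pi[pairs[, 1]], pi[pairs[, 2]])]
    code <- pmin(code, as.vector(B %*% 2^(newslot - 1)))
  }
  reps <- which(code == 0:(nmask - 1))   # self-canonical masks (+1 offset)
  out <- list()
  for (mask in reps - 1) {
    bits <- state_bits(mask, ns)[1, ]
    if (sum(bits) < n - 1) next          # too few edges to be connected
    e <- pairs[bits == 1, , drop = FALSE]
    adj <- matrix(FALSE, n, n)
    adj[e] <- TRUE
    adj <- adj | t(adj)
    # BFS connectivity
    seen <- logical(n)
    seen[1] <- TRUE
    frontier <- 1L
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen)) next
    out[[length(out) + 1]] <-
      weighted_digraph(n, c(e[, 1], e[, 2]), c(e[, 2], e[, 1]), 1)
  }
  out
}

is_complete_graph <- function(g) {
  length(g$from) == g$n * (g$n - 1) && all(g$weight == 1)
}
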