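#' Weighted directed population-structure graph
#'
#' A `weighted_digraph` represents a population structure for the Moran
#' process: `N` sites (vertices), and directed arcs `u -> v` with weight
#' `w[u,v]` in `(0, 1]` giving the strength with which an individual at `u`
#' places offspring on `v`. Absence of an arc encodes weight 0. Self-loops
#' are forbidden and the graph must be strongly connected through
#' positive-weight arcs, which guarantees that the Moran process absorbs
#' into fixation or extinction with probability 1.
#'
#' @param n_vertices Number of vertices `N >= 2`. Vertices are `1..N`.
#' @param from,to Integer vectors of arc endpoints (1-based vertex ids).
#' @param weight Numeric vector of arc weights in `(0, 1]`; recycled if
#'   length 1.
#' @param family Optional family tag (`"complete"`, `"ring"`, `"star"`,
#'   `"bipartite"`, `"fan"`, or `"custom"`).
#' @param family_params Optional named list of family parameters (e.g.
#'   `m`, `n` part sizes for bipartite; `blades`, `epsilon` for fan).
#' @param check If `TRUE` (default), run [validate_graph()] and stop on
#'   any violated invariant.
#' @return An object of class `weighted_digraph`: a list with elements
#'   `n` (vertex count), `from`, `to`, `weight` (parallel arc vectors,
#'   sorted by `(from, to)`), `family`, and `family_params`.
#' @seealso [make_family()], [make_random_strongly_connected()],
#'   [validate_graph()], [read_edge_list()]
#' @examples
#' g <- weighted_digraph(3, from = c(1, 2, 3), to = c(2, 3, 1), weight = 1)
#' validate_graph(g)$is_valid
#' @export
weighted_digraph <- function(n_vertices, from, to, weight = 1,
                             family = "custom", family_params = list(),
                             check = TRUE) {
  n_vertices <- as.integer(n_vertices)
  from <- as.integer(from)
  to <- as.integer(to)
  weight <- as.numeric(weight)
  if (length(weight) == 1L) weight <- rep(weight, length(from))
  stopifnot(length(from) == length(to), length(from) == length(weight))
  ord <- order(from, to)
  g <- structure(
    list(n = n_vertices, from = from[ord], to = to[ord],
         weight = weight[ord], family = family,
         family_params = family_params),
    class = "weighted_digraph"
  )
  if (check) assert_valid_graph(g)
  g
}

#' @export
print.weighted_digraph <- function(x, ...) {
  fam <- if (identical(x$family, "custom")) "" else sprintf(" [%s]", x$family)
  cat(sprintf("weighted_digraph%s: %d vertices, %d arcs\n",
              fam, x$n, length(x$from)))
  if (length(x$weight) > 0) {
    w <- range(x$weight)
    cat(sprintf("  weights in [%g, %g]\n", w[1], w[2]))
  }
  invisible(x)
}

n_vertices <- function(g) g$n
n_arcs <- function(g) length(g$from)

#' Dense weight matrix of a graph
#'
#' @param g A [weighted_digraph()].
#' @return An `N x N` numeric matrix `W` with `W[u, v]` the weight of arc
#'   `u -> v` (0 where no arc exists).
#' @export
weight_matrix <- function(g) {
  W <- matrix(0, g$n, g$n)
  W[cbind(g$from, g$to)] <- g$weight
  W
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$from, to = g$to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(g$n))
  )
}

#' Construct a named graph family
#'
#' Builds the population structures used throughout: the Complete graph
#' `K_N` (the well-mixed baseline), the Ring `R_N` (cycle, both
#' directions), the Star `S_N` (one hub joined to `N - 1` leaves), the
#' Complete Bipartite graph `B_{m,n}` (all cross-part pairs), and the
#' weighted Fan `F_{N,eps}`: a star on `2N + 1` vertices whose `2N` leaves
#' are paired into `N` two-leaf "blades" (leaves within a blade joined
#' with weight 1), with every center-to-leaf arc downweighted to
#' `epsilon` and every leaf-to-center arc kept at weight 1.
#'
#' Unweighted undirected edges are materialized as mirrored arc pairs of
#' weight 1. The Star and Fan center is vertex 1; the Bipartite smaller
#' part comes first.
#'
#' @param kind One of `"complete"`, `"ring"`, `"star"`, `"bipartite"`,
#'   `"fan"`.
#' @param n Number of vertices (complete `n >= 2`, ring `n >= 3`, star
#'   `n >= 3`); for `"bipartite"`, the second part size (`>= 1`).
#' @param m First (by convention smaller) part size for `"bipartite"`.
#' @param blades Number of two-leaf blades for `"fan"` (`>= 1`); the fan
#'   has `2 * blades + 1` vertices.
#' @param epsilon Center-to-leaf weight in `(0, 1)` for `"fan"`.
#' @return A validated [weighted_digraph()] carrying its family tag.
#' @examples
#' make_family("star", n = 10)
#' make_family("fan", blades = 2, epsilon = 0.5)
#' @export
make_family <- function(kind = c("complete", "ring", "star", "bipartite", "fan"),
                        n = NULL, m = NULL, blades = NULL, epsilon = NULL) {
  kind <- match.arg(kind)
  if (kind == "complete") {
    stopifnot(!is.null(n), n >= 2)
    pairs <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
    weighted_digraph(n, pairs[, 1], pairs[, 2], 1,
                     family = "complete", family_params = list(n = n))
  } else if (kind == "ring") {
    stopifnot(!is.null(n), n >= 3)
    i <- seq_len(n)
    nxt <- c(seq_len(n)[-1], 1L)
    weighted_digraph(n, c(i, nxt), c(nxt, i), 1,
                     family = "ring", family_params = list(n = n))
  } else if (kind == "star") {
    stopifnot(!is.null(n), n >= 3)
    leaves <- 2:n
    weighted_digraph(n, c(rep(1L, n - 1), leaves), c(leaves, rep(1L, n - 1)), 1,
                     family = "star", family_params = list(n = n))
  } else if (kind == "bipartite") {
    stopifnot(!is.null(m), !is.null(n), m >= 1, n >= 1, m + n >= 2)
    if (m > n) stop("bipartite convention: the first part `m` is the smaller one")
    p1 <- seq_len(m)
    p2 <- m + seq_len(n)
    pairs <- expand.grid(a = p1, b = p2)
    weighted_digraph(m + n, c(pairs$a, pairs$b), c(pairs$b, pairs$a), 1,
                     family = "bipartite", family_params = list(m = m, n = n))
  } else { # fan
    stopifnot(!is.null(blades), blades >= 1)
    if (is.null(epsilon) || !is.numeric(epsilon) || epsilon <= 0 || epsilon >= 1)
      stop("fan requires `epsilon` in (0, 1)")
    nb <- as.integer(blades)
    leaves <- 1L + seq_len(2L * nb)
    first <- leaves[seq(1L, 2L * nb, by = 2L)]  # first leaf of each blade
    second <- first + 1L
    from <- c(rep(1L, 2L * nb), leaves, first, second)
    to <- c(leaves, rep(1L, 2L * nb), second, first)
    w <- c(rep(epsilon, 2L * nb), rep(1, 2L * nb), rep(1, 2L * nb))
    weighted_digraph(2L * nb + 1L, from, to, w, family = "fan",
                     family_params = list(blades = nb, epsilon = epsilon))
  }
}

#' Random strongly connected digraph (test-fixture generator)
#'
#' Starts from a random Hamiltonian cycle (which guarantees strong
#' connectivity), then adds each remaining ordered pair independently
#' with probability `arc_density`; optionally draws weights uniformly
#' from `(0, 1]`. Deterministic given `seed`.
#'
#' @param n Number of vertices (`>= 2`).
#' @param arc_density Probability in `(0, 1]` of including each ordered
#'   pair beyond the backbone cycle.
#' @param weighted If `TRUE`, arc weights are `runif(.)` in `(0, 1]`;
#'   otherwise all weights are 1.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A validated [weighted_digraph()].
#' @export
make_random_strongly_connected <- function(n, arc_density = 0.3,
                                           weighted = FALSE, seed) {
  stopifnot(n >= 2, arc_density > 0, arc_density <= 1)
  with_preserved_seed(seed, {
    perm <- sample.int(n)
    from <- perm
    to <- c(perm[-1], perm[1])
    extra <- which(matrix(TRUE, n, n) & !diag(n), arr.ind = TRUE)
    on_cycle <- paste(from, to) # mark backbone arcs
    cand <- paste(extra[, 1], extra[, 2])
    keep <- !(cand %in% on_cycle) & stats::runif(nrow(extra)) < arc_density
    from <- c(from, extra[keep, 1])
    to <- c(to, extra[keep, 2])
    w <- if (weighted) 1 - stats::runif(length(from)) else rep(1, length(from))
    weighted_digraph(as.integer(n), from, to, w)
  })
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Validate a population-structure graph
#'
#' Checks the invariants the Moran-process machinery relies on: no
#' self-loops, weights strictly in `(0, 1]`, strong connectivity through
#' positive-weight arcs, 1..N vertex-id contiguity, and no duplicate
#' arcs. Also reports whether the graph is symmetric-unweighted (every
#' arc mirrored, all weights 1), i.e. an ordinary undirected graph.
#'
#' @param g A [weighted_digraph()].
#' @return A list of logical diagnostics: `no_self_loops`,
#'   `weights_in_range`, `strongly_connected`, `ids_contiguous`,
#'   `no_duplicate_arcs`, `symmetric_unweighted`, and the conjunction
#'   `is_valid` (which does not include `symmetric_unweighted`).
#' @export
validate_graph <- function(g) {
  ids_ok <- length(g$from) > 0 &&
    all(g$from >= 1 & g$from <= g$n) && all(g$to >= 1 & g$to <= g$n) &&
    setequal(union(g$from, g$to), seq_len(g$n))
  no_loops <- all(g$from != g$to)
  w_ok <- all(is.finite(g$weight) & g$weight > 0 & g$weight <= 1)
  dup <- anyDuplicated(cbind(g$from, g$to)) > 0
  sc <- if (ids_ok && no_loops && !dup) {
    igraph::is_connected(as_igraph(g), mode = "strong")
  } else FALSE
  key <- paste(g$from, g$to)
  rkey <- paste(g$to, g$from)
  sym_unw <- !dup && all(rkey %in% key) && all(g$weight == 1)
  checks <- list(
    no_self_loops = no_loops,
    weights_in_range = w_ok,
    strongly_connected = sc,
    ids_contiguous = ids_ok,
    no_duplicate_arcs = !dup,
    symmetric_unweighted = sym_unw
  )
  checks$is_valid <- no_loops && w_ok && sc && ids_ok && !dup
  checks
}

assert_valid_graph <- function(g) {
  v <- validate_graph(g)
  if (!v$is_valid) {
    bad <- names(v)[!vapply(v, isTRUE, logical(1))]
    bad <- setdiff(bad, c("symmetric_unweighted", "is_valid"))
    stop("invalid graph: failed checks: ", paste(bad, collapse = ", "))
  }
  invisible(g)
}

#' Average out-degree
#'
#' The mean number of out-neighbors, `d = (number of positive-weight
#' arcs) / N`. This is the `d` entering the death-Birth amplification
#' bound [lemma1_bound()]; for weighted graphs arcs are counted, not
#' weight-summed.
#'
#' @param g A [weighted_digraph()].
#' @return A single number `d > 0`.
#' @examples
#' average_out_degree(make_family("star", n = 10)) # 18/10
#' @export
average_out_degree <- function(g) {
  length(g$from) / g$n
}

#' Read or write a graph as a TSV edge list
#'
#' Plain-text interchange format: comment lines start with `#`; a header
#' comment records the format version and vertex count; data lines are
#' `source<TAB>target<TAB>weight` with 0-based vertex ids and weights
#' printed to full precision (17 significant digits), so a write/read
#' round trip reproduces the graph exactly.
#'
#' @param path File path.
#' @param g A validated [weighted_digraph()] (write only).
#' @return `read_edge_list()` returns a validated [weighted_digraph()];
#'   `write_edge_list()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_edge_list(make_family("complete", n = 3), tf)
#' read_edge_list(tf)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  nv <- NA_integer_
  hdr <- grep("^#\\s*vertices:", lines, value = TRUE)
  if (length(hdr) > 0)
    nv <- as.integer(sub("^#\\s*vertices:\\s*", "", hdr[1]))
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no data lines in ", path)
  parse_line <- function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3)
      stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("line %d: non-numeric field", i))
    if (vals[1] != floor(vals[1]) || vals[2] != floor(vals[2]))
      stop(sprintf("line %d: non-integer vertex id", i))
    if (vals[1] == vals[2])
      stop(sprintf("line %d: self-loop (%d -> %d)", i, vals[1], vals[2]))
    if (vals[3] <= 0 || vals[3] > 1)
      stop(sprintf("line %d: weight %g outside (0, 1]", i, vals[3]))
    vals
  }
  m <- t(vapply(keep, parse_line, numeric(3)))
  ids <- sort(unique(c(m[, 1], m[, 2])))
  n <- if (is.na(nv)) max(ids) + 1L else nv
  if (!identical(as.numeric(ids), as.numeric(0:(n - 1))))
    stop("vertex ids are not contiguous 0..N-1")
  weighted_digraph(n, m[, 1] + 1L, m[, 2] + 1L, m[, 3])
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(g, path) {
  assert_valid_graph(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# moranamp edge list v1",
               sprintf("# vertices: %d", g$n),
               "# source\ttarget\tweight"), con)
  writeLines(sprintf("%d\t%d\t%.17g", g$from - 1L, g$to - 1L, g$weight), con)
  invisible(path)
}
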