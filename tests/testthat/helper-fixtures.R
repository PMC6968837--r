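# Shared fixtures and independent oracles for the test suite.

# The five named families at small size (total vertices <= 10), used for
# full-solver cross-checks.
small_families <- function() {
  list(complete = make_family("complete", n = 8),
       ring = make_family("ring", n = 8),
       star = make_family("star", n = 8),
       bipartite = make_family("bipartite", m = 3, n = 5),
       fan = make_family("fan", blades = 3, epsilon = 0.5))
}

# Brute-force reachability: can every vertex reach every other through
# positive-weight arcs? Independent of igraph (plain BFS on the arc list).
brute_force_strongly_connected <- function(g) {
  adj <- split(g$to, g$from)
  all(vapply(seq_len(g$n), function(s) {
    seen <- logical(g$n)
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- setdiff(unlist(adj[as.character(frontier)]), which(seen))
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    all(seen)
  }, logical(1)))
}

# Fixation probability of a birth-death chain by first-step enumeration:
# rho = 1 / (1 + sum_k prod_{i<=k} gamma_i). Used as an independent check
# of the gamma-product code path with directly hand-computed step
# probabilities.
bd_chain_fixation <- function(p_up, p_down) {
  1 / (1 + sum(cumprod(p_down / p_up)))
}
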