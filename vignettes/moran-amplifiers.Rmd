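---
title: "Fixation probabilities and the limits of amplification under death-Birth updating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation probabilities and the limits of amplification under death-Birth updating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranamp)
```

## The model

A population of `N` individuals occupies the vertices of a strongly
connected graph `G_N`; each directed arc `u -> v` carries a weight
`w[u,v]` in `(0, 1]` measuring how strongly `u` places offspring on `v`
(absence of an arc is weight 0; self-loops are excluded). One vertex,
chosen uniformly at random, initially hosts a mutant with relative
fitness `r > 0` (`r > 1` is the advantageous case of interest); all
other individuals are residents with fitness 1. The population then
evolves by discrete Moran steps until the mutant lineage either fixates
(occupies every vertex) or goes extinct. Strong connectivity guarantees
one of the two happens with probability 1.

Each step is one of two classical update rules:

* **Birth-death (Bd)**: an individual `u` reproduces with probability
  proportional to its fitness `f(u)`, and its offspring replaces an
  out-neighbor `v` chosen with probability proportional to `w[u,v]`.
* **death-Birth (dB)**: an individual `v` dies uniformly at random, and
  the in-neighbors `u` of `v` compete to fill the vacancy with
  probability proportional to `f(u) * w[u,v]`. The dying individual's
  own fitness plays no role.

The **mixed delta-dB process** performs a dB step with probability
`delta` and a Bd step otherwise, interpolating between pure Bd
(`delta = 0`) and pure dB (`delta = 1`). The central quantity is the
**fixation probability** `rho(G_N, r)` of the uniformly placed single
mutant. A graph **amplifies selection** at `(r, delta)` when its
fixation probability exceeds the well-mixed baseline, the complete graph
`K_N` at the same `N` and `r`.

On `K_N` the baselines are closed forms:
`rho_Bd = (1 - 1/r) / (1 - 1/r^N)` and
`rho_dB = (1 - 1/N) (1 - 1/r) / (1 - 1/r^(N-1))`; for mixed updating the
exact value has no simple closed form, so the conventional baseline is
the linear interpolation
`rho_hat = delta * rho_dB + (1 - delta) * rho_Bd`, which tracks the
exact value within about 1% (exactly at `N = 2` and at the endpoints).
The package provides both: `rho_hat_interpolation()` and the exact
count-chain value `rho_delta_complete_exact()`.

## Exact solvers

`fixation_exact()` builds the absorbing Markov chain over all `2^N`
mutant configurations (bitmask-encoded, bit `i` = vertex `i` mutant) and
solves the first-step system `x(S) = sum_T P(S -> T) x(T)` with
boundary values 0 and 1 at the two absorbing configurations. Because
both update rules change at most one vertex per step, the kernel is
assembled from two `2^N x N` matrices of per-vertex "flip"
probabilities, computed for all configurations at once by a handful of
matrix products with the weight matrix. The default state-space cap is
`N <= 14`.

The linear system is solved sparsely. Systems of up to 2048 transient
states go through a direct sparse LU factorization; beyond that the
hypercube adjacency causes severe LU fill-in, so the solver switches to
the fixed-point iteration `x <- Q x + b` started at `x = b`. For a
substochastic transient kernel this iteration increases monotonically to
the solution, with error decaying at the chain's absorption-tail rate;
it stops when successive sweeps differ by less than 1e-13 and falls back
to the direct factorization in the (unobserved) event that the residual
still exceeds 1e-10. Every result carries its verified max-norm
residual, typically below 1e-12.

`delta` is mixed at the kernel level — one mixed transition kernel, one
solve — rather than by combining two separate processes, so mixed
results are exact to solver precision.

### Symmetry-lumped chains

For the five named families the automorphism group makes whole orbits of
configurations equivalent, and `fixation_lumped()` solves the exact
orbit chain instead:

| family | orbit descriptor | states |
|---|---|---|
| complete `K_N` | mutant count `k` | `N + 1` |
| ring `R_N` | mutant-arc length `k` | `N + 1` |
| star `S_N` | (center occupant, mutant leaves) | `2N` |
| bipartite `B_{m,n}` | (mutants in part 1, part 2) | `(m+1)(n+1)` |
| fan `F_{B,eps}` | (center, #1-mutant blades, #2-mutant blades) | `(B+1)(B+2)` |

Rather than hand-deriving per-family transition algebra, the builder
evaluates the *same* exact kernel at one representative configuration
per orbit and maps successors by index arithmetic. Correctness rests on
two facts, both tested: orbit members are dynamically exchangeable
(verified by the full `2^N` solver on every family with at most 10
vertices, to 1e-10, over a grid of `r` and `delta`), and on the ring a
mutant set that starts as one contiguous arc stays one contiguous arc
under both update rules (only vertices at the arc boundary can flip;
asserted directly on one-step distributions). This reaches `N = 400`
routinely:

```{r star400}
fixation_lumped(make_family("star", n = 400), r = 2, delta = 0)
```

The leaf-start value approaches `1 - 1/r^2` while the center-start value
collapses toward 0 — the star is the canonical quadratic Bd amplifier —
and the population average sits near `1 - 1/r^2 = 0.75`.

### Monte Carlo

`estimate_fixation_mc()` simulates the verbatim update rules (a compiled
per-step loop) and reports a binomial estimate with standard error and a
95% Wilson score interval. One seeded sequential RNG stream drives each
batch, so batches are bit-reproducible given `(seed, replicates)`;
parallel substreams are deliberately out of scope. Simulation is the
route for large irregular graphs where neither the full nor a lumped
chain applies; exact routes take precedence everywhere else.

## The limits of dB amplification

The package exposes the amplification bounds as computable functions.
With `d` the average out-degree (arc count over `N` — for weighted
graphs we *count* positive-weight arcs; bound checks on weighted graphs
are reported as advisory, since the weighted reading of `d` is a
modeling choice):

* `lemma1_bound(d, r) = d r / (d r + d + r - 1)`: no graph's dB fixation
  probability exceeds it. Intuition: the initial mutant dies before
  reproducing often enough that even `r -> Inf` cannot push fixation to
  1.
* `theorem2_bound(r) = 1 - 1/(r + 1)`: the supremum of the above over
  `d` — dB amplification is *bounded*; no dB super amplifiers exist, and
  the implied scale of fitness never exceeds `r + 1`.
* `theorem1_threshold(n) = 2 n^2`: beyond this fitness, no non-complete
  graph amplifies under dB — all dB amplification is *transient*.
* `theorem4_bound(r, delta) = 1 - 1/((r/delta) + 1)`: the mixed-update
  analogue, coinciding with the dB bound at `delta = 1` and becoming
  vacuous as `delta -> 0` (pure Bd updating admits unbounded
  amplification). `delta = 0` is rejected rather than returning the
  uninformative 1.

`classify_amplifier()` compares a graph against the well-mixed baseline
and returns an amplifier/suppressor/neutral verdict;
`transient_threshold_scan()` locates the amplification range on a
fitness grid. Scans are grid-relative by design: a graph could in
principle alternate between amplifying and suppressing between grid
points, so the scan reports grid evidence, not a proof.

```{r star-verdicts}
classify_amplifier(make_family("star", n = 10), r = 2, delta = 0.2)$verdict
classify_amplifier(make_family("star", n = 10), r = 2, delta = 0.5)$verdict
```

The default mixed-update baseline is the interpolation `rho_hat` (the
convention in this literature). Near the ratio-1 contour its up-to-1%
error can matter, so `baseline = "exact-complete"` switches to the exact
count chain; both are exact at `delta` 0 or 1. The neutral verdict band
is `|ratio - 1| <= 1e-9`, the scale of accumulated solver residual —
exact ties (e.g. the ring under Bd, by the isothermal property) land
inside it, and any genuine amplification this small is below what the
solver can certify.

## Verification suites

Three properties anchor the test suite beyond spot values:

* **Neutrality**: at `r = 1` every structure gives fixation probability
  exactly `1/N`, for any `delta` — a strong whole-kernel invariant.
* **Exhaustive small-graph checks**: `all_connected_graphs(n)`
  enumerates the connected unweighted graphs up to isomorphism
  (1, 2, 6, 21, 112 classes for `n = 2..6`) by canonical-code filtering
  (minimum adjacency bitcode over all `n!` relabelings — affordable at
  these sizes and requiring no external canonical-labeling machinery).
  Every bound above is verified on all 142 graphs, and the transience
  threshold on every non-complete one, by exact solves.
* **Calibration**: Monte Carlo batches agree with exact values within
  3.5 standard errors, and 95% intervals cover the exact value in at
  least 90% of 200 seeded batches.

## Synthetic graphs and what the tests do and do not show

`make_random_strongly_connected()` is the package's random-structure
generator: a random Hamiltonian cycle (guaranteeing strong connectivity
by construction) plus independent extra arcs with probability
`arc_density`, optionally with uniform `(0,1]` weights. It emulates
arbitrary small directed population structures for bound verification;
it does not emulate degree-heterogeneous scale-free networks, spatial
lattices, or any empirical contact structure, so the randomized suites
certify the *universally quantified* claims (bounds, neutrality,
transience) on a broad sample of small digraphs rather than any
particular realistic topology. The named families are the structures
with scientific meaning here and are computed exactly.

## Numerical choices

* Closed forms are evaluated via geometric sums (`1 / sum(r^-k)`), which
  are algebraically identical to the textbook ratio forms, stable for
  all `r > 0`, and yield the `1/N` limit at `r = 1` with no special
  case.
* Problem sizes in tests: full solves up to `N = 12`, lumped chains up
  to `N = 400` (star) and 8001 states (bipartite), Monte Carlo batches
  of 2000–30000 replicates. These sizes make every suite exact or
  well-powered while keeping a full run in minutes on one core.
* The Fig-style interpolation grid is `N in {2, 5, 10, 20}`,
  `r in {1.25, 2, 4}`, `delta in {0, 0.1, ..., 1}`, declared in output
  metadata.
* Bipartite family grids default to smaller part `ceiling(sqrt(N))`
  (e.g. `B_{10,90}` at `N = 100`), the parameterization under which
  bipartite graphs behave as strong but delta-robust amplifiers;
  configurable.
* Step cap in simulation (default 1e9) raises an explicit error instead
  of silently truncating: absorption is almost sure, so hitting the cap
  means something is wrong.

## Known limitations

* Exact full solves stop at `N = 14` (16384 configurations); only the
  five named families are lumped — there is no automatic orbit detection
  for arbitrary graphs.
* Fixation *times* are not computed (only per-trajectory step counts in
  simulation); no mutation–selection dynamics with recurrent mutation.
* Asymptotic family classification (super/quadratic/linear amplifier
  labels as `N -> Inf` limit statements) is out of scope; the package
  computes finite-`N` implied-scale-of-fitness curves instead.
* The fan family at extreme parameters (hundreds of blades,
  `epsilon ~ 1e-5`) is supported by the lumped solver but treated as
  exploratory: no pinned reference values exist at those sizes.
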