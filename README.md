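# moranamp

Fixation probabilities and amplifiers of natural selection for the Moran
process on graphs, in R.

## The problem

When a single mutant with relative fitness *r* invades a structured
population of *N* residents, its fate depends not only on *r* but on the
population structure, modeled as a strongly connected graph whose
weighted arcs `w(u,v) ∈ (0,1]` say how strongly the individual at *u*
places offspring on *v*. The key quantity is the **fixation
probability** ρ(G_N, r) — the chance the mutant lineage takes over the
whole graph rather than dying out. Structures whose ρ beats the
well-mixed baseline (the complete graph K_N) **amplify selection**.

Whether amplifiers exist depends on the update rule:

- **Birth-death (Bd)**: reproduce first (proportional to fitness
  *f(u)*), offspring replaces a random out-neighbor (∝ `w(u,v)`).
  Amplifiers abound — the star graph effectively squares the mutant's
  fitness.
- **death-Birth (dB)**: a uniformly random individual dies first,
  in-neighbors compete to fill the vacancy (∝ `f(u)·w(u,v)`). Here
  amplification is fundamentally limited: for any graph with average
  out-degree *d*,

  ```
  ρ_dB(G_N, r) ≤ d·r / (d·r + d + r − 1) ≤ 1 − 1/(r+1)
  ```

  (bounded amplification), and beyond r\* = 2N² no non-complete graph
  amplifies at all (transient amplification).
- **δ-dB**: each step is dB with probability δ, Bd otherwise. For any
  δ > 0, ρ^δ ≤ 1 − 1/((r/δ)+1): at most linear amplification.

The well-mixed baselines are `ρ_Bd(K_N, r) = (1 − 1/r)/(1 − 1/r^N)`,
`ρ_dB(K_N, r) = (1 − 1/N)(1 − 1/r)/(1 − 1/r^(N−1))`, and for mixed
updating the linear interpolation ρ̂^δ = δ·ρ_dB + (1 − δ)·ρ_Bd (within
~1% of the exact K_N value, which the package also computes exactly via
the mutant-count birth–death chain).

The package is for researchers in evolutionary graph theory /
population genetics who need exact or simulated fixation probabilities
on arbitrary small graphs and on the classical families (Complete,
Ring, Star, Complete Bipartite, weighted Fan) at large N, plus the
bounds and classification machinery above.

## What it computes

- `fixation_exact()` — exact solve of the full `2^N`-configuration
  absorbing Markov chain (N ≤ 14), any graph, any (r, δ); per-starting-
  vertex values and verified solver residual.
- `fixation_lumped()` — exact symmetry-reduced chains for the five named
  families (e.g. 2N states for the star instead of 2^N), practical at
  N = 400 and beyond.
- `rho_complete_closed()`, `rho_hat_interpolation()`,
  `rho_delta_complete_exact()` — well-mixed baselines.
- `estimate_fixation_mc()` — seeded, bit-reproducible Monte Carlo with
  Wilson 95% intervals (compiled inner loop).
- `lemma1_bound()`, `theorem2_bound()`, `theorem4_bound()`,
  `theorem1_threshold()`, `implied_scale_of_fitness()`,
  `classify_amplifier()`, `transient_threshold_scan()`,
  `compare_bd_db()`, `all_connected_graphs()` — amplification theory and
  exhaustive verification suites.
- `run_delta_grid()`, `run_interpolation_check()`, `run_isf_curves()` —
  reproducible experiment tables (annotated TSV).

## Worked example

The star graph on 10 vertices at r = 2 amplifies under mostly-Bd mixed
updating but suppresses once half the steps are dB:

```r
library(moranamp)
s10 <- make_family("star", n = 10)

fixation_exact(s10, r = 2, delta = 0.2)
#> Fixation probability (full-solve) on star (N=10)
#>   r = 2, delta = 0.2
#>   average rho = 0.4942077278
#>   solver residual = 1.89e-15

rho_hat_interpolation(10, 2, 0.2)   # well-mixed baseline: 0.4905671
```

0.4942 > 0.4906: the star is a δ-dB amplifier at δ = 0.2. At δ = 0.5
the verdict flips:

```r
classify_amplifier(s10, r = 2, delta = 0.5)
#> Amplification report: star (N=10) at r = 2, delta = 0.5
#>   rho = 0.3656636 (lumped), baseline = 0.47568469 (interpolation)
#>   ratio = 0.76871004 -> suppressor; isf = 1.57645
```

At large N under pure Bd updating the star's average fixation
probability approaches 1 − 1/r² (fitness effectively squared):

```r
fixation_lumped(make_family("star", n = 400), r = 2, delta = 0)
#> Fixation probability (lumped) on star (N=400)
#>   r = 2, delta = 0
#>   average rho = 0.747198025
#>   solver residual = 1.11e-16
```

Monte Carlo agrees with the exact value to within its standard error:

```r
estimate_fixation_mc(s10, r = 2, delta = 0.2, replicates = 100000, seed = 42)
#> Monte Carlo fixation estimate on star (N=10)
#>   r = 2, delta = 0.2, replicates = 100000, seed = 42
#>   estimate = 0.49357 (SE 0.00158), 95% CI [0.490472, 0.496669]
```

A thin command-line interface over the same functions ships at
`system.file("cli", "moranamp", package = "moranamp")` with subcommands
`generate`, `exact`, `mc`, `bounds`, `classify`, `scan`, `grid`,
`interp-check`, `isf`.

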