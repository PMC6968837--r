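#' Simulate one delta-dB Moran trajectory
#'
#' Repeats single update steps (a Bernoulli(`delta`) choice of dB vs Bd,
#' then the corresponding sampling) from a single starting mutant until
#' the mutant set is empty or full. Uses R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @inheritParams step_distribution
#' @param start Starting mutant vertex (1-based).
#' @param step_cap Abort (with an error) if absorption has not occurred
#'   after this many steps; absorption is almost-surely certain on valid
#'   inputs, so a breach signals a bug rather than slow mixing.
#' @return A list with `fixated` (logical) and `steps` (integer).
#' @examples
#' set.seed(1)
#' simulate_trajectory(make_family("complete", n = 4), r = 2, delta = 1,
#'                     start = 1)
#' @export
simulate_trajectory <- function(g, r, delta = 1, start, step_cap = 1e9) {
  check_params(r, delta)
  assert_valid_graph(g)
  stopifnot(start >= 1, start <= g$n)
  out <- cpp_simulate_trajectory(weight_matrix(g), r, delta,
                                 as.integer(start), step_cap)
  list(fixated = out[1] == 1L, steps = out[2])
}

#' Monte Carlo estimate of the fixation probability
#'
#' Runs independent seeded trajectories (by default each starting from a
#' uniformly random vertex, the single-invader convention) and aggregates
#' them into a binomial estimate with standard error and a 95% Wilson
#' score interval.
#'
#' @inheritParams simulate_trajectory
#' @param replicates Number of trajectories (`>= 1`).
#' @param seed Integer seed; the batch is bit-reproducible given the
#'   seed (a single sequential RNG stream). The caller's RNG state is
#'   preserved. If `NULL`, the current RNG stream is used.
#' @param start `"uniform"` or a fixed starting vertex id.
#' @return A `simulation_batch`: replicate and fixation counts, point
#'   `estimate`, binomial `std_error`, 95% score `conf_int`, the
#'   extinct-on-first-step count, and a parameter echo.
#' @examples
#' estimate_fixation_mc(make_family("complete", n = 6), r = 2, delta = 0.5,
#'                      replicates = 2000, seed = 42)
#' @export
estimate_fixation_mc <- function(g, r, delta = 1, replicates, seed = NULL,
                                 start = "uniform", step_cap = 1e9) {
  check_params(r, delta)
  assert_valid_graph(g)
  stopifnot(replicates >= 1)
  run <- function() {
    starts <- if (identical(start, "uniform"))
      sample.int(g$n, replicates, replace = TRUE)
    else rep(as.integer(start), replicates)
    cpp_simulate_batch(weight_matrix(g), r, delta, starts, step_cap)
  }
  out <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  fixations <- out[1]
  est <- fixations / replicates
  se <- sqrt(est * (1 - est) / replicates)
  ci <- wilson_interval(fixations, replicates)
  structure(list(replicates = as.integer(replicates),
                 fixations = as.integer(fixations),
                 estimate = est, std_error = se, conf_int = ci,
                 extinct_step1 = as.integer(out[3]),
                 mean_steps = out[2] / replicates,
                 r = r, delta = delta, seed = seed, start = start,
                 graph = graph_label(g)),
            class = "simulation_batch")
}

# 95% Wilson score interval for a binomial proportion; always inside [0,1]
# and non-degenerate at 0 or n successes (unlike the Wald interval).
wilson_interval <- function(x, n, z = stats::qnorm(0.975)) {
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' @export
print.simulation_batch <- function(x, ...) {
  cat(sprintf("Monte Carlo fixation estimate on %s\n", x$graph))
  cat(sprintf("  r = %g, delta = %g, replicates = %d%s\n", x$r, x$delta,
              x$replicates,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  cat(sprintf("  estimate = %.6g (SE %.3g), 95%% CI [%.6g, %.6g]\n",
              x$estimate, x$std_error, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}
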