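test_that("one-step distribution on K_2 matches hand-computed rows", {
  g <- make_family("complete", n = 2)
  # pure dB: the dying vertex is uniform, the sole neighbor fills
  d1 <- step_distribution(g, state = 1, r = 2, delta = 1)
  expect_equal(d1$prob[d1$state == 0], 1 / 2)
  expect_equal(d1$prob[d1$state == 3], 1 / 2)
  # pure Bd: reproducer proportional to fitness 2:1
  d0 <- step_distribution(g, state = 1, r = 2, delta = 0)
  expect_equal(d0$prob[d0$state == 3], 2 / 3)
  expect_equal(d0$prob[d0$state == 0], 1 / 3)
  # mixture is the convex combination of the two rows
  dm <- step_distribution(g, state = 1, r = 2, delta = 0.5)
  expect_equal(dm$prob[dm$state == 3], 7 / 12)
  expect_equal(dm$prob[dm$state == 0], 5 / 12)
})

test_that("one-step distributions are stochastic on assorted graphs", {
  set.seed(42)
  graphs <- c(small_families(),
              lapply(1:5, function(s)
                make_random_strongly_connected(6, 0.4, weighted = TRUE,
                                               seed = s)))
  for (g in graphs) {
    for (state in sample(0:(2^g$n - 1), 8)) {
      for (delta in c(0, 0.3, 1)) {
        d <- step_distribution(g, state, r = 1.7, delta = delta)
        expect_equal(sum(d$prob), 1, tolerance = 1e-12)
        expect_true(all(d$prob > 0))
        expect_false(anyDuplicated(d$state) > 0)  # successors merged
      }
    }
  }
})

test_that("closed forms evaluate Eq-style fractions and their r = 1 limits", {
  expect_equal(rho_complete_closed(10, 2, "Bd"), 512 / 1023)
  expect_equal(rho_complete_closed(10, 2, "dB"), 0.45 * 512 / 511)
  # dB at N = 2 cancels the r-dependence
  for (r in c(0.5, 1, 2, 7, 100))
    expect_equal(rho_complete_closed(2, r, "dB"), 0.5)
  # r = 1 analytic limit 1/n, both updates, stable nearby
  for (n in c(2, 5, 10, 400)) {
    expect_equal(rho_complete_closed(n, 1, "Bd"), 1 / n)
    expect_equal(rho_complete_closed(n, 1, "dB"), 1 / n)
    expect_equal(rho_complete_closed(n, 1 + 1e-12, "Bd"), 1 / n,
                 tolerance = 1e-9)
  }
})

test_that("full solver reproduces closed forms and the gamma-product chain on K_n", {
  for (n in c(2, 4, 8, 12)) {
    g <- make_family("complete", n = n)
    expect_equal(fixation_exact(g, 2, delta = 0)$average,
                 rho_complete_closed(n, 2, "Bd"), tolerance = 1e-10)
    expect_equal(fixation_exact(g, 2, delta = 1)$average,
                 rho_complete_closed(n, 2, "dB"), tolerance = 1e-10)
    for (d in c(0.25, 0.5, 0.75))
      expect_equal(fixation_exact(g, 2, delta = d)$average,
                   rho_delta_complete_exact(n, 2, d), tolerance = 1e-10)
  }
})

test_that("K_2 fixation under dB is exactly 1/2 regardless of fitness", {
  g <- make_family("complete", n = 2)
  expect_equal(fixation_exact(g, 7, delta = 1)$average, 0.5)
})

test_that("neutral mutants fixate with probability 1/N on every structure", {
  set.seed(7)
  graphs <- c(small_families(),
              lapply(1:5, function(s)
                make_random_strongly_connected(7, 0.35, weighted = TRUE,
                                               seed = s)))
  for (g in graphs)
    for (d in c(0, 0.5, 1))
      expect_equal(fixation_exact(g, 1, d)$average, 1 / g$n,
                   tolerance = 1e-10)
})

test_that("extinction and fixation probabilities are complementary", {
  # independent dense solve assembled from step_distribution rows: solve
  # for fixation AND extinction separately; they must sum to 1, and the
  # fixation column must match the sparse solver.
  g <- make_family("star", n = 6)
  S <- 2^g$n
  P <- matrix(0, S, S)
  for (s in 0:(S - 1)) {
    d <- step_distribution(g, s, r = 2, delta = 0.3)
    P[s + 1, d$state + 1] <- d$prob
  }
  trans <- 2:(S - 1)
  A <- diag(S - 2) - P[trans, trans]
  x_fix <- solve(A, P[trans, S])
  x_ext <- solve(A, P[trans, 1])
  expect_equal(x_fix + x_ext, rep(1, S - 2), tolerance = 1e-10)
  res <- fixation_exact(g, 2, 0.3)
  expect_equal(x_fix[2^(0:(g$n - 1))], res$per_start, tolerance = 1e-10)
})

test_that("fixation probability is nondecreasing in r and bounded in [0,1]", {
  for (g in list(make_family("complete", n = 8), make_family("star", n = 8),
                 make_family("ring", n = 8))) {
    for (d in c(0, 0.5, 1)) {
      rhos <- vapply(c(1, 1.5, 2, 4, 10),
                     function(r) fixation_exact(g, r, d)$average, numeric(1))
      expect_true(all(diff(rhos) >= -1e-12))
      expect_true(all(rhos >= 0 & rhos <= 1))
    }
  }
})

test_that("solver residuals are reported and tiny", {
  res <- fixation_exact(make_family("star", n = 10), 2, 0.2)
  expect_lt(res$residual, 1e-10)
  expect_identical(res$method, "full-solve")
  expect_equal(res$average, mean(res$per_start))
})

test_that("state-space guard directs oversized graphs elsewhere", {
  g <- make_family("complete", n = 15)
  expect_error(fixation_exact(g, 2, 1), "max_n")
})

test_that("gamma-product chain matches endpoints and hand-built count chain", {
  for (n in c(2, 5, 10, 50)) for (r in c(1.3, 2, 5)) {
    expect_equal(rho_delta_complete_exact(n, r, 0),
                 rho_complete_closed(n, r, "Bd"), tolerance = 1e-12)
    expect_equal(rho_delta_complete_exact(n, r, 1),
                 rho_complete_closed(n, r, "dB"), tolerance = 1e-12)
  }
  # N = 2: the interpolation is exact for every delta
  for (r in c(1.2, 2, 6)) for (d in c(0.1, 0.5, 0.9))
    expect_equal(rho_delta_complete_exact(2, r, d),
                 rho_hat_interpolation(2, r, d), tolerance = 1e-12)
  # independent oracle: hand-computed dB count-chain steps on K_4, r = 3.
  # With k mutants: die uniform 1/4; filler competes by fitness among the
  # other 3 vertices.
  n <- 4; r <- 3
  k <- 1:3
  p_up <- (n - k) / n * (r * k) / (r * k + n - 1 - k)
  p_down <- k / n * (n - k) / (r * (k - 1) + n - k)
  expect_equal(rho_delta_complete_exact(4, 3, 1),
               bd_chain_fixation(p_up, p_down), tolerance = 1e-14)
})
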