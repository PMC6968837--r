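test_that("bound formulas evaluate correctly, including limits", {
  expect_equal(lemma1_bound(1.8, 2), 0.5625)          # star S_10 at r = 2
  expect_equal(lemma1_bound(4, 1e12), 4 / 5, tolerance = 1e-10)
  expect_equal(lemma1_bound(1e12, 2), 2 / 3, tolerance = 1e-10)
  expect_equal(theorem2_bound(2), 2 / 3)
  expect_equal(theorem2_bound(1), 1 / 2)
  expect_equal(theorem4_bound(2, 1), theorem2_bound(2))
  expect_equal(theorem4_bound(2, 0.5), 0.8)
  expect_gt(theorem4_bound(2, 1e-9), 1 - 1e-8)        # vacuous as delta -> 0
  expect_error(theorem4_bound(2, 0), "vacuous")
  expect_equal(theorem1_threshold(10), 200)
  expect_equal(theorem1_threshold(2), 8)
  # the Lemma 1 fraction never exceeds the d -> Inf envelope
  for (d in c(0.5, 2, 7)) for (r in c(1.1, 2, 50))
    expect_lte(lemma1_bound(d, r), theorem2_bound(r))
})

test_that("implied scale of fitness inverts the fixation probability", {
  expect_equal(implied_scale_of_fitness(0.5), 2)
  expect_equal(implied_scale_of_fitness(0), 1)
  expect_identical(implied_scale_of_fitness(1), Inf)
  expect_error(implied_scale_of_fitness(1.2))
  # complete graphs: isf ~ r at large N, both updates
  expect_equal(implied_scale_of_fitness(rho_complete_closed(400, 2, "Bd")), 2,
               tolerance = 0.01)
  expect_equal(implied_scale_of_fitness(rho_complete_closed(400, 2, "dB")), 2,
               tolerance = 0.01)
  # Bd stars are quadratic amplifiers: isf ~ r^2
  rho <- fixation_lumped(make_family("star", n = 400), 2, 0)$average
  expect_equal(implied_scale_of_fitness(rho), 4, tolerance = 0.05)
})

test_that("exhaustive small-graph enumeration hits the known class counts", {
  counts <- vapply(2:6, function(n) length(all_connected_graphs(n)),
                   numeric(1))
  expect_equal(counts, c(1, 2, 6, 21, 112))
  suite <- all_connected_graphs(5)
  for (g in suite) {
    v <- validate_graph(g)
    expect_true(v$is_valid && v$symmetric_unweighted)
  }
  # no two representatives are isomorphic (igraph as independent check)
  igs <- lapply(suite, moranamp:::as_igraph)
  for (i in seq_along(igs)) for (j in seq_len(i - 1)) {
    if (length(suite[[i]]$from) != length(suite[[j]]$from)) next
    expect_false(igraph::isomorphic(igs[[i]], igs[[j]],
                                    method = "direct"))
  }
})

test_that("exact dB fixation respects Lemma 1 and the boundedness cap", {
  suite <- c(unlist(lapply(2:5, all_connected_graphs), recursive = FALSE),
             lapply(1:40, function(s)
               make_random_strongly_connected(4 + (s %% 5), 0.35,
                                              weighted = FALSE, seed = s)))
  for (g in suite) {
    d <- average_out_degree(g)
    for (r in c(1.5, 2, 10)) {
      rho <- fixation_exact(g, r, 1)$average
      expect_lte(rho, lemma1_bound(d, r) + 1e-12)
      expect_lte(lemma1_bound(d, r), theorem2_bound(r))
      for (dd in c(0.25, 0.5))
        expect_lte(fixation_exact(g, r, dd)$average,
                   theorem4_bound(r, dd) + 1e-12)
    }
  }
})

test_that("no non-complete small graph amplifies beyond r* = 2N^2", {
  suite <- unlist(lapply(2:5, all_connected_graphs), recursive = FALSE)
  for (g in suite) {
    if (moranamp:::is_complete_graph(g)) next
    rstar <- theorem1_threshold(g$n)
    expect_lt(fixation_exact(g, rstar, 1)$average,
              rho_complete_closed(g$n, rstar, "dB"))
  }
})

test_that("amplifier classification reproduces the known star/ring verdicts", {
  s10 <- make_family("star", n = 10)
  expect_identical(classify_amplifier(s10, 2, 0.2)$verdict, "amplifier")
  expect_identical(classify_amplifier(s10, 2, 0.5)$verdict, "suppressor")
  expect_identical(classify_amplifier(make_family("ring", n = 10), 2, 0)$verdict,
                   "neutral-within-tolerance")
  # the complete graph against its own exact baseline is neutral exactly
  for (r in c(1.5, 3)) for (d in c(0.2, 0.7))
    expect_identical(
      classify_amplifier(make_family("complete", n = 7), r, d,
                         baseline = "exact-complete")$verdict,
      "neutral-within-tolerance")
  # Monte Carlo route gives a CI-aware verdict
  rep_mc <- classify_amplifier(s10, 4, 0, method = "mc", replicates = 20000,
                               seed = 2)
  expect_identical(rep_mc$verdict, "amplifier")
  expect_identical(rep_mc$method, "monte-carlo")
})

test_that("bound reports flag satisfied bounds on exact solves", {
  br <- bound_report(make_family("star", n = 10), 2, 1)
  expect_equal(br$d, 1.8)
  expect_equal(br$lemma1, 0.5625)
  expect_true(br$satisfied$lemma1)
  expect_true(br$satisfied$theorem2)
  expect_true(br$satisfied$theorem4)
  expect_equal(br$r_star, 200)
  br0 <- bound_report(make_family("star", n = 10), 2, 0)
  expect_true(is.na(br0$satisfied$lemma1))
})

test_that("threshold scan: the star is a universal Bd but transient dB amplifier", {
  s8 <- make_family("star", n = 8)
  # Bd: amplifies at every grid point
  scan_bd <- transient_threshold_scan(s8, delta = 0,
                                      r_grid = c(1.1, 2, 5, 10, 20))
  expect_true(all(scan_bd$table$amplifies))
  expect_true(is.na(scan_bd$first_non_amplifying_tail))
  # delta = 0.5: not amplifying at r = 2
  scan_mix <- transient_threshold_scan(s8, delta = 0.5, r_grid = c(1.5, 2, 4))
  expect_false(scan_mix$table$amplifies[scan_mix$table$r == 2])
  # dB: grid ending at 2N^2 finishes non-amplifying
  scan_db <- transient_threshold_scan(s8, delta = 1,
                                      r_grid = c(1.5, 2, theorem1_threshold(8)))
  expect_false(scan_db$table$amplifies[nrow(scan_db$table)])
  expect_true(scan_db$grid_relative)
})

test_that("Bd beats dB for every structure once fitness is large", {
  expect_equal(unlist(compare_bd_db(make_family("complete", n = 10), 2)[1:2]),
               c(rho_bd = 0.5004888, rho_db = 0.4508806), tolerance = 1e-6)
  set.seed(3)
  for (s in 1:10) {
    g <- make_random_strongly_connected(6, 0.4, weighted = FALSE, seed = s)
    cmp <- compare_bd_db(g, theorem1_threshold(g$n))
    expect_true(cmp$bd_larger)
  }
  # at r = 1 both are 1/N
  cmp1 <- compare_bd_db(make_family("star", n = 9), 1)
  expect_equal(cmp1$rho_bd, 1 / 9, tolerance = 1e-10)
  expect_equal(cmp1$rho_db, 1 / 9, tolerance = 1e-10)
})
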