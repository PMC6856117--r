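test_that("genome architecture validates the cabal-minority constraint", {
  g <- genome_architecture(1e6, 0.5, 1e-11, 1e-11)
  expect_equal(distorter_interval(g), 1 / (0.5e6 * 1e-11))
  expect_equal(suppressor_lag(g), 1 / (0.5e6 * 1e-11))
  expect_error(genome_architecture(1e6, 0.6, 1e-11, 1e-11), "majority")
  expect_error(genome_architecture(1e6, 0.3, 0, 1e-11), "\\(0, 1\\)")
})

test_that("closed-form average distortion is piecewise in the threshold", {
  tr <- fig4_response()  # t = k, c_trait = k/2
  g <- genome_architecture(1e6, 0.1, 1e-11, 1e-11)
  # suppressed regime: k theta rho_D / ((1 - theta) rho_S)
  expect_equal(average_distortion_approx(g, tr, 0.1, 0.6), 0.6 * 0.1 / 0.9)
  # below the suppression threshold (c_trait(k) < c_sup) the average is k
  expect_equal(average_distortion_approx(g, tr, 0.1, 0.15), 0.15)
})

test_that("average distortion vanishes as the cabal shrinks", {
  tr <- fig4_response()
  prev <- Inf
  for (th in c(1e-3, 1e-5, 1e-7)) {
    g <- genome_architecture(1e10, th, 1e-11, 1e-11)
    v <- average_distortion_approx(g, tr, 0.1, 0.6)
    expect_lt(v, prev)
    prev <- v
  }
  expect_lt(prev, 1e-6)
})

test_that("genome size and baseline mutation rate cancel out", {
  tr <- fig4_response()
  base <- genome_architecture(1e6, 0.3, 1e-11, 1e-11)
  v0 <- average_distortion_approx(base, tr, 0.1, 0.6)
  # doubling gamma, rho, or both introduction probabilities jointly
  expect_equal(average_distortion_approx(
    genome_architecture(2e6, 0.3, 1e-11, 1e-11), tr, 0.1, 0.6), v0,
    tolerance = 1e-12)
  expect_equal(average_distortion_approx(
    genome_architecture(1e6, 0.3, 1e-11, 1e-11, rho = 2), tr, 0.1, 0.6), v0,
    tolerance = 1e-12)
  expect_equal(average_distortion_approx(
    genome_architecture(1e6, 0.3, 2e-11, 2e-11), tr, 0.1, 0.6), v0,
    tolerance = 1e-12)
  # and for the exact numerical cycle, up to the integer-generation lag
  g1 <- genome_architecture(1e6, 0.3, 1e-9, 1e-9)
  g2 <- genome_architecture(2e6, 0.3, 1e-9, 1e-9, rho = 0.5)
  c1 <- suppressWarnings(
    cycle_exact(g1, tr, conflict_params(0.1, 0.6), 0.6, keep_series = FALSE))
  c2 <- suppressWarnings(
    cycle_exact(g2, tr, conflict_params(0.1, 0.6), 0.6, keep_series = FALSE))
  expect_equal(c1$evo_average, c2$evo_average, tolerance = 1e-10)
})

test_that("the exact cycle ranges between a peak of k and a trough of 0", {
  tr <- fig4_response()
  g <- genome_architecture(1e6, 0.5, 1e-11, 1e-11)
  cyc <- suppressWarnings(cycle_exact(g, tr, conflict_params(0.1, 0.6), 0.6))
  expect_equal(cyc$peak, 0.6, tolerance = 1e-3)
  expect_lt(cyc$trough, 1e-6)
  expect_true(all(cyc$series >= 0 & cyc$series <= 0.6 + 1e-12))
  expect_equal(cyc$lag, round(suppressor_lag(g)))
  expect_gt(cyc$purge_generation, cyc$lag)
  # below the suppression threshold there is no suppression phase
  cyc2 <- cycle_exact(g, tr, conflict_params(0.1, 0.15), 0.15)
  expect_false(cyc2$suppressed)
  expect_equal(cyc2$evo_average, 0.15)
})

test_that("exact cycle averages track the closed form within 25 percent", {
  tr <- fig4_response()
  for (th in c(0.1, 0.3, 0.5)) {
    for (k in seq(0.3, 0.9, by = 0.2)) {
      g <- genome_architecture(1e6, th, 1e-9, 1e-9)
      exact <- suppressWarnings(
        cycle_exact(g, tr, conflict_params(0.1, k), k, keep_series = FALSE))
      approx <- average_distortion_approx(g, tr, 0.1, k)
      expect_lt(abs(exact$evo_average - approx) / approx, 0.25,
                label = sprintf("theta=%.1f k=%.1f", th, k))
    }
  }
})

test_that("the separation-of-timescales error shrinks as rates are scaled down", {
  tr <- fig4_response()
  rel <- vapply(c(1e-8, 1e-9, 1e-10), function(r) {
    g <- genome_architecture(1e6, 0.3, r, r)
    exact <- suppressWarnings(
      cycle_exact(g, tr, conflict_params(0.1, 0.6), 0.6, keep_series = FALSE))
    approx <- average_distortion_approx(g, tr, 0.1, 0.6)
    abs(exact$evo_average - approx) / approx
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
})

test_that("distortion surface is monotone in k and ordered in theta", {
  tr <- fig4_response()
  g <- genome_architecture(1e6, 0.1, 1e-9, 1e-9)
  surf <- distortion_surface(g, tr, 0.1, seq(0.1, 0.9, by = 0.1),
                             c(0.1, 0.3, 0.5), method = "approx")
  # within each regime the average rises with k (it drops discontinuously
  # at the suppression threshold itself)
  for (th in c(0.1, 0.3, 0.5)) for (rg in c("unsuppressed", "suppressed")) {
    v <- surf$average_distortion[surf$theta == th & surf$regime == rg]
    expect_true(all(diff(v) >= 0))
  }
  # suppressed regime: smaller cabals give lower averages and flatter slopes
  sup <- surf[surf$regime == "suppressed", ]
  v1 <- sup$average_distortion[sup$theta == 0.1]
  v5 <- sup$average_distortion[sup$theta == 0.5]
  expect_true(all(v1 < v5))
  expect_lt(diff(range(v1)), diff(range(v5)))
  # below the threshold theta has no effect
  uns <- surf[surf$regime == "unsuppressed", ]
  for (k in unique(uns$k))
    expect_equal(length(unique(uns$average_distortion[uns$k == k])), 1L)
})
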