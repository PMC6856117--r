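test_that("single-locus recursion matches hand evaluation and fixed points", {
  tr <- trait_response(function(k) 0.6 + 0 * k, function(k) 0.3 + 0 * k)
  # wbar = 0.7 (0.0001 + 0.0198) + 0.9801; p' = 0.7 (0.0001 + 0.99*0.01*1.6)/wbar
  expect_equal(step_single_locus(0.01, tr, 0.5), 0.011225, tolerance = 1e-4)
  expect_equal(step_single_locus(0, tr, 0.5), 0)
  expect_equal(step_single_locus(1, tr, 0.5), 1)
  # neutral case: identity map
  trn <- power_response(0, 1, 0, 1)
  for (p in c(0.1, 0.5, 0.9)) expect_equal(step_single_locus(p, trn, 0.5), p)
})

test_that("fixation of an invading distorter is locally stable", {
  # derivative of the map at p = 1 below 1 wherever invasion holds
  k <- 0.5
  h <- 1e-7
  for (a in seq(0.1, 1, length.out = 8)) for (b in seq(0.1, 1, length.out = 8)) {
    tr <- power_response(a, 1, b, 1.5)
    if (!distorter_invades(tr, k)) next
    d <- (step_single_locus(1, tr, k) - step_single_locus(1 - h, tr, k)) / h
    expect_lt(d, 1)
  }
})

test_that("compiled single-locus iteration agrees with the R stepper", {
  tr <- fig1_response()
  p <- 1e-4
  res <- iterate_single_locus(p, tr, 0.3, n_gen = 50, record = TRUE)
  for (i in 1:50) p <- step_single_locus(p, tr, 0.3)
  expect_equal(res$p, p, tolerance = 1e-14)
  expect_length(res$series, 50)
})

test_that("two-locus stepper has the trivial equilibria", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.6)
  expect_equal(step_two_locus(c(1, 0, 0, 0), tr, params), c(1, 0, 0, 0))
  expect_equal(step_two_locus(c(0, 0, 1, 0), tr, params), c(0, 0, 1, 0))
})

test_that("two-locus stepper matches the mating-table oracle on random states", {
  tr <- fig1_response()
  set.seed(101)
  for (rep in 1:50) {
    k <- runif(1, 0.05, 0.95)
    cs <- runif(1, 0, 0.5)
    params <- conflict_params(cs, k)
    x <- random_state(4L)
    got <- step_two_locus(x, tr, params)
    want <- oracle_step_two_locus(x, tr$t(k), tr$c_trait(k), cs)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # specific derived case
  trc <- trait_response(function(k) 0.6 + 0 * k, function(k) 0.3 + 0 * k)
  x <- c(0.5, 0, 0.5, 0)
  got <- step_two_locus(x, trc, conflict_params(0.1, 0.5))
  expect_equal(got, oracle_step_two_locus(x, 0.6, 0.3, 0.1), tolerance = 1e-12)
})

test_that("obligate-mode stepper matches the oracle with constitutive costs", {
  tr <- fig1_response()
  set.seed(202)
  for (rep in 1:50) {
    k <- runif(1, 0.05, 0.95)
    cs <- runif(1, 0, 0.5)
    params <- conflict_params(cs, k, suppressor = "obligate")
    x <- random_state(4L)
    got <- step_two_locus(x, tr, params)
    want <- oracle_step_two_locus(x, tr$t(k), tr$c_trait(k), cs, obligate = TRUE)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("compiled two-locus iteration agrees with the R stepper", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.6)
  x <- c(0.0995, 5e-4, 0.8995, 5e-4)
  res <- iterate_two_locus(x, tr, params, tol = 0, max_gen = 100)
  for (i in 1:100) x <- step_two_locus(x, tr, params)
  expect_equal(res$state, x, tolerance = 1e-13)
})

test_that("stepper outputs are normalised and non-negative", {
  tr <- fig1_response()
  params <- conflict_params(0.2, 0.7)
  p6 <- conflict_params(0.2, 0.4, k_hat = 0.7)
  set.seed(303)
  for (rep in 1:25) {
    x4 <- step_two_locus(random_state(4L), tr, params)
    expect_equal(sum(x4), 1, tolerance = 1e-12)
    expect_true(all(x4 >= 0))
    x6 <- step_three_allele(random_state(6L), tr, p6)
    expect_equal(sum(x6), 1, tolerance = 1e-12)
    expect_true(all(x6 >= 0))
  }
})

test_that("the distorter-fixed Jacobian matches its closed-form eigenvalue", {
  tr <- fig1_response()
  for (cs in seq(0.05, 0.5, length.out = 10)) {
    for (k in seq(0.3, 0.95, length.out = 10)) {
      params <- conflict_params(cs, k)
      J <- suppressor_jacobian(tr, params)
      closed <- (1 - cs) / (1 - tr$c_trait(k))
      expect_equal(leading_eigenvalue(J), max(closed, 1 - tr$t(k)),
                   tolerance = 1e-10)
      expect_equal(attr(J, "leading_eigenvalue"), closed)
    }
  }
  # marginal stability when the two costs coincide: c_sup = c_trait(k)
  k <- 0.6
  cs <- tr$c_trait(k)
  expect_equal(attr(suppressor_jacobian(tr, conflict_params(cs, k)),
                    "leading_eigenvalue"), 1)
  # derived example: t = 0.522, c_trait = 0.4183, c_sup = 0.15
  J <- suppressor_jacobian(tr, conflict_params(0.15, 0.6))
  expect_equal(leading_eigenvalue(J), 0.85 / (1 - 0.9 * 0.6^1.5),
               tolerance = 1e-10)
})

test_that("the analytic Jacobian matches finite differences of the map", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.6)
  J <- suppressor_jacobian(tr, params)
  Jn <- numeric_jacobian(function(x) step_two_locus(x, tr, params, validate = FALSE),
                         c(0, 0, 1, 0))
  expect_equal(unname(J), unname(Jn), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("suppressor invasion by iteration occurs iff c_trait > c_sup", {
  set.seed(404)
  for (ct in seq(0.1, 0.6, by = 0.1)) for (cs in seq(0.05, 0.65, by = 0.15)) {
    if (abs(ct - cs) < 0.02) next  # knife edge
    tr <- trait_response(function(k) 0.5 + 0 * k, function(k) ct + 0 * k)
    params <- conflict_params(cs, 0.5)
    x0 <- c(0.0095, 5e-4, 0.9895, 5e-4)
    res <- iterate_two_locus(x0, tr, params, tol = 0, max_gen = 300)
    s_freq <- res$state[2] + res$state[4]
    expect_equal(s_freq > 1e-3, ct > cs,
                 info = sprintf("ct=%.2f cs=%.2f", ct, cs))
  }
})

test_that("facultative suppression purges the distorter; obligate retains it silenced", {
  tr <- fig1_response()
  x0 <- introduce_suppressor(0.9, 1e-3)
  fac <- iterate_two_locus(x0, tr, conflict_params(0.15, 0.6),
                           tol = 1e-12, max_gen = 1e7, record = TRUE)
  expect_true(fac$converged)
  expect_lt(fac$state[3] + fac$state[4], 1e-9)
  expect_equal(fac$state[1] + fac$state[2], 1, tolerance = 1e-9)
  # suppressor settles at an internal frequency
  s_int <- fac$state[2] + fac$state[4]
  expect_gt(s_int, 0)
  expect_lt(s_int, 1)
  ob <- iterate_two_locus(x0, tr,
                          conflict_params(0.15, 0.6, suppressor = "obligate"),
                          tol = 1e-12, max_gen = 1e7, record = TRUE)
  expect_true(ob$converged)
  expect_gt(ob$state[2] + ob$state[4], 1 - 1e-4)   # suppressor (near) fixation
  expect_gt(ob$state[3] + ob$state[4], 0.5)        # distorter retained ...
  expect_lt(tail(ob$distortion, 1), 1e-9)          # ... but silenced
})

test_that("starting at an equilibrium converges immediately", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.6)
  res <- iterate_to_equilibrium(c(1, 0, 0, 0),
                                function(x) step_two_locus(x, tr, params))
  expect_true(res$converged)
  expect_lte(res$generations, 1)
})

test_that("rarity thresholds do not change the purge outcome", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.6)
  for (s0 in c(1e-4, 1e-3)) {
    res <- iterate_two_locus(introduce_suppressor(0.9, s0), tr, params,
                             tol = 0, max_gen = 3e7, purge_tol = 1e-9)
    expect_true(res$purged, label = paste("s0 =", s0))
  }
  # at extreme rarity the non-distorter background underflows and the
  # suppressor fixes instead of equilibrating internally, but the expressed
  # distortion is driven out all the same
  res6 <- iterate_two_locus(introduce_suppressor(0.9, 1e-6), tr, params,
                            tol = 0, max_gen = 3e7, purge_tol = 1e-9,
                            dist_tol = 1e-9)
  expect_true(res6$purged)
  for (p0 in c(1e-4, 1e-6)) {
    g <- time_to_purge(tr, params, p0 = p0)
    expect_false(attr(g, "capped"), label = paste("p0 =", p0))
  }
})

test_that("stronger distorters are purged faster; flat costs purge slower", {
  tr <- fig1_response()
  ks <- c(0.35, 0.5, 0.7, 0.9)
  res <- lapply(ks, function(k) time_to_purge(tr, conflict_params(0.15, k)))
  # just above the threshold the purge outlasts the generation cap, which
  # the capped result reports at its face value
  gens <- vapply(res, as.numeric, numeric(1))
  expect_true(all(diff(gens) <= 0))
  expect_false(all(vapply(res, function(g) attr(g, "capped"), logical(1))))
  # a transmission bias that persists while the cost barely grows above the
  # suppression threshold prolongs the distorter's stay
  tr_flat  <- trait_response(function(k) 0.9 + 0 * k, function(k) 0.16 + 0.01 * k)
  tr_steep <- trait_response(function(k) 0.9 + 0 * k, function(k) 0.16 + 0.5 * k)
  g_flat  <- time_to_purge(tr_flat,  conflict_params(0.15, 0.5))
  g_steep <- time_to_purge(tr_steep, conflict_params(0.15, 0.5))
  expect_gt(as.numeric(g_flat), as.numeric(g_steep))
  # below the suppression threshold the distorter is never purged
  expect_error(time_to_purge(tr, conflict_params(0.15, 0.2)), "never purged")
})

test_that("six-gamete stepper matches the mating-table oracle on random states", {
  tr <- fig1_response()
  set.seed(505)
  for (rep in 1:50) {
    k <- runif(1, 0.05, 0.9)
    kh <- runif(1, 0.05, 0.9)
    if (abs(kh - k) < 1e-3) next
    cs <- runif(1, 0, 0.5)
    x <- random_state(6L)
    for (mode in c("dominant", "additive")) {
      params <- conflict_params(cs, k, k_hat = kh, dominance = mode)
      got <- step_three_allele(x, tr, params)
      want <- oracle_step_six(x, tr, k, kh, cs, dominance = mode)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  # fixed mutant is an equilibrium
  params <- conflict_params(0.15, 0.4, k_hat = 0.6)
  e5 <- c(0, 0, 0, 0, 1, 0)
  expect_equal(step_three_allele(e5, tr, params), e5)
})

test_that("mutant invasion criterion equals the six-gamete eigenvalue test", {
  tr <- fig1_response()
  cs <- 0.9  # keep the suppressor direction stable so the mutant leads
  x_star <- c(0, 0, 1, 0, 0, 0)
  for (k in c(0.1, 0.25, 0.4)) for (kh in c(0.15, 0.3, 0.5, 0.6)) {
    if (abs(kh - k) < 1e-6) next
    for (mode in c("dominant", "additive")) {
      params <- conflict_params(cs, k, k_hat = kh, dominance = mode)
      J <- numeric_jacobian(function(x) step_three_allele(x, tr, params,
                                                          validate = FALSE),
                            x_star)
      # growth of the rare mutant classes around the resident-fixed state
      lam <- leading_eigenvalue(J[5:6, 5:6, drop = FALSE])
      crit <- mutant_invades(tr, k, kh, mode = mode)
      if (abs(lam - 1) < 1e-6) next
      expect_equal(lam > 1, crit,
                   info = sprintf("mode=%s k=%.2f kh=%.2f", mode, k, kh))
    }
  }
})

test_that("post-invasion equilibria split by the suppression threshold", {
  tr <- fig1_response()
  # suppressor catches the sweep: all distorters purged, non-distorter fixes
  xA <- mutant_intro_state(0.9)
  pA <- conflict_params(0.15, 0.6, k_hat = 0.8)
  resA <- iterate_to_equilibrium(xA, function(x)
    step_three_allele(x, tr, pA, validate = FALSE), tol = 1e-12, max_gen = 5e5)
  expect_true(resA$converged)
  expect_lt(resA$state[3] + resA$state[4], 1e-9)
  expect_lt(resA$state[5] + resA$state[6], 1e-9)
  expect_equal(resA$state[1] + resA$state[2], 1, tolerance = 1e-9)
  # suppression too costly (c_sup > c_trait(k_hat)): the mutant sweeps
  xB <- mutant_intro_state(0.9)
  pB <- conflict_params(0.5, 0.1, k_hat = 0.25)
  resB <- iterate_to_equilibrium(xB, function(x)
    step_three_allele(x, tr, pB, validate = FALSE), tol = 1e-12, max_gen = 5e5)
  expect_true(resB$converged)
  expect_equal(resB$state[5], 1, tolerance = 1e-6)
})

test_that("adaptive walk climbs to k_target and stops", {
  tr <- fig1_response()
  params <- conflict_params(0.15, 0.05)
  kt <- k_target(tr)$k
  walk <- adaptive_walk(tr, params, k0 = 0.05, delta = 0.005)
  expect_true(all(diff(walk) > 0))
  final <- walk[length(walk)]
  expect_gte(final, kt - 0.005)
  expect_lte(final, kt + 0.005)
  # large steps can overshoot the target
  big <- adaptive_walk(tr, params, k0 = 0.05, delta = 0.3)
  expect_gt(big[length(big)], kt)
  # no transmission benefit: the walk never leaves 0
  expect_equal(adaptive_walk(power_response(0, 1, 0.5, 1.5), params, k0 = 0),
               0)
})
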