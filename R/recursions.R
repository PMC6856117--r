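#' One generation of the single-locus distorter recursion
#'
#' Advances the population frequency `p` of a dominant trait distorter of
#' strength `k` by one generation of random mating, meiotic drive
#' `(1 + t(k))/2` in heterozygotes, and viability selection `1 - c_trait(k)`
#' on distorter carriers:
#' `wbar p' = (1 - c_trait)(p^2 + (1 - p) p (t + 1))`, with
#' `wbar = (1 - c_trait)(p^2 + 2 p (1 - p)) + (1 - p)^2`.
#'
#' @param p current distorter allele frequency in `[0, 1]`.
#' @param tr a [trait_response()].
#' @param k distorter strength.
#' @return The next-generation frequency `p'`.
#' @export
step_single_locus <- function(p, tr, k) {
  stopifnot(inherits(tr, "trait_response"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  tv <- tr$t(k)
  cv <- tr$c_trait(k)
  wbar <- (1 - cv) * (p^2 + 2 * p * (1 - p)) + (1 - p)^2
  if (any(wbar <= 0)) stop("degenerate population: mean fitness is zero")
  (1 - cv) * (p^2 + (1 - p) * p * (tv + 1)) / wbar
}

two_locus_rhs <- function(x, tv, cv, cs, obligate = FALSE) {
  x00 <- x[1L]; x01 <- x[2L]; x10 <- x[3L]; x11 <- x[4L]
  h <- (1 - cs) / 2
  # obligate suppression also taxes S1 carriers with no distorter
  ob <- if (obligate) 1 - cs else 1
  r00 <- x00 * x00 + ob * x00 * x01 + (1 - tv) * (1 - cv) * x00 * x10 +
    h * x00 * x11 + h * x01 * x10
  r01 <- ob * x00 * x01 + h * x00 * x11 + ob * x01 * x01 +
    h * x01 * x10 + (1 - cs) * x01 * x11
  r10 <- (1 + tv) * (1 - cv) * x00 * x10 + h * x00 * x11 + h * x01 * x10 +
    (1 - cv) * x10 * x10 + (1 - cs) * x10 * x11
  r11 <- h * x00 * x11 + h * x01 * x10 + (1 - cs) * x01 * x11 +
    (1 - cs) * x10 * x11 + (1 - cs) * x11 * x11
  c(r00, r01, r10, r11)
}

check_gamete_state <- function(x, n) {
  if (length(x) != n || anyNA(x)) stop("gamete state must be numeric of length ", n)
  if (any(x < -1e-15)) stop("gamete frequencies must be non-negative")
  if (abs(sum(x) - 1) > 1e-8) stop("gamete frequencies must sum to 1")
  pmax(x, 0)
}

#' One generation of the two-locus distorter-suppressor recursion
#'
#' Advances the frequencies of the four gametes `D0/S0`, `D0/S1`, `D1/S0`,
#' `D1/S1` (`x = c(x00, x01, x10, x11)`) by one generation. The distorter is
#' dominant and drives with bias `t(k)` unless a dominant suppressor allele
#' is present; trait distortion costs `c_trait(k)`, expressed suppression
#' costs `c_sup`. With `params$suppressor = "obligate"` the suppressor is
#' constitutively expressed, so its cost also falls on `S1` carriers that
#' harbour no distorter.
#'
#' @param x gamete frequency vector of length 4, summing to 1.
#' @param tr a [trait_response()].
#' @param params a [conflict_params()].
#' @param validate check the input state (disable inside tight loops or for
#'   finite-difference Jacobians).
#' @return The next-generation gamete frequency vector (normalised).
#' @export
step_two_locus <- function(x, tr, params, validate = TRUE) {
  stopifnot(inherits(tr, "trait_response"), inherits(params, "conflict_params"))
  if (validate) x <- check_gamete_state(x, 4L)
  r <- two_locus_rhs(x, tr$t(params$k), tr$c_trait(params$k), params$c_sup,
                     obligate = params$suppressor == "obligate")
  wbar <- sum(r)
  if (wbar <= 0) stop("degenerate population: mean fitness is zero")
  pmax(r / wbar, 0)
}

#' Jacobian of the two-locus recursion at the distorter-fixed equilibrium
#'
#' The stability matrix of the two-locus map at `x* = (0, 0, 1, 0)` (the
#' unsuppressed distorter fixed, the suppressor absent). Its leading
#' eigenvalue is `(1 - c_sup)/(1 - c_trait)`, so a rare facultative
#' suppressor invades exactly when `c_trait(k) > c_sup`.
#'
#' @param tr a [trait_response()].
#' @param params a [conflict_params()] (facultative mode).
#' @return A 4x4 matrix with attribute `leading_eigenvalue` (the closed
#'   form) ordered as `(x00, x01, x10, x11)`.
#' @export
suppressor_jacobian <- function(tr, params) {
  stopifnot(inherits(tr, "trait_response"), inherits(params, "conflict_params"))
  if (params$suppressor != "facultative")
    stop("the distorter-fixed stability matrix applies to facultative suppression")
  tv <- tr$t(params$k)
  cv <- tr$c_trait(params$k)
  cs <- params$c_sup
  if (cv >= 1) stop("c_trait = 1: equilibrium fitness is zero, Jacobian undefined")
  a <- (1 - cs) / (2 * (1 - cv))
  J <- matrix(c(
    1 - tv,      a,  0,  0,
    0,           a,  0,  0,
    tv - 1, -3 * a,  0, -2 * a,
    0,           a,  0,  2 * a
  ), nrow = 4L, byrow = TRUE)
  attr(J, "leading_eigenvalue") <- (1 - cs) / (1 - cv)
  J
}

#' Leading eigenvalue (largest modulus) of a matrix
#'
#' @param J a square numeric matrix.
#' @return The modulus of the eigenvalue of largest modulus.
#' @export
leading_eigenvalue <- function(J) {
  max(Mod(eigen(J, only.values = TRUE)$values))
}

#' Iterate a gamete-frequency map to equilibrium
#'
#' Repeatedly applies `stepper` until the maximum absolute per-class change
#' falls below `tol` or `max_gen` generations have elapsed.
#'
#' @param x0 initial state (any numeric vector the stepper accepts).
#' @param stepper a function mapping a state to the next-generation state.
#' @param tol convergence tolerance on the maximum per-class change.
#' @param max_gen generation cap.
#' @return A list with `state`, `generations` and `converged`.
#' @export
iterate_to_equilibrium <- function(x0, stepper, tol = 1e-12, max_gen = 1e6) {
  stopifnot(tol > 0, max_gen >= 1)
  x <- x0
  gen <- 0
  converged <- FALSE
  while (gen < max_gen) {
    xn <- stepper(x)
    gen <- gen + 1
    if (max(abs(xn - x)) < tol) {
      x <- xn
      converged <- TRUE
      break
    }
    x <- xn
  }
  list(state = x, generations = gen, converged = converged)
}

#' Iterate the single-locus recursion (compiled loop)
#'
#' Fast path for long runs of the recursion in [step_single_locus()]. Either
#' runs a fixed number of generations (`n_gen > 0`) or iterates until the
#' per-generation change drops below `tol`.
#'
#' @inheritParams step_single_locus
#' @param p0 initial distorter frequency.
#' @param n_gen if positive, run exactly this many generations.
#' @param tol convergence tolerance (used when `n_gen <= 0`).
#' @param max_gen generation cap for tolerance mode.
#' @param record record the frequency at every generation.
#' @return A list with `p`, `generations`, `converged`, and (if recorded)
#'   `series` of per-generation frequencies.
#' @export
iterate_single_locus <- function(p0, tr, k, n_gen = 0, tol = 1e-12,
                                 max_gen = 1e7, record = FALSE) {
  stopifnot(inherits(tr, "trait_response"))
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  cpp_iterate_single(p0, tr$t(k), tr$c_trait(k), as.double(n_gen),
                     tol, as.double(max_gen), record)
}

#' Iterate the two-locus recursion (compiled loop)
#'
#' Fast path for long runs of [step_two_locus()]. Stops when the state
#' converges (max per-class change below `tol`), when the distorter is purged
#' (`x10 + x11 < purge_tol`, if `purge_tol > 0`), or at `max_gen`.
#' Optionally records the per-generation population mean trait distortion
#' `k * P(individual carries >= 1 expressed, unsuppressed distorter)`
#' computed from the gamete frequencies under random union.
#'
#' @inheritParams step_two_locus
#' @param x0 initial gamete frequency vector of length 4.
#' @param tol convergence tolerance.
#' @param max_gen generation cap.
#' @param purge_tol if positive, stop once `x10 + x11` falls below it.
#' @param record record the mean-distortion series.
#' @param record_every thinning interval for the recorded series.
#' @param dist_tol if positive, additionally stop (as purged) once the mean
#'   individual distortion falls below it -- the phenotypic purge criterion
#'   used by the long-term cycle model, where a distorter that fixed during
#'   the suppressor lag is silenced rather than lost.
#' @return A list with `state`, `generations`, `converged`, `purged`, and,
#'   when recording, `distortion` (series), `peak` and `trough`.
#' @export
iterate_two_locus <- function(x0, tr, params, tol = 1e-12, max_gen = 1e7,
                              purge_tol = 0, record = FALSE,
                              record_every = 1L, dist_tol = 0) {
  stopifnot(inherits(tr, "trait_response"), inherits(params, "conflict_params"))
  x0 <- check_gamete_state(x0, 4L)
  cpp_iterate_two(x0, tr$t(params$k), tr$c_trait(params$k), params$c_sup,
                  params$suppressor == "obligate", tol, as.double(max_gen),
                  purge_tol, params$k, record, as.integer(record_every),
                  dist_tol)
}

#' Generations from distorter introduction to purging
#'
#' Introduces a distorter and its facultative suppressor from rarity and
#' iterates the two-locus recursions until the distorter gamete frequency
#' `x10 + x11` falls below `purge_tol`, or the cap of 2e7 generations is
#' reached. Requires `c_trait(k) > c_sup`; otherwise the suppressor cannot
#' invade and the distorter is never purged.
#'
#' Under the default `scheme = "simultaneous"` both alleles start rare and
#' in linkage equilibrium (the distorter at `p0`, the suppressor at `s0`):
#' the distorter sweeps first, the suppressor follows once its target is
#' common, and the distorter is then driven out. With `scheme = "staged"`
#' the distorter first spreads alone to frequency `f` under the
#' single-locus recursion, and the suppressor is then introduced at `s0`.
#'
#' @inheritParams step_two_locus
#' @param scheme introduction scheme, see Details.
#' @param f distorter frequency at which the suppressor is introduced
#'   (staged scheme).
#' @param p0 introduction frequency of the distorter.
#' @param s0 introduction frequency of the suppressor.
#' @param purge_tol distorter frequency below which it counts as purged.
#' @param cap generation cap (default 2e7); if reached, the result carries
#'   attribute `capped = TRUE`.
#' @return Number of generations from distorter introduction to purging,
#'   with attribute `capped`.
#' @export
time_to_purge <- function(tr, params, scheme = c("simultaneous", "staged"),
                          f = 0.99, p0 = 1e-6, s0 = 1e-3,
                          purge_tol = 1e-9, cap = 2e7) {
  stopifnot(inherits(tr, "trait_response"), inherits(params, "conflict_params"))
  scheme <- match.arg(scheme)
  k <- params$k
  if (tr$c_trait(k) <= params$c_sup)
    stop("c_trait(k) <= c_sup: the suppressor cannot invade, ",
         "the distorter is never purged")
  gen <- 0
  if (scheme == "simultaneous") {
    x0 <- c((1 - p0) * (1 - s0), (1 - p0) * s0, p0 * (1 - s0), p0 * s0)
  } else {
    if (!distorter_invades(tr, k))
      stop("the distorter does not reach frequency f: it cannot invade ",
           "from rarity at this strength")
    p <- p0
    while (p < f && gen < cap) {
      p <- step_single_locus(p, tr, k)
      gen <- gen + 1
    }
    x0 <- introduce_suppressor(p, s0)
  }
  res <- iterate_two_locus(x0, tr, params, tol = 0, max_gen = cap - gen,
                           purge_tol = purge_tol)
  total <- gen + res$generations
  attr(total, "capped") <- !res$purged
  total
}

#' Introduce a rare suppressor into a distorter-segregating population
#'
#' Converts a single-locus distorter frequency `p` into a four-gamete state
#' in which a suppressor of total frequency `s0` is split evenly between the
#' distorter and non-distorter backgrounds:
#' `x = (1 - p - s0/2, s0/2, p - s0/2, s0/2)`.
#'
#' @param p distorter frequency.
#' @param s0 total suppressor introduction frequency.
#' @return A gamete frequency vector of length 4.
#' @export
introduce_suppressor <- function(p, s0 = 1e-3) {
  stopifnot(p >= 0, p <= 1, s0 > 0, s0 < 1)
  d0 <- 1 - p
  # even split between backgrounds; a background smaller than s0/2 (the
  # distorter at or near fixation) cedes its share to the other
  x01 <- min(s0 / 2, d0)
  x11 <- min(s0 - x01, p)
  x01 <- s0 - x11
  x <- c(d0 - x01, x01, p - x11, x11)
  x / sum(x)
}

six_gamete_rhs <- function(x, tk, th, ck, ch, c01, c02, c12, cs) {
  # transcription of the printed recursions; c01/c02/c12 are the trait costs
  # of the unsuppressed D0D1, D0D2 and D1D2 heterozygotes
  x00 <- x[1L]; x01 <- x[2L]; x10 <- x[3L]
  x11 <- x[4L]; x20 <- x[5L]; x21 <- x[6L]
  h <- (1 - cs) / 2
  r00 <- x00 * x00 + x00 * x01 + (1 - tk) * (1 - c01) * x00 * x10 +
    h * x00 * x11 + (1 - th) * (1 - c02) * x00 * x20 + h * x00 * x21 +
    h * x01 * x10 + h * x01 * x20
  r01 <- x00 * x01 + h * x00 * x11 + h * x00 * x21 + x01 * x01 +
    h * x01 * x10 + (1 - cs) * x01 * x11 + h * x01 * x20 +
    (1 - cs) * x01 * x21
  r10 <- (1 + tk) * (1 - c01) * x00 * x10 + h * x00 * x11 + h * x01 * x10 +
    (1 - ck) * x10 * x10 + (1 - cs) * x10 * x11 +
    (1 + tk - th) * (1 - c12) * x10 * x20 + h * x10 * x21 + h * x11 * x20
  r11 <- h * x00 * x11 + h * x01 * x10 + (1 - cs) * x01 * x11 +
    (1 - cs) * x10 * x11 + h * x10 * x21 + (1 - cs) * x11 * x11 +
    h * x11 * x20 + (1 - cs) * x11 * x21
  r20 <- (1 + th) * (1 - c02) * x00 * x20 + h * x00 * x21 + h * x01 * x20 +
    (1 - tk + th) * (1 - c12) * x10 * x20 + h * x10 * x21 + h * x11 * x20 +
    (1 - ch) * x20 * x20 + (1 - cs) * x20 * x21
  r21 <- h * x00 * x21 + h * x01 * x20 + (1 - cs) * x01 * x21 +
    h * x10 * x21 + h * x11 * x20 + (1 - cs) * x11 * x21 +
    (1 - cs) * x20 * x21 + (1 - cs) * x21 * x21
  c(r00, r01, r10, r11, r20, r21)
}

#' One generation of the resident + mutant distorter recursion
#'
#' Advances the six gamete frequencies `D0/S0, D0/S1, D1/S0, D1/S1, D2/S0,
#' D2/S1` (`x = c(x00, x01, x10, x11, x20, x21)`) where `D1` is a resident
#' distorter of strength `k` and `D2` a mutant of strength `k_hat`, both
#' silenced by the same dominant facultative suppressor at cost `c_sup`.
#' In dominant mode the stronger distorter of a `D1 D2` heterozygote sets the
#' trait cost (`c_trait(max(k, k_hat))`) and the mutant gains drive
#' `(1 + t(k_hat) - t(k))/2`; in additive mode heterozygote costs are the
#' mean of the two allele costs (a non-distorting allele costing 0).
#'
#' @param x gamete frequency vector of length 6, summing to 1.
#' @inheritParams step_two_locus
#' @return The next-generation gamete frequency vector (normalised).
#' @export
step_three_allele <- function(x, tr, params, validate = TRUE) {
  stopifnot(inherits(tr, "trait_response"), inherits(params, "conflict_params"))
  if (is.null(params$k_hat)) stop("params$k_hat must be set for the mutant recursion")
  if (validate) x <- check_gamete_state(x, 6L)
  k <- params$k; kh <- params$k_hat
  tk <- tr$t(k); th <- tr$t(kh)
  ck <- tr$c_trait(k); ch <- tr$c_trait(kh)
  if (params$dominance == "dominant") {
    c01 <- ck; c02 <- ch
    c12 <- tr$c_trait(max(k, kh))
  } else {
    c01 <- ck / 2; c02 <- ch / 2
    c12 <- (ck + ch) / 2
  }
  r <- six_gamete_rhs(x, tk, th, ck, ch, c01, c02, c12, params$c_sup)
  wbar <- sum(r)
  if (wbar <= 0) stop("degenerate population: mean fitness is zero")
  pmax(r / wbar, 0)
}

#' Adaptive walk of distorter strength under delta-weak selection
#'
#' Starting from a resident strength `k0`, repeatedly proposes a slightly
#' stronger mutant `k + delta` (dominant mode: weaker mutants are recessive
#' and never invade) and replaces the resident whenever
#' [mutant_invades()] holds, stopping at the first rejected mutant, at
#' strength 1, or after `n_steps` proposals. Under small `delta` the walk
#' terminates within `delta` of the interior [k_target()].
#'
#' @inheritParams mutant_invades
#' @param params a [conflict_params()] (only the dominance mode is used).
#' @param k0 initial resident strength.
#' @param delta mutant step size.
#' @param n_steps maximum number of proposals.
#' @return Numeric vector of successive resident strengths (starting at `k0`).
#' @export
adaptive_walk <- function(tr, params, k0 = 0, delta = 0.005, n_steps = 1000L) {
  stopifnot(inherits(tr, "trait_response"), delta > 0, k0 >= 0, k0 <= 1)
  ks <- k0
  k <- k0
  for (i in seq_len(n_steps)) {
    kh <- min(k + delta, 1)
    if (kh == k) break
    if (!mutant_invades(tr, k, kh, mode = "dominant")) break
    k <- kh
    ks <- c(ks, k)
  }
  ks
}

#' Export a trajectory of gamete frequencies as a tidy table
#'
#' @param states a matrix of per-generation states (rows = generations,
#'   columns = gamete classes) or a numeric vector of mean distortions.
#' @param mean_distortion optional per-generation mean distortion.
#' @return A data.frame with a `generation` column.
#' @export
trajectory_table <- function(states, mean_distortion = NULL) {
  if (is.matrix(states)) {
    nm <- if (ncol(states) == 4L) c("x00", "x01", "x10", "x11")
          else c("x00", "x01", "x10", "x11", "x20", "x21")
    out <- as.data.frame(states)
    names(out) <- nm
  } else {
    out <- data.frame(mean_distortion = states)
  }
  out <- cbind(generation = seq_len(nrow(out)), out)
  if (!is.null(mean_distortion)) out$mean_distortion <- mean_distortion
  out
}
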