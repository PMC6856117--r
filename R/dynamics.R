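#' Genome architecture for the long-term conflict dynamics
#'
#' Describes the genome over which distorters and suppressors arise: `gamma`
#' loci of which a fraction `theta` (the cabal, `0 < theta <= 0.5`) favour
#' the trait distortion and the remaining fraction `1 - theta` (the
#' commonwealth) favour suppressing it. New distorters arise at a rate
#' `rho_D1` per cabal locus per generation, so one appears every
#' `1/(theta gamma rho_D1)` generations; the dedicated suppressor of each
#' follows `1/((1 - theta) gamma rho_S1)` generations later. Both per-locus
#' probabilities scale linearly with the baseline mutation rate `rho`.
#'
#' @param gamma number of loci in the genome.
#' @param theta proportional cabal size, in `(0, 0.5]`.
#' @param rho_D1 per-locus per-generation distorter origination probability.
#' @param rho_S1 per-locus per-generation suppressor origination probability.
#' @param rho baseline mutation-rate multiplier applied to both rates.
#' @return An object of class `genome_architecture`.
#' @export
genome_architecture <- function(gamma, theta, rho_D1, rho_S1, rho = 1) {
  stopifnot(is.numeric(gamma), gamma >= 1)
  if (!is.numeric(theta) || theta <= 0 || theta > 0.5)
    stop("theta must lie in (0, 0.5]: the cabal can never be the majority")
  for (r in list(rho_D1 = rho_D1, rho_S1 = rho_S1))
    if (!is.numeric(r) || r <= 0 || r >= 1)
      stop("introduction probabilities must lie in (0, 1)")
  stopifnot(rho > 0)
  g <- structure(list(gamma = gamma, theta = theta,
                      rho_D1 = rho_D1, rho_S1 = rho_S1, rho = rho),
                 class = "genome_architecture")
  if (!is.finite(distorter_interval(g)) || !is.finite(suppressor_lag(g)))
    stop("introduction interval and suppressor lag must be finite")
  g
}

#' @rdname genome_architecture
#' @param genome a `genome_architecture`.
#' @export
distorter_interval <- function(genome) {
  1 / (genome$theta * genome$gamma * genome$rho_D1 * genome$rho)
}

#' @rdname genome_architecture
#' @export
suppressor_lag <- function(genome) {
  1 / ((1 - genome$theta) * genome$gamma * genome$rho_S1 * genome$rho)
}

#' Separation-of-timescales average trait distortion
#'
#' The closed-form evolutionary-time average of individual trait distortion
#' under deterministic introduction of distorters and suppressors, assuming
#' allele frequencies equilibrate fast relative to introductions. For
#' distorters too weak to trigger suppression (`c_sup > c_trait(k)`) the
#' average is simply `k`; otherwise it is
#' `k theta rho_D1 / ((1 - theta) rho_S1)`: the fraction of evolutionary
#' time a distorter segregates, times its strength. Genome size `gamma` and
#' the baseline rate `rho` cancel and do not appear.
#'
#' @param genome a [genome_architecture()].
#' @param tr a [trait_response()].
#' @param c_sup suppression cost.
#' @param k distorter strength.
#' @return Average trait distortion.
#' @export
average_distortion_approx <- function(genome, tr, c_sup, k) {
  stopifnot(inherits(genome, "genome_architecture"),
            inherits(tr, "trait_response"))
  check_unit_interval(c_sup, "c_sup")
  check_unit_interval(k, "k")
  if (genome$theta >= 1) stop("theta = 1 leaves no commonwealth; undefined")
  if (tr$c_trait(k) > c_sup) {
    k * genome$theta * genome$rho_D1 / ((1 - genome$theta) * genome$rho_S1)
  } else {
    k
  }
}

#' Exact deterministic introduction-suppression cycle
#'
#' Runs one full cycle of the long-term dynamics numerically: a distorter of
#' strength `k` is introduced from rarity and spreads under the single-locus
#' recursion for the suppressor lag `1/((1 - theta) gamma rho_S1)`
#' generations; its dedicated suppressor is then introduced from rarity and
#' the two-locus recursions are iterated until the distorter is purged
#' (generation `X`). The per-generation population mean individual
#' distortion is recorded throughout, and the evolutionary-time average is
#' the cycle mean weighted by the fraction of evolutionary time a distorter
#' segregates, `X * theta * gamma * rho_D1`.
#'
#' For `c_sup >= c_trait(k)` no suppressor can invade: the distorter simply
#' fixes, there is no suppression phase, and the evolutionary-time average
#' is `k`.
#'
#' @inheritParams average_distortion_approx
#' @param params a [conflict_params()] carrying `c_sup` (its `k` is ignored
#'   in favour of the `k` argument).
#' @param k distorter strength for this cycle.
#' @param p0 distorter introduction frequency.
#' @param s0 suppressor introduction frequency.
#' @param purge_tol distorter frequency below which it counts as purged.
#' @param max_gen cap on the suppression phase.
#' @param keep_series retain the per-generation distortion series.
#' @param residual numerical floor on the non-distorter allele frequency at
#'   suppressor introduction. The recursion approaches distorter fixation
#'   only asymptotically, but in double precision `p` can round to exactly 1
#'   within a long suppressor lag, which would extinguish the non-distorter
#'   allele the purge phase restores; the floor preserves it at the
#'   infinitesimal frequency the exact dynamics imply.
#' @return An object of class `cycle_result`: a list with `lag`,
#'   `purge_generation` (X), `peak`, `trough`, `cycle_average`,
#'   `evo_average`, `seg_fraction` (X theta gamma rho_D1), `suppressed`
#'   and optionally `series`.
#' @export
cycle_exact <- function(genome, tr, params, k, p0 = 1e-6, s0 = 1e-3,
                        purge_tol = 1e-9, max_gen = 2e7,
                        keep_series = TRUE, residual = 1e-9) {
  stopifnot(inherits(genome, "genome_architecture"),
            inherits(tr, "trait_response"),
            inherits(params, "conflict_params"))
  check_unit_interval(k, "k")
  lag <- max(1, round(suppressor_lag(genome)))
  rate_d <- 1 / distorter_interval(genome)
  if (params$c_sup >= tr$c_trait(k)) {
    ph <- iterate_single_locus(p0, tr, k, n_gen = lag, record = keep_series)
    series <- if (keep_series) k * (1 - (1 - ph$series)^2) else NULL
    return(structure(list(
      lag = lag, purge_generation = NA_real_,
      peak = k * (1 - (1 - ph$p)^2), trough = 0,
      cycle_average = k, evo_average = k, seg_fraction = 1,
      suppressed = FALSE, series = series
    ), class = "cycle_result"))
  }
  ph1 <- iterate_single_locus(p0, tr, k, n_gen = lag, record = TRUE)
  dist1 <- k * (1 - (1 - ph1$series)^2)
  cpar <- conflict_params(params$c_sup, k, suppressor = params$suppressor)
  x0 <- introduce_suppressor(min(ph1$p, 1 - residual), s0)
  ph2 <- iterate_two_locus(x0, tr, cpar, tol = 0, max_gen = max_gen,
                           purge_tol = purge_tol, record = TRUE,
                           dist_tol = purge_tol * k)
  if (!ph2$purged)
    stop("distorter not purged within max_gen generations")
  X <- lag + ph2$generations
  series <- c(dist1, ph2$distortion)
  seg <- X * genome$theta * genome$gamma * genome$rho_D1 * genome$rho
  if (seg > 1)
    warning("cycle length exceeds the distorter introduction interval ",
            "(X * theta * gamma * rho_D1 = ", signif(seg, 3),
            "): distorters co-segregate and the no-overlap cycle is only approximate")
  cyc_avg <- mean(series)
  structure(list(
    lag = lag, purge_generation = X,
    peak = max(series), trough = min(series),
    cycle_average = cyc_avg, evo_average = cyc_avg * seg,
    seg_fraction = seg, suppressed = TRUE,
    series = if (keep_series) series else NULL
  ), class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result>\n")
  cat(sprintf("  suppressor lag: %g generations\n", x$lag))
  if (x$suppressed) {
    cat(sprintf("  purge generation X: %g\n", x$purge_generation))
    cat(sprintf("  segregating fraction of evolutionary time: %.4g\n", x$seg_fraction))
  } else {
    cat("  suppressor cannot invade: distorter fixes unsuppressed\n")
  }
  cat(sprintf("  distortion peak %.4g, trough %.4g\n", x$peak, x$trough))
  cat(sprintf("  cycle average %.4g, evolutionary-time average %.4g\n",
              x$cycle_average, x$evo_average))
  invisible(x)
}

#' Average-distortion surface over distorter strength and cabal size
#'
#' Evaluates the evolutionary-time average trait distortion on a grid of
#' distorter strengths `k` and proportional cabal sizes `theta`, either with
#' the closed-form separation-of-timescales approximation
#' ([average_distortion_approx()]) or the exact numerical cycle
#' ([cycle_exact()]).
#'
#' @inheritParams cycle_exact
#' @param c_sup suppression cost.
#' @param k_values,theta_values grid values.
#' @param method `"approx"` or `"exact"`.
#' @param ... further arguments passed to [cycle_exact()].
#' @return A tidy data.frame with columns `k`, `theta`,
#'   `average_distortion` and `regime`.
#' @export
distortion_surface <- function(genome, tr, c_sup, k_values, theta_values,
                               method = c("approx", "exact"), ...) {
  method <- match.arg(method)
  grid <- expand.grid(k = k_values, theta = theta_values,
                      KEEP.OUT.ATTRS = FALSE)
  avg <- numeric(nrow(grid))
  regime <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- genome_architecture(genome$gamma, grid$theta[i],
                             genome$rho_D1, genome$rho_S1, genome$rho)
    suppressed <- tr$c_trait(grid$k[i]) > c_sup
    regime[i] <- if (suppressed) "suppressed" else "unsuppressed"
    avg[i] <- if (method == "approx" || !suppressed) {
      average_distortion_approx(g, tr, c_sup, grid$k[i])
    } else {
      cycle_exact(g, tr, conflict_params(c_sup, grid$k[i]), grid$k[i],
                  keep_series = FALSE, ...)$evo_average
    }
  }
  cbind(grid, average_distortion = avg, regime = regime)
}
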