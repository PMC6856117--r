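#' Total suppression of a distorter locus (discrete multilocus model)
#'
#' In the discrete genome-wide model every distorter has fixed strength `k`
#' and every suppressor is all-or-nothing. A distorter at a cabal locus faces
#' total suppression 1 if its dedicated suppressor is present in the
#' individual, and otherwise `min(z q, 1)` where `q` is the number of
#' expressed suppressors in the individual and `z` the background
#' (generalist) suppression fraction: `z = 0.5` for low-sophistication
#' distorters, `z = 0` for high-sophistication ones. A suppressor is
#' expressed only when its own target distorter is present.
#'
#' @param dedicated logical (vectorised): is the dedicated suppressor present?
#' @param q number of expressed suppressors in the individual.
#' @param z background suppression fraction.
#' @return Total suppression in `[0, 1]`.
#' @export
total_suppression_discrete <- function(dedicated, q, z) {
  stopifnot(all(q >= 0), z >= 0, z <= 1)
  ifelse(dedicated, 1, pmin(z * q, 1))
}

#' Total suppression of a distorter locus (continuous multilocus model)
#'
#' With continuously evolving suppressor strengths, a distorter at locus `i`
#' faces `min(max(m_ai, m_bi) + z * sum_j max(m_aj, m_bj), 1)` where the sum
#' runs over the expressed suppressors dedicated to the individual's other
#' distorter loci.
#'
#' @param m_own expressed strength of the dedicated suppressor (0 if absent
#'   or unexpressed).
#' @param m_others vector of expressed strengths of the suppressors dedicated
#'   to the individual's other distorter loci.
#' @param z background suppression fraction.
#' @return Total suppression in `[0, 1]`.
#' @export
total_suppression_continuous <- function(m_own, m_others, z) {
  stopifnot(m_own >= 0, m_own <= 1, z >= 0, z <= 1)
  min(m_own + z * sum(m_others), 1)
}

#' Phenotype of a multilocus distorter carrier
#'
#' Given the total suppression and strength of each distorter locus an
#' individual carries, computes the expressed trait distortion
#' `Dist = max_i (1 - TotSup_i) k_i` (the least-suppressed, inter-locus
#' dominant distorter; ties broken by the lowest locus index), the redundant
#' gene-product load `Waste = sum_{i != i_dom} (1 - TotSup_i) k_i`, and
#' viability `1 - c_trait(Dist) - c_rec(Waste) - c_sup * sum_i TotSup_i`.
#' The inter-locus-recessive cost applies the trait-cost curve to the waste
#' load, `c_rec(W) = r_rec * c_trait(W)` with scaling factor `r_rec` of 1
#' (low sophistication) or 3/5 (high): one unsuppressed recessive distorter
#' then costs exactly `r_rec * c_trait(Dist)`, and fully suppressed
#' background distorters add no waste cost.
#'
#' @param tot_sup vector of total suppression per carried distorter locus.
#' @param strengths vector of distorter strengths per carried locus (all
#'   equal to `k` in the discrete model).
#' @param tr a [trait_response()] (only `c_trait` is used).
#' @param c_sup suppression cost per expressed suppressor.
#' @param sophistication `"low"` or `"high"`.
#' @return A list with `Dist`, `Waste`, `i_dom` (index into the input
#'   vectors, `NA` if no distorters), `c_rec` and `fitness` (unclamped; the
#'   simulator samples with `max(fitness, 0)`).
#' @export
distorter_phenotype <- function(tot_sup, strengths, tr, c_sup,
                                sophistication = c("low", "high")) {
  stopifnot(inherits(tr, "trait_response"), length(tot_sup) == length(strengths))
  sophistication <- match.arg(sophistication)
  if (length(tot_sup) == 0L) {
    return(list(Dist = 0, Waste = 0, i_dom = NA_integer_, c_rec = 0, fitness = 1))
  }
  eff <- (1 - tot_sup) * strengths
  i_dom <- which.max(eff)  # which.max returns the first (lowest) index on ties
  Dist <- eff[i_dom]
  Waste <- sum(eff) - Dist
  ct <- tr$c_trait(Dist)
  r <- if (sophistication == "low") 1 else 3 / 5
  c_rec <- if (Waste > 0) r * tr$c_trait(Waste) else 0
  list(Dist = Dist, Waste = Waste, i_dom = i_dom, c_rec = c_rec,
       fitness = 1 - ct - c_rec - c_sup * sum(tot_sup))
}

#' Genome-wide agent-based simulation of distorter-suppressor conflict
#'
#' Simulates `N` diploid individuals whose genome of `gamma` loci contains a
#' cabal fraction `theta` at which trait distorters can arise and a
#' commonwealth fraction `1 - theta` supplying one dedicated suppressor
#' locus per activated distorter locus. Loci are initially dormant; each
#' generation a dormant cabal locus activates with probability `rho_D1` and,
#' provided some distorter still lacks a dedicated suppressor
#' (`n_cabal > n_commonwealth`), a dormant commonwealth locus activates with
#' probability `rho_S1`, targeting the next unmatched distorter locus.
#' Activation seeds one functional allele in one random individual.
#'
#' In `"discrete"` mode distorters have fixed strength `k` and suppressors
#' strength 1, and alleles flip between functional and neutral with
#' probability `flip_prob` per generation. In `"continuous"` mode strengths
#' evolve freely in `[0, 1]` under the truncated-normal kernel
#' (`mut_prob`, `mut_var`). Suppression, inter-locus dominance, waste costs
#' and unit meiotic drive follow [total_suppression_discrete()],
#' [total_suppression_continuous()] and [distorter_phenotype()]; all the
#' heterozygous distorter loci of a parent drive through meiosis as a single
#' unit pulled by its least-suppressed member.
#'
#' The trait-cost function must belong to the power family
#' ([power_response()]), `c_trait(Dist) = a Dist^b`; the drive probabilities
#' of this model use allele strengths directly.
#'
#' Uses the current R random number generator state; call `set.seed()` for
#' reproducible runs.
#'
#' @param genome a [genome_architecture()].
#' @param tr a [power_response()]; only the cost component is used.
#' @param c_sup suppression cost per expressed suppressor.
#' @param k distorter strength (discrete mode).
#' @param mode `"discrete"` or `"continuous"`.
#' @param sophistication `"low"` (background suppression `z = 0.5`, full
#'   recessive cost) or `"high"` (`z = 0`, reduced recessive cost).
#' @param N population size.
#' @param T_end number of generations.
#' @param z background suppression fraction; defaults to 0.5/0 by
#'   sophistication.
#' @param flip_prob functional/neutral flip probability (discrete mode).
#' @param mut_prob,mut_var mutation kernel (continuous mode).
#' @return A list with `trajectory` (data.frame: `generation`,
#'   `mean_distortion`, `n_cabal`, `n_commonwealth`), `average_distortion`
#'   (time average of the population mean `Dist`), and
#'   `negative_fitness_events`.
#' @export
run_multilocus <- function(genome, tr, c_sup, k = 0.5,
                           mode = c("discrete", "continuous"),
                           sophistication = c("low", "high"),
                           N = 2000L, T_end = 30000L, z = NULL,
                           flip_prob = 0.001, mut_prob = 0.01,
                           mut_var = 0.2) {
  stopifnot(inherits(genome, "genome_architecture"),
            inherits(tr, "trait_response"))
  mode <- match.arg(mode)
  sophistication <- match.arg(sophistication)
  check_unit_interval(c_sup, "c_sup")
  check_unit_interval(k, "k")
  if (!identical(tr$family, "power"))
    stop("the multilocus engine requires a power_response() trait cost")
  if (is.null(z)) z <- if (sophistication == "low") 0.5 else 0
  res <- cpp_run_multilocus(
    as.integer(N), as.integer(T_end),
    genome$theta * genome$gamma, (1 - genome$theta) * genome$gamma,
    genome$rho_D1 * genome$rho, genome$rho_S1 * genome$rho,
    mode == "continuous", k, z, c_sup,
    unname(tr$coef["c_coef"]), unname(tr$coef["c_exp"]),
    if (sophistication == "low") 1 else 3 / 5,
    flip_prob, mut_prob, sqrt(mut_var))
  list(
    trajectory = data.frame(
      generation = seq_len(T_end),
      mean_distortion = res$mean_distortion,
      n_cabal = res$n_cabal,
      n_commonwealth = res$n_commonwealth
    ),
    average_distortion = res$average_distortion,
    negative_fitness_events = res$negative_fitness_events,
    config = list(mode = mode, sophistication = sophistication, N = N,
                  T_end = T_end, k = k, z = z, c_sup = c_sup,
                  gamma = genome$gamma, theta = genome$theta,
                  rho_D1 = genome$rho_D1, rho_S1 = genome$rho_S1,
                  rho = genome$rho)
  )
}

#' Replicate runner for the genome-wide simulation
#'
#' Runs [run_multilocus()] `n_rep` times with seeds `seed + 1, ...,
#' seed + n_rep` and summarises the per-replicate time-averaged distortion.
#'
#' @param n_rep number of replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param ... passed to [run_multilocus()].
#' @return A list with `values` (per-replicate time-averaged distortion),
#'   `mean`, `se` and `runs` (the individual results, trajectories dropped
#'   beyond the first).
#' @export
run_multilocus_reps <- function(n_rep, seed, ...) {
  stopifnot(n_rep >= 1)
  vals <- numeric(n_rep)
  first <- NULL
  for (i in seq_len(n_rep)) {
    set.seed(seed + i)
    r <- run_multilocus(...)
    vals[i] <- r$average_distortion
    if (i == 1L) first <- r
  }
  s <- if (n_rep >= 2L) summarize_replicates(vals) else list(mean = vals, se = NA_real_)
  list(values = vals, mean = s$mean, se = s$se, first_run = first)
}
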