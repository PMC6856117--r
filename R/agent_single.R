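#' Individual fitness in the single-locus agent-based model
#'
#' Diploid individuals carry two distorter alleles of strengths `ka`, `kb`
#' and two suppressor alleles of strengths `ma`, `mb`; within each locus the
#' strongest allele is dominant. An individual with an active distorter
#' (`max(ka, kb) > 0`) has fitness
#' `1 - c_trait(max(ka, kb)) (1 - max(ma, mb)) - c_sup max(ma, mb)`;
#' an individual without one has fitness 1 (the suppressor is facultative
#' and unexpressed in the absence of its target).
#'
#' @param ka,kb,ma,mb allele strength vectors in `[0, 1]` (recycled).
#' @param tr a [trait_response()].
#' @param c_sup suppression cost.
#' @return Numeric vector of absolute fitnesses.
#' @export
fitness_single_locus <- function(ka, kb, ma, mb, tr, c_sup) {
  stopifnot(inherits(tr, "trait_response"))
  mk <- pmax(ka, kb)
  mm <- pmax(ma, mb)
  ifelse(mk > 0, 1 - tr$c_trait(mk) * (1 - mm) - c_sup * mm, 1)
}

#' Meiotic drive probability in the single-locus agent-based model
#'
#' The probability that the allele of strength `ka` (rather than `kb`) is
#' transmitted: `(1 + (t(ka) - t(kb)) (1 - max(ma, mb)))/2`. Suppression
#' (dominant `m` allele) cancels the drive; suppressor alleles themselves
#' segregate in Mendelian fashion.
#'
#' @inheritParams fitness_single_locus
#' @return Numeric vector of transmission probabilities for the `ka` allele.
#' @export
drive_probability <- function(ka, kb, ma, mb, tr) {
  stopifnot(inherits(tr, "trait_response"))
  (1 + (tr$t(ka) - tr$t(kb)) * (1 - pmax(ma, mb))) / 2
}

#' Sample gametes from one parent in the single-locus agent-based model
#'
#' Draws `n` gametes: the distorter allele is `ka` with probability
#' [drive_probability()] (else `kb`), and the suppressor allele is `ma` or
#' `mb` with equal probability; the two unlinked loci assort independently.
#'
#' @inheritParams fitness_single_locus
#' @param n number of gametes to draw.
#' @return A list with numeric vectors `k` and `m` of length `n`.
#' @export
meiosis_single_locus <- function(ka, kb, ma, mb, tr, n = 1L) {
  p <- drive_probability(ka, kb, ma, mb, tr)
  list(k = ifelse(runif(n) < p, ka, kb),
       m = ifelse(runif(n) < 0.5, ma, mb))
}

#' Single-locus coevolution of distorter and suppressor strength
#'
#' Forward-time simulation of `N` hermaphroditic diploids with one distorter
#' and one unlinked suppressor locus, both with continuous allele strengths
#' in `[0, 1]`. Each generation, `N` breeding pairs are drawn with
#' replacement with probability proportional to fitness
#' ([fitness_single_locus()]); each pair produces one offspring via
#' [meiosis_single_locus()] and the parents die (non-overlapping
#' generations). Each allele mutates with probability `mut_prob` per
#' generation to a value drawn from a normal centred on its current value
#' with variance `mut_var`, truncated to `[0, 1]` (by clamping, or by
#' resampling with `truncation = "resample"`).
#'
#' Uses the current R random number generator state; call `set.seed()` for
#' reproducible runs.
#'
#' @inheritParams fitness_single_locus
#' @param N population size.
#' @param T_end number of generations.
#' @param mut_prob per-allele per-generation mutation probability.
#' @param mut_var variance of the mutation kernel.
#' @param init_k,init_m initial allele strengths: a scalar, or a vector of
#'   length `2 N` giving every allele copy.
#' @param truncation how normal draws outside `[0, 1]` are handled.
#' @param no_selfing if `TRUE`, redraw the second parent of a pair until it
#'   differs from the first (default allows selfing, as hermaphrodites drawn
#'   with replacement do).
#' @param record_every thinning interval for the trajectory.
#' @return A data.frame with columns `generation`, `mean_k`, `mean_m` (the
#'   population mean distorter and suppressor allele strengths E\[k\], E\[m\]).
#' @export
run_single_locus <- function(tr, c_sup, N = 2000L, T_end = 20000L,
                             mut_prob = 0.01, mut_var = 0.2,
                             init_k = 0, init_m = 0,
                             truncation = c("clamp", "resample"),
                             no_selfing = FALSE, record_every = 1L) {
  stopifnot(inherits(tr, "trait_response"), N >= 2, T_end >= 1)
  truncation <- match.arg(truncation)
  mut_sd <- sqrt(mut_var)
  expand_init <- function(v) {
    if (length(v) == 1L) rep(as.numeric(v), 2L * N)
    else { stopifnot(length(v) == 2L * N); as.numeric(v) }
  }
  kal <- expand_init(init_k)  # alleles: first N = haplotype a, last N = b
  mal <- expand_init(init_m)
  ka <- kal[seq_len(N)]; kb <- kal[N + seq_len(N)]
  ma <- mal[seq_len(N)]; mb <- mal[N + seq_len(N)]
  keep <- seq(record_every, T_end, by = record_every)
  mean_k <- numeric(length(keep)); mean_m <- numeric(length(keep))
  ki <- 0L
  mutate <- function(v) {
    hit <- runif(length(v)) < mut_prob
    n_hit <- sum(hit)
    if (n_hit == 0L) return(v)
    draw <- rnorm(n_hit, mean = v[hit], sd = mut_sd)
    if (truncation == "clamp") {
      draw <- pmin(pmax(draw, 0), 1)
    } else {
      bad <- draw < 0 | draw > 1
      while (any(bad)) {
        draw[bad] <- rnorm(sum(bad), mean = v[hit][bad], sd = mut_sd)
        bad <- draw < 0 | draw > 1
      }
    }
    v[hit] <- draw
    v
  }
  for (gen in seq_len(T_end)) {
    w <- fitness_single_locus(ka, kb, ma, mb, tr, c_sup)
    w <- pmax(w, 0)
    if (all(w <= 0)) stop("population fitness collapsed to zero at generation ", gen)
    p1 <- sample.int(N, N, replace = TRUE, prob = w)
    p2 <- sample.int(N, N, replace = TRUE, prob = w)
    if (no_selfing) {
      same <- which(p1 == p2)
      while (length(same)) {
        p2[same] <- sample.int(N, length(same), replace = TRUE, prob = w)
        same <- same[p1[same] == p2[same]]
      }
    }
    gamete <- function(idx) {
      pd <- drive_probability(ka[idx], kb[idx], ma[idx], mb[idx], tr)
      list(k = ifelse(runif(N) < pd, ka[idx], kb[idx]),
           m = ifelse(runif(N) < 0.5, ma[idx], mb[idx]))
    }
    g1 <- gamete(p1); g2 <- gamete(p2)
    ka <- mutate(g1$k); kb <- mutate(g2$k)
    ma <- mutate(g1$m); mb <- mutate(g2$m)
    if (gen %% record_every == 0L) {
      ki <- ki + 1L
      mean_k[ki] <- mean(c(ka, kb))
      mean_m[ki] <- mean(c(ma, mb))
    }
  }
  data.frame(generation = keep, mean_k = mean_k, mean_m = mean_m)
}

#' Average single-locus simulation trajectories over replicates
#'
#' Runs [run_single_locus()] `n_rep` times with seeds `seed + 1, ...,
#' seed + n_rep` and averages the trajectories.
#'
#' @param n_rep number of replicate runs.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param ... passed to [run_single_locus()].
#' @return A data.frame with `generation`, `mean_k`, `mean_m` averaged over
#'   replicates, with the per-replicate trajectories in attribute
#'   `replicates`.
#' @export
run_single_locus_reps <- function(n_rep, seed, ...) {
  stopifnot(n_rep >= 1)
  runs <- lapply(seq_len(n_rep), function(i) {
    set.seed(seed + i)
    run_single_locus(...)
  })
  out <- runs[[1L]]
  if (n_rep > 1L) {
    out$mean_k <- rowMeans(sapply(runs, `[[`, "mean_k"))
    out$mean_m <- rowMeans(sapply(runs, `[[`, "mean_m"))
  }
  attr(out, "replicates") <- runs
  out
}
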