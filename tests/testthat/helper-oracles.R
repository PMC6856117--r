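# Brute-force mating-table oracles for the gamete-frequency recursions.
# These enumerate every ordered gamete pairing, apply viability by diploid
# genotype and the meiotic transmission distribution, and are kept fully
# independent of the package's steppers.

# Two-locus: gametes indexed 1..4 = D0S0, D0S1, D1S0, D1S1.
oracle_step_two_locus <- function(x, tval, ct, cs, obligate = FALSE) {
  D <- c(0L, 0L, 1L, 1L)
  S <- c(0L, 1L, 0L, 1L)
  out <- numeric(4L)
  for (i in 1:4) for (j in 1:4) {
    w <- x[i] * x[j]
    if (w == 0) next
    has_d <- D[i] + D[j] > 0L
    has_s <- S[i] + S[j] > 0L
    expressed <- if (obligate) has_s else (has_s && has_d)
    v <- if (expressed && has_d) 1 - cs
         else if (expressed) 1 - cs       # obligate cost without distorter
         else if (has_d) 1 - ct
         else 1
    # D-locus transmission: drive only in unsuppressed heterozygotes
    p_d1 <- if (D[i] + D[j] == 2L) 1
            else if (D[i] + D[j] == 0L) 0
            else if (has_s) 0.5 else (1 + tval) / 2
    p_s1 <- (S[i] + S[j]) / 2
    for (d in 0:1) for (s in 0:1) {
      pr <- (if (d == 1L) p_d1 else 1 - p_d1) * (if (s == 1L) p_s1 else 1 - p_s1)
      cls <- 2L * d + s + 1L
      out[cls] <- out[cls] + w * v * pr
    }
  }
  out / sum(out)
}

# Six-gamete (resident D1 strength k, mutant D2 strength k_hat):
# gametes 1..6 = D0S0, D0S1, D1S0, D1S1, D2S0, D2S1.
oracle_step_six <- function(x, tr, k, kh, cs,
                            dominance = c("dominant", "additive")) {
  dominance <- match.arg(dominance)
  D <- c(0L, 0L, 1L, 1L, 2L, 2L)
  S <- c(0L, 1L, 0L, 1L, 0L, 1L)
  kv <- c(0, k, kh)
  tv <- c(0, tr$t(k), tr$t(kh))
  cv <- c(0, tr$c_trait(k), tr$c_trait(kh))
  out <- numeric(6L)
  for (i in 1:6) for (j in 1:6) {
    w <- x[i] * x[j]
    if (w == 0) next
    di <- D[i]; dj <- D[j]
    has_d <- di > 0L || dj > 0L
    has_s <- S[i] + S[j] > 0L
    if (has_d && has_s) {
      v <- 1 - cs
      p_i <- 0.5
    } else if (has_d) {
      cost <- if (di == dj) cv[di + 1L]
              else if (dominance == "dominant") {
                cv[(if (kv[di + 1L] >= kv[dj + 1L]) di else dj) + 1L]
              } else {
                (cv[di + 1L] + cv[dj + 1L]) / 2
              }
      v <- 1 - cost
      p_i <- if (di == dj) 0.5 else (1 + tv[di + 1L] - tv[dj + 1L]) / 2
    } else {
      v <- 1
      p_i <- 0.5
    }
    p_s1 <- (S[i] + S[j]) / 2
    dk_opts <- unique(c(di, dj))
    for (dk in dk_opts) {
      pd <- if (di == dj) 1 else if (dk == di) p_i else 1 - p_i
      for (s in 0:1) {
        pr <- pd * (if (s == 1L) p_s1 else 1 - p_s1)
        if (pr == 0) next
        cls <- 2L * dk + s + 1L
        out[cls] <- out[cls] + w * v * pr
      }
    }
  }
  out / sum(out)
}

# random frequency vector on the simplex
random_state <- function(n) {
  x <- runif(n)
  x / sum(x)
}

# finite-difference Jacobian of a map on the frequency simplex (forward
# differences: negative frequencies are outside the maps' domain)
numeric_jacobian <- function(f, x, h = 1e-7) {
  n <- length(x)
  J <- matrix(0, n, n)
  f0 <- f(x)
  for (j in seq_len(n)) {
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

# six-gamete start: resident at q, mutant at eps, suppressor at total s in
# linkage equilibrium, non-distorter D0 retaining the remainder
mutant_intro_state <- function(q, eps = 1e-3, s = 1e-3) {
  d0 <- 1 - q - eps
  x <- c(d0 * (1 - s), d0 * s, q * (1 - s), q * s, eps * (1 - s), eps * s)
  x / sum(x)
}

fig1_response <- function() power_response(0.87, 1, 0.9, 1.5)
fig4_response <- function() power_response(1, 1, 0.5, 1)
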