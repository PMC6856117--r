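#' Trait-distortion response functions
#'
#' A `trait_response` bundles the two functions that characterise a trait
#' distorter of strength `k`: the transmission bias `t(k)` it gains at meiosis
#' in heterozygotes (the distorting allele is transmitted to a proportion
#' `(1 + t(k))/2` of offspring) and the individual viability cost
#' `c_trait(k)` its trait distortion imposes on the carrier. Both functions
#' must map `[0, 1]` into `[0, 1]` and be non-decreasing; the constructor
#' verifies this on a sampled grid and refuses violating inputs.
#'
#' First derivatives are needed for the gene-level optimum [k_target()]. If
#' analytic derivatives are not supplied they are approximated by central
#' differences with step `1e-6` (one-sided at the boundaries).
#'
#' @param transmission_bias function of `k` giving `t(k)`.
#' @param trait_cost function of `k` giving `c_trait(k)`.
#' @param d_transmission,d_cost optional analytic first derivatives.
#' @param grid_n number of grid points used to verify range and monotonicity.
#' @return An object of class `trait_response` with elements `t`, `c_trait`,
#'   `dt`, `dc` (all functions of `k`) and `family`.
#' @seealso [power_response()] for the built-in power-law family.
#' @examples
#' tr <- power_response(0.87, 1, 0.9, 1.5)
#' tr$t(0.3)
#' distorter_invades(tr, 0.3)
#' @export
trait_response <- function(transmission_bias, trait_cost,
                           d_transmission = NULL, d_cost = NULL,
                           grid_n = 201L) {
  stopifnot(is.function(transmission_bias), is.function(trait_cost))
  kk <- seq(0, 1, length.out = grid_n)
  tv <- vapply(kk, transmission_bias, numeric(1))
  cv <- vapply(kk, trait_cost, numeric(1))
  check_response_grid(tv, "transmission bias t(k)")
  check_response_grid(cv, "trait cost c_trait(k)")
  structure(
    list(
      t = function(k) transmission_bias(k),
      c_trait = function(k) trait_cost(k),
      dt = d_transmission %||% numeric_derivative(transmission_bias),
      dc = d_cost %||% numeric_derivative(trait_cost),
      family = "custom"
    ),
    class = "trait_response"
  )
}

#' Power-law trait-response family
#'
#' Builds the power-law family `t(k) = t_coef * k^t_exp`,
#' `c_trait(k) = c_coef * k^c_exp`, with analytic derivatives. This family
#' covers every parameterisation used by the packaged experiments (for
#' example `t = 0.87 k`, `c_trait = 0.9 k^1.5`, or `t = k`, `c_trait = k/2`).
#'
#' @param t_coef,t_exp coefficient and exponent of the transmission bias.
#' @param c_coef,c_exp coefficient and exponent of the trait cost.
#' @return A `trait_response` with `family = "power"` and the coefficients
#'   retained (used by the compiled multilocus simulator).
#' @export
power_response <- function(t_coef, t_exp, c_coef, c_exp) {
  stopifnot(t_coef >= 0, c_coef >= 0, t_exp >= 0, c_exp >= 0,
            t_coef <= 1, c_coef <= 1)
  tr <- trait_response(
    function(k) t_coef * k^t_exp,
    function(k) c_coef * k^c_exp,
    d_transmission = function(k) if (t_exp == 0) 0 * k else t_coef * t_exp * k^(t_exp - 1),
    d_cost = function(k) if (c_exp == 0) 0 * k else c_coef * c_exp * k^(c_exp - 1)
  )
  tr$family <- "power"
  tr$coef <- c(t_coef = t_coef, t_exp = t_exp, c_coef = c_coef, c_exp = c_exp)
  tr
}

#' @export
print.trait_response <- function(x, ...) {
  cat("<trait_response>", if (x$family == "power") {
    sprintf("t(k) = %g k^%g, c_trait(k) = %g k^%g",
            x$coef["t_coef"], x$coef["t_exp"], x$coef["c_coef"], x$coef["c_exp"])
  } else "custom functions", "\n")
  invisible(x)
}

check_response_grid <- function(v, label) {
  if (anyNA(v)) stop(label, " evaluates to NA on [0, 1]")
  if (any(v < -1e-12) || any(v > 1 + 1e-12))
    stop(label, " must lie in [0, 1] for all k in [0, 1]")
  if (any(diff(v) < -1e-10))
    stop(label, " must be non-decreasing on [0, 1]")
  invisible(TRUE)
}

numeric_derivative <- function(f, h = 1e-6) {
  force(f); force(h)
  function(k) {
    lo <- pmax(k - h, 0)
    hi <- pmin(k + h, 1)
    (f(hi) - f(lo)) / (hi - lo)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conflict parameter set
#'
#' Collects the parameters shared by the distorter-suppressor models: the
#' suppression cost `c_sup`, the resident distorter strength `k`, an optional
#' mutant strength `k_hat`, the dominance mode for distorter strength in
#' heterozygotes, and whether the suppressor is expressed facultatively (only
#' when its target distorter is present) or obligately (constitutively).
#'
#' @param c_sup individual fitness cost of expressed suppression, in `[0, 1]`.
#' @param k resident distorter strength in `[0, 1]`.
#' @param k_hat optional mutant distorter strength in `[0, 1]`.
#' @param dominance `"dominant"` (stronger distorter dominant) or `"additive"`.
#' @param suppressor `"facultative"` or `"obligate"`.
#' @return An object of class `conflict_params`.
#' @export
conflict_params <- function(c_sup, k, k_hat = NULL,
                            dominance = c("dominant", "additive"),
                            suppressor = c("facultative", "obligate")) {
  dominance <- match.arg(dominance)
  suppressor <- match.arg(suppressor)
  check_unit_interval(c_sup, "c_sup")
  check_unit_interval(k, "k")
  if (!is.null(k_hat)) check_unit_interval(k_hat, "k_hat")
  structure(list(c_sup = c_sup, k = k, k_hat = k_hat,
                 dominance = dominance, suppressor = suppressor),
            class = "conflict_params")
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a single value in [0, 1]")
  invisible(TRUE)
}

#' Can a trait distorter invade from rarity?
#'
#' A rare dominant distorter of strength `k` invades a population fixed for
#' the non-distorting allele exactly when the offspring it gains through
#' biased transmission outnumber those it loses to reduced viability:
#' `c_trait(k) < t(k) (1 - c_trait(k))` (strict; equality is the neutral
#' knife-edge and returns `FALSE`).
#'
#' @param tr a [trait_response()].
#' @param k distorter strength in `[0, 1]`.
#' @return `TRUE` if the distorter invades from rarity.
#' @export
distorter_invades <- function(tr, k) {
  stopifnot(inherits(tr, "trait_response"))
  check_unit_interval(k, "k")
  cv <- tr$c_trait(k)
  cv < tr$t(k) * (1 - cv)
}

#' Gene-level optimum distorter strength
#'
#' The strength `k_target` towards which successive slightly stronger mutant
#' distorters evolve under delta-weak selection: the root of the
#' marginal-balance equation `dt/dk (1 - c_trait) = dc_trait/dk` (dominant
#' mode), or `2 dt/dk (1 - c_trait) = dc_trait/dk` (additive mode). If the
#' marginal net benefit keeps one sign throughout `(0, 1]`, the corresponding
#' boundary (1 when always beneficial, 0 when never) is returned with a flag.
#' When several roots exist the smallest is returned with a warning.
#'
#' @param tr a [trait_response()].
#' @param mode `"dominant"` or `"additive"`.
#' @param tol absolute root-finding tolerance.
#' @param grid_n grid resolution used to bracket sign changes.
#' @return A list with `k` (the target strength) and `boundary`
#'   (`"none"`, `"upper"` or `"lower"`).
#' @export
k_target <- function(tr, mode = c("dominant", "additive"),
                     tol = 1e-10, grid_n = 1024L) {
  stopifnot(inherits(tr, "trait_response"))
  mode <- match.arg(mode)
  mult <- if (mode == "additive") 2 else 1
  g <- function(k) mult * tr$dt(k) * (1 - tr$c_trait(k)) - tr$dc(k)
  kk <- seq(1e-7, 1, length.out = grid_n)
  gv <- vapply(kk, g, numeric(1))
  eps <- 1e-12
  if (all(gv >= -eps)) return(list(k = 1, boundary = "upper"))
  if (all(gv <= eps)) return(list(k = 0, boundary = "lower"))
  sign_change <- which(gv[-length(gv)] > eps & gv[-1] < -eps)
  if (length(sign_change) == 0L) {
    # fall back to any crossing (e.g. negative-to-positive, non-monotone g)
    sign_change <- which(diff(sign(gv)) != 0)
  }
  if (length(sign_change) > 1L)
    warning("marginal-balance equation has multiple roots; returning the smallest")
  i <- sign_change[1L]
  root <- uniroot(g, lower = kk[i], upper = kk[i + 1L], tol = tol)$root
  list(k = root, boundary = "none")
}

#' Can a mutant trait distorter invade a resident?
#'
#' Invasion of a rare mutant distorter of strength `k_hat` against an
#' unsuppressed resident of strength `k` fixed in the population. In dominant
#' mode (the stronger distorter is dominant) weaker mutants are recessive and
#' can never invade; stronger mutants invade when
#' `dt (1 - c_trait(k_hat)) > dc` where `dt = t(k_hat) - t(k)` and
#' `dc = c_trait(k_hat) - c_trait(k)`. In additive mode the single criterion
#' `dt (2 - c_trait(k) - c_trait(k_hat)) > dc` applies in both directions.
#'
#' @param tr a [trait_response()].
#' @param k resident strength.
#' @param k_hat mutant strength (must differ from `k`).
#' @param mode `"dominant"` or `"additive"`.
#' @return `TRUE` if the mutant invades from rarity.
#' @export
mutant_invades <- function(tr, k, k_hat, mode = c("dominant", "additive")) {
  stopifnot(inherits(tr, "trait_response"))
  mode <- match.arg(mode)
  check_unit_interval(k, "k")
  check_unit_interval(k_hat, "k_hat")
  if (k_hat == k) stop("k_hat must differ from k (not a mutant)")
  dt_ <- tr$t(k_hat) - tr$t(k)
  dc_ <- tr$c_trait(k_hat) - tr$c_trait(k)
  if (mode == "dominant") {
    if (k_hat < k) return(FALSE)
    dt_ * (1 - tr$c_trait(k_hat)) > dc_
  } else {
    dt_ * (2 - tr$c_trait(k) - tr$c_trait(k_hat)) > dc_
  }
}
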