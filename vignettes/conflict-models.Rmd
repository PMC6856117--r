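---
title: "Models of trait-distorter / suppressor conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of trait-distorter / suppressor conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneconflict)
```

## The question the models address

Selfish genetic elements can bias an organism's trait away from the value
that maximises individual fitness in order to gain a transmission advantage.
`geneconflict` models the conflict between such a *trait distorter* — here a
meiotic driver of strength $k$ transmitted to a proportion $(1+t(k))/2$ of a
heterozygote's offspring — and the rest of the genome, which is selected to
silence it. Only the fraction $\theta$ of loci that share the distorter's
transmission interest (its *cabal*) favours the distortion; the remaining
*commonwealth* ($1-\theta$ of loci, always the majority since
$\theta \le 0.5$) supplies dedicated suppressors. The package asks how much
trait distortion individuals actually experience once suppressors are free
to evolve: at single-locus equilibrium, over long evolutionary timescales
with recurrent introductions, and in finite populations with stochastic
mutation and drift.

## Trait-response functions

Every model is parameterised by two monotone non-decreasing maps of
distorter strength $k \in [0,1]$: the transmission bias $t(k) \in [0,1]$ and
the carrier viability cost $c_\mathrm{trait}(k) \in [0,1]$. `trait_response()`
verifies both properties on a 201-point grid and rejects violations;
`power_response(a, b, c, d)` builds the power-law family
$t = a k^b$, $c_\mathrm{trait} = c k^d$ with analytic derivatives, which
covers every parameter set used by the packaged experiments. For custom
functions, derivatives (needed only for the gene-level optimum) default to
central differences with step $10^{-6}$.

Key closed-form results, each exposed as a function and checked against
independent numerics in the test suite:

* **Distorter invasion** (`distorter_invades`): a rare dominant distorter
  spreads iff $c_\mathrm{trait}(k) < t(k)\,(1 - c_\mathrm{trait}(k))$. Fixation is then
  assured (the map's derivative at fixation stays below 1). Strict
  inequality; equality is reported as non-invasion (the knife edge is
  measure zero).
* **Suppressor invasion** (`suppressor_jacobian`): a rare facultative
  suppressor of cost $c_\mathrm{sup}$ invades a distorter-fixed population iff
  $c_\mathrm{trait}(k) > c_\mathrm{sup}$; the stability matrix's leading eigenvalue is
  $(1-c_\mathrm{sup})/(1-c_\mathrm{trait})$.
* **Gene-level optimum** (`k_target`): strength evolves toward the root of
  $\tfrac{dt}{dk}(1 - c_\mathrm{trait}) = \tfrac{dc_\mathrm{trait}}{dk}$ (additive
  heterozygote effects double the left-hand side). Roots are bracketed on a
  1024-point grid and bisected to $10^{-10}$; a one-signed marginal balance
  returns the boundary (0 or 1) with a flag, and multiple roots return the
  smallest with a warning, since the walk from low $k$ stops there.

## Deterministic recursions

`step_single_locus`, `step_two_locus` (gametes $D_0/S_0$, $D_0/S_1$,
$D_1/S_0$, $D_1/S_1$) and `step_three_allele` (adding a mutant distorter
$D_2$ of strength $\hat k$) implement the gamete-frequency recursions with
viability selection, meiotic drive in unsuppressed heterozygotes, free
recombination between the unlinked loci, and normalisation by mean fitness.
The test suite holds each stepper to an independently coded mating-table
enumeration (all ordered gamete pairings × Mendelian/driven meiosis ×
genotype viabilities) at $10^{-12}$ on random states.

Conventions worth stating:

* **Facultative vs obligate suppression.** The default suppressor is
  expressed only when its target distorter is present; `suppressor = "obligate"`
  additionally charges $c_\mathrm{sup}$ to suppressor carriers with no distorter
  (the only three terms of the recursions that change). At equilibrium the
  facultative system purges the distorter with the suppressor at an internal
  frequency, while the obligate system fixes the suppressor and retains the
  distorter in a silenced, neutral state — both outcomes are asserted in the
  tests.
* **Dominance of the stronger distorter.** In $D_1 D_2$ heterozygotes the
  stronger allele sets the trait cost ($c_\mathrm{trait}(\max(k,\hat k))$) and the
  drive difference $t(\hat k) - t(k)$ sets transmission. Under
  `dominance = "additive"` heterozygote costs are the mean of the two allele
  costs (a non-distorting allele costing 0), which reproduces the additive
  invasion criterion
  $\Delta t\,(2 - c_\mathrm{trait}(k) - c_\mathrm{trait}(\hat k)) > \Delta c_\mathrm{trait}$ as the
  leading-eigenvalue condition at the resident-fixed equilibrium — the
  cross-check test derives the eigenvalue numerically from the recursions.
* **Introduction from rarity.** Defaults: distorters at $10^{-6}$,
  suppressors at $10^{-3}$ split evenly between distorter and non-distorter
  backgrounds (`introduce_suppressor`). The purge-time analysis
  (`time_to_purge`) introduces both simultaneously; the equilibrium analyses
  let the distorter reach a frequency $f$ (default 0.99) first. Outcomes are
  threshold-driven and insensitive to these values, with one numerical
  caveat below.
* **Convergence and purging.** Equilibrium iteration stops when the largest
  per-class change falls below $10^{-12}$; a distorter counts as purged when
  $x_{10}+x_{11} < 10^{-9}$; purge runs are capped at $2\times 10^7$
  generations (reported as capped — near the suppression threshold the true
  purge time genuinely exceeds any practical cap).

**Numerical caveat: extinction by underflow.** Frequencies that the exact
dynamics keep infinitesimally positive can reach 0 (or `1 - p` can reach 0)
in double precision, after which selection can no longer act on them. Two
places handle this explicitly. First, the long-term cycle restores the
non-distorter allele at a floor of $10^{-9}$ when a long suppressor lag has
rounded the distorter to fixation (`residual` argument of `cycle_exact`).
Second, when suppression is introduced at extreme rarity ($10^{-6}$) the
non-distorter background can underflow before the suppressor equilibrates,
so the system reaches the silenced rather than allelically purged
equilibrium; expressed distortion still vanishes, and the phenotypic purge
criterion (`dist_tol`) captures that.

## The long-term cycle model

With recurrent introductions, a distorter of strength $k$ arises somewhere
in the cabal every $1/(\theta\gamma\rho_{D_1})$ generations and its
dedicated suppressor follows $1/((1-\theta)\gamma\rho_{S_1})$ generations
later (`genome_architecture`; both rates scale with the baseline mutation
rate $\rho$). `cycle_exact` runs one cycle: the single-locus sweep for the
lag (rounded to whole generations), then the two-locus phase until the
distorter is purged at generation $X$ — by allele loss or, when the
distorter fixed during the lag, by loss of expressed distortion (the
phenotypic criterion above; the cycle's accounting is identical either way
because each cycle concerns a fresh locus). Population mean distortion per
generation is $k \cdot P(\text{carries an unsuppressed distorter})$ under
random gamete union. The evolutionary-time average weights the cycle mean
by the fraction of time a distorter segregates, $X\theta\gamma\rho_{D_1}$,
and is compared to the separation-of-timescales closed form
$$\bar D \;=\; \frac{k\,\theta\,\rho_{D_1}}{(1-\theta)\,\rho_{S_1}},$$
in which genome size and baseline mutation rate cancel
(`average_distortion_approx`; the unsuppressed regime
$c_\mathrm{sup} > c_\mathrm{trait}(k)$ trivially averages $k$). The tests freeze a 25%
relative-error band for the exact-vs-closed-form comparison across
$k \in [0.3, 0.9]$, $\theta \in \{0.1, 0.3, 0.5\}$, and require the error to
shrink monotonically as both introduction rates are scaled down three
decades. At the headline parameter set
($\rho_{D_1}=\rho_{S_1}=10^{-11}$, $\gamma=10^6$, $\theta=0.5$, $k=0.6$) the
cycle slightly overruns the introduction interval
($X\theta\gamma\rho_{D_1}\approx 1.7$); `cycle_exact` warns and proceeds,
as the peak/trough structure is unaffected.

## Agent-based simulators

### Single locus (`run_single_locus`)

$N$ hermaphroditic diploids with continuous allele strengths at one
distorter and one suppressor locus; the stronger allele within each locus
is dominant. Each generation, $2N$ fitness-proportional draws with
replacement form $N$ breeding pairs (selfing permitted under the literal
sampling rule; a `no_selfing` flag redraws coincident pairs), each pair
leaves one offspring, and generations do not overlap. Fitness is
$1 - c_\mathrm{trait}(\max(k_a,k_b))(1-\max(m_a,m_b)) - c_\mathrm{sup}\max(m_a,m_b)$ for
distorter carriers and 1 otherwise; the $k_a$ allele is transmitted with
probability $(1 + (t(k_a)-t(k_b))(1-\max(m_a,m_b)))/2$ while suppressor
alleles are Mendelian. Alleles mutate with probability 0.01 per generation
to a normal deviate around their value (variance 0.2) truncated to $[0,1]$
by clamping — a `resample` option exists and does not change the headline
behaviour, as clamping merely concentrates some mass on the boundaries.
With mutation off and strengths pinned to $\{0,k\}$ and $\{0,1\}$ the
simulator is a finite-population image of the two-locus recursions; a test
at $N = 20{,}000$ holds six replicate means to the deterministic trajectory
within three Monte-Carlo standard errors at four checkpoints over 200
generations.

### Genome-wide (`run_multilocus`)

The compiled simulator holds only *activated* loci (genotypes stored
individual-major so that the phenotype scan, meiosis and parental reads are
contiguous). Each generation a binomial number of dormant cabal loci
activate (probability $\rho_{D_1}$ per locus), each seeding one functional
allele in one random individual; commonwealth loci activate at $\rho_{S_1}$
only while some distorter lacks its dedicated suppressor, pairing with the
oldest unmatched cabal locus. In discrete mode alleles flip
functional/neutral at 0.001 per generation; in continuous mode strengths
evolve under the 0.01/variance-0.2 kernel, and a newly activated locus
seeds $|N(0, 0.2)|$ truncated to $[0,1]$ (one kernel step away from
neutral).

Within an individual, a suppressor is expressed only if its target locus
carries a distorter; total suppression is $\mathrm{TotSup}_i = 1$ with the
dedicated suppressor present, else $\min(zq, 1)$ over the $q$ expressed
suppressors (discrete), or
$\min(\max(m_{ai},m_{bi}) + z\sum_{j\ne i}\max(m_{aj},m_{bj}),\,1)$
(continuous). The background fraction is $z = 0.5$ for low-sophistication
distorters and $z = 0$ for high-sophistication ones. The least-suppressed
distorter is inter-locus dominant:
$\mathrm{Dist} = \max_i (1-\mathrm{TotSup}_i)k_i$ (ties to the lowest
index, for determinism), the rest contribute
$\mathrm{Waste} = \sum_{i \ne i_\mathrm{dom}} (1-\mathrm{TotSup}_i)k_i$, and fitness is
$1 - c_\mathrm{trait}(\mathrm{Dist}) - c_\mathrm{rec}(\mathrm{Waste}) - c_\mathrm{sup}\sum_i \mathrm{TotSup}_i$,
clamped at 0 for sampling (clamp events are counted and reported). The
waste cost applies the trait-cost curve to the waste load,
$c_\mathrm{rec}(W) = r\,c_\mathrm{trait}(W)$ with $r = 1$ (low sophistication) or $3/5$
(high): one unsuppressed inter-locus-recessive distorter then costs exactly
$r\,c_\mathrm{trait}(\mathrm{Dist})$ under the linear cost the genome-wide
experiments use, and a fully suppressed background distorter adds no waste
cost (it still incurs its $c_\mathrm{sup}$ term). All heterozygous distorter loci
drive through meiosis as one unit pulled by the least-suppressed member,
with probability $(1 + \max_i (1-\mathrm{TotSup}_i)\,|k_{ai}-k_{bi}|)/2$ of
transmitting the stronger allele at every such locus; suppressor loci
segregate independently. Drive probabilities use allele strengths directly
(the genome-wide experiments set $t = k$), so the engine takes only the
trait-cost power law. Mutation events are drawn as a binomial count of
slots with replacement; at the modelled rates the collision probability is
negligible relative to Monte-Carlo noise.

**An emergent behaviour worth knowing about.** Because functional/neutral
flips are symmetric, distorter alleles at long-suppressed loci drift toward
50% occupancy instead of disappearing. Their dedicated suppressors
therefore remain widely expressed, and under background suppression
($z = 0.5$) newly arising distorters face $\min(zq,1)$ silencing from birth
once a few loci have accumulated. A $z = 0$ control confirms this is the
mechanism, and it is exactly why low-sophistication distortion *falls* with
genome size while high-sophistication distortion *rises* (their
co-segregation is productive: overlapping unsuppressed distorters keep
expressed distortion high through purge phases). It also means the
closed-form $\bar D$ is recovered by the stochastic model only while few
loci have accumulated; the corresponding test separates timescales cleanly
(suppressor lag 1000 generations against ~100-generation sweeps, arrivals
every 10,000 generations) and uses the frozen 25% band plus four replicate
standard errors.

## What the simulations do and do not emulate

The generators reproduce the study conditions: hermaphroditic random
mating, non-overlapping generations, unlinked autosomal loci, dominant
suppression, fixed per-locus activation probabilities, and the printed
parameter sets ($N = 2000$, $T = 20{,}000$–$30{,}000$, mutation 0.01 with
variance 0.2, flips at 0.001, $c_\mathrm{sup}$ of 0.01–0.15). They do not model
linkage, sexes or mating structure, overlapping generations, spatial
structure, frequency-dependent $t$ or $c_\mathrm{trait}$, or sequence-level
dormant-locus evolution (activation collapses the drift-to-one-step-away
process into a single event). Passing tests therefore speak to the
population-genetic logic of distorter-suppressor conflict, not to any
organism-specific prediction.

## Problem sizes used by the packaged checks

The test suite and acceptance script run the deterministic analyses at full
precision and the stochastic ones at desk scale, chosen once: the
genome-size experiment at $N = 1000$, 20,000 generations,
$\gamma \in \{10^5, 10^6, 10^7\}$ with 10 replicates at the smallest genome
(whose few-cycle noise is largest and runtime smallest) and 5 elsewhere;
the single-locus collapse at 3 replicates × 20,000 generations; the
recursion-tracking check at 6 replicates of $N = 20{,}000$ over 200
generations. `run_experiment()` exposes the full-scale configurations
(e.g. 36 replicates × 30,000 generations for the genome-size experiment)
through its `scale` argument.

## Known limitations

* The quasi-stationary phase of a near-threshold purge is extremely slow;
  purge times just above $c_\mathrm{trait}(k) = c_\mathrm{sup}$ are reported as capped at
  $2\times 10^7$ generations rather than resolved.
* Post-invasion equilibria of the three-allele system are numerically
  reachable only when the suppressor sweep outpaces drive-driven loss of
  the non-distorter background; otherwise the system settles into the
  silenced suppressor-fixed state (see the underflow caveat). Both states
  carry zero expressed distortion.
* `c_rec` applied to Waste matches the stated per-distorter identities
  exactly for a linear trait cost; for non-linear costs no single-argument
  function of Waste can satisfy them at every distorter count, and the
  waste-load form is the package's chosen generalisation.
* The multilocus engine requires the power-law cost family; arbitrary cost
  callables are supported everywhere else.
* The genome-size trend for high-sophistication distorters at a large cabal
  is hump-shaped rather than monotone in this implementation: average
  distortion rises from $\gamma = 10^5$ to $10^6$ but not on to $10^7$,
  where dedicated suppressors arrive within ~50 generations of each
  distorter and truncate its unsuppressed window faster than co-segregation
  compensates, while at $\gamma = 10^5$ rare, very long unsuppressed waits
  prop the average up. The endpoint comparison in the test suite records
  this directly (the low-sophistication decrease and the near-flatness at a
  small cabal both reproduce).
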