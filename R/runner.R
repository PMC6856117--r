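#' Mean and standard error over replicate runs
#'
#' @param x numeric vector of per-replicate values (at least 2).
#' @return A list with `mean`, `se` (sample SD over `sqrt(n)`) and `n`.
#' @export
summarize_replicates <- function(x) {
  if (length(x) < 2L) stop("at least 2 replicates are needed for a standard error")
  list(mean = mean(x), se = sd(x) / sqrt(length(x)), n = length(x))
}

experiment_ids <- c("fig1a", "fig1b", "fig2a", "fig2b",
                    "fig4a", "fig4b", "fig5a", "fig5b")

#' Run a packaged experiment
#'
#' Regenerates the computational content of the package's headline analyses
#' from their caption parameter sets, producing tidy tables:
#'
#' * `fig1a`: equilibrium mean trait distortion against distorter strength
#'   `k` (`c_sup = 0.15`, `t = 0.87 k`, `c_trait = 0.9 k^1.5`), showing the
#'   discontinuity at the suppression threshold `c_trait(k) = c_sup`.
#' * `fig1b`: log10 generations from distorter introduction to purging, for
#'   strengths above the threshold (same parameters).
#' * `fig2a`: replicate-averaged `E[k]`, `E[m]` trajectories of the
#'   single-locus agent-based model (`c_sup = 0.1`, `t = k`,
#'   `c_trait = max(ka, kb)/2`).
#' * `fig2b`: equilibrium distortion over a grid of suppression cost and
#'   target strength (cost family `c_trait = k^beta`, `t = k`).
#' * `fig4a`: the deterministic introduction-suppression cycle time series
#'   (`c_sup = 0.1`, `t = k`, `c_trait = k/2`, `rho_S1 = rho_D1 = 1e-11`,
#'   `gamma = 1e6`, `theta = 0.5`, `k = 0.6`).
#' * `fig4b`: average distortion against `k` for
#'   `theta` in `{0.1, 0.3, 0.5}` (same parameters), exact cycle solution.
#' * `fig5a`/`fig5b`: genome-wide simulation average distortion against
#'   genome size for low/high-sophistication distorters
#'   (`c_sup = 0.01`, `c_trait = Dist/2`, `rho_S1 = 4e-9`,
#'   `rho_D1 = 4e-9` (low) or `2e-9` (high), `k = 0.5`,
#'   `theta` in `{0.1, 0.5}`).
#'
#' @param id experiment identifier (see above).
#' @param scale multiplier applied to replicate counts and (for the
#'   stochastic experiments) generation counts, for desk-scale runs.
#' @param seed base seed for stochastic engines.
#' @param out_dir if non-NULL, tables are written there as CSV together with
#'   a JSON manifest of the resolved configuration.
#' @param overrides named list of configuration overrides (e.g.
#'   `list(gamma_values = c(1e5, 1e6))`).
#' @return A list with `tables` (named data.frames), `config` (the resolved
#'   configuration) and `config_hash`.
#' @export
run_experiment <- function(id, scale = 1, seed = 1, out_dir = NULL,
                           overrides = list()) {
  if (!id %in% experiment_ids)
    stop("unknown experiment id '", id, "'; available: ",
         paste(experiment_ids, collapse = ", "))
  runner <- switch(id,
    fig1a = exp_fig1a, fig1b = exp_fig1b,
    fig2a = exp_fig2a, fig2b = exp_fig2b,
    fig4a = exp_fig4a, fig4b = exp_fig4b,
    fig5a = function(scale, seed, ov) exp_fig5(scale, seed, ov, "low"),
    fig5b = function(scale, seed, ov) exp_fig5(scale, seed, ov, "high"))
  res <- runner(scale, seed, overrides)
  res$config <- c(list(experiment = id, scale = scale, seed = seed),
                  res$config)
  res$config_hash <- config_hash(res$config)
  for (nm in names(res$tables))
    attr(res$tables[[nm]], "config_hash") <- res$config_hash
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$tables))
      write.csv(res$tables[[nm]],
                file.path(out_dir, paste0(id, "_", nm, ".csv")),
                row.names = FALSE)
    manifest <- c(res$config,
                  list(config_hash = res$config_hash,
                       package_version = as.character(utils::packageVersion("geneconflict"))))
    jsonlite::write_json(manifest, file.path(out_dir, paste0(id, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

merge_config <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# equilibrium mean distortion for one k: distorter invades alone, suppressor
# introduced at frequency f, two-locus system iterated to equilibrium
equilibrium_distortion <- function(tr, c_sup, k, f = 0.99, p0 = 1e-6,
                                   s0 = 1e-3, max_gen = 2e7) {
  if (!distorter_invades(tr, k)) return(0)
  res1 <- iterate_single_locus(p0, tr, k, tol = 1e-12, max_gen = max_gen)
  if (res1$p < f) {  # distorter equilibrated below f: use its equilibrium
    p <- res1$p
  } else {
    p <- p0
    while (p < f) p <- step_single_locus(p, tr, k)
  }
  x0 <- introduce_suppressor(p, s0)
  params <- conflict_params(c_sup, k)
  res <- iterate_two_locus(x0, tr, params, tol = 1e-12, max_gen = max_gen,
                           record = TRUE)
  d <- res$distortion
  d[length(d)]
}

exp_fig1a <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup = 0.15, t_coef = 0.87, t_exp = 1,
                           c_coef = 0.9, c_exp = 1.5,
                           k_values = seq(0.05, 0.95, by = 0.05)), ov)
  tr <- power_response(cfg$t_coef, cfg$t_exp, cfg$c_coef, cfg$c_exp)
  dist <- vapply(cfg$k_values, function(k)
    equilibrium_distortion(tr, cfg$c_sup, k), numeric(1))
  tab <- data.frame(k = cfg$k_values, distortion = dist,
                    suppressed = tr$c_trait(cfg$k_values) > cfg$c_sup)
  list(tables = list(equilibrium_distortion = tab), config = cfg)
}

exp_fig1b <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup = 0.15, t_coef = 0.87, t_exp = 1,
                           c_coef = 0.9, c_exp = 1.5,
                           k_values = seq(0.35, 0.95, by = 0.1)), ov)
  tr <- power_response(cfg$t_coef, cfg$t_exp, cfg$c_coef, cfg$c_exp)
  ks <- cfg$k_values[tr$c_trait(cfg$k_values) > cfg$c_sup]
  gens <- vapply(ks, function(k)
    as.numeric(time_to_purge(tr, conflict_params(cfg$c_sup, k))), numeric(1))
  tab <- data.frame(k = ks, generations = gens, log10_generations = log10(gens))
  list(tables = list(purge_time = tab), config = cfg)
}

exp_fig2a <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup = 0.1, t_coef = 1, t_exp = 1,
                           c_coef = 0.5, c_exp = 1,
                           N = 2000L, T_end = 20000L, n_rep = 20L), ov)
  n_rep <- max(1L, round(cfg$n_rep * scale))
  T_end <- max(100L, round(cfg$T_end * scale))
  tr <- power_response(cfg$t_coef, cfg$t_exp, cfg$c_coef, cfg$c_exp)
  traj <- run_single_locus_reps(n_rep, seed, tr = tr, c_sup = cfg$c_sup,
                                N = cfg$N, T_end = T_end,
                                record_every = max(1L, T_end %/% 2000L))
  attr(traj, "replicates") <- NULL
  list(tables = list(trajectory = traj),
       config = c(cfg, list(n_rep_used = n_rep, T_end_used = T_end)))
}

exp_fig2b <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup_values = seq(0.05, 0.5, by = 0.05),
                           beta_values = seq(1.2, 3, by = 0.2),
                           delta = 0.005), ov)
  grid <- expand.grid(c_sup = cfg$c_sup_values, beta = cfg$beta_values,
                      KEEP.OUT.ATTRS = FALSE)
  kt <- numeric(nrow(grid)); dist <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- power_response(1, 1, 1, grid$beta[i])
    ktar <- k_target(tr)$k
    kt[i] <- ktar
    # evolved distorter of strength k_target: suppressed (and purged) iff
    # c_trait(k_target) exceeds the suppression cost
    dist[i] <- if (tr$c_trait(ktar) > grid$c_sup[i]) 0 else ktar
  }
  tab <- cbind(grid, k_target = kt, distortion = dist)
  list(tables = list(distortion_grid = tab), config = cfg)
}

fig4_genome <- function(cfg, theta) {
  genome_architecture(cfg$gamma, theta, cfg$rho_D1, cfg$rho_S1)
}

exp_fig4a <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup = 0.1, t_coef = 1, t_exp = 1,
                           c_coef = 0.5, c_exp = 1,
                           rho_D1 = 1e-11, rho_S1 = 1e-11, gamma = 1e6,
                           theta = 0.5, k = 0.6, record_every = 100L), ov)
  tr <- power_response(cfg$t_coef, cfg$t_exp, cfg$c_coef, cfg$c_exp)
  cyc <- cycle_exact(fig4_genome(cfg, cfg$theta), tr,
                     conflict_params(cfg$c_sup, cfg$k), cfg$k)
  idx <- seq(1L, length(cyc$series), by = cfg$record_every)
  tab <- data.frame(generation = idx, mean_distortion = cyc$series[idx])
  summ <- data.frame(lag = cyc$lag, purge_generation = cyc$purge_generation,
                     peak = cyc$peak, trough = cyc$trough,
                     cycle_average = cyc$cycle_average,
                     evo_average = cyc$evo_average)
  list(tables = list(cycle_series = tab, cycle_summary = summ), config = cfg)
}

exp_fig4b <- function(scale, seed, ov) {
  cfg <- merge_config(list(c_sup = 0.1, t_coef = 1, t_exp = 1,
                           c_coef = 0.5, c_exp = 1,
                           rho_D1 = 1e-11, rho_S1 = 1e-11, gamma = 1e6,
                           theta_values = c(0.1, 0.3, 0.5),
                           k_values = seq(0.1, 0.9, by = 0.1),
                           method = "exact"), ov)
  tr <- power_response(cfg$t_coef, cfg$t_exp, cfg$c_coef, cfg$c_exp)
  tab <- distortion_surface(fig4_genome(cfg, cfg$theta_values[1L]), tr,
                            cfg$c_sup, cfg$k_values, cfg$theta_values,
                            method = cfg$method)
  list(tables = list(surface = tab), config = cfg)
}

exp_fig5 <- function(scale, seed, ov, sophistication) {
  rho_D_default <- if (sophistication == "low") 4e-9 else 2e-9
  cfg <- merge_config(list(c_sup = 0.01, c_coef = 0.5, c_exp = 1,
                           rho_S1 = 4e-9, rho_D1 = rho_D_default,
                           k = 0.5, N = 2000L, T_end = 30000L,
                           n_rep = 36L,
                           gamma_values = c(1e5, 1e6, 1e7),
                           theta_values = c(0.1, 0.5)), ov)
  n_rep <- max(2L, round(cfg$n_rep * scale))
  T_end <- max(1000L, round(cfg$T_end * scale))
  tr <- power_response(1, 1, cfg$c_coef, cfg$c_exp)
  grid <- expand.grid(gamma = cfg$gamma_values, theta = cfg$theta_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- genome_architecture(grid$gamma[i], grid$theta[i],
                             cfg$rho_D1, cfg$rho_S1)
    r <- run_multilocus_reps(n_rep, seed + 1000L * i, genome = g, tr = tr,
                             c_sup = cfg$c_sup, k = cfg$k, mode = "discrete",
                             sophistication = sophistication,
                             N = cfg$N, T_end = T_end)
    data.frame(gamma = grid$gamma[i], theta = grid$theta[i],
               sophistication = sophistication,
               mean_distortion = r$mean, se = r$se, n_rep = n_rep)
  })
  list(tables = list(distortion_vs_gamma = do.call(rbind, rows)),
       config = c(cfg, list(sophistication = sophistication,
                            n_rep_used = n_rep, T_end_used = T_end)))
}
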