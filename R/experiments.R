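#' Named, reproducible experiments
#'
#' Each experiment maps one figure-style protocol onto the package's
#' operations and returns tidy tables. Default parameters are the
#' figure-scale values (N_x = N_y = N_z = 1000, alpha = beta = 1, many runs);
#' the `"desk"` scale preset substitutes reduced sizes (N = 250,
#' n_runs = 50) so every experiment runs in minutes on one CPU.
#'
#' @return `list_experiments()` returns the registered experiment names.
#' @export
list_experiments <- function() names(experiment_registry())

experiment_registry <- function() {
  list(
    fig1d = exp_fig1d, fig2b = exp_fig2b, fig2c = exp_fig2c,
    fig2d = exp_fig2d, fig2e = exp_fig2e, fig3c = exp_fig3c,
    fig3d = exp_fig3d, fig4a = exp_fig4a, fig4b = exp_fig4b,
    fig4d = exp_fig4d, fig5b = exp_fig5b, fig5c = exp_fig5c,
    fig6c = exp_fig6c, fig6d = exp_fig6d,
    suppfig1 = exp_suppfig1, suppfig2 = exp_suppfig2,
    suppfig3 = exp_suppfig3, suppfig4 = exp_suppfig4,
    suppfig6 = exp_suppfig6)
}

desk_defaults <- function() list(N_x = 250, N_y = 250, N_z = 100, n_runs = 50)

#' Run a named experiment
#'
#' Dispatches to the owning module, optionally writing one CSV per result
#' table, a JSON manifest echoing the fully resolved configuration (from
#' which [rerun_manifest()] reproduces the run), and a timing log.
#'
#' @param name experiment name, see [list_experiments()].
#' @param seed root seed.
#' @param params named list of parameter overrides (validated against the
#'   experiment's defaults).
#' @param scale `"full"` (figure-scale defaults) or `"desk"` (reduced).
#' @param out_dir optional output directory.
#' @return list with `tables` (named data frames), `config`, and `timings`.
#' @export
run_experiment <- function(name, seed = 1, params = list(),
                           scale = c("full", "desk"), out_dir = NULL) {
  reg <- experiment_registry()
  if (!name %in% names(reg))
    stop_invalid("unknown experiment '%s'; available: %s", name,
                 paste(names(reg), collapse = ", "))
  scale <- match.arg(scale)
  fn <- reg[[name]]
  defaults <- formals(fn)$defaults
  defaults <- eval(defaults)
  if (scale == "desk")
    defaults <- modifyList(defaults,
                           desk_defaults()[names(desk_defaults()) %in%
                                             names(defaults)])
  bad <- setdiff(names(params), names(defaults))
  if (length(bad) > 0)
    stop_invalid("invalid parameter(s) for '%s': %s", name,
                 paste(bad, collapse = ", "))
  config <- modifyList(defaults, params)
  t0 <- proc.time()[["elapsed"]]
  tables <- fn(seed = seed, defaults = config)
  elapsed <- proc.time()[["elapsed"]] - t0
  out <- list(tables = tables,
              config = list(experiment = name, seed = seed, scale = scale,
                            params = config,
                            package_version =
                              as.character(utils::packageVersion("twopathway"))),
              timings = data.frame(stage = name, seconds = elapsed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      write.csv(tables[[nm]], file.path(out_dir, paste0(name, "_", nm, ".csv")),
                row.names = FALSE)
    jsonlite::write_json(out$config,
                         file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(sprintf("%s: %.2f s (seed %d)", name, elapsed, seed),
               file.path(out_dir, paste0(name, "_log.txt")))
  }
  out
}

#' Re-run an experiment from its emitted manifest
#'
#' @param manifest_path path to a `*_manifest.json` written by
#'   [run_experiment()].
#' @param out_dir optional output directory for the re-run.
#' @return as [run_experiment()].
#' @export
rerun_manifest <- function(manifest_path, out_dir = NULL) {
  cfg <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  params <- cfg$params
  # block_schedule round-trips as a data frame for the reaching experiments
  if (!is.null(params$block_schedule))
    params$block_schedule <- as.data.frame(params$block_schedule)
  run_experiment(cfg$experiment, seed = cfg$seed, params = params,
                 scale = cfg$scale, out_dir = out_dir)
}

# ---- experiment implementations --------------------------------------------

exp_fig1d <- function(seed, defaults = list(N_x = 1000, P_ratio = 2,
                                            n_runs = 1000)) {
  d <- defaults
  cv <- estimate_forgetting_curve(d$N_x, as.integer(d$P_ratio * d$N_x),
                                  d$n_runs, seed = seed)
  th <- theory_curve(cv$tau)
  list(simulation = as.data.frame(cv), theory = as.data.frame(th))
}

exp_suppfig1 <- function(seed, defaults = list(N_x = 250, P_ratio = 2,
                                               n_runs = 200,
                                               learning_rate = 0.05,
                                               n_steps = 100)) {
  d <- defaults
  cv <- estimate_gd_forgetting_curve(d$N_x, as.integer(d$P_ratio * d$N_x),
                                     d$n_runs, seed = seed,
                                     learning_rate = d$learning_rate,
                                     n_steps = d$n_steps)
  list(simulation = as.data.frame(cv))
}

two_curve_tables <- function(res) {
  out <- list(unrepeated = as.data.frame(res$unrepeated))
  if (!is.null(res$repeated)) out$repeated <- res$repeated
  out
}

exp_fig2b <- function(seed, defaults = list(N_x = 1000, N_y = 1000, alpha = 1,
                                            beta = 1, n_repeats = 10,
                                            n_repeated_patterns = 6,
                                            n_runs = 100)) {
  d <- defaults
  P <- 2L * (d$N_x + d$N_y) %/% 2L + d$N_x  # ~ N_x + N_y lag for early patterns
  lags <- round(seq(0.55, 0.95, length.out = d$n_repeated_patterns) * P)
  repeated <- stats::setNames(as.list(rep(d$n_repeats,
                                          d$n_repeated_patterns)),
                              as.character(lags))
  res <- estimate_two_pathway_forgetting_curve(
    d$N_x, d$N_y, d$alpha, d$beta, P = P, repeated = repeated,
    n_runs = d$n_runs, seed = seed)
  base <- estimate_two_pathway_forgetting_curve(
    d$N_x, d$N_y, d$alpha, d$beta, P = P, n_runs = d$n_runs,
    seed = seed + 1)
  c(two_curve_tables(res), list(no_repeats = as.data.frame(base$unrepeated)))
}

exp_fig2c <- function(seed, defaults = list(N_x = 500, N_y = 500, alpha = 1,
                                            beta = 1,
                                            n_rep_grid = c(1, 2, 5, 10, 20),
                                            tau_grid = c(0.25, 0.5, 1, 1.5, 2),
                                            n_runs = 100)) {
  d <- defaults
  rows <- list()
  for (n in d$n_rep_grid) {
    for (tt in d$tau_grid) {
      lag <- as.integer(round(tt * d$N_x))
      res <- estimate_two_pathway_forgetting_curve(
        d$N_x, d$N_y, d$alpha, d$beta, P = lag + 1L,
        repeated = stats::setNames(list(n), as.character(lag)),
        n_runs = d$n_runs, seed = seed + n * 1000L + lag)
      err <- if (n > 1) res$repeated$error[1] else
        res$unrepeated$error[res$unrepeated$tau == lag / d$N_x]
      rows[[length(rows) + 1L]] <-
        data.frame(n_rep = n, tau = tt, error = err,
                   theory = theoretical_error_two_pathway(
                     tt, d$N_y / d$N_x, d$alpha, d$beta, n))
    }
  }
  list(errors = do.call(rbind, rows))
}

exp_fig2d <- function(seed, defaults = list(N_x = 500, N_y = 500, alpha = 1,
                                            beta = 1,
                                            n_rep_grid = c(1, 2, 4, 8, 16, 32),
                                            tau = 1, n_runs = 100)) {
  d <- defaults
  d$tau_grid <- d$tau
  d$n_rep_grid <- d$n_rep_grid
  exp_fig2c(seed, defaults = d[c("N_x", "N_y", "alpha", "beta", "n_rep_grid",
                                 "tau_grid", "n_runs")])
}

exp_fig2e <- function(seed, defaults = list(N_x = 250, N_y = 250, alpha = 1,
                                            beta = 1,
                                            intervals = c(125, 250, 500, 750),
                                            p_theta = 0.1, n_runs = 100,
                                            n_cap = 512)) {
  d <- defaults
  rows <- lapply(d$intervals, function(iv) {
    r <- repetitions_to_threshold(d$N_x, d$N_y, d$alpha, d$beta,
                                  interval = iv, p_theta = d$p_theta,
                                  n_runs = d$n_runs, seed = seed + iv,
                                  n_cap = d$n_cap)
    data.frame(interval = iv, n_required = r$n, attained = r$attained)
  })
  list(repetitions = do.call(rbind, rows))
}

exp_fig3c <- function(seed, defaults = list(N_x = 1000, N_y = 1000,
                                            N_z = 1000, alpha = 1, beta = 1,
                                            n_reps = 20, n_networks = 10,
                                            burn_P = 500)) {
  d <- defaults
  traces <- lapply(seq_len(d$n_networks), function(k) {
    ens <- generate_patterns(d$burn_P + 1L, d$N_x, d$N_y, d$N_z,
                             seed = seed + k)
    st <- two_pathway_state(d$N_x, d$N_y, d$N_z, d$alpha, d$beta)
    st <- train_two_pathway(ens, st)$state
    mu <- d$burn_P + 1L
    pr <- present_pattern(st, ens$X[mu, ], ens$Y[mu, ], ens$Zhat[mu, ],
                          n = d$n_reps)
    cbind(network = k, pr$trace)
  })
  tr <- do.call(rbind, traces)
  agg <- stats::aggregate(tr[c("alignment", "control_ratio")],
                          by = list(rep = tr$rep), FUN = mean)
  list(trace = agg)
}

exp_fig3d <- function(seed, defaults = list(N_x = 1000, N_y = 1000,
                                            N_z = 250, alpha = 1, beta = 1,
                                            P = 1000, repeated_lag = 500,
                                            n_repeats = 10, n_networks = 20)) {
  d <- defaults
  rows <- list()
  for (k in seq_len(d$n_networks)) {
    ens <- generate_patterns(d$P, d$N_x, d$N_y, d$N_z, seed = seed + k)
    sch <- make_repetition_schedule(
      d$P, special = stats::setNames(list(d$n_repeats),
                                     as.character(d$P - d$repeated_lag)))
    ens <- set_schedule(ens, sch)
    st <- two_pathway_state(d$N_x, d$N_y, d$N_z, d$alpha, d$beta,
                            nbar = ens$nbar)
    st <- train_two_pathway(ens, st)$state
    for (mode in c("intact", "m_zero", "h_zero")) {
      lt <- lesion_test(st, ens, mode)
      rows[[length(rows) + 1L]] <-
        data.frame(network = k, mode = mode, pattern = lt$pattern,
                   lag = d$P - lt$pattern,
                   repeated = lt$pattern == d$P - d$repeated_lag,
                   error = lt$error)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab["error"],
                          by = tab[c("mode", "repeated", "lag")], FUN = mean)
  list(errors = agg)
}

rl_alignment_tables <- function(seed, variant, defaults) {
  d <- defaults
  seeds <- child_seeds(seed, 2)
  set.seed(seeds[1])
  x <- rnorm(d$N_x); y <- rnorm(d$N_y); zhat <- sgn(runif(d$N_z) - 0.5)
  st <- rl_state(d$N_x, d$N_y, d$N_z, eta = d$eta, eta2 = d$eta2,
                 beta = d$beta, variant = variant)
  res <- train_rl(st, x, y, zhat, d$n_trials, seed = seeds[2])
  robust <- data.frame(
    drop = c("none", "m", "h"),
    match_fraction = vapply(c("none", "m", "h"), function(dr)
      rl_match_fraction(res$state, x, y, zhat, drop = dr), numeric(1)))
  list(traces = res$traces, lesion = robust)
}

exp_fig4a <- function(seed, defaults = list(N_x = 1000, N_y = 1000, N_z = 10,
                                            eta = 1, eta2 = 0.01, beta = 0.01,
                                            n_trials = 3000)) {
  rl_alignment_tables(seed, "RL_plus_HL", defaults)
}

exp_fig4b <- function(seed, defaults = list(N_x = 1000, N_y = 1000, N_z = 10,
                                            eta = 1, eta2 = 0.01, beta = 0.01,
                                            n_trials = 3000)) {
  rl_alignment_tables(seed, "RL_plus_RL", defaults)
}

exp_fig4d <- function(seed, defaults = list(N_x = 1000, N_y = 1000, N_z = 10,
                                            eta = 1, beta = 0.01,
                                            n_nu_grid = c(0, 200, 1000, 3000),
                                            accuracy_criterion = 0.75,
                                            trial_cap = 10000)) {
  d <- defaults
  rows <- list()
  for (variant in c("RL_only", "RL_plus_HL")) {
    for (n_nu in d$n_nu_grid) {
      r <- habit_experiment(variant, n_nu,
                            accuracy_criterion = d$accuracy_criterion,
                            seed = seed + n_nu, N_x = d$N_x, N_y = d$N_y,
                            N_z = d$N_z, eta = d$eta, beta = d$beta,
                            trial_cap = d$trial_cap)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = variant, n_nu = n_nu,
                   trials_to_criterion = r$trials_to_criterion,
                   attained = r$attained)
    }
  }
  list(repetitions = do.call(rbind, rows))
}

exp_fig5b <- function(seed, defaults = list(N_x = 1000, N_y = 1000, N_z = 250,
                                            alpha = 1, beta = 1,
                                            n_rep_grid = c(1, 5, 10, 20, 40),
                                            sigma_grid = c(0, 0.5, 1, 2, 4),
                                            burn_P = 500, n_networks = 10,
                                            n_noise_draws = 100)) {
  d <- defaults
  rows <- list()
  for (k in seq_len(d$n_networks)) {
    for (n in d$n_rep_grid) {
      ens <- generate_patterns(d$burn_P + 1L, d$N_x, d$N_y, d$N_z,
                               seed = seed + 131L * k)
      sch <- make_repetition_schedule(
        d$burn_P + 1L,
        special = stats::setNames(list(n), as.character(d$burn_P + 1L)))
      ens <- set_schedule(ens, sch)
      st <- two_pathway_state(d$N_x, d$N_y, d$N_z, d$alpha, d$beta,
                              nbar = ens$nbar)
      st <- train_two_pathway(ens, st)$state
      test <- new_pattern_ensemble(
        ens$X[d$burn_P + 1L, , drop = FALSE],
        ens$Y[d$burn_P + 1L, , drop = FALSE],
        ens$Zhat[d$burn_P + 1L, , drop = FALSE], 1L, 1L)
      for (sg in d$sigma_grid) {
        e <- lesion_test(st, test, "intact", sigma_m = sg,
                         n_noise_draws = d$n_noise_draws,
                         seed = seed + k)$error
        rows[[length(rows) + 1L]] <-
          data.frame(network = k, n_rep = n, sigma_m = sg, error = e)
      }
      e0 <- lesion_test(st, test, "m_zero")$error
      rows[[length(rows) + 1L]] <-
        data.frame(network = k, n_rep = n, sigma_m = Inf, error = e0)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab["error"], by = tab[c("n_rep", "sigma_m")],
                          FUN = mean)
  list(errors = agg)
}

exp_fig5c <- function(seed, defaults = list(N_x = 1000, N_y = 1000, N_z = 250,
                                            alpha = 1, beta = 1,
                                            n_rep_grid = c(1, 2, 5, 10, 20, 40),
                                            burn_P = 500, n_networks = 10)) {
  d <- defaults
  rows <- list()
  for (k in seq_len(d$n_networks)) {
    ens <- generate_patterns(d$burn_P + 1L, d$N_x, d$N_y, d$N_z,
                             seed = seed + k)
    mu <- d$burn_P + 1L
    for (n in d$n_rep_grid) {
      st <- two_pathway_state(d$N_x, d$N_y, d$N_z, d$alpha, d$beta)
      base <- new_pattern_ensemble(ens$X[-mu, , drop = FALSE],
                                   ens$Y[-mu, , drop = FALSE],
                                   ens$Zhat[-mu, , drop = FALSE],
                                   rep(1L, d$burn_P), seq_len(d$burn_P))
      st <- train_two_pathway(base, st)$state
      st <- present_pattern(st, ens$X[mu, ], ens$Y[mu, ], ens$Zhat[mu, ],
                            n = n)$state
      ov <- population_similarity(st, ens$X[mu, ], ens$Y[mu, ])
      rows[[length(rows) + 1L]] <-
        data.frame(network = k, n_rep = n, overlap_m0_h0 = ov[1],
                   overlap_m0_intact = ov[2])
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(tab[c("overlap_m0_h0", "overlap_m0_intact")],
                          by = list(n_rep = tab$n_rep), FUN = mean)
  list(overlaps = agg)
}

exp_fig6c <- function(seed, defaults = list(block_schedule = data.frame(
                                              target = 1:4,
                                              n_trials = c(2000L, 500L,
                                                           500L, 500L)),
                                            eta_SL = 1e-3, eta_HL = 1e-6)) {
  d <- defaults
  out <- list()
  for (cond in c("SL_only", "SL_plus_HL")) {
    sp <- reaching_spec(block_schedule = d$block_schedule, eta_SL = d$eta_SL,
                        eta_HL = d$eta_HL, condition = cond)
    tr <- train_blocks(sp, seed = seed)
    out[[paste0("loss_", tolower(cond))]] <-
      cbind(condition = cond, tr$loss_trace)
  }
  list(loss = do.call(rbind, out))
}

exp_fig6d <- function(seed, defaults = list(n_networks = 21,
                                            block_schedule = data.frame(
                                              target = 1:4,
                                              n_trials = c(2000L, 500L,
                                                           500L, 500L)),
                                            eta_SL = 1e-3, eta_HL = 1e-6)) {
  d <- defaults
  out <- list()
  for (cond in c("SL_only", "SL_plus_HL", "SL_interleaved")) {
    sp <- reaching_spec(block_schedule = d$block_schedule, eta_SL = d$eta_SL,
                        eta_HL = d$eta_HL, condition = cond)
    nets <- lapply(seq_len(d$n_networks),
                   function(k) train_blocks(sp, seed = seed + k)$net)
    ret <- evaluate_retention(nets)
    out[[cond]] <- cbind(condition = cond, ret)
  }
  list(retention = do.call(rbind, out))
}

sweep_curves <- function(seed, grid, d) {
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, , drop = FALSE]
    res <- estimate_two_pathway_forgetting_curve(
      d$N_x, as.integer(g$ratio * d$N_x), alpha = g$alpha, beta = g$beta,
      P = as.integer(2 * d$N_x), n_runs = d$n_runs, seed = seed + i)
    cv <- as.data.frame(res$unrepeated)
    rows[[i]] <- cbind(alpha = g$alpha, beta = g$beta, ratio = g$ratio, cv)
  }
  list(curves = do.call(rbind, rows))
}

exp_suppfig2 <- function(seed, defaults = list(N_x = 500, n_runs = 100,
                                               alpha_grid = c(0.25, 1, 4),
                                               beta = 1, ratio = 1)) {
  d <- defaults
  sweep_curves(seed, data.frame(alpha = d$alpha_grid, beta = d$beta,
                                ratio = d$ratio), d)
}

exp_suppfig3 <- function(seed, defaults = list(N_x = 500, n_runs = 100,
                                               beta_grid = c(0.25, 1, 4),
                                               alpha = 1, ratio = 1)) {
  d <- defaults
  sweep_curves(seed, data.frame(alpha = d$alpha, beta = d$beta_grid,
                                ratio = d$ratio), d)
}

exp_suppfig4 <- function(seed, defaults = list(N_x = 500, N_y = 500,
                                               alpha = 1, beta = 1,
                                               n_repeated_grid = c(2, 6, 18),
                                               n_repeats = 10, n_runs = 50)) {
  d <- defaults
  rows <- list()
  for (k in d$n_repeated_grid) {
    P <- d$N_x + d$N_y
    lags <- round(seq(0.5, 0.9, length.out = k) * P)
    res <- estimate_two_pathway_forgetting_curve(
      d$N_x, d$N_y, d$alpha, d$beta, P = P,
      repeated = stats::setNames(as.list(rep(d$n_repeats, k)),
                                 as.character(lags)),
      n_runs = d$n_runs, seed = seed + k)
    rows[[length(rows) + 1L]] <-
      cbind(n_repeated_patterns = k, res$repeated)
  }
  list(repeated = do.call(rbind, rows))
}

exp_suppfig6 <- function(seed, defaults = list(N_x = 250, N_y = 250,
                                               alpha = 1, beta = 1,
                                               n_repeats = 10,
                                               gaps = c(0, 5, 25, 100),
                                               test_lag = 250, n_runs = 100)) {
  d <- defaults
  P <- d$test_lag + max(d$gaps) * d$n_repeats + 50L
  rows <- list()
  for (g in d$gaps) {
    mu_star <- P - d$test_lag - g * (d$n_repeats - 1L)
    seeds <- child_seeds(seed + g, d$n_runs)
    errs <- vapply(seq_len(d$n_runs), function(r) {
      ens <- generate_patterns(P, d$N_x, d$N_y, 1, seed = seeds[r])
      sch <- make_repetition_schedule(
        P, special = stats::setNames(list(d$n_repeats),
                                     as.character(mu_star)),
        default_gap = g)
      ens <- set_schedule(ens, sch)
      st <- two_pathway_state(d$N_x, d$N_y, 1, d$alpha, d$beta,
                              nbar = ens$nbar)
      st <- train_two_pathway(ens, st)$state
      dec <- pathway_decomposition(st, ens$X[mu_star, ], ens$Y[mu_star, ],
                                   ens$Zhat[mu_star, ])
      as.numeric(dec$z != ens$Zhat[mu_star, 1])
    }, numeric(1))
    rows[[length(rows) + 1L]] <-
      data.frame(gap = g, error = mean(errs),
                 se = sd(errs) / sqrt(d$n_runs))
  }
  list(spacing = do.call(rbind, rows))
}
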