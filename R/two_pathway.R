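#' Create a two-pathway learner state
#'
#' A population of `N_z` readout units receiving a fast pathway (weights `W`,
#' N_z x N_x, trained by the one-step margin rule on the total current) and a
#' slow pathway (weights `V`, N_z x N_y, trained by a Hebbian rule with weight
#' decay):
#'
#'   dV = -(alpha * n_mu / (N_y * nbar)) V
#'        + sqrt(2) * (beta * n_mu / (N_y * nbar)) zhat y^T
#'
#' `alpha` sets the decay of old associations, `beta` the strength of each
#' Hebbian increment, and `n_mu` the number of times a pattern is repeated
#' when trained. With `beta = 0` (or `N_y = 0`) every output of this module
#' reduces exactly to the single-pathway model.
#'
#' @param N_x,N_y,N_z dimensions (N_y may be 0).
#' @param alpha,beta nonnegative Hebbian decay and learning rates.
#' @param kappa margin of the fast pathway.
#' @param nbar mean repetition count of the training schedule (fixed at
#'   construction, not updated online).
#' @param hebbian_application `"per_repetition"` (each of the n presentations
#'   applies the rule with n_mu = 1; the default) or `"aggregated"` (one
#'   combined call with n_mu = n after the first supervised step).
#' @param normalization fast-pathway update normalization.
#' @param init `"zero"` (default; the regime the forgetting theory assumes,
#'   with stationarity reached through burn-in) or `"random"`, which draws
#'   both weight matrices so that each pathway's current is O(1) per readout
#'   unit, emulating an untrained but active network.
#' @param init_seed seed for the random initialization.
#' @return object of class `two_pathway_state`.
#' @export
two_pathway_state <- function(N_x, N_y, N_z = 1, alpha = 1, beta = 1,
                              kappa = 1, nbar = 1,
                              hebbian_application = c("per_repetition",
                                                      "aggregated"),
                              normalization = c("by_N_x", "by_input_norm"),
                              init = c("zero", "random"), init_seed = 1) {
  N_x <- check_count(N_x, "N_x"); N_y <- check_count(N_y, "N_y", min = 0)
  N_z <- check_count(N_z, "N_z")
  stopifnot(alpha >= 0, beta >= 0, kappa > 0, nbar > 0)
  init <- match.arg(init)
  if (init == "random") {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(init_seed))
    W0 <- matrix(rnorm(N_z * N_x, sd = 1 / sqrt(N_x)), N_z, N_x)
    V0 <- matrix(rnorm(N_z * max(N_y, 0), sd = 1 / sqrt(max(N_y, 1))),
                 N_z, max(N_y, 0))
  } else {
    W0 <- matrix(0, N_z, N_x); V0 <- matrix(0, N_z, max(N_y, 0))
  }
  structure(list(W = W0, V = V0,
                 alpha = alpha, beta = beta, kappa = kappa, nbar = nbar,
                 hebbian_application = match.arg(hebbian_application),
                 normalization = match.arg(normalization)),
            class = "two_pathway_state")
}

#' @export
print.two_pathway_state <- function(x, ...) {
  cat(sprintf("two_pathway_state: N_x = %d, N_y = %d, N_z = %d\n",
              ncol(x$W), ncol(x$V), nrow(x$W)))
  cat(sprintf("  alpha = %g, beta = %g, kappa = %g, nbar = %g (%s)\n",
              x$alpha, x$beta, x$kappa, x$nbar, x$hebbian_application))
  invisible(x)
}

#' Hebbian update of the slow-pathway weights
#'
#' @param V current N_z x N_y weight matrix.
#' @param y second-pathway input vector.
#' @param zhat target vector (entries -1/+1), one per readout row.
#' @param alpha,beta decay and learning rates.
#' @param n_mu repetition count of the trained pattern.
#' @param nbar mean repetition count.
#' @return the updated matrix.
#' @examples
#' hebbian_update(matrix(0, 1, 2), y = c(1, 1), zhat = 1,
#'                alpha = 1, beta = 1, n_mu = 1, nbar = 1)  # sqrt(2)/2 each
#' @export
hebbian_update <- function(V, y, zhat, alpha, beta, n_mu = 1, nbar = 1) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  N_y <- ncol(V)
  if (N_y == 0) return(V)
  stopifnot(n_mu >= 1, nbar > 0, length(y) == N_y, nrow(V) == length(zhat))
  check_pm1(zhat)
  a <- alpha * n_mu / (N_y * nbar)
  b <- sqrt(2) * beta * n_mu / (N_y * nbar)
  (1 - a) * V + b * tcrossprod(zhat, y)
}

#' Decompose the input currents to the readout population
#'
#' `m = W x` is the fast-pathway current and `h = V y` the slow-pathway
#' current. `alignment` is the normalized overlap `m.h / (|m||h|)` (0 if
#' either norm vanishes) and `control_ratio` the share of the readout-direction
#' drive carried by the slow pathway, `(h.zhat) / ((m+h).zhat)` (0 when h = 0,
#' 1 when m = 0).
#'
#' @param state a [two_pathway_state()].
#' @param x,y input vectors.
#' @param zhat target vector for the control ratio.
#' @return object of class `pathway_decomposition`: list with `m`, `h`,
#'   `alignment`, `control_ratio`, and the realized readout `z = sgn(m + h)`.
#' @export
pathway_decomposition <- function(state, x, y, zhat) {
  stopifnot(inherits(state, "two_pathway_state"))
  m <- as.numeric(state$W %*% x)
  h <- if (ncol(state$V) > 0) as.numeric(state$V %*% y) else numeric(nrow(state$W))
  nm <- sqrt(sum(m^2)); nh <- sqrt(sum(h^2))
  alignment <- if (nm > 0 && nh > 0) sum(m * h) / (nm * nh) else 0
  tot <- sum((m + h) * zhat)
  control_ratio <- if (all(h == 0)) 0
    else if (all(m == 0)) 1
    else if (tot != 0) sum(h * zhat) / tot else NA_real_
  structure(list(m = m, h = h, alignment = alignment,
                 control_ratio = control_ratio, z = sgn(m + h)),
            class = "pathway_decomposition")
}

#' Present one pattern for n repetitions
#'
#' Per repetition, the fast pathway is updated first (the supervised step is
#' fast relative to the Hebbian step) on the total current `u = m + h`, then
#' the Hebbian rule is applied using the target `zhat` (by the time the slow
#' pathway changes appreciably, the realized output has attained the target).
#' In `"aggregated"` mode the n Hebbian increments are collapsed into one call
#' with `n_mu = n` after a single supervised step.
#'
#' @param state a [two_pathway_state()].
#' @param x,y input vectors.
#' @param zhat target vector.
#' @param n repetition count (>= 1).
#' @return list with the updated `state` and `trace`, a data frame with one
#'   row per repetition (`rep`, `alignment`, `control_ratio`, `error`).
#' @export
present_pattern <- function(state, x, y, zhat, n = 1) {
  stopifnot(inherits(state, "two_pathway_state"))
  n <- check_count(n, "n")
  check_pm1(zhat)
  aggregated <- state$hebbian_application == "aggregated"
  reps <- if (aggregated) 1L else n
  trace <- data.frame(rep = seq_len(reps), alignment = NA_real_,
                      control_ratio = NA_real_, error = NA_real_)
  for (r in seq_len(reps)) {
    dec <- pathway_decomposition(state, x, y, zhat)
    u <- dec$m + dec$h
    D <- if (state$normalization == "by_input_norm") sum(x^2) else ncol(state$W)
    gain <- ifelse(u * zhat < state$kappa, (state$kappa * zhat - u) / D, 0)
    state$W <- state$W + tcrossprod(gain, x)
    state$V <- hebbian_update(state$V, y, zhat, state$alpha, state$beta,
                              n_mu = if (aggregated) n else 1,
                              nbar = state$nbar)
    dec <- pathway_decomposition(state, x, y, zhat)
    trace$alignment[r] <- dec$alignment
    trace$control_ratio[r] <- dec$control_ratio
    trace$error[r] <- mean(dec$z != zhat)
  }
  list(state = state, trace = trace)
}

#' Train the population on a full schedule
#'
#' Applies [present_pattern()] semantics over the ensemble's presentation
#' order (use [set_schedule()] to repeat chosen patterns), recording the
#' alignment and control ratio of each presented pattern at training time.
#'
#' @param ensemble a [pattern_ensemble][generate_patterns].
#' @param state a [two_pathway_state()].
#' @param record_traces record per-presentation alignment/control summaries.
#' @return list with `state` and (optionally) `traces`, one row per
#'   presentation: `pattern`, `alignment`, `control_ratio`, `error`.
#' @export
train_two_pathway <- function(ensemble, state, record_traces = FALSE) {
  stopifnot(inherits(ensemble, "pattern_ensemble"),
            inherits(state, "two_pathway_state"))
  aggregated <- state$hebbian_application == "aggregated"
  if (aggregated) {
    pres <- seq_len(nrow(ensemble$X))
    n_pres <- as.numeric(ensemble$repeats)
  } else {
    pres <- ensemble$order
    n_pres <- rep(1, length(pres))
  }
  res <- cpp_train_two(ensemble$X, ensemble$Y, ensemble$Zhat,
                       as.integer(pres), n_pres, state$W, state$V,
                       state$kappa, state$alpha, state$beta, state$nbar,
                       state$normalization == "by_input_norm", record_traces)
  state$W <- res$W; state$V <- res$V
  out <- list(state = state)
  if (record_traces) {
    tr <- as.data.frame(res$traces)
    names(tr) <- c("pattern", "alignment", "control_ratio", "error")
    out$traces <- tr
  }
  out
}

#' Per-pattern test errors for a trained population
#'
#' The readout is `sgn(m' + h')` with the selected current either intact,
#' zeroed ("lesioned"), or perturbed by i.i.d. Gaussian noise of amplitude
#' `sigma_m` added to `m` (intact mode only). The per-pattern error is the
#' fraction of the N_z readout units whose output differs from the target,
#' averaged over noise draws where applicable.
#'
#' @param state a trained [two_pathway_state()].
#' @param ensemble the ensemble to test on.
#' @param mode `"intact"`, `"m_zero"`, or `"h_zero"`.
#' @param sigma_m noise amplitude on `m` (intact mode).
#' @param n_noise_draws Monte-Carlo draws when `sigma_m > 0`.
#' @param seed seed for the noise draws.
#' @return data frame with columns `pattern` and `error`.
#' @export
lesion_test <- function(state, ensemble, mode = c("intact", "m_zero", "h_zero"),
                        sigma_m = 0, n_noise_draws = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(sigma_m >= 0)
  if (sigma_m > 0 && mode != "intact")
    stop_invalid("noise applies only in intact mode")
  M <- ensemble$X %*% t(state$W)            # P x N_z fast currents
  H <- if (ncol(state$V) > 0) ensemble$Y %*% t(state$V) else 0 * M
  Zhat <- ensemble$Zhat
  P <- nrow(M)
  err <- numeric(P)
  if (mode == "m_zero") {
    err <- rowMeans(sgn(H) != Zhat)
  } else if (mode == "h_zero") {
    err <- rowMeans(sgn(M) != Zhat)
  } else if (sigma_m == 0) {
    err <- rowMeans(sgn(M + H) != Zhat)
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    for (d in seq_len(n_noise_draws)) {
      Xi <- matrix(rnorm(length(M)), nrow = P)
      err <- err + rowMeans(sgn(M + sigma_m * Xi + H) != Zhat)
    }
    err <- err / n_noise_draws
  }
  data.frame(pattern = seq_len(P), error = err)
}

#' Population-activity similarity under pathway silencing
#'
#' Compares the +-1 population vectors produced with only the slow pathway
#' (`m = 0`), only the fast pathway (`h = 0`), and both intact, via their
#' normalized overlaps (mean elementwise product).
#'
#' @param state a trained [two_pathway_state()] with `N_z >= 2`.
#' @param x,y the pattern's input vectors.
#' @return named numeric vector: `overlap_m0_h0` (z with m = 0 vs z with
#'   h = 0) and `overlap_m0_intact` (z with m = 0 vs z intact).
#' @export
population_similarity <- function(state, x, y) {
  stopifnot(inherits(state, "two_pathway_state"), nrow(state$W) >= 2)
  m <- as.numeric(state$W %*% x)
  h <- if (ncol(state$V) > 0) as.numeric(state$V %*% y) else numeric(length(m))
  z_m0 <- sgn(h); z_h0 <- sgn(m); z_in <- sgn(m + h)
  c(overlap_m0_h0 = mean(z_m0 * z_h0), overlap_m0_intact = mean(z_m0 * z_in))
}

#' Monte-Carlo forgetting curves for the two-pathway model
#'
#' As [estimate_forgetting_curve()], but with the slow pathway active and
#' testing via `sgn(m + h)`, and with selected patterns repeated during
#' training. `repeated` maps lags (in patterns before the end of training) to
#' repetition counts; patterns at those lags are each repeated consecutively.
#' Separate curves are returned for the repeated and unrepeated classes.
#'
#' @param N_x,N_y input dimensions.
#' @param alpha,beta Hebbian rates.
#' @param P number of tested patterns.
#' @param repeated named vector/list mapping lag (0-based, in patterns) to
#'   repetition count, e.g. `c("500" = 10)`.
#' @param n_runs Monte-Carlo runs.
#' @param seed root seed.
#' @param burn_in burn-in patterns (trained once each, never tested).
#' @param kappa margin.
#' @return list with `unrepeated` (a `forgetting_curve`) and `repeated` (a
#'   data frame with `tau`, `n_rep`, `error`, `se`, `n_runs`).
#' @export
estimate_two_pathway_forgetting_curve <- function(N_x, N_y, alpha = 1, beta = 1,
                                                  P = 2 * N_x,
                                                  repeated = c(),
                                                  n_runs = 100, seed = 1,
                                                  burn_in = 4 * N_x,
                                                  kappa = 1) {
  N_x <- check_count(N_x, "N_x"); N_y <- check_count(N_y, "N_y")
  n_runs <- check_count(n_runs, "n_runs")
  lags <- as.integer(names(repeated))
  counts <- as.integer(unlist(repeated, use.names = FALSE))
  if (length(lags) > 0 && any(lags < 0 | lags >= P))
    stop_invalid("repeated lags must lie in [0, P)")
  reps <- rep(1L, P)
  reps[P - lags] <- counts
  nbar <- mean(c(rep(1L, burn_in), reps))
  seeds <- child_seeds(seed, n_runs)
  acc <- numeric(P)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    acc <- acc + cpp_two_forgetting_run(N_x, N_y, P, reps,
                                        as.integer(burn_in), kappa, alpha,
                                        beta, nbar, FALSE)
  }
  p <- acc / n_runs
  tau <- (P - seq_len(P)) / N_x
  se <- sqrt(p * (1 - p) / n_runs)
  is_rep <- reps > 1L
  un <- new_forgetting_curve(tau[!is_rep], p[!is_rep], se[!is_rep], n_runs)
  out <- list(unrepeated = un[order(un$tau), ])
  if (any(is_rep)) {
    out$repeated <- data.frame(tau = tau[is_rep], n_rep = reps[is_rep],
                               error = p[is_rep], se = se[is_rep],
                               n_runs = n_runs)
  }
  out
}

#' Repetitions needed to reach an error threshold
#'
#' Finds the smallest repetition count `n` such that the Monte-Carlo error of
#' a pattern repeated `n` times during training, tested after `interval`
#' subsequent patterns, falls below `p_theta`. Searched by doubling followed
#' by bisection; the error is monotone non-increasing in `n` up to
#' Monte-Carlo noise.
#'
#' @param N_x,N_y,alpha,beta model parameters.
#' @param interval train-test interval in patterns (the tested pattern's lag).
#' @param p_theta error threshold in (0, 0.5).
#' @param n_runs Monte-Carlo runs per evaluation.
#' @param seed root seed.
#' @param n_cap largest repetition count tried.
#' @param burn_in burn-in length.
#' @return list with `n` (smallest sufficient count, or the cap), logical
#'   `attained`, and `evaluations` (data frame n/error).
#' @export
repetitions_to_threshold <- function(N_x, N_y, alpha = 1, beta = 1, interval,
                                     p_theta = 0.1, n_runs = 200, seed = 1,
                                     n_cap = 512, burn_in = 2 * N_x) {
  stopifnot(p_theta > 0, p_theta < 0.5, interval >= 0)
  evals <- list()
  err_at <- function(n) {
    key <- as.character(n)
    if (!is.null(evals[[key]])) return(evals[[key]])
    res <- estimate_two_pathway_forgetting_curve(
      N_x, N_y, alpha, beta, P = interval + 1L,
      repeated = stats::setNames(list(n), as.character(interval)),
      n_runs = n_runs, seed = seed + n, burn_in = burn_in)
    e <- if (n > 1) res$repeated$error[1] else {
      # n = 1 leaves no repeated class; read the lag-interval point
      res$unrepeated$error[res$unrepeated$tau == interval / N_x]
    }
    evals[[key]] <<- e
    e
  }
  if (err_at(1L) < p_theta)
    return(list(n = 1L, attained = TRUE, evaluations = eval_table(evals)))
  lo <- 1L; hi <- 2L
  while (hi <= n_cap && err_at(hi) >= p_theta) { lo <- hi; hi <- 2L * hi }
  if (hi > n_cap)
    return(list(n = n_cap, attained = FALSE, evaluations = eval_table(evals)))
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (err_at(mid) < p_theta) hi <- mid else lo <- mid
  }
  list(n = hi, attained = TRUE, evaluations = eval_table(evals))
}

eval_table <- function(evals) {
  n <- as.integer(names(evals))
  ord <- order(n)
  data.frame(n = n[ord], error = unlist(evals, use.names = FALSE)[ord])
}
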