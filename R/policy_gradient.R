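#' Create a reinforcement-learning state
#'
#' The readout units fire stochastically: `z_i = +1` with probability
#' `sigma(m_i + h_i)` where `sigma` is the logistic function. The scalar
#' reward is the normalized overlap of the realized activity with the target,
#' `R = z . zhat / sqrt(N_z)`, and the fast pathway follows the REINFORCE
#' policy gradient with a low-pass reward baseline:
#'
#'   dW_ij = (eta / N_x) (R - Rbar) z_i sigma(-z_i (m_i + h_i)) x_j
#'
#' Variants: `"RL_plus_HL"` (slow pathway Hebbian, rate `beta`), `"RL_plus_RL"`
#' (slow pathway REINFORCE with rate `eta2`), `"RL_only"` (no slow pathway
#' learning).
#'
#' @param N_x,N_y,N_z dimensions; defaults follow the habit-formation
#'   experiments (1000, 1000, 10).
#' @param eta fast-pathway learning rate.
#' @param eta2 slow-pathway rate in the RL+RL variant.
#' @param beta slow-pathway Hebbian rate in the RL+HL variant.
#' @param alpha Hebbian decay rate.
#' @param tau_R baseline time constant in trials (default 10).
#' @param variant learning-rule combination.
#' @param use_realized_output if TRUE the Hebbian rule uses the realized
#'   activity `z` instead of the target `zhat`. The realized-output form is
#'   the purely associative reading of the rule (no access to the target);
#'   the two coincide while performance is high.
#' @param init `"random"` initializes both weight matrices so that each
#'   pathway's current is O(1) per readout unit (a randomly initialized
#'   network, the default), `"zero"` starts from silent weights.
#' @param init_seed seed for the random initialization.
#' @return object of class `rl_state`.
#' @export
rl_state <- function(N_x = 1000, N_y = 1000, N_z = 10, eta = 1, eta2 = 0.01,
                     beta = 0.01, alpha = 1, tau_R = 10,
                     variant = c("RL_plus_HL", "RL_plus_RL", "RL_only"),
                     use_realized_output = FALSE,
                     init = c("random", "zero"), init_seed = 1) {
  stopifnot(tau_R >= 1, eta >= 0, eta2 >= 0, beta >= 0, alpha >= 0)
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
                 eta = eta, eta2 = eta2, beta = beta, alpha = alpha,
                 tau_R = tau_R, Rbar = 0, variant = match.arg(variant),
                 use_realized_output = isTRUE(use_realized_output)),
            class = "rl_state")
}

#' @export
print.rl_state <- function(x, ...) {
  cat(sprintf("rl_state (%s): N_x = %d, N_y = %d, N_z = %d\n", x$variant,
              ncol(x$W), ncol(x$V), nrow(x$W)))
  cat(sprintf("  eta = %g, eta2 = %g, beta = %g, tau_R = %g, Rbar = %.4f\n",
              x$eta, x$eta2, x$beta, x$tau_R, x$Rbar))
  invisible(x)
}

#' Stochastic readout
#'
#' @param m,h input currents per readout unit.
#' @return -1/+1 vector; `z_i = +1` with probability `sigma(m_i + h_i)`.
#' @export
stochastic_readout <- function(m, h = 0) {
  p <- 1 / (1 + exp(-(m + h)))
  sgn(p - runif(length(m)))
}

#' Reward: normalized overlap with the target
#'
#' @param z realized -1/+1 activity.
#' @param zhat target -1/+1 activity.
#' @return `z . zhat / sqrt(N_z)`.
#' @export
compute_reward <- function(z, zhat) {
  stopifnot(length(z) == length(zhat))
  check_pm1(z, "z"); check_pm1(zhat)
  sum(z * zhat) / sqrt(length(z))
}

#' REINFORCE update of the fast-pathway weights
#'
#' @param W current N_z x N_x matrix.
#' @param x input vector.
#' @param z realized activity.
#' @param m,h currents used for the trial.
#' @param R,Rbar reward and baseline.
#' @param eta learning rate.
#' @return the updated matrix.
#' @export
reinforce_update <- function(W, x, z, m, h, R, Rbar, eta) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  s <- 1 / (1 + exp(z * (m + h)))
  W + (eta / ncol(W)) * (R - Rbar) * tcrossprod(z * s, x)
}

#' Low-pass reward baseline
#'
#' `Rbar' = (1 - 1/tau_R) Rbar + R / tau_R`; constant reward streams converge
#' to the reward geometrically at rate `1 - 1/tau_R`.
#'
#' @param Rbar current baseline.
#' @param R reward of the trial.
#' @param tau_R time constant (>= 1).
#' @return updated baseline.
#' @export
update_baseline <- function(Rbar, R, tau_R = 10) {
  stopifnot(tau_R >= 1)
  (1 - 1 / tau_R) * Rbar + R / tau_R
}

#' Train with reinforcement learning on one fixed pattern
#'
#' Per trial: compute the currents, draw the stochastic readout, compute the
#' reward and update the baseline, then update the plastic pathways according
#' to the state's variant.
#'
#' @param state an [rl_state()].
#' @param x,y input vectors.
#' @param zhat target -1/+1 vector.
#' @param n_trials trials.
#' @param seed seed for the stochastic readout.
#' @return list with the updated `state` and `traces`, a data frame with one
#'   row per trial: `trial`, `reward`, `Rbar`, `alignment`, `control_ratio`,
#'   `match_fraction`.
#' @export
train_rl <- function(state, x, y, zhat, n_trials, seed = NULL) {
  stopifnot(inherits(state, "rl_state"))
  check_pm1(zhat)
  if (!is.null(seed)) set.seed(as.integer(seed))
  variant <- match(state$variant, c("RL_only", "RL_plus_HL", "RL_plus_RL")) - 1L
  res <- cpp_rl_train(state$W, state$V, x, y, zhat, as.integer(n_trials),
                      variant, state$eta, state$eta2, state$beta, state$alpha,
                      state$tau_R, state$Rbar, state$use_realized_output)
  state$W <- res$W; state$V <- res$V; state$Rbar <- res$Rbar
  tr <- as.data.frame(res$traces)
  names(tr) <- c("reward", "Rbar", "alignment", "control_ratio",
                 "match_fraction")
  tr <- cbind(trial = seq_len(nrow(tr)), tr)
  list(state = state, traces = tr)
}

#' Match fraction with one pathway silenced
#'
#' Deterministic readout `sgn` of the remaining current, compared with the
#' target; used to probe robustness of a trained network to removal of the
#' fast input.
#'
#' @param state an [rl_state()].
#' @param x,y inputs.
#' @param zhat target.
#' @param drop `"none"`, `"m"`, or `"h"`.
#' @return fraction of readout units matching the target.
#' @export
rl_match_fraction <- function(state, x, y, zhat, drop = c("none", "m", "h")) {
  drop <- match.arg(drop)
  m <- as.numeric(state$W %*% x)
  h <- if (ncol(state$V) > 0) as.numeric(state$V %*% y) else numeric(length(m))
  u <- switch(drop, none = m + h, m = h, h = m)
  mean(sgn(u) == zhat)
}

#' Habit-formation experiment
#'
#' Trains on `(x, zhat1)` for `n_nu` trials, then switches the target to a
#' fresh random pattern `zhat2` (same input) and counts the trials until the
#' smoothed per-unit match with the new target (moving average over `window`
#' trials) reaches `accuracy_criterion`. Reports non-attainment at
#' `trial_cap` post-switch trials. With Hebbian learning in the slow pathway,
#' the old association persists: more initial repetitions mean more
#' post-switch trials, up to complete failure to realign - a habit.
#'
#' The Hebbian rule here uses the realized activity by default
#' (`use_realized_output = TRUE`): after the target switch the slow pathway
#' has no access to the new target, so it keeps reinforcing whatever the
#' population actually does - the self-sustaining loop that makes the habit
#' persistent. (With the target-based form the slow pathway would be
#' supervised onto the new target and the habit would dissolve on a fixed
#' timescale independent of practice.)
#'
#' @param variant `"RL_only"` or `"RL_plus_HL"`.
#' @param n_nu repetitions on the first target (0 = no pre-training).
#' @param accuracy_criterion required smoothed match fraction, in (0.5, 1].
#' @param seed root seed (patterns and readout noise).
#' @param N_x,N_y,N_z,eta,beta,alpha,tau_R model parameters.
#' @param window smoothing window (trials).
#' @param trial_cap post-switch trial budget.
#' @return list with `trials_to_criterion` (NA if unattained), `attained`,
#'   and the post-switch smoothed match trace.
#' @export
habit_experiment <- function(variant = c("RL_only", "RL_plus_HL"), n_nu,
                             accuracy_criterion = 0.75, seed = 1,
                             N_x = 1000, N_y = 1000, N_z = 10, eta = 1,
                             beta = 0.01, alpha = 1, tau_R = 10, window = 20,
                             trial_cap = 10000, use_realized_output = TRUE) {
  variant <- match.arg(variant)
  stopifnot(accuracy_criterion > 0.5, accuracy_criterion <= 1, n_nu >= 0)
  seeds <- child_seeds(seed, 3)
  set.seed(seeds[1])
  x <- rnorm(N_x); y <- rnorm(N_y)
  zhat1 <- sgn(runif(N_z) - 0.5)
  zhat2 <- sgn(runif(N_z) - 0.5)
  state <- rl_state(N_x, N_y, N_z, eta = eta, beta = beta, alpha = alpha,
                    tau_R = tau_R, variant = variant,
                    use_realized_output = use_realized_output,
                    init_seed = seeds[1])
  if (n_nu > 0)
    state <- train_rl(state, x, y, zhat1, n_nu, seed = seeds[2])$state
  post <- train_rl(state, x, y, zhat2, trial_cap, seed = seeds[3])
  match <- post$traces$match_fraction
  smoothed <- stats::filter(match, rep(1 / window, window), sides = 1)
  hit <- which(!is.na(smoothed) & smoothed >= accuracy_criterion)
  attained <- length(hit) > 0
  list(trials_to_criterion = if (attained) hit[1] else NA_integer_,
       attained = attained, smoothed_match = as.numeric(smoothed))
}
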