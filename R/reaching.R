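#' Specification of the center-out reaching task
#'
#' A cursor starts at the origin and must reach one of four targets at
#' (1,0), (0,1), (-1,0), (0,-1) (arena units) in `T` timesteps, following the
#' minimum-jerk velocity profile of [minimum_jerk_velocity()]. The controller
#' is a two-pathway network with `N_x`- and `N_y`-unit input populations, an
#' `N_z`-unit hidden layer, and a fixed 2-D linear readout; the fast pathway
#' is trained by gradient descent on the squared velocity error (rate
#' `eta_SL`) and the slow pathway by the Hebbian rule
#' `dV = eta_HL (-V + z y^T)` per step.
#'
#' @param T steps per trial.
#' @param N_x,N_y,N_z population sizes.
#' @param eta_SL,eta_HL learning rates.
#' @param block_schedule data frame with columns `target` (1..4) and
#'   `n_trials`: the ordered training blocks. The default trains target 1
#'   longest, then targets 2-4 (chosen so that the first block's loss
#'   plateaus at the default `eta_SL`).
#' @param condition `"SL_only"`, `"SL_plus_HL"`, or `"SL_interleaved"`
#'   (targets sampled uniformly at random each trial, same total count).
#' @param feedback `"velocity"` (input populations receive fixed random
#'   projections of the previous velocity command, i.e. of the network
#'   readout at the previous timestep; the default) or `"position"` (of the
#'   current cursor position). The velocity form produces much stronger
#'   interference between targets, and with it the full retention contrast
#'   between conditions; the position form is retained as a variant.
#' @return object of class `reaching_spec`.
#' @export
reaching_spec <- function(T = 10, N_x = 50, N_y = 50, N_z = 10,
                          eta_SL = 1e-3, eta_HL = 1e-6,
                          block_schedule = data.frame(
                            target = 1:4,
                            n_trials = c(2000L, 500L, 500L, 500L)),
                          condition = c("SL_plus_HL", "SL_only",
                                        "SL_interleaved"),
                          feedback = c("velocity", "position")) {
  stopifnot(T >= 1, eta_SL >= 0, eta_HL >= 0, nrow(block_schedule) >= 1,
            all(block_schedule$target %in% 1:4),
            all(block_schedule$n_trials >= 1))
  structure(list(T = as.integer(T), N_x = N_x, N_y = N_y, N_z = N_z,
                 eta_SL = eta_SL, eta_HL = eta_HL,
                 block_schedule = block_schedule,
                 condition = match.arg(condition),
                 feedback = match.arg(feedback),
                 targets = matrix(c(1, 0, 0, 1, -1, 0, 0, -1), ncol = 2,
                                  byrow = TRUE)),
            class = "reaching_spec")
}

#' Minimum-jerk target velocity
#'
#' `uhat(t) = r_i * (30 (t/T)^2 - 60 (t/T)^3 + 30 (t/T)^4)`: the bell-shaped
#' speed profile of a minimum-jerk reach. It vanishes at both endpoints and
#' integrates to 1 over normalized time, so the displacement accumulated at
#' `dt = 1/T` reproduces the target up to Riemann discretization error.
#'
#' @param t step in `[0, T]`.
#' @param T steps per trial.
#' @param target 2-D target position.
#' @return 2-D velocity.
#' @export
minimum_jerk_velocity <- function(t, T, target) {
  if (any(t < 0) || any(t > T)) stop_invalid("t must lie in [0, T]")
  u <- t / T
  target * (30 * u^2 - 60 * u^3 + 30 * u^4)
}

#' Initialize a reaching network
#'
#' Input populations receive a tonic target-specific cue (one fixed random
#' vector per target per population) plus fixed random projections of the
#' feedback signal. Fast-pathway weights start at small random values scaled
#' by the inverse square root of fan-in; slow-pathway weights start at zero.
#'
#' @param spec a [reaching_spec()].
#' @param seed integer seed for the fixed random structure.
#' @return object of class `reaching_network`.
#' @export
reaching_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "reaching_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  structure(list(
    spec = spec, seed = as.integer(seed),
    W = matrix(rnorm(spec$N_z * spec$N_x, sd = 1 / sqrt(spec$N_x)),
               spec$N_z, spec$N_x),
    V = matrix(0, spec$N_z, spec$N_y),
    A = matrix(rnorm(2 * spec$N_z, sd = 1 / sqrt(spec$N_z)), 2, spec$N_z),
    Bx = matrix(rnorm(spec$N_x * 2), spec$N_x, 2),
    By = matrix(rnorm(spec$N_y * 2), spec$N_y, 2),
    CueX = matrix(rnorm(spec$N_x * 4), spec$N_x, 4),
    CueY = matrix(rnorm(spec$N_y * 4), spec$N_y, 4)),
    class = "reaching_network")
}

#' @export
print.reaching_network <- function(x, ...) {
  cat(sprintf("reaching_network: N_x = %d, N_y = %d, N_z = %d, T = %d (%s)\n",
              x$spec$N_x, x$spec$N_y, x$spec$N_z, x$spec$T,
              x$spec$condition))
  invisible(x)
}

reach_run <- function(net, trial_targets, learn, hl_on, record_last = FALSE) {
  sp <- net$spec
  res <- cpp_reach_run(net$W, net$V, net$A, net$Bx, net$By, net$CueX,
                       net$CueY, sp$targets, as.integer(trial_targets),
                       sp$T, sp$eta_SL, sp$eta_HL, hl_on, learn,
                       if (sp$feedback == "position") 0L else 1L,
                       record_last)
  net$W <- res$W; net$V <- res$V
  list(net = net, loss = as.numeric(res$loss), last_trial = res$last_trial)
}

#' Simulate (and optionally train on) one reaching trial
#'
#' Rolls the network for `T` steps from the origin. With `learn = TRUE`,
#' fast-pathway weights receive one per-trial batch gradient-descent update
#' against the minimum-jerk velocity target (gradient truncated at the
#' feedback loop), and the slow pathway receives per-step Hebbian updates
#' when the condition includes HL.
#'
#' @param net a [reaching_network()].
#' @param target_index target in 1..4.
#' @param learn apply weight updates.
#' @return list with the updated `net` and `trace`, a `trial_trace`: list of
#'   `positions` ((T+1) x 2), `velocities` (T x 2), `step_loss`, and scalar
#'   `loss` (mean squared velocity error over steps and output dimensions).
#' @export
simulate_trial <- function(net, target_index, learn = FALSE) {
  stopifnot(inherits(net, "reaching_network"), target_index %in% 1:4)
  hl_on <- net$spec$condition == "SL_plus_HL"
  res <- reach_run(net, target_index, learn, hl_on, record_last = TRUE)
  trace <- structure(list(positions = res$last_trial$positions,
                          velocities = res$last_trial$velocities,
                          step_loss = as.numeric(res$last_trial$step_loss),
                          loss = res$loss[1]),
                     class = "trial_trace")
  list(net = res$net, trace = trace)
}

#' Train a reaching network through its block schedule
#'
#' Blocks are trained in order (for `"SL_interleaved"`, the same total number
#' of trials is drawn with targets sampled uniformly at random). Hebbian
#' learning is active only in the `"SL_plus_HL"` condition.
#'
#' @param spec a [reaching_spec()].
#' @param seed seed for the network's fixed random structure (and the
#'   interleaved target sequence).
#' @return list with the trained `net` and `loss_trace`, a data frame with
#'   columns `trial`, `target`, `loss`.
#' @export
train_blocks <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "reaching_spec"))
  net <- reaching_network(spec, seed = seed)
  sched <- spec$block_schedule
  targets <- rep(sched$target, sched$n_trials)
  if (spec$condition == "SL_interleaved") {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed) + 1L)
    targets <- sample(1:4, length(targets), replace = TRUE)
  }
  hl_on <- spec$condition == "SL_plus_HL"
  res <- reach_run(net, targets, learn = TRUE, hl_on = hl_on)
  list(net = res$net,
       loss_trace = data.frame(trial = seq_along(targets), target = targets,
                               loss = res$loss))
}

#' Test-set retention after training
#'
#' Frozen-weight rollouts on each target for each trained network; returns
#' per-target mean and SEM of the loss over networks.
#'
#' @param nets list of trained [reaching_network()]s (>= 2 for an SEM).
#' @param n_test_trials rollouts per target per network (the rollout is
#'   deterministic, so these agree; kept for interface symmetry). Zero
#'   returns an empty result.
#' @return data frame with columns `target`, `mean_loss`, `sem`, and the
#'   per-network losses as attribute `"losses"` (networks x targets).
#' @export
evaluate_retention <- function(nets, n_test_trials = 1) {
  if (n_test_trials == 0 || length(nets) == 0)
    return(data.frame(target = integer(0), mean_loss = numeric(0),
                      sem = numeric(0)))
  losses <- t(vapply(nets, function(net) {
    vapply(1:4, function(tg) {
      mean(replicate(n_test_trials,
                     reach_run(net, tg, learn = FALSE, hl_on = FALSE)$loss))
    }, numeric(1))
  }, numeric(4)))
  out <- data.frame(target = 1:4, mean_loss = colMeans(losses),
                    sem = apply(losses, 2, sd) / sqrt(nrow(losses)))
  attr(out, "losses") <- losses
  out
}
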