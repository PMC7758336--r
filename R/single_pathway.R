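#' Create a single-pathway (margin perceptron) state
#'
#' A single readout unit with `N_x` plastic input weights trained by the
#' one-step margin rule: when the summed input `u = w . x` satisfies
#' `u * zhat < kappa`, the weights jump to the correct side of the
#' classification boundary with margin `kappa`.
#'
#' Two normalizations of the jump are available: `"by_N_x"` divides the update
#' by the input dimension (the model's canonical form; attains the margin up
#' to O(1/sqrt(N_x)) fluctuations of `|x|^2/N_x`), while `"by_input_norm"`
#' divides by `|x|^2` and attains the margin exactly.
#'
#' @param N_x input dimension.
#' @param kappa positive margin; default 1 (any other value can be absorbed
#'   into a rescaling of the weights).
#' @param normalization `"by_N_x"` or `"by_input_norm"`.
#' @param w optional initial weights (default zeros).
#' @return object of class `single_pathway_state`.
#' @export
single_pathway_state <- function(N_x, kappa = 1,
                                 normalization = c("by_N_x", "by_input_norm"),
                                 w = NULL) {
  N_x <- check_count(N_x, "N_x")
  if (!is.numeric(kappa) || kappa <= 0) stop_invalid("kappa must be > 0")
  normalization <- match.arg(normalization)
  if (is.null(w)) w <- numeric(N_x)
  stopifnot(length(w) == N_x, all(is.finite(w)))
  structure(list(w = as.numeric(w), kappa = kappa,
                 normalization = normalization),
            class = "single_pathway_state")
}

#' @export
print.single_pathway_state <- function(x, ...) {
  cat(sprintf("single_pathway_state: N_x = %d, kappa = %g, normalization = %s\n",
              length(x$w), x$kappa, x$normalization))
  cat(sprintf("  |w| = %.4f\n", sqrt(sum(x$w^2))))
  invisible(x)
}

#' One-step supervised (margin) update
#'
#' The summed input `u` is supplied by the caller so that the same rule serves
#' the two-pathway model, where `u` includes the slow-pathway current.
#'
#' @param state a [single_pathway_state()].
#' @param x input vector of length `N_x`.
#' @param zhat target, -1 or +1.
#' @param u summed input driving the readout (for the bare perceptron,
#'   `w . x`).
#' @return list with the updated `state` and logical `applied`.
#' @examples
#' st <- single_pathway_state(2)
#' supervised_update(st, x = c(1, 1), zhat = 1, u = 0)$state$w  # (0.5, 0.5)
#' @export
supervised_update <- function(state, x, zhat, u) {
  stopifnot(inherits(state, "single_pathway_state"), length(x) == length(state$w))
  check_pm1(zhat)
  if (u * zhat >= state$kappa) return(list(state = state, applied = FALSE))
  D <- if (state$normalization == "by_input_norm") sum(x^2) else length(x)
  state$w <- state$w + (state$kappa * zhat - u) * x / D
  list(state = state, applied = TRUE)
}

#' Sequential (one-pass) training
#'
#' Applies the margin update once per presentation, following the ensemble's
#' presentation order; no pattern is revisited after the schedule moves on.
#' This is the palimpsest regime in which later learning gradually overwrites
#' earlier learning.
#'
#' @param ensemble a [pattern_ensemble][generate_patterns] with `N_y = 0`.
#' @param state a [single_pathway_state()].
#' @param snapshots if TRUE, also return the weight vector after every
#'   presentation.
#' @return list with `state`, `n_updates`, and optionally `snapshots`
#'   (presentations x N_x matrix).
#' @export
train_sequential <- function(ensemble, state, snapshots = FALSE) {
  stopifnot(inherits(ensemble, "pattern_ensemble"),
            inherits(state, "single_pathway_state"))
  if (ncol(ensemble$Y) != 0)
    stop_invalid("train_sequential expects a single-pathway ensemble (N_y = 0)")
  res <- cpp_train_seq_single(ensemble$X, ensemble$Zhat[, 1], state$w,
                              state$kappa,
                              state$normalization == "by_input_norm",
                              ensemble$order, snapshots)
  state$w <- as.numeric(res$w)
  out <- list(state = state, n_updates = res$n_updates)
  if (snapshots) out$snapshots <- res$snapshots
  out
}

#' Cycled training to convergence
#'
#' Repeats full passes through all patterns until one pass makes no update
#' (all patterns classified with margin >= kappa) or `max_epochs` is reached.
#' For random Gaussian patterns with random labels this converges with high
#' probability when P < 2 N_x (large N_x) and fails beyond that capacity.
#'
#' Because the projection update drives a violated margin exactly onto the
#' boundary, margins can sit an infinitesimal distance below `kappa` for many
#' passes; a pass counts as converged when no margin is violated by more than
#' `tol` (the updates themselves still fire on any strict violation, so the
#' returned weights classify all patterns with margin `>= kappa - tol`).
#'
#' @inheritParams train_sequential
#' @param max_epochs epoch cap.
#' @param tol convergence tolerance on the margin.
#' @return list with `state`, logical `converged`, and `epochs` used.
#' @export
train_cycled <- function(ensemble, state, max_epochs = 10000, tol = 1e-6) {
  stopifnot(inherits(ensemble, "pattern_ensemble"),
            inherits(state, "single_pathway_state"))
  if (ncol(ensemble$Y) != 0)
    stop_invalid("train_cycled expects a single-pathway ensemble (N_y = 0)")
  res <- cpp_train_cycled(ensemble$X, ensemble$Zhat[, 1], state$w, state$kappa,
                          state$normalization == "by_input_norm",
                          as.integer(max_epochs), tol)
  state$w <- as.numeric(res$w)
  list(state = state, converged = res$converged, epochs = res$epochs)
}

#' Classify patterns with a weight vector
#'
#' @param ensemble a pattern ensemble with `N_y = 0`.
#' @param state a single-pathway state.
#' @return integer vector: 1 where `sgn(w . x) != zhat`, else 0.
#' @export
classification_errors <- function(ensemble, state) {
  u <- as.numeric(ensemble$X %*% state$w)
  as.integer(sgn(u) != ensemble$Zhat[, 1])
}

new_forgetting_curve <- function(tau, error, se, n_runs) {
  structure(data.frame(tau = tau, error = error, se = se, n_runs = n_runs),
            class = c("forgetting_curve", "data.frame"))
}

#' Monte-Carlo forgetting curve for the single-pathway model
#'
#' For each run, a burn-in of `burn_in` extra patterns is trained first (so
#' that tested patterns see the stationary weight regime), then `P` fresh
#' patterns are trained sequentially and every pattern `nu` is classified with
#' the final weights. Errors are averaged over runs at each normalized lag
#' `tau = (P - nu) / N_x`; the curve depends on the lag only through this
#' ratio, so memory is extensive in the number of synapses.
#'
#' @param N_x input dimension.
#' @param P number of tested patterns.
#' @param n_runs Monte-Carlo runs.
#' @param seed root seed.
#' @param burn_in burn-in length (default `4 * N_x`).
#' @param kappa margin.
#' @param normalization update normalization, see [single_pathway_state()].
#' @return a `forgetting_curve` data frame with columns `tau`, `error`, `se`,
#'   `n_runs`.
#' @export
estimate_forgetting_curve <- function(N_x, P, n_runs, seed = 1,
                                      burn_in = 4 * N_x, kappa = 1,
                                      normalization = "by_N_x") {
  N_x <- check_count(N_x, "N_x"); P <- check_count(P, "P")
  n_runs <- check_count(n_runs, "n_runs")
  seeds <- child_seeds(seed, n_runs)
  acc <- numeric(P)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    acc <- acc + cpp_forgetting_run(N_x, P, as.integer(burn_in), kappa,
                                    normalization == "by_input_norm")
  }
  p <- acc / n_runs
  tau <- (P - seq_len(P)) / N_x
  curve <- new_forgetting_curve(tau, p, sqrt(p * (1 - p) / n_runs), n_runs)
  curve[order(curve$tau), ]
}

#' Write a forgetting curve to CSV
#' @param curve a `forgetting_curve` (or theory curve) data frame.
#' @param path output file.
#' @export
write_forgetting_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Gradient-descent variant of sequential training
#'
#' Instead of the one-step jump, each pattern receives `n_steps` small
#' hinge-loss gradient steps (loss `max(0, kappa - u * zhat)`, whose minimum
#' reproduces the margin condition) before the schedule moves to the next
#' pattern. Produces a qualitatively similar forgetting curve to the one-step
#' rule.
#'
#' @inheritParams train_sequential
#' @param learning_rate positive step size.
#' @param n_steps gradient steps per pattern.
#' @return list with the updated `state`.
#' @export
train_gradient_descent <- function(ensemble, state, learning_rate = 0.05,
                                   n_steps = 100) {
  stopifnot(inherits(ensemble, "pattern_ensemble"),
            inherits(state, "single_pathway_state"))
  if (ncol(ensemble$Y) != 0)
    stop_invalid("train_gradient_descent expects N_y = 0")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_invalid("learning_rate must be > 0")
  n_steps <- check_count(n_steps, "n_steps", min = 0)
  w <- cpp_train_gd(ensemble$X, ensemble$Zhat[, 1], state$w, state$kappa,
                    learning_rate, n_steps, ensemble$order)
  state$w <- as.numeric(w)
  list(state = state)
}

#' Monte-Carlo forgetting curve for gradient-descent learning
#'
#' @inheritParams estimate_forgetting_curve
#' @param learning_rate,n_steps gradient-descent parameters per pattern.
#' @return a `forgetting_curve` data frame.
#' @export
estimate_gd_forgetting_curve <- function(N_x, P, n_runs, seed = 1,
                                         burn_in = 4 * N_x, kappa = 1,
                                         learning_rate = 0.05, n_steps = 100) {
  seeds <- child_seeds(seed, n_runs)
  acc <- numeric(P)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    ens <- generate_patterns(P + burn_in, N_x, 0, 1,
                             seed = sample.int(.Machine$integer.max - 1L, 1))
    st <- single_pathway_state(N_x, kappa)
    st <- train_gradient_descent(ens, st, learning_rate, n_steps)$state
    test <- seq(burn_in + 1, burn_in + P)
    u <- as.numeric(ens$X[test, , drop = FALSE] %*% st$w)
    acc <- acc + as.integer(sgn(u) != ens$Zhat[test, 1])
  }
  p <- acc / n_runs
  tau <- (P - seq_len(P)) / N_x
  curve <- new_forgetting_curve(tau, p, sqrt(p * (1 - p) / n_runs), n_runs)
  curve[order(curve$tau), ]
}

#' Storage-capacity estimate for cycled training
#'
#' For each load `P/N_x` on a grid, runs cycled training from fresh random
#' ensembles for `n_seeds` seeds and records the fraction that converge
#' within `max_epochs`. The critical capacity is estimated as the load at
#' which the (monotonized) converged fraction crosses 1/2, by linear
#' interpolation between grid points.
#'
#' @param N_x input dimension.
#' @param ratios grid of loads P/N_x.
#' @param n_seeds seeds per grid point.
#' @param max_epochs epoch cap for each run.
#' @param seed root seed.
#' @param kappa margin (does not change the capacity: the margin can be
#'   absorbed into the weight norm).
#' @return list with `table` (data frame: ratio, frac_converged) and the
#'   `critical_ratio` estimate.
#' @export
estimate_capacity <- function(N_x, ratios = seq(1.5, 2.5, by = 0.1),
                              n_seeds = 20, max_epochs = 10000, seed = 1,
                              kappa = 1) {
  N_x <- check_count(N_x, "N_x")
  seeds <- matrix(child_seeds(seed, n_seeds * length(ratios)),
                  nrow = length(ratios))
  frac <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    P <- max(1L, as.integer(round(ratios[i] * N_x)))
    conv <- logical(n_seeds)
    for (s in seq_len(n_seeds)) {
      ens <- generate_patterns(P, N_x, 0, 1, seed = seeds[i, s])
      st <- single_pathway_state(N_x, kappa)
      conv[s] <- train_cycled(ens, st, max_epochs)$converged
    }
    frac[i] <- mean(conv)
  }
  tab <- data.frame(ratio = ratios, frac_converged = frac)
  # monotonize (non-increasing in load) before locating the 50% crossing
  mono <- cummin(frac)
  crit <- NA_real_
  ix <- which(mono <= 0.5)
  if (length(ix) > 0 && ix[1] > 1) {
    i2 <- ix[1]; i1 <- i2 - 1
    crit <- ratios[i1] + (0.5 - mono[i1]) * (ratios[i2] - ratios[i1]) /
      (mono[i2] - mono[i1])
  } else if (length(ix) > 0) {
    crit <- ratios[1]
  }
  list(table = tab, critical_ratio = crit)
}
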