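test_that("the stochastic readout has the stated firing probabilities", {
  set.seed(1)
  z <- replicate(10000, stochastic_readout(0, 0))
  expect_lt(abs(mean(z == 1) - 0.5), 4 * sqrt(0.25 / 10000))
  expect_true(all(stochastic_readout(rep(20, 50)) == 1))

  m <- 0.7
  p <- 1 / (1 + exp(-m))
  z2 <- replicate(10000, stochastic_readout(m))
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(z2) - (2 * p - 1)), 4 * 2 * se)
})

test_that("reward is the normalized target overlap", {
  expect_equal(compute_reward(c(1, 1, 1, 1), c(1, 1, 1, 1)), 2)
  expect_equal(compute_reward(c(1, 1, 1, 1), c(-1, -1, -1, -1)), -2)
  expect_equal(compute_reward(c(1, 1, -1, -1), c(1, -1, 1, -1)), 0)
})

test_that("the REINFORCE update matches direct substitution", {
  # N_x = 1, eta = 1, R - Rbar = 0.5, z = +1, m + h = 0, x = 2
  W <- matrix(0, 1, 1)
  W2 <- reinforce_update(W, x = 2, z = 1, m = 0, h = 0, R = 0.5, Rbar = 0,
                         eta = 1)
  expect_equal(W2[1, 1], 0.5 * 1 * 0.5 * 2)
  # R = Rbar: no update
  expect_equal(reinforce_update(W, 2, 1, 0.3, 0.1, R = 1, Rbar = 1, eta = 1),
               W)
})

test_that("the expected update aligns with the supervised direction", {
  # brute-force expectation over all 2^N_z readout outcomes vs Monte Carlo
  N_z <- 4; N_x <- 3
  set.seed(5)
  x <- rnorm(N_x); zhat <- c(1, -1, 1, 1)
  u <- rnorm(N_z, sd = 0.8)  # currents (h = 0)
  Rbar <- 0.2; eta <- 1
  sigma <- function(v) 1 / (1 + exp(-v))
  EdW <- matrix(0, N_z, N_x)
  for (k in 0:(2^N_z - 1)) {
    z <- 2 * as.integer(intToBits(k)[1:N_z]) - 1
    pz <- prod(ifelse(z == 1, sigma(u), 1 - sigma(u)))
    R <- sum(z * zhat) / sqrt(N_z)
    EdW <- EdW + pz * (eta / N_x) * (R - Rbar) *
      tcrossprod(z * sigma(-z * u), x)
  }
  # positive projection on the supervised direction zhat x^T
  expect_gt(sum(EdW * tcrossprod(zhat, x)), 0)

  n_mc <- 4000
  set.seed(6)
  acc <- matrix(0, N_z, N_x)
  draws <- array(0, dim = c(n_mc, N_z, N_x))
  for (i in seq_len(n_mc)) {
    z <- stochastic_readout(u)
    R <- compute_reward(z, zhat)
    d <- reinforce_update(matrix(0, N_z, N_x), x, z, u, 0, R, Rbar, eta)
    draws[i, , ] <- d
    acc <- acc + d
  }
  mc <- acc / n_mc
  se <- apply(draws, c(2, 3), sd) / sqrt(n_mc)
  expect_true(all(abs(mc - EdW) < 3 * se + 1e-12))
})

test_that("the reward baseline follows its exact filter", {
  expect_equal(update_baseline(0, 1, tau_R = 10), 0.1)
  expect_equal(update_baseline(0.7, 0.7, tau_R = 5), 0.7)
  # constant reward stream: geometric closed form
  Rbar <- 0; R <- 2; tau <- 10
  for (n in 1:25) Rbar <- update_baseline(Rbar, R, tau)
  expect_equal(Rbar, R * (1 - (1 - 1 / tau)^25), tolerance = 1e-12)
})

test_that("frozen learning rates leave the weights invariant", {
  st <- rl_state(N_x = 50, N_y = 50, N_z = 5, eta = 0, beta = 0,
                 variant = "RL_plus_HL", alpha = 0)
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50); zhat <- sgn(runif(5) - 0.5)
  fit <- train_rl(st, x, y, zhat, 200, seed = 3)
  expect_identical(fit$state$W, st$W)
  expect_identical(fit$state$V, st$V)
})

test_that("reinforcement learning improves reward on a single pattern", {
  final <- sapply(1:20, function(s) {
    st <- rl_state(N_x = 200, N_y = 0, N_z = 10, variant = "RL_only",
                   init_seed = s)
    set.seed(100 + s)
    x <- rnorm(200); zhat <- sgn(runif(10) - 0.5)
    tr <- train_rl(st, x, numeric(0), zhat, 2000, seed = 200 + s)$traces
    c(first = mean(tr$reward[1:200]), last = mean(tr$reward[1801:2000]))
  })
  expect_gt(mean(final["last", ]), mean(final["first", ]))
  expect_gt(mean(final["last", ]), 0.8 * sqrt(10))
})

test_that("RL+HL alignment keeps growing after reward saturates", {
  st <- rl_state(variant = "RL_plus_HL", init_seed = 7)
  set.seed(8)
  x <- rnorm(1000); y <- rnorm(1000); zhat <- sgn(runif(10) - 0.5)
  tr <- train_rl(st, x, y, zhat, 2500, seed = 9)$traces
  sat <- which(tr$Rbar > 0.9 * sqrt(10))[1]
  expect_false(is.na(sat))
  al <- tr$alignment[sat:nrow(tr)]
  iso <- isoreg(seq_along(al), al)
  expect_lt(mean(abs(iso$yf - al)), 0.05)
  expect_gt(al[length(al)] - al[1], 0.1)
})

test_that("habit persistence grows with practice only under Hebbian learning", {
  cap <- 3000
  res <- expand.grid(n_nu = c(0, 300), variant = c("RL_only", "RL_plus_HL"),
                     seed = 1:2)
  res$trials <- mapply(function(n, v, s) {
    r <- habit_experiment(as.character(v), n, seed = 37 * s, trial_cap = cap)
    if (r$attained) r$trials_to_criterion else cap
  }, res$n_nu, res$variant, res$seed)
  base <- with(res, tapply(trials, list(n_nu, variant), mean))
  # no pre-training: both variants realign in comparable (short) time
  expect_lt(base["0", "RL_only"], 200)
  expect_lt(base["0", "RL_plus_HL"], 200)
  # practiced association: the Hebbian pathway locks the habit in
  expect_gt(base["300", "RL_plus_HL"], base["300", "RL_only"])
})
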