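test_that("the Hebbian rule matches its closed-form examples", {
  V <- hebbian_update(matrix(0, 1, 2), y = c(1, 1), zhat = 1,
                      alpha = 1, beta = 1, n_mu = 1, nbar = 1)
  expect_equal(as.numeric(V), c(sqrt(2) / 2, sqrt(2) / 2))

  # fixed point under repetition of one pattern: v* = sqrt(2) beta/alpha z y
  y <- c(0.5, -1, 2); zhat <- -1; alpha <- 0.5; beta <- 2
  vstar <- matrix(sqrt(2) * beta / alpha * zhat * y, 1)
  expect_equal(hebbian_update(vstar, y, zhat, alpha, beta), vstar)

  # alpha = beta = 0 is the identity
  V0 <- matrix(rnorm(6), 2, 3)
  expect_equal(hebbian_update(V0, rnorm(3), c(1, -1), 0, 0), V0)

  # N_y = 0 is a no-op
  expect_equal(ncol(hebbian_update(matrix(0, 1, 0), numeric(0), 1, 1, 1)), 0)
})

test_that("pathway decomposition identities hold", {
  st <- two_pathway_state(3, 3, N_z = 2)
  st$W <- matrix(c(1, 0, 0, 1, 0, 0), 2, 3)
  x <- c(1, 2, 3); y <- c(0, 0, 0); zhat <- c(1, -1)
  d <- pathway_decomposition(st, x, y, zhat)
  expect_equal(d$alignment, 0)       # |h| = 0 convention
  expect_equal(d$control_ratio, 0)   # h = 0

  st$V <- matrix(1, 2, 3); st$W <- matrix(0, 2, 3)
  d2 <- pathway_decomposition(st, x, c(1, 1, 1), zhat)
  expect_equal(d2$control_ratio, 1)  # m = 0

  st$W <- matrix(rnorm(6), 2, 3)
  d3 <- pathway_decomposition(st, x, c(1, 1, 1), zhat)
  expect_gte(d3$alignment, -1); expect_lte(d3$alignment, 1)
})

test_that("repetition grows alignment and transfers control", {
  st <- two_pathway_state(500, 500, N_z = 100, init = "random", init_seed = 2)
  set.seed(11)
  x <- rnorm(500); y <- rnorm(500); zhat <- sgn(runif(100) - 0.5)
  pr <- present_pattern(st, x, y, zhat, n = 25)
  tr <- pr$trace
  # correct output from the first repetition on (margin rule on u = m + h)
  expect_equal(tr$error, rep(0, 25))
  # alignment non-decreasing, control ratio toward slow-pathway dominance
  expect_true(all(diff(tr$alignment) > -1e-9))
  expect_gt(tr$alignment[25], tr$alignment[1])
  expect_true(all(diff(tr$control_ratio) > -1e-6))
  expect_gt(tr$control_ratio[25], 0.9)
})

test_that("beta = 0 reduces the module exactly to the single-pathway model", {
  ens <- generate_patterns(60, 40, 40, 1, seed = 13)
  st2 <- two_pathway_state(40, 40, 1, alpha = 1, beta = 0)
  fit2 <- train_two_pathway(ens, st2)
  expect_equal(as.numeric(fit2$state$V), rep(0, 40))

  ens1 <- twopathway:::new_pattern_ensemble(
    ens$X, matrix(0, 60, 0), ens$Zhat, ens$repeats, ens$order)
  fit1 <- train_sequential(ens1, single_pathway_state(40))
  expect_equal(as.numeric(fit2$state$W), fit1$state$w)
})

test_that("aggregated and per-repetition Hebbian modes agree at small beta", {
  ens <- generate_patterns(30, 50, 50, 1, seed = 17)
  ens <- set_schedule(ens, make_repetition_schedule(30, special = c("10" = 6)))
  fits <- lapply(c("per_repetition", "aggregated"), function(mode) {
    st <- two_pathway_state(50, 50, 1, alpha = 1, beta = 0.05, nbar = ens$nbar,
                            hebbian_application = mode)
    train_two_pathway(ens, st)$state
  })
  expect_lt(max(abs(fits[[1]]$V - fits[[2]]$V)), 0.02)
  expect_lt(max(abs(fits[[1]]$W - fits[[2]]$W)), 0.05)
})

test_that("slow-pathway weights stay bounded under long training", {
  N_y <- 30
  st <- two_pathway_state(30, N_y, 1, alpha = 1, beta = 1)
  set.seed(19)
  bound <- 10 * (1 / 1) * sqrt(2)  # 10 (beta/alpha) sqrt(2) max|y| with |y|<=1
  for (k in seq_len(10 * N_y)) {
    y <- runif(N_y, -1, 1)
    st$V <- hebbian_update(st$V, y, sgn(runif(1) - 0.5), 1, 1)
    expect_true(all(abs(st$V) <= bound))
  }
})

test_that("population overlaps start near zero and grow with repetition", {
  st <- two_pathway_state(400, 400, N_z = 400, init = "random", init_seed = 23)
  set.seed(29)
  x <- rnorm(400); y <- rnorm(400); zhat <- sgn(runif(400) - 0.5)
  ov0 <- population_similarity(st, x, y)
  # untrained pathways drive independent random signs
  expect_lt(abs(ov0["overlap_m0_h0"]), 4 / sqrt(400))
  # the intact readout shares the slow current, so its overlap with the
  # slow-only readout starts near the independent-pathway value 1/2
  expect_lt(abs(ov0["overlap_m0_intact"] - 0.5), 4 / sqrt(400))

  st5 <- present_pattern(st, x, y, zhat, n = 5)$state
  ov5 <- population_similarity(st5, x, y)
  st40 <- present_pattern(st5, x, y, zhat, n = 35)$state
  ov40 <- population_similarity(st40, x, y)
  expect_gt(ov5["overlap_m0_h0"], ov0["overlap_m0_h0"])
  expect_gt(ov40["overlap_m0_h0"], 0.8)
  # fully transferred pattern: slow pathway alone reproduces the intact output
  expect_gt(ov40["overlap_m0_intact"], 0.95)
})

test_that("lesion modes and noise perturbations behave as documented", {
  ens <- generate_patterns(40, 30, 30, 5, seed = 31)
  st <- two_pathway_state(30, 30, 5)
  st <- train_two_pathway(ens, st)$state
  base <- lesion_test(st, ens, "intact")
  noise0 <- lesion_test(st, ens, "intact", sigma_m = 0)
  expect_equal(base$error, noise0$error)   # zero noise identical to standard
  big <- lesion_test(st, ens, "intact", sigma_m = 50, n_noise_draws = 200,
                     seed = 4)
  expect_gt(mean(big$error), mean(base$error))
  expect_error(lesion_test(st, ens, "m_zero", sigma_m = 1), "intact")
})

test_that("repetitions_to_threshold searches the repetition count correctly", {
  # interval 0: a single presentation already yields zero error
  r <- repetitions_to_threshold(100, 100, interval = 0, p_theta = 0.1,
                                n_runs = 30, seed = 1, burn_in = 100)
  expect_true(r$attained)
  expect_equal(r$n, 1L)

  r2 <- repetitions_to_threshold(100, 100, interval = 150, p_theta = 0.1,
                                 n_runs = 60, seed = 2, burn_in = 200)
  expect_true(r2$attained)
  expect_gt(r2$n, 1L)
})
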