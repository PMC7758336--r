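test_that("the minimum-jerk profile has its closed-form properties", {
  tg <- c(1, 0)
  expect_equal(minimum_jerk_velocity(0, 10, tg), c(0, 0))
  expect_equal(minimum_jerk_velocity(10, 10, tg), c(0, 0))
  expect_error(minimum_jerk_velocity(11, 10, tg), "t must")

  # displacement accumulated at dt = 1/T reproduces the target up to the
  # Riemann discretization error of the quartic profile
  T <- 10
  disp <- Reduce(`+`, lapply(1:T, function(t)
    minimum_jerk_velocity(t, T, c(1, -1)) / T))
  expect_equal(disp, c(1, -1), tolerance = 0.02)
})

test_that("trial rollouts are deterministic and internally consistent", {
  sp <- reaching_spec()
  net <- reaching_network(sp, seed = 3)
  r1 <- simulate_trial(net, 1, learn = FALSE)
  r2 <- simulate_trial(net, 1, learn = FALSE)
  expect_identical(r1$trace$positions, r2$trace$positions)
  expect_gt(r1$trace$loss, 0)

  # positions integrate the velocities with dt = 1/T
  pos <- r1$trace$positions; vel <- r1$trace$velocities
  expect_equal(pos[nrow(pos), ] - pos[1, ], colSums(vel) / sp$T,
               tolerance = 1e-12)
  # reported loss is the mean squared velocity error over steps and dims
  uhat <- t(sapply(1:sp$T, function(t) minimum_jerk_velocity(t, sp$T, c(1, 0))))
  expect_equal(r1$trace$loss, mean((vel - uhat)^2))
})

test_that("zero Hebbian rate makes SL+HL and SL-only bit-identical", {
  bs <- data.frame(target = c(1, 2), n_trials = c(50L, 50L))
  sp_hl <- reaching_spec(eta_HL = 0, condition = "SL_plus_HL",
                         block_schedule = bs)
  sp_sl <- reaching_spec(eta_HL = 0, condition = "SL_only",
                         block_schedule = bs)
  f1 <- train_blocks(sp_hl, seed = 5)
  f2 <- train_blocks(sp_sl, seed = 5)
  expect_identical(f1$net$W, f2$net$W)
  expect_identical(f1$loss_trace$loss, f2$loss_trace$loss)
})

test_that("training reduces the loss within each block", {
  sp <- reaching_spec(condition = "SL_only")
  ok <- sapply(1:5, function(s) {
    tr <- train_blocks(sp, seed = s)$loss_trace
    sapply(split(tr, cumsum(c(1, diff(tr$target) != 0))), function(b) {
      n <- nrow(b)
      lead <- mean(b$loss[1:min(50, n)])
      trail <- mean(b$loss[max(1, n - 49):n])
      trail <= lead
    })
  })
  expect_gt(mean(ok), 0.8)

  # sequential overwriting: target-1 loss rises after training target 2
  rose <- sapply(1:5, function(s) {
    net <- reaching_network(reaching_spec(condition = "SL_only"), seed = s)
    r1 <- twopathway:::reach_run(net, rep(1L, 2000), TRUE, FALSE)
    l1 <- twopathway:::reach_run(r1$net, 1L, FALSE, FALSE)$loss
    r2 <- twopathway:::reach_run(r1$net, rep(2L, 500), TRUE, FALSE)
    l2 <- twopathway:::reach_run(r2$net, 1L, FALSE, FALSE)$loss
    l2 > l1
  })
  expect_gt(mean(rose), 0.7)
})

test_that("interleaved training balances the four targets", {
  sp <- reaching_spec(condition = "SL_interleaved")
  nets <- lapply(1:4, function(s) train_blocks(sp, seed = s)$net)
  ret <- evaluate_retention(nets)
  expect_equal(nrow(ret), 4)
  expect_lt(max(ret$mean_loss) / max(min(ret$mean_loss), 1e-6), 6)
})

test_that("retention evaluation handles the degenerate empty request", {
  out <- evaluate_retention(list(), n_test_trials = 0)
  expect_equal(nrow(out), 0)
  sp <- reaching_spec()
  out2 <- evaluate_retention(list(train_blocks(sp, 1)$net), n_test_trials = 0)
  expect_equal(nrow(out2), 0)
})
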