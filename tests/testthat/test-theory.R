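test_that("stationary statistics solve the balance condition", {
  for (prm in list(c(a = 1, b = 0), c(a = 1, b = 1), c(a = 0.5, b = 2))) {
    st <- stationary_input_stats(alpha = unname(prm["a"]),
                                 beta = unname(prm["b"]))
    s <- st$sigma_u; c0 <- 1 / s
    resid <- (1 + 2 * st$sigma_h2 - s^2) * pnorm(c0) + s * dnorm(c0)
    expect_lt(abs(resid), 1e-8)
    expect_equal(st$sigma_w2 + st$sigma_h2, s^2)
    expect_equal(st$q, pnorm(1 / s))
  }
  expect_error(stationary_input_stats(alpha = 0, beta = 1), "alpha")
})

test_that("the single-pathway curve has the right limits and shape", {
  expect_equal(theoretical_error_single(0), 0)
  expect_lt(abs(theoretical_error_single(1000) - 0.5), 1e-3)
  tau <- c(0.1, 0.25, 0.5, 1, 2, 4, 8)
  f <- theoretical_error_single(tau)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 0.5))
  expect_error(theoretical_error_single(-1), "tau")
})

test_that("the two-pathway curve reduces to and extends the single one", {
  tau <- c(0.25, 0.5, 1, 2)
  f <- theoretical_error_single(tau)
  g0 <- theoretical_error_two_pathway(tau, ratio = 1, alpha = 1, beta = 1e-9,
                                      n_ratio = 1)
  expect_equal(g0, f, tolerance = 1e-4)

  # error decreases with practice at fixed lag
  for (tt in c(0.5, 1, 2)) {
    g <- theoretical_error_two_pathway(tt, 1, 1, 1,
                                       n_ratio = c(1, 2, 5, 10, 20))
    expect_true(all(diff(g) < 0))
  }
  expect_equal(theoretical_error_two_pathway(0, 1, 1, 1, 5), 0)
})

test_that("practice shifts the theoretical curves in parallel", {
  taus <- seq(0.2, 3, by = 0.01)
  g5 <- theoretical_error_two_pathway(taus, 1, 1, 1, 5)
  g10 <- theoretical_error_two_pathway(taus, 1, 1, 1, 10)
  shifts <- sapply(c(0.1, 0.2, 0.3), function(L)
    approx(g10, taus, L)$y - approx(g5, taus, L)$y)
  expect_true(all(shifts > 0))
  expect_lt(sd(shifts) / mean(shifts), 0.25)
})

test_that("theory curves tabulate with method metadata", {
  tc <- theory_curve(c(0, 0.5, 1), beta = 1, n_ratio = 2)
  expect_s3_class(tc, "theory_curve")
  expect_equal(tc$method, rep("numeric_drift_diffusion", 3))
  path <- tempfile(fileext = ".csv")
  write_forgetting_curve(tc, path)
  back <- read.csv(path)
  expect_equal(back$error, tc$error)
  unlink(path)
})
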