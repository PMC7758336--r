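test_that("generated ensembles satisfy the shape and value contracts", {
  ens <- generate_patterns(P = 1, N_x = 3, N_y = 0, N_z = 1, seed = 0)
  expect_equal(dim(ens$X), c(1, 3))
  expect_equal(dim(ens$Y), c(1, 0))
  expect_true(all(ens$Zhat %in% c(-1, 1)))
  expect_equal(ens$repeats, 1L)
  expect_equal(ens$nbar, 1)

  ens2 <- generate_patterns(P = 5, N_x = 4, N_y = 6, N_z = 3, seed = 2)
  expect_equal(dim(ens2$Y), c(5, 6))
  expect_equal(dim(ens2$Zhat), c(5, 3))

  expect_error(generate_patterns(0, 10), "P")
  expect_error(generate_patterns(10, 0), "N_x")
  expect_error(generate_patterns(10, 10, 0, 0), "N_z")
})

test_that("entries are i.i.d. standard normal at statistical tolerance", {
  ens <- generate_patterns(P = 1000, N_x = 10, N_y = 10, N_z = 1, seed = 3)
  n <- length(ens$X)
  expect_lt(abs(mean(ens$X)), 4 / sqrt(n))
  expect_lt(abs(var(as.numeric(ens$X)) - 1), 4 * sqrt(2 / n))
  expect_lt(abs(mean(ens$Y)), 4 / sqrt(n))
  # fair targets
  expect_lt(abs(mean(ens$Zhat)), 4 / sqrt(nrow(ens$Zhat)))
})

test_that("generation is bit-for-bit reproducible under a fixed seed", {
  a <- generate_patterns(20, 15, 5, 2, seed = 7)
  b <- generate_patterns(20, 15, 5, 2, seed = 7)
  c <- generate_patterns(20, 15, 5, 2, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$X, c$X))
})

test_that("repetition schedules place repeats as specified", {
  s <- make_repetition_schedule(3, special = c("2" = 5))
  expect_equal(s$repeats, c(1L, 5L, 1L))
  expect_equal(s$order, c(1L, rep(2L, 5), 3L))

  s0 <- make_repetition_schedule(3)
  expect_equal(s0$repeats, rep(1L, 3))
  expect_equal(s0$order, 1:3)

  # spaced repetition: one other pattern between the two presentations
  s1 <- make_repetition_schedule(4, special = c("1" = 2), default_gap = 1)
  pos <- which(s1$order == 1L)
  expect_length(pos, 2)
  expect_equal(pos[2] - pos[1], 2L)
  expect_equal(sort(tabulate(s1$order, 4)), c(1L, 1L, 1L, 2L))

  expect_error(make_repetition_schedule(3, special = c("9" = 2)), "indices")
})

test_that("schedules attach to ensembles and update nbar", {
  ens <- generate_patterns(4, 5, 5, 1, seed = 1)
  ens <- set_schedule(ens, make_repetition_schedule(4, special = c("2" = 3)))
  expect_equal(ens$repeats, c(1L, 3L, 1L, 1L))
  expect_equal(ens$nbar, 1.5)
  expect_length(ens$order, 6)
})

test_that("ensembles survive a serialization round trip", {
  ens <- generate_patterns(6, 4, 3, 2, seed = 9)
  path <- tempfile(fileext = ".rds")
  write_ensemble(ens, path)
  expect_identical(read_ensemble(path), ens)
  unlink(path)
})
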