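test_that("closed-form counts obey the rate law", {
  kin <- nucleation_kinetics(1.2, 100)
  expect_identical(nucleation_counts(0, kin), 0)
  # pinned against an independent high-precision evaluation
  expect_equal(nucleation_counts(10, kin), 11.307956328284252, tolerance = 1e-12)
  # saturation limit
  expect_equal(nucleation_counts(1e6, nucleation_kinetics(1, 50)), 50,
               tolerance = 1e-6 / 50)
  # vectorizes
  expect_length(nucleation_counts(0:10, kin), 11L)
  # initial slope is k (analytic derivative at 0)
  h <- 1e-7
  expect_equal(nucleation_counts(h, kin) / h, 1.2, tolerance = 1e-6)
})

test_that("domain errors are rejected", {
  expect_error(nucleation_kinetics(-1, 10))
  expect_error(nucleation_kinetics(1, 0))
  expect_error(nucleation_kinetics(1, 10, switch_time = 50))
  expect_error(nucleation_counts(-1, nucleation_kinetics(1, 10)))
  expect_error(count_trajectory(c(0, 1, 1), c(0, 1, 2)))
  expect_error(count_trajectory(c(0, 1), c(0, -1)))
})

test_that("discrete trajectory reproduces the per-second recursion", {
  # linear regime: one MT per second while far from capacity
  tr <- nucleation_trajectory(nucleation_kinetics(1, 1e9), duration = 5)
  expect_equal(tr$count, 0:5, tolerance = 1e-8)
  # hand-evaluated recursion
  tr2 <- nucleation_trajectory(nucleation_kinetics(2, 4), duration = 3)
  expect_equal(tr2$count, c(0, 2, 3, 3.5))
  # exact initial slope
  tr3 <- nucleation_trajectory(nucleation_kinetics(7.3, 55), 10, dt = 0.5)
  expect_equal((tr3$count[2] - tr3$count[1]) / 0.5, 7.3)
})

test_that("trajectories are monotone and bounded for random parameters", {
  set.seed(42)
  for (i in 1:25) {
    kin <- nucleation_kinetics(runif(1, 0, 60), runif(1, 1, 500))
    tr <- nucleation_trajectory(kin, duration = 200,
                                dt = sample(c(0.5, 1, 2), 1))
    expect_true(all(diff(tr$count) >= 0))
    expect_true(all(tr$count <= kin$n_max + 1e-9))
  }
})

test_that("discrete trajectory converges to the closed form as dt shrinks", {
  for (pars in list(c(24.5, 300), c(1.2, 100), c(50, 60))) {
    kin <- nucleation_kinetics(pars[1], pars[2])
    tr <- nucleation_trajectory(kin, duration = 150, dt = 1 / 16)
    dev <- max(abs(tr$count - nucleation_counts(tr$time_s, kin)))
    expect_lt(dev, 0.01 * kin$n_max)
  }
})

test_that("two-phase trajectory switches rate and capacity continuously", {
  slow <- nucleation_kinetics(2.4, 60)
  wt <- nucleation_kinetics(24.5, 300)
  # degenerate: switch at the end -> single-phase slow
  expect_equal(two_phase_trajectory(slow, wt, 300, 300)$count,
               nucleation_trajectory(slow, 300)$count)
  # self-switch -> single-phase wildtype (equal up to the capacity
  # restart on the almost-exhausted remainder)
  expect_equal(two_phase_trajectory(wt, wt, 150, 300)$count,
               nucleation_trajectory(wt, 300)$count, tolerance = 1e-5)
  # pinned against an independent evaluation of the recursion
  tp <- two_phase_trajectory(slow, wt, 150, 300)
  expect_equal(tp$count[tp$time_s == 150], 59.86852711098634, tolerance = 1e-10)
  expect_equal(tp$count[tp$time_s == 160], 218.13849370224352, tolerance = 1e-10)
  # continuity: one-step jump at the switch bounded by the new rate
  i <- which(tp$time_s == 151)
  expect_lte(tp$count[i] - tp$count[i - 1], 24.5 * (1 + 1e-12))
  expect_true(all(diff(tp$count) >= 0))
})

test_that("exhausted wildtype capacity floors at zero without MT removal", {
  slow <- nucleation_kinetics(5, 100)
  tiny <- nucleation_kinetics(24.5, 10)   # capacity below N(switch)
  expect_message(tp <- two_phase_trajectory(slow, tiny, 50, 100),
                 "floored")
  n50 <- tp$count[tp$time_s == 50]
  expect_true(all(tp$count[tp$time_s >= 50] == n50))
})

test_that("trajectory CSVs round-trip byte-identically", {
  kin <- nucleation_kinetics(24.5, 300)
  tr <- nucleation_trajectory(kin, 150)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_trajectory(tr, p1)
  back <- read_trajectory(p1)
  expect_equal(back$count, tr$count, tolerance = 1e-11)
  write_trajectory(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
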