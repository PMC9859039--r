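wt_traj <- function(k = 24.5, n_max = 300, ts = seq(0, 150, 2)) {
  count_trajectory(ts, nucleation_counts(ts, nucleation_kinetics(k, n_max)))
}

test_that("noise-free parameter recovery is exact over the working range", {
  f <- fit_nucleation(wt_traj())
  expect_true(f$converged)
  expect_equal(f$k_hat, 24.5, tolerance = 1e-4)
  expect_equal(f$n_max_hat, 300, tolerance = 1e-4)
  for (k in c(0.5, 5, 50)) {
    for (nm in c(10, 100, 1000)) {
      fi <- fit_nucleation(wt_traj(k, nm))
      expect_equal(fi$k_hat, k, tolerance = 1e-3)
    }
  }
})

test_that("near-linear trajectories give the slope with weak capacity", {
  ts <- seq(0, 150, 2)
  f <- fit_nucleation(count_trajectory(ts, 1.2 * ts))
  expect_equal(f$k_hat, 1.2, tolerance = 0.01)
  expect_gt(f$n_max_hat, 10 * max(1.2 * ts) * 0.5)
  expect_true(f$weakly_identified)
})

test_that("per-second discrete data bias the rate by less than 5%", {
  tr <- nucleation_trajectory(nucleation_kinetics(24.5, 300), 150)
  f <- fit_nucleation(tr)
  expect_lt(abs(f$k_hat - 24.5) / 24.5, 0.05)
  # the discrete trajectory is itself exponential with rate
  # -n_max*log(1 - k/n_max); the fit should land there
  expect_equal(f$k_hat, -300 * log(1 - 24.5 / 300), tolerance = 1e-3)
})

test_that("fit errors and degenerate inputs are handled", {
  expect_error(fit_nucleation(count_trajectory(c(0, 2, 4), c(0, 1, 2))),
               "at least 5")
  flat <- fit_nucleation(count_trajectory(seq(0, 150, 10),
                                          rep(0, 16)))
  expect_false(isTRUE(flat$converged) && flat$k_hat > 1)
})

test_that("scaling time and rate inversely leaves the capacity invariant", {
  for (cc in c(0.5, 4)) {
    ts <- seq(0, 150, 2)
    a <- fit_nucleation(wt_traj(24.5, 300, ts))
    b <- fit_nucleation(count_trajectory(
      ts * cc, nucleation_counts(ts * cc,
                                 nucleation_kinetics(24.5 / cc, 300))),
      window = c(0, 150 * cc))
    expect_equal(a$n_max_hat, b$n_max_hat, tolerance = 1e-4)
    expect_equal(b$k_hat * cc, a$k_hat, tolerance = 1e-4)
  }
})

test_that("rate recovery is unbiased under count noise", {
  set.seed(2024)
  ts <- seq(0, 150, 2)
  mu <- nucleation_counts(ts, nucleation_kinetics(24.5, 300))
  ks <- replicate(100, {
    y <- rpois(length(mu), mu)
    fit_nucleation(count_trajectory(ts, y))$k_hat
  })
  expect_lt(abs(mean(ks) - 24.5) / 24.5, 0.1)
})

test_that("late-phase slope measures the residual nucleation rate", {
  ts <- seq(0, 150, 1)
  expect_equal(late_slope(count_trajectory(ts, rep(88, length(ts)) + ts * 0)),
               0, tolerance = 1e-10)
  expect_equal(late_slope(count_trajectory(ts, 0.15 * ts + 3)), 0.15)
  # wildtype-like curve saturating by ~30 s: small residual slope,
  # pinned from an independent least-squares evaluation
  wt <- wt_traj()
  expect_equal(late_slope(wt), 0.14499631560700638, tolerance = 1e-8)
  expect_lt(late_slope(wt), 0.05 * 24.5)
  expect_error(late_slope(count_trajectory(c(0, 100, 200), c(0, 1, 2))),
               "at least 3")
})

test_that("replicate aggregation gives mean and SEM of the rate", {
  agg <- aggregate_replicates(c(10, 12, 14))
  expect_equal(agg$mean_k, 12)
  expect_equal(agg$sem_k, 2 / sqrt(3))
  expect_true(is.na(aggregate_replicates(5)$sem_k))
  expect_equal(aggregate_replicates(rep(7, 4))$sem_k, 0)
  expect_error(aggregate_replicates(numeric()))
  expect_error(aggregate_replicates(list()))
})

test_that("condition comparison is a two-sided unpaired t-test", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$t, 0)
  # textbook case, p pinned from an independent implementation
  cmp <- compare_conditions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$p_value, 0.021311641128757, tolerance = 1e-10)
  expect_true(cmp$significant)
  set.seed(1)
  big <- compare_conditions(rnorm(200), rnorm(200, 10))
  expect_lt(big$p_value, 1e-6)
  expect_equal(compare_conditions(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(compare_conditions(1, c(1, 2)))
})

test_that("normalization divides by the control (mean or paired)", {
  expect_equal(normalize_condition(c(2, 4), c(1, 1, 1)), c(2, 4))
  ctrl <- c(1.9, 2.1)
  expect_equal(mean(normalize_condition(ctrl, ctrl)), 1)
  # per-experiment pairing on a 2x4 toy table, hand arithmetic
  treated <- c(4, 6, 10, 3)
  buffers <- c(2, 3, 4, 2)
  norm <- normalize_condition(treated, buffers, paired = TRUE)
  expect_equal(norm, c(2, 2, 2.5, 1.5))
  expect_equal(mean(norm), 2)
  expect_equal(sd(norm) / 2, sd(c(2, 2, 2.5, 1.5)) / sqrt(4), tolerance = 1e-12)
  expect_error(normalize_condition(1, c(0, 0)))
})

test_that("trajectory files fit into a condition summary", {
  dir <- tempfile(); dir.create(dir)
  files <- character(0); conds <- character(0)
  for (cond in c("buffer", "activator")) {
    k <- if (cond == "buffer") 1.2 else 24.5
    for (r in 1:2) {
      ts <- seq(0, 150, 2)
      f <- file.path(dir, sprintf("%s_%d.csv", cond, r))
      write_trajectory(count_trajectory(
        ts, nucleation_counts(ts, nucleation_kinetics(k * (1 + 0.02 * (r - 1.5)),
                                                      300))), f)
      files <- c(files, f); conds <- c(conds, cond)
    }
  }
  res <- fit_trajectories(files, conds, control = "buffer")
  expect_true(all(res$fits$converged))
  act <- res$summary[res$summary$condition == "activator", ]
  expect_equal(round(act$fold_change), 20)
  expect_lt(act$p_value, 0.05)
  expect_equal(res$summary$fold_change[res$summary$condition == "buffer"], 1)
})
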