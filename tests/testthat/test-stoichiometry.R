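test_that("stathmin sequestration arithmetic", {
  # 4 uM stathmin removes 8 uM tubulin from a 15 uM reaction
  expect_equal(free_tubulin(sequestration_state(15, 4)), 7)
  # no stathmin leaves the pool untouched
  expect_equal(free_tubulin(sequestration_state(11.3, 0)), 11.3)
  # excess stathmin floors at zero
  expect_equal(free_tubulin(sequestration_state(15, 10)), 0)
  # exogenous stathmin adds to the endogenous pool
  expect_equal(sequestration_state(15, 1.5, stathmin_added = 2.7)$stathmin,
               4.2)
  expect_error(sequestration_state(-1, 2))
})

test_that("sequestration conserves mass", {
  set.seed(7)
  for (i in 1:20) {
    st <- sequestration_state(runif(1, 0, 30), runif(1, 0, 10),
                              stoichiometry = sample(1:3, 1))
    removed <- min(st$stoichiometry * st$stathmin, st$tubulin_total)
    expect_equal(st$tubulin_free + removed, st$tubulin_total)
    expect_lte(st$tubulin_free, st$tubulin_total)
  }
})

test_that("fold change is a plain ratio with a guarded reference", {
  expect_equal(round(fold_change(24.5, 1.2)), 20)   # the ~20-fold activation
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_equal(fold_change(0, 5), 0)
  expect_error(fold_change(1, 0))
  expect_error(fold_change(1, -2))
})

test_that("dimer occupancy splits retained and lost fractions", {
  occ <- dimer_occupancy(50, 150)
  expect_equal(occ$retained, 1 / 3)
  expect_equal(round(occ$lost * 100), 67)   # two thirds lost their dimer
  expect_equal(dimer_occupancy(0, 150), list(retained = 0, lost = 1))
  expect_equal(dimer_occupancy(150, 150), list(retained = 1, lost = 0))
  expect_equal(dimer_occupancy(200, 150)$retained, 1)  # capped
  expect_error(dimer_occupancy(50, 0))
})
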