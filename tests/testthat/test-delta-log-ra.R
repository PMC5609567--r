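test_that("a mutant identical to WT gives exactly zero, not significant", {
  d <- deltaLogRAFromSummary(9.5, 30, 9.5, 30, 100)
  expect_identical(d@delta, 0)
  expect_identical(d@se, 0)
  expect_false(d@significant)
})

test_that("noiseless constructed truths are reproduced to 1e-9", {
  cases <- data.frame(
    wp = c(10.0, 9.2, 8.5), we = c(30, 25, 40),
    mp = c(8.0, 9.2, 10.1), me = c(15, 12, 44),
    f = c(1.0, 0.8, 1.25))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      truth <- (log10(we) + wp) - (log10(me) + mp - log10(f))
      d <- deltaLogRAFromSummary(wp, we, mp, me, 100 * f)
      expect_lt(abs(d@delta - truth), 1e-9)
    })
  }
})

test_that("swapping WT and mutant (expression inverted) negates delta; SE is symmetric", {
  set.seed(5)
  for (r in 1:25) {
    wp <- runif(1, 8, 10); we <- runif(1, 20, 40)
    mp <- runif(1, 6, 10); me <- runif(1, 5, 40)
    f <- runif(1, 0.5, 1.5)
    ses <- runif(5, 0.01, 0.3)
    a <- deltaLogRAFromSummary(wp, we, mp, me, 100 * f,
                               ses[1], ses[2] * we, ses[3], ses[4] * me,
                               ses[5] * 100 * f)
    b <- deltaLogRAFromSummary(mp, me, wp, we, 100 / f,
                               ses[3], ses[4] * me, ses[1], ses[2] * we,
                               ses[5] * 100 / f)
    expect_equal(b@delta, -a@delta, tolerance = 1e-12)
    expect_equal(b@se, a@se, tolerance = 1e-12)
  }
})

test_that("scaling mutant expression by k shifts delta by exactly log10(k)", {
  base <- deltaLogRAFromSummary(10, 30, 9, 20, 100)
  for (k in c(0.25, 0.5, 2, 10)) {
    d <- deltaLogRAFromSummary(10, 30, 9, 20, 100 * k)
    expect_equal(d@delta - base@delta, log10(k), tolerance = 1e-12)
  }
})

test_that("the relative-activity unit constant cancels in the difference", {
  # multiplying both Emax values by any common unit factor leaves delta
  # unchanged (Emax nM over EC50 M is a convention, not a dependency)
  a <- deltaLogRAFromSummary(10, 30, 9, 20, 95)
  for (u in c(1e-9, 1e-3, 1e3)) {
    b <- deltaLogRAFromSummary(10, 30 * u, 9, 20 * u, 95)
    expect_equal(b@delta, a@delta, tolerance = 1e-9)
  }
})

test_that("significance is exactly the CI-excludes-zero rule", {
  sig <- deltaLogRAFromSummary(10, 30, 9, 20, 100, wtPec50SE = 0.1)
  expect_true(sig@significant)
  expect_true(sig@ciLow > 0)
  null <- deltaLogRAFromSummary(10, 30, 9.95, 29, 100, wtPec50SE = 0.2,
                                mutPec50SE = 0.2)
  expect_false(null@significant)
  expect_true(null@ciLow < 0 && null@ciHigh > 0)
})

test_that("invalid expression or Emax inputs are rejected", {
  expect_error(deltaLogRAFromSummary(10, 30, 9, 20, 0), "positive")
  expect_error(deltaLogRAFromSummary(10, 30, 9, 20, -5), "positive")
  expect_error(deltaLogRAFromSummary(10, -1, 9, 20, 100), "positive")
})

test_that("per-experiment and summary modes agree at assay-like noise", {
  truth <- pharmTruth(mut = c(pec50 = 7.6, emax = 19, basal = 2),
                      expressionFraction = 0.95)
  sim <- simulatePharmDataset(truth, seed = 7)
  wt <- fitLogisticByExperiment(sim$cre[sim$cre$receptor == "wt", ])
  mu <- fitLogisticByExperiment(sim$cre[sim$cre$receptor == "mut", ])
  expr <- normalizeElisa(sim$elisa)
  per <- deltaLogRAFromFits(wt, mu, expr)
  sw <- summariseFits(wt); sm <- summariseFits(mu)
  summ <- deltaLogRAFromSummary(sw$pec50, sw$emax, sm$pec50, sm$emax,
                                expr@percentOfWT)
  expect_equal(per@mode, "per-experiment")
  expect_lt(abs(per@delta - summ@delta) / abs(summ@delta), 0.05)
  expect_equal(per@nExperiments, 5L)
})

test_that("unusable fits propagate as an unavailable result", {
  flat <- fitLogistic(concGrid(), rep(5, 8))
  d <- deltaLogRAFromFits(list(flat), list(flat), 100)
  expect_true(is.na(d@delta))
  expect_false(d@significant)
  expect_equal(d@nExperiments, 0L)
})

test_that("fold potency change is a pure log-ratio", {
  expect_equal(foldPotencyChange(9, 9), 1.0)
  expect_equal(foldPotencyChange(9, 10), 10.0)
  set.seed(3)
  for (r in 1:20) {
    a <- runif(1, 5, 12); b <- runif(1, 5, 12)
    expect_equal(foldPotencyChange(a, b) * foldPotencyChange(b, a), 1,
                 tolerance = 1e-12)
  }
  expect_error(foldPotencyChange(NA, 9), "finite")
})
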