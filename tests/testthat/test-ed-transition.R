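test_that("the elastic network is zero at its reference with zero gradient", {
  set.seed(2)
  x <- matrix(rnorm(36, sd = 3), 12, 3)
  pot <- buildToyPotential(x, cutoff = 8, k = 0.5)
  expect_equal(potentialEnergy(pot, x), 0)
  expect_lt(max(abs(potentialGradient(pot, x))), 1e-12)
})

test_that("two atoms stretched by d store k d^2 / 2", {
  ref <- rbind(c(0, 0, 0), c(2, 0, 0))
  pot <- buildToyPotential(ref, cutoff = 5, k = 0.7)
  for (d in c(-0.5, 0.3, 1.2)) {
    x <- rbind(c(0, 0, 0), c(2 + d, 0, 0))
    expect_equal(potentialEnergy(pot, x), 0.7 * d^2 / 2, tolerance = 1e-12)
  }
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(4)
  ref <- matrix(rnorm(60, sd = 3), 20, 3)
  pot <- buildToyPotential(ref, cutoff = 9, k = 0.4)
  x <- ref + matrix(rnorm(60, sd = 0.4), 20, 3)
  g <- potentialGradient(pot, x)
  h <- 1e-5
  gn <- matrix(0, 20, 3)
  for (i in 1:20) {
    for (c3 in 1:3) {
      xp <- x; xm <- x
      xp[i, c3] <- x[i, c3] + h
      xm[i, c3] <- x[i, c3] - h
      gn[i, c3] <- (potentialEnergy(pot, xp) - potentialEnergy(pot, xm)) /
        (2 * h)
    }
  }
  expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-5)
})

test_that("an empty pair list or bad config is rejected", {
  expect_error(buildToyPotential(rbind(c(0, 0, 0), c(100, 0, 0)), cutoff = 5),
               "no atom pairs")
  expect_error(buildToyPotential(matrix(0, 1, 3)), "2 atoms")
  expect_error(edConfig(c(1, 1, 0)), "unit norm")
})

edFixture <- function() {
  fx <- twoStateFixture()
  two <- concatEnsembles(fx$inactive, fx$active)
  es <- essentialSubspace(two)
  p <- projectOntoPC(es, two)
  list(fx = fx, v = es@vectors[, 1], span = p[2] - p[1],
       pot = buildToyPotential(fx$inactive, cutoff = 12, k = 0.02,
                               endpoint = fx$active))
}

test_that("zero increment leaves the projection fixed while the structure fluctuates", {
  f <- edFixture()
  cfg <- edConfig(f$v, increment = 0, steps = 50, stride = 25, seed = 3)
  tr <- edDrive(f$fx$inactive, cfg, f$pot)
  expect_lt(max(abs(tr@projections - tr@projections[1])), 1e-9)
  expect_gt(coordRMSD(frameCoords(tr@trajectory, nFrames(tr@trajectory)),
                      frameCoords(f$fx$inactive), fit = FALSE), 0)
})

test_that("the projection series is affine in the step index", {
  f <- edFixture()
  inc <- f$span / 200
  cfg <- edConfig(f$v, increment = inc, steps = 200, stride = 100, seed = 5)
  tr <- edDrive(f$fx$inactive, cfg, f$pot)
  s <- seq_along(tr@projections) - 1L
  expect_lt(max(abs(tr@projections - (tr@projections[1] + s * inc))), 1e-6)
})

test_that("driving is reproducible and reversible", {
  f <- edFixture()
  cfg <- edConfig(f$v, increment = f$span / 100, steps = 100, stride = 50,
                  seed = 8)
  a <- edDrive(f$fx$inactive, cfg, f$pot)
  b <- edDrive(f$fx$inactive, cfg, f$pot)
  expect_identical(a@trajectory@coords, b@trajectory@coords)
  fin <- frameCoords(a@trajectory, nFrames(a@trajectory))
  back <- edDrive(fin, edConfig(f$v, increment = -f$span / 100, steps = 100,
                                stride = 50, seed = 9), f$pot,
                  atoms = atomTable(f$fx$inactive))
  expect_lt(abs(back@projections[101] - a@projections[1]), 1e-6)
})

test_that("relaxation at zero temperature never increases the energy", {
  b <- buildBundle()
  pot <- buildToyPotential(b, cutoff = 10, k = 0.05)
  start <- sampleEnsemble(b, 0.3, 1, seed = 6)
  cfg <- edConfig(rep(1, 3 * nAtoms(b)) / sqrt(3 * nAtoms(b)),
                  increment = 0, steps = 150, stride = 5, kT = 0, seed = 1)
  tr <- edDrive(start, cfg, pot)
  expect_true(all(diff(tr@energies) <= 1e-9))
  expect_lt(tr@energies[length(tr@energies)], tr@energies[1])
})

test_that("driving reaches the active endpoint", {
  f <- edFixture()
  r0 <- coordRMSD(frameCoords(f$fx$inactive), frameCoords(f$fx$active))
  cfg <- edConfig(f$v, increment = f$span / 1500, steps = 1500, stride = 500,
                  seed = 1)
  tr <- edDrive(f$fx$inactive, cfg, f$pot)
  fin <- frameCoords(tr@trajectory, nFrames(tr@trajectory))
  expect_lt(coordRMSD(fin, frameCoords(f$fx$active)) / r0, 0.25)
})

test_that("the harmonic-restraint constraint tracks the same schedule", {
  f <- edFixture()
  cfg <- edConfig(f$v, increment = f$span / 300, steps = 300, stride = 300,
                  seed = 2, constraint = "restraint", restraintK = 500)
  tr <- edDrive(f$fx$inactive, cfg, f$pot)
  target <- tr@projections[1] + f$span
  expect_lt(abs(tr@projections[301] - target) / abs(f$span), 0.05)
})

test_that("best-score combination reproduces a brute-force argmin", {
  f <- edFixture()
  cfg <- edConfig(f$v, increment = f$span / 60, steps = 60, stride = 20,
                  seed = 1, nReplicates = 3L)
  reps <- edDriveReplicates(f$fx$inactive, cfg, f$pot)
  expect_length(reps, 3L)
  scorer <- energyScorer(f$pot)
  comb <- combineBestScore(reps, scorer)
  nf <- nFrames(comb$trajectory)
  for (fr in seq_len(nf)) {
    sc <- vapply(reps, function(r)
      scorer(frameCoords(r@trajectory, fr)), numeric(1))
    expect_equal(comb$chosen[fr], which.min(sc))
    expect_identical(frameCoords(comb$trajectory, fr),
                     frameCoords(reps[[which.min(sc)]]@trajectory, fr))
  }
})

test_that("best-score ties go to the first replicate; single replicate is identity", {
  e <- randomEnsemble(nAtom = 6, nFrame = 4)
  one <- combineBestScore(list(e), function(x) 0)
  expect_identical(one$trajectory@coords, e@coords)
  tie <- combineBestScore(list(e, randomEnsemble(nAtom = 6, nFrame = 4,
                                                 seed = 2)),
                          function(x) 1)
  expect_identical(tie$chosen, rep(1L, 4))
  expect_identical(tie$trajectory@coords, e@coords)
  short <- randomEnsemble(nAtom = 6, nFrame = 3)
  expect_error(combineBestScore(list(e, short), function(x) 0),
               "equal frame counts")
})
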