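test_that("ideal helix geometry: a 10-residue helix spans 9 x 1.5 A axially", {
  spec <- bundleSpec(helixRanges = list(TM1 = 1:10))
  b <- buildBundle(spec)
  z <- frameCoords(b)[, 3]
  expect_equal(max(z) - min(z), 13.5, tolerance = 1e-9)
})

test_that("seven helix axes sit symmetrically on the bundle circle", {
  spec <- bundleSpec()
  bases <- t(sapply(1:7, function(h) rampkit:::.axisBase(spec, h)))
  seps <- sqrt(rowSums((bases - bases[c(2:7, 1), ])^2))
  expect_equal(max(seps) - min(seps), 0, tolerance = 1e-9)
})

test_that("construction is deterministic and annotations carry the label map", {
  a <- buildBundle()
  b <- buildBundle()
  expect_identical(a@coords, b@coords)
  at <- atomTable(a)
  expect_equal(at$wootten[at$resno == 345], "6.49b")
  expect_equal(at$resname[at$resno == 190], "VAL")
  expect_equal(at$helix[at$resno == 305], "TM5")
  expect_equal(at$helix[at$resno == 374], "TM7")
})

test_that("overlapping helix axes are a construction error", {
  expect_error(buildBundle(bundleSpec(bundleRadius = 1)), "4 Angstrom")
})

test_that("a zero pivot with zero kink is the identity", {
  b <- buildBundle()
  act <- applyActivationPivot(b, 0, 0)
  expect_equal(act$structure@coords, b@coords, tolerance = 1e-12)
  expect_equal(nrow(act$broken), 0L)
  expect_equal(nrow(act$formed), 0L)
  expect_error(applyActivationPivot(b, 120), "0, 90")
})

test_that("a constructed 43-degree TM6 kink is measured within 2 degrees", {
  b <- buildBundle()
  act <- applyActivationPivot(b, 0, kinkAngle = 43)$structure
  bend <- helixBendAngle(act, "TM6", 336)
  expect_lt(abs(bend$mean - 43), 2)
  straight <- helixBendAngle(b, "TM6", 336)
  expect_lt(straight$mean, 2)
})

test_that("the TM6 cytoplasmic displacement grows monotonically with the pivot", {
  b <- buildBundle()
  at <- atomTable(b)
  cyt <- at$helix == "TM6" & at$resno < 336
  disp <- vapply(c(0, 5, 10, 15, 20, 25, 30), function(a) {
    act <- applyActivationPivot(b, a)$structure
    sqrt(mean(rowSums((frameCoords(act)[cyt, ] -
                       frameCoords(b)[cyt, ])^2)))
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
})

test_that("the pivot separates TM6 from TM7 and brings TM5 toward TM4", {
  fx <- twoStateFixture()
  brokenHelices <- paste(fx$broken$helix1, fx$broken$helix2)
  formedHelices <- paste(fx$formed$helix1, fx$formed$helix2)
  expect_true(any(grepl("TM6 TM7|TM7 TM6", brokenHelices)))
  expect_true(any(grepl("TM4 TM5|TM5 TM4", formedHelices)))
})

test_that("noise-free sampling is the identity; noisy RMSF matches closed form", {
  b <- buildBundle(bundleSpec(helixRanges = list(TM1 = 1:10)))
  same <- sampleEnsemble(b, 0, 5, seed = 1)
  for (f in 1:5)
    expect_identical(frameCoords(same, f), frameCoords(b))
  expect_identical(sampleEnsemble(b, 0.3, 4, seed = 7)@coords,
                   sampleEnsemble(b, 0.3, 4, seed = 7)@coords)
  big <- sampleEnsemble(b, 0.5, 10000, seed = 2)
  dev <- sweep(big@coords, c(1, 2), frameCoords(b))
  rmsf <- sqrt(apply(dev^2, 1, mean) * 3)   # per-atom RMSF over frames
  expect_lt(max(abs(rmsf - 0.5 * sqrt(3))) / (0.5 * sqrt(3)), 0.02)
})

test_that("the two-state ensemble separates cleanly along PC1", {
  fx <- twoStateFixture()
  ia <- sampleEnsemble(fx$inactive, 0.1, 15, seed = 1)
  ac <- sampleEnsemble(fx$active, 0.1, 15, seed = 2)
  es <- essentialSubspace(concatEnsembles(ia, ac))
  p <- projectOntoPC(es, concatEnsembles(ia, ac))
  lab <- c(rep("inactive", 15), rep("active", 15))
  sep <- abs(mean(p[lab == "active"]) - mean(p[lab == "inactive"]))
  within <- max(sd(p[lab == "active"]), sd(p[lab == "inactive"]))
  expect_gte(sep, 5 * within)
})
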