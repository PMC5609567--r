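test_that("superposition removes an arbitrary rigid motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_equal(superpose(ref, ref)$rmsd, 0, tolerance = 1e-10)
  mob <- randomRigid(ref, seed = 2)
  s <- superpose(mob, ref)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(s$coords, ref, tolerance = 1e-9)
})

test_that("a constructed 1 A per-atom displacement gives RMSD exactly 1", {
  # square in the xy-plane with alternating z displacements: zero net
  # translation and zero cross-covariance with z, so the optimal rotation
  # is the identity and every atom is displaced by exactly 1 A
  ref <- rbind(c(3, 3, 0), c(-3, 3, 0), c(-3, -3, 0), c(3, -3, 0))
  mob <- ref + cbind(0, 0, c(1, -1, 1, -1))
  expect_equal(superpose(mob, ref)$rmsd, 1.0, tolerance = 1e-9)
  # oracle: axis-angle scans around the identity find nothing better
  rotAbout <- function(axis, deg) {
    a <- deg * pi / 180
    k <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  }
  cm <- colMeans(mob); cr <- colMeans(ref)
  best <- Inf
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))) {
    for (deg in seq(-20, 20, by = 0.1)) {
      r <- sweep(sweep(mob, 2, cm) %*% t(rotAbout(axis, deg)), 2, cr, "+")
      best <- min(best, sqrt(mean(rowSums((r - ref)^2))))
    }
  }
  expect_gte(best, 1.0 - 1e-9)
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(7)
  for (r in 1:5) {
    ref <- matrix(rnorm(45, sd = 6), 15, 3)
    mob <- randomRigid(ref + matrix(rnorm(45, sd = 0.8), 15, 3), seed = r)
    ours <- superpose(mob, ref)$rmsd
    theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)),
                          fit = TRUE)
    expect_lt(abs(ours - theirs), 6e-4)   # bio3d rounds to 3 decimals
  }
})

test_that("mismatched atom counts are rejected", {
  expect_error(superpose(matrix(0, 4, 3), matrix(0, 5, 3)), "equal size")
})

test_that("a concatenated two-state ensemble has exactly one non-zero eigenvalue", {
  fx <- twoStateFixture()
  two <- concatEnsembles(fx$inactive, fx$active)
  es <- essentialSubspace(two)
  expect_equal(sum(es@values > 1e-8 * es@values[1]), 1L)
  # endpoint projections: separated by the aligned inter-endpoint distance,
  # active positive
  p <- projectOntoPC(es, two)
  expect_gt(p[2], p[1])
  d <- sqrt(sum((superpose(frameCoords(fx$active),
                           frameCoords(fx$inactive))$coords -
                 frameCoords(fx$inactive))^2))
  expect_equal(abs(p[2] - p[1]), d, tolerance = 1e-6)
})

test_that("identical frames give all-zero eigenvalues; one frame errors", {
  b <- buildBundle()
  same <- sampleEnsemble(b, 0, 4, seed = 1)
  es <- essentialSubspace(same)
  expect_lt(max(es@values), 1e-12)
  expect_error(essentialSubspace(same[1]), "2 frames")
})

test_that("eigenvectors are orthonormal and eigenvalues conserve the trace", {
  e <- randomEnsemble(nAtom = 10, nFrame = 8, sigma = 0.5)
  es <- essentialSubspace(e)
  g <- crossprod(es@vectors)
  expect_lt(max(abs(g - diag(ncol(es@vectors)))), 1e-8)
  expect_equal(sum(es@values), es@totalVariance, tolerance = 1e-6)
  expect_false(is.unsorted(rev(es@values)))
})

test_that("eigenvalues are invariant under a global rigid motion", {
  e <- randomEnsemble(nAtom = 10, nFrame = 6, sigma = 0.4, seed = 3)
  moved <- e
  for (f in seq_len(nFrames(e)))
    moved@coords[, , f] <- randomRigid(e@coords[, , f], seed = 99)
  a <- essentialSubspace(e)@values
  b <- essentialSubspace(moved)@values
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("PC1 recovers a known collective displacement between noisy clusters", {
  set.seed(17)
  base <- matrix(rnorm(60, sd = 4), 20, 3)
  disp <- matrix(rnorm(60), 20, 3)
  disp <- 5 * disp / sqrt(sum(disp^2))   # 5 A collective shift
  coords <- array(NA_real_, dim = c(20, 3, 40))
  for (f in 1:20) coords[, , f] <- base + matrix(rnorm(60, sd = 0.1), 20, 3)
  for (f in 21:40) coords[, , f] <- base + disp +
      matrix(rnorm(60, sd = 0.1), 20, 3)
  ens <- ConformationEnsemble(coords, data.frame(resno = 1:20),
                              frameLabels = rep(c("inactive", "active"),
                                                each = 20))
  es <- essentialSubspace(ens)
  # oracle direction: the inter-cluster displacement after optimal alignment
  dispAligned <- superpose(base + disp, base)$coords - base
  u <- as.numeric(t(dispAligned)) / sqrt(sum(dispAligned^2))
  cosine <- abs(sum(es@vectors[, 1] * u))
  expect_gte(cosine, 0.99)
})
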