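test_that("distance series: closed form, self-pair and missing residues", {
  coords <- rbind(c(0, 0, 0), c(3, 4, 0))
  e <- ConformationEnsemble(coords, data.frame(resno = c(10L, 20L)))
  expect_equal(as.numeric(distanceSeries(e, 10, 20)), 5.0)
  expect_error(distanceSeries(e, 10, 10), "differ")
  expect_error(distanceSeries(e, 10, 99), "99")
})

test_that("tightening TM2 toward TM3 shifts the monitored distance by 1 A", {
  b <- buildBundle()
  at <- atomTable(b)
  xyz <- frameCoords(b)
  u <- xyz[at$resno == 218, ] - xyz[at$resno == 190, ]
  u <- u / sqrt(sum(u^2))
  mutant <- xyz
  mutant[at$helix == "TM2", ] <- sweep(mutant[at$helix == "TM2", ], 2, u, "+")
  mutEns <- ConformationEnsemble(mutant, at)
  wtSample <- sampleEnsemble(b, 0.1, 50, seed = 1)
  mutSample <- sampleEnsemble(mutEns, 0.1, 50, seed = 2)
  dWt <- attr(distanceSeries(wtSample, 190, 218), "mean")
  dMut <- attr(distanceSeries(mutSample, 190, 218), "mean")
  expect_lt(abs((dWt - dMut) - 1.0), 0.1)
})

test_that("a static structure's persistent contacts equal the brute-force set", {
  e <- randomEnsemble(nAtom = 15, nFrame = 1, sigma = 0, seed = 5)
  got <- persistentContacts(e, cutoff = 6, persistence = 0.8)
  want <- bruteContacts(frameCoords(e), atomTable(e)$resno, cutoff = 6)
  expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
  if (!is.null(want))
    expect_setequal(paste(got$resno1, got$resno2),
                    paste(want[, 1], want[, 2]))
})

test_that("persistence is a strict per-simulation threshold", {
  # three atoms far apart in sequence; pair (1,2) in contact in 79/100
  # frames, pair (1,3) in 81/100
  coords <- array(0, dim = c(3, 3, 100))
  coords[2, 1, ] <- c(rep(4, 79), rep(50, 21))
  coords[3, 2, ] <- c(rep(4, 81), rep(50, 19))
  e <- ConformationEnsemble(coords, data.frame(resno = c(1L, 10L, 20L)))
  got <- persistentContacts(e, cutoff = 5, persistence = 0.8)
  expect_equal(nrow(got), 1L)
  expect_equal(got$resno1, 1L)
  expect_equal(got$resno2, 20L)
  # occupancy exactly at the threshold is excluded (strictly greater)
  coords[3, 2, ] <- c(rep(4, 80), rep(50, 20))
  e80 <- ConformationEnsemble(coords, data.frame(resno = c(1L, 10L, 20L)))
  expect_equal(nrow(persistentContacts(e80, 5, 0.8)), 0L)
})

test_that("a pair must pass the threshold in every simulation", {
  mk <- function(nIn) {
    coords <- array(0, dim = c(2, 3, 10))
    coords[2, 1, ] <- c(rep(4, nIn), rep(50, 10 - nIn))
    ConformationEnsemble(coords, data.frame(resno = c(1L, 10L)))
  }
  sims <- list(mk(10), mk(10), mk(10), mk(5))
  expect_equal(nrow(persistentContacts(sims, 5, 0.8)), 0L)
  expect_equal(nrow(persistentContacts(sims[1:3], 5, 0.8)), 1L)
})

test_that("raising the cutoff never removes a persistent contact", {
  e <- sampleEnsemble(buildBundle(), 0.2, 10, seed = 9)
  small <- persistentContacts(e, cutoff = 5)
  large <- persistentContacts(e, cutoff = 6.5)
  expect_true(all(paste(small$resno1, small$resno2) %in%
                  paste(large$resno1, large$resno2)))
})

test_that("rearrangements of an ensemble against itself are all Shared", {
  e <- sampleEnsemble(buildBundle(), 0.1, 5, seed = 4)
  tab <- rearrangementTable(e, e)
  expect_true(nrow(tab) > 0)
  expect_true(all(tab$conformation == "Shared"))
})

test_that("the rearrangement table recovers the generator's designed contact changes", {
  fx <- twoStateFixture()
  tab <- rearrangementTable(fx$inactive, fx$active)
  key <- function(d, r1 = "resno1", r2 = "resno2")
    sort(paste(d[[r1]], d[[r2]]))
  expect_identical(key(tab[tab$conformation == "Inactive", ]),
                   key(fx$broken))
  expect_identical(key(tab[tab$conformation == "Active", ]),
                   key(fx$formed))
  expect_named(tab, c("residue_1", "residue_2", "resno1", "resno2",
                      "helix1", "helix2", "conformation"))
  # display labels carry residue identity and class-B numbering, e.g. 6.49b
  l345 <- tab[tab$resno1 == 345 | tab$resno2 == 345, ]
  if (nrow(l345) > 0)
    expect_true(any(grepl("L345/6.49b", c(l345$residue_1, l345$residue_2))))
})

test_that("helix bend angles: straight, kinked, and invariances", {
  b <- buildBundle()
  act <- applyActivationPivot(b, 0, kinkAngle = 60)$structure
  bent <- helixBendAngle(act, "TM6", 336)
  expect_lt(abs(bent$mean - 60), 2)
  # rigid rotation of every frame leaves the angle unchanged
  moved <- act
  moved@coords[, , 1] <- randomRigid(act@coords[, , 1], seed = 8)
  expect_equal(helixBendAngle(moved, "TM6", 336)$mean, bent$mean,
               tolerance = 1e-6)
  # frame permutation changes the series order, not the summary
  ens <- sampleEnsemble(act, 0.1, 6, seed = 2)
  perm <- ens[c(4, 1, 6, 2, 5, 3)]
  a <- helixBendAngle(ens, "TM6", 336)
  p <- helixBendAngle(perm, "TM6", 336)
  expect_equal(sort(a$angles), sort(p$angles))
  expect_equal(a$mean, p$mean)
  expect_equal(a$sd, p$sd)
  expect_equal(a$max, p$max)
  expect_error(helixBendAngle(b, "TM6", 320), "4 residues")
})

test_that("the representative frame is the argmin RMSD to the mean", {
  same <- sampleEnsemble(buildBundle(bundleSpec(helixRanges = list(TM1 = 1:10))),
                         0, 4, seed = 1)
  expect_equal(representativeFrame(same), 1L)
  # frame 2 is the exact coordinate mean of frames 1 and 3
  base <- matrix(rnorm(30), 10, 3)
  off <- matrix(rnorm(30, sd = 0.5), 10, 3)
  coords <- array(NA_real_, dim = c(10, 3, 3))
  coords[, , 1] <- base - off
  coords[, , 2] <- base
  coords[, , 3] <- base + off
  e <- ConformationEnsemble(coords, data.frame(resno = 1:10))
  expect_equal(representativeFrame(e), 2L)
  # oracle: exhaustive scan over a noisy ensemble
  noisy <- randomEnsemble(nAtom = 8, nFrame = 50, sigma = 0.5, seed = 12)
  al <- rampkit:::.iterativeMeanAlign(noisy@coords)
  r <- vapply(1:50, function(f)
    sqrt(mean(rowSums((al$coords[, , f] - al$mean)^2))), numeric(1))
  expect_equal(representativeFrame(noisy), which.min(r))
})
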