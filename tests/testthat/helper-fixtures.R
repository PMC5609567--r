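# shared fixtures and independent oracles, built in code

# noiseless three-parameter logistic responses
logisticResponse <- function(conc, basal, emax, pec50) {
  basal + (emax - basal) / (1 + 10^(-(log10(conc) + pec50)))
}

concGrid <- function(n = 8) 10^seq(-12, -6, length.out = n)

# independent profiled least squares over a fine pEC50 lattice, with the
# linear part solved by lm() — the oracle route for the logistic fit
gridSearchLogistic <- function(conc, y, grid = seq(4, 14, by = 0.01)) {
  x <- log10(conc)
  rss <- vapply(grid, function(p) {
    w <- 1 / (1 + 10^(-(x + p)))
    sum(resid(lm(y ~ w))^2)
  }, numeric(1))
  list(pec50 = grid[which.min(rss)], rss = min(rss))
}

# brute-force contact list of a single conformation (independent of the
# package's vectorised path)
bruteContacts <- function(xyz, resno, cutoff = 5, minSeqSep = 3L) {
  out <- NULL
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(resno[i] - resno[j]) < minSeqSep) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff)
        out <- rbind(out, c(resno[i], resno[j]))
    }
  }
  out
}

# small random ensemble around a random base structure
randomEnsemble <- function(nAtom = 12, nFrame = 5, sigma = 0.3, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(nAtom * 3, sd = 4), nAtom, 3)
  coords <- array(NA_real_, dim = c(nAtom, 3, nFrame))
  for (f in seq_len(nFrame))
    coords[, , f] <- base + matrix(rnorm(nAtom * 3, sd = sigma), nAtom, 3)
  ConformationEnsemble(coords, data.frame(resno = seq_len(nAtom) * 3L))
}

# random rigid motion applied to an n x 3 matrix
randomRigid <- function(xyz, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(xyz %*% q, 2, rnorm(3, sd = 10), "+")
}

# standard two-state bundle fixture for PCA / ED tests
twoStateFixture <- function(pivot = 15) {
  inactive <- buildBundle()
  act <- applyActivationPivot(inactive, pivot)
  list(inactive = inactive, active = act$structure,
       broken = act$broken, formed = act$formed)
}
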