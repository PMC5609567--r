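#' Principal component analysis of positional fluctuations
#'
#' Frames are iteratively superposed onto the converged ensemble mean, the
#' covariance of Calpha coordinates about the mean is formed (divisor
#' \code{n_frames}, non-mass-weighted) and diagonalised. For a concatenated
#' ensemble of two distinct conformations exactly one eigenvalue is non-zero
#' and the corresponding eigenvector is the inactive-to-active reaction
#' coordinate used by [edDrive()].
#'
#' The sign of PC1 is fixed so that frames labelled \code{"active"} project
#' positively relative to frames labelled \code{"inactive"} (when both labels
#' are present); otherwise each eigenvector's first component of magnitude
#' above 1e-12 is made positive.
#'
#' @param ensemble a [ConformationEnsemble-class] with at least 2 frames.
#' @param tol convergence tolerance (Angstrom) of the iterative mean.
#' @return an [EssentialSubspace-class].
#' @examples
#' b <- buildBundle()
#' act <- applyActivationPivot(b, pivotAngle = 20)$structure
#' two <- concatEnsembles(b, act)
#' es <- essentialSubspace(two)
#' sum(es@values > 1e-8 * es@values[1])  # exactly 1
#' @export
essentialSubspace <- function(ensemble, tol = 1e-6) {
  stopifnot(is(ensemble, "ConformationEnsemble"))
  nf <- nFrames(ensemble)
  if (nf < 2L)
    stop("at least 2 frames are required (a single frame has no fluctuations)")
  al <- .iterativeMeanAlign(ensemble@coords, tol = tol)
  X <- t(apply(al$coords, 3, function(m) as.numeric(t(m))))  # frames x 3N
  mu <- as.numeric(t(al$mean))
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  values <- s$d^2 / nf
  vectors <- s$v
  # deterministic sign convention
  p <- Xc %*% vectors
  lab <- frameLabels(ensemble)
  for (k in seq_len(ncol(vectors))) {
    flip <- FALSE
    if (k == 1L && any(lab == "active") && any(lab == "inactive")) {
      flip <- mean(p[lab == "active", k]) < mean(p[lab == "inactive", k])
    } else {
      first <- which(abs(vectors[, k]) > 1e-12)[1]
      flip <- !is.na(first) && vectors[first, k] < 0
    }
    if (flip) vectors[, k] <- -vectors[, k]
  }
  new("EssentialSubspace",
      meanCoords = al$mean, vectors = vectors, values = values,
      totalVariance = sum(Xc^2) / nf, atoms = atomTable(ensemble))
}

setMethod("show", "EssentialSubspace", function(object) {
  nz <- sum(object@values > 1e-8 * max(object@values, 1e-300))
  cat(sprintf("EssentialSubspace: %d atoms, %d components (%d non-zero)\n",
              nrow(object@meanCoords), length(object@values), nz))
  cat(sprintf("  leading eigenvalues (A^2): %s\n",
              paste(signif(head(object@values, 5), 4), collapse = " ")))
})

#' Project conformations onto a principal component
#'
#' Each frame is superposed onto the subspace's mean structure, and the dot
#' product of (frame - mean), flattened row-wise, with the requested
#' eigenvector is returned.
#'
#' @param subspace an [EssentialSubspace-class].
#' @param x a [ConformationEnsemble-class] or an \code{n x 3} matrix.
#' @param pc which component (default 1).
#' @param align superpose onto the mean first (default TRUE).
#' @return numeric vector of projections (Angstrom), one per frame.
#' @export
projectOntoPC <- function(subspace, x, pc = 1L, align = TRUE) {
  v <- subspace@vectors[, pc]
  mu <- as.numeric(t(subspace@meanCoords))
  frames <- if (is(x, "ConformationEnsemble")) {
    lapply(seq_len(nFrames(x)), function(i) frameCoords(x, i))
  } else list(as.matrix(x))
  vapply(frames, function(m) {
    if (align) m <- superpose(m, subspace@meanCoords)$coords
    sum((as.numeric(t(m)) - mu) * v)
  }, numeric(1))
}
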