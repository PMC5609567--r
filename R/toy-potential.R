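#' Build a toy elastic-network potential
#'
#' Harmonic springs on the distances of all Calpha pairs within a cutoff of
#' the reference structure:
#' \deqn{E(x) = \sum_{(i,j)} \frac{k}{2}\,(d_{ij}(x) - d_{ij}^{ref})^2}
#' The energy is zero (and the gradient vanishes) at the reference, and the
#' potential is invariant under rigid motions since it acts on distances.
#' This engine stands in for an all-atom force field only to exercise the
#' essential-dynamics constraint algorithm at toy scale.
#'
#' When a second endpoint structure is supplied, the network is restricted
#' to the conserved scaffold: only pairs whose distance changes by less than
#' \code{scaffoldTol} between the two endpoints are kept, with \code{r0} set
#' to the mean of the two distances. Both endpoints are then (near) minima
#' and the transition mode between them is soft, emulating a system with
#' two metastable states connected by the driven coordinate.
#'
#' @param structure a [ConformationEnsemble-class] (first frame used) or an
#'   \code{n x 3} coordinate matrix with \code{n >= 2}.
#' @param cutoff pair-list cutoff in Angstrom (default 12).
#' @param k spring constant, energy / Angstrom^2 (default 0.02).
#' @param endpoint optional second structure (same atoms) defining the
#'   scaffold network described above.
#' @param scaffoldTol Angstrom (default 0.5); pairs whose endpoint distances
#'   differ by more than this are dropped when \code{endpoint} is given.
#' @return a [ToyPotential-class].
#' @export
buildToyPotential <- function(structure, cutoff = 12, k = 0.02,
                              endpoint = NULL, scaffoldTol = 0.5) {
  x <- if (is(structure, "ConformationEnsemble")) frameCoords(structure, 1L)
       else as.matrix(structure)
  if (nrow(x) < 2L) stop("at least 2 atoms are required")
  if (cutoff <= 0) stop("cutoff must be positive")
  d <- as.matrix(dist(x))
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (!is.null(endpoint)) {
    y <- if (is(endpoint, "ConformationEnsemble")) frameCoords(endpoint, 1L)
         else as.matrix(endpoint)
    if (!all(dim(y) == dim(x)))
      stop("endpoint must have the same atoms as structure")
    d2 <- as.matrix(dist(y))
    keep <- abs(d2[hit] - d[hit]) < scaffoldTol
    hit <- hit[keep, , drop = FALSE]
    if (nrow(hit) == 0L) stop("no conserved pairs within the cutoff")
    r0 <- (d[hit] + d2[hit]) / 2
  } else {
    r0 <- d[hit]
  }
  if (nrow(hit) == 0L) stop("no atom pairs within the cutoff")
  new("ToyPotential", refCoords = x,
      pairs = cbind(as.integer(hit[, 1]), as.integer(hit[, 2])),
      k = rep(k, nrow(hit)), r0 = r0, cutoff = cutoff)
}

#' @rdname potentialEnergy
#' @export
setMethod("potentialEnergy", "ToyPotential", function(potential, x) {
  x <- as.matrix(x)
  dv <- x[potential@pairs[, 1], , drop = FALSE] -
        x[potential@pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  sum(potential@k / 2 * (d - potential@r0)^2)
})

#' @rdname potentialEnergy
#' @export
setMethod("potentialGradient", "ToyPotential", function(potential, x) {
  x <- as.matrix(x)
  i <- potential@pairs[, 1]; j <- potential@pairs[, 2]
  dv <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  d[d < 1e-12] <- 1e-12
  f <- potential@k * (d - potential@r0) / d   # dE/dd, divided by d
  contrib <- dv * f
  g <- matrix(0, nrow(x), 3)
  si <- rowsum(contrib, i)
  g[as.integer(rownames(si)), ] <- g[as.integer(rownames(si)), ] + si
  sj <- rowsum(contrib, j)
  g[as.integer(rownames(sj)), ] <- g[as.integer(rownames(sj)), ] - sj
  g
})

setMethod("show", "ToyPotential", function(object) {
  cat(sprintf(
    "ToyPotential: %d atoms, %d springs (cutoff %.1f A, k %.3g /A^2)\n",
    nrow(object@refCoords), nrow(object@pairs), object@cutoff, object@k[1]))
})
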