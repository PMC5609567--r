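#' Construct a conformational ensemble
#'
#' @param coords either an \code{n_atoms x 3} matrix (a single conformation)
#'   or an \code{n_atoms x 3 x n_frames} array, in Angstrom.
#' @param atoms atom table: data.frame with columns \code{resno},
#'   \code{resname}, \code{helix}, \code{wootten}, \code{chain}. Missing
#'   optional columns are filled with defaults.
#' @param provenance one of \code{"inactive"}, \code{"active"},
#'   \code{"transition"}, \code{"synthetic"}.
#' @param frameLabels optional per-frame labels; defaults to the provenance.
#' @return a [ConformationEnsemble-class].
#' @examples
#' atoms <- data.frame(resno = 1:4, resname = "ALA")
#' xyz <- matrix(rnorm(12), 4, 3)
#' ens <- ConformationEnsemble(xyz, atoms)
#' nFrames(ens)
#' @export
ConformationEnsemble <- function(coords, atoms,
                                 provenance = "synthetic",
                                 frameLabels = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  atoms <- .completeAtomTable(atoms)
  if (is.null(frameLabels)) frameLabels <- rep(provenance, dim(coords)[3])
  new("ConformationEnsemble",
      coords = coords, atoms = atoms,
      provenance = provenance, frameLabels = as.character(frameLabels))
}

.completeAtomTable <- function(atoms) {
  atoms <- as.data.frame(atoms)
  if (!"resno" %in% names(atoms))
    stop("atom table must have a 'resno' column")
  if (!"resname" %in% names(atoms)) atoms$resname <- "ALA"
  if (!"helix" %in% names(atoms)) atoms$helix <- "loop"
  if (!"wootten" %in% names(atoms)) atoms$wootten <- ""
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  atoms$resno <- as.integer(atoms$resno)
  atoms[c("resno", "resname", "helix", "wootten", "chain")]
}

#' @rdname ConformationEnsemble
#' @export
setMethod("nFrames", "ConformationEnsemble", function(x) dim(x@coords)[3])

#' @rdname ConformationEnsemble
#' @export
setMethod("nAtoms", "ConformationEnsemble", function(x) dim(x@coords)[1])

#' @rdname ConformationEnsemble
#' @export
setMethod("frameCoords", "ConformationEnsemble", function(x, i = 1L) {
  stopifnot(i >= 1L, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' @rdname ConformationEnsemble
#' @export
setMethod("atomTable", "ConformationEnsemble", function(x) x@atoms)

#' @rdname ConformationEnsemble
#' @export
setMethod("provenance", "ConformationEnsemble", function(x) x@provenance)

#' @rdname ConformationEnsemble
#' @export
setMethod("frameLabels", "ConformationEnsemble", function(x) x@frameLabels)

#' @describeIn ConformationEnsemble subset frames.
#' @param j,drop,... ignored (frames are selected with \code{i}).
#' @export
setMethod("[", "ConformationEnsemble", function(x, i, j, ..., drop = FALSE) {
  ConformationEnsemble(x@coords[, , i, drop = FALSE], x@atoms,
                       provenance = x@provenance,
                       frameLabels = x@frameLabels[i])
})

setMethod("show", "ConformationEnsemble", function(object) {
  cat(sprintf("ConformationEnsemble: %d atoms x %d frames (%s)\n",
              nAtoms(object), nFrames(object), object@provenance))
  hx <- table(object@atoms$helix)
  cat("  helices:", paste(sprintf("%s(%d)", names(hx), hx), collapse = " "),
      "\n")
})

#' Concatenate ensembles over a common atom table
#'
#' Used to build the combined inactive + active ensemble whose
#' positional-fluctuation covariance defines the activation reaction
#' coordinate.
#'
#' @param ... two or more [ConformationEnsemble-class] objects sharing the
#'   same atom table.
#' @param provenance provenance of the result (default \code{"synthetic"}).
#' @return a [ConformationEnsemble-class] whose \code{frameLabels} record the
#'   provenance of each source frame.
#' @export
concatEnsembles <- function(..., provenance = "synthetic") {
  ens <- list(...)
  stopifnot(length(ens) >= 2L)
  ref <- atomTable(ens[[1]])
  for (e in ens[-1]) {
    if (!identical(atomTable(e)$resno, ref$resno))
      stop("ensembles must share the same atom table")
  }
  coords <- do.call(abind3, lapply(ens, function(e) e@coords))
  labels <- unlist(lapply(ens, frameLabels), use.names = FALSE)
  ConformationEnsemble(coords, ref, provenance = provenance,
                       frameLabels = labels)
}

# bind 3-d arrays along the third dimension (frames)
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])[1:2]
  nf <- vapply(xs, function(a) dim(a)[3], integer(1))
  out <- array(NA_real_, dim = c(d, sum(nf)))
  at <- 0L
  for (a in xs) {
    k <- dim(a)[3]
    out[, , at + seq_len(k)] <- a
    at <- at + k
  }
  out
}

# index of atoms for a residue number; error names the residue if absent
.atomIndex <- function(atoms, resno) {
  i <- match(resno, atoms$resno)
  if (is.na(i)) stop(sprintf("residue %s not present in the structure", resno))
  i
}
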