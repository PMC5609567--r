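#' @rdname ConformationEnsemble
#' @param x a \code{ConformationEnsemble}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname ConformationEnsemble
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname ConformationEnsemble
#' @param i frame index (1-based).
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname ConformationEnsemble
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ConformationEnsemble
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ConformationEnsemble
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))

#' Potential energy of a structure under a toy potential
#'
#' @param potential a [ToyPotential-class].
#' @param x coordinates, \code{n x 3} matrix (Angstrom).
#' @return scalar energy, or (for [potentialGradient()]) an \code{n x 3}
#'   gradient matrix.
#' @export
setGeneric("potentialEnergy",
           function(potential, x) standardGeneric("potentialEnergy"))

#' @rdname potentialEnergy
#' @export
setGeneric("potentialGradient",
           function(potential, x) standardGeneric("potentialGradient"))
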