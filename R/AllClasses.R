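#' Conformational ensemble of Calpha coordinates
#'
#' Ordered frames of labelled Calpha coordinates (in Angstrom) over a fixed
#' atom table. The atom table carries the 1-based primary-sequence residue
#' number, a three-letter residue name, a transmembrane helix id (\code{"TM1"}
#' .. \code{"TM7"} or \code{"loop"}), an optional class-B (Wootten) label such
#' as \code{"6.49b"} carried as an opaque string, and a chain id.
#'
#' @slot coords numeric array, \code{n_atoms x 3 x n_frames}, Angstrom.
#' @slot atoms data.frame with columns \code{resno}, \code{resname},
#'   \code{helix}, \code{wootten}, \code{chain}; one row per atom.
#' @slot provenance single string: \code{"inactive"}, \code{"active"},
#'   \code{"transition"} or \code{"synthetic"}.
#' @slot frameLabels character vector, one label per frame (used e.g. to
#'   orient the principal component of a concatenated two-state ensemble).
#'
#' @seealso [ConformationEnsemble()] for the user constructor.
#' @exportClass ConformationEnsemble
setClass("ConformationEnsemble",
  slots = c(
    coords = "array",
    atoms = "data.frame",
    provenance = "character",
    frameLabels = "character"
  )
)

setValidity("ConformationEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  need <- c("resno", "resname", "helix", "wootten", "chain")
  if (!all(need %in% names(object@atoms)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@atoms) != d[1])
    return("atoms table must have one row per atom")
  if (anyDuplicated(object@atoms$resno))
    return("residue numbers must be unique")
  if (length(object@provenance) != 1L)
    return("provenance must be a single string")
  if (length(object@frameLabels) != d[3])
    return("frameLabels must have one entry per frame")
  TRUE
})

#' Essential subspace of positional fluctuations
#'
#' Mean structure, orthonormal eigenvectors and eigenvalues (Angstrom^2,
#' descending) of the covariance of aligned Calpha coordinates about the
#' ensemble mean.
#'
#' @slot meanCoords numeric matrix \code{n_atoms x 3}, the converged mean
#'   structure used as the alignment reference.
#' @slot vectors numeric matrix \code{3*n_atoms x k}, orthonormal columns.
#' @slot values numeric vector of length \code{k}, non-negative, descending.
#' @slot totalVariance total mean-square fluctuation (trace of the covariance).
#' @slot atoms atom table of the source ensemble.
#' @exportClass EssentialSubspace
setClass("EssentialSubspace",
  slots = c(
    meanCoords = "matrix",
    vectors = "matrix",
    values = "numeric",
    totalVariance = "numeric",
    atoms = "data.frame"
  )
)

setValidity("EssentialSubspace", function(object) {
  if (any(object@values < -1e-8))
    return("eigenvalues must be non-negative")
  if (is.unsorted(rev(object@values), strictly = FALSE))
    return("eigenvalues must be sorted in descending order")
  if (nrow(object@vectors) != 3L * nrow(object@meanCoords))
    return("eigenvectors must be 3*n_atoms-dimensional")
  g <- crossprod(object@vectors)
  if (max(abs(g - diag(ncol(object@vectors)))) > 1e-8)
    return("eigenvectors must be mutually orthonormal to 1e-8")
  TRUE
})

#' Toy elastic-network potential
#'
#' Harmonic springs between all Calpha pairs within a cutoff of a reference
#' structure, acting on pair distances (so the energy is invariant under rigid
#' motions). Energy is zero at the reference by construction.
#'
#' @slot refCoords reference coordinates, \code{n x 3} (Angstrom).
#' @slot pairs integer matrix, two columns of atom indices (i < j).
#' @slot k per-pair spring constant (energy / Angstrom^2).
#' @slot r0 per-pair reference distance (Angstrom).
#' @slot cutoff the cutoff used to build the pair list (Angstrom).
#' @exportClass ToyPotential
setClass("ToyPotential",
  slots = c(
    refCoords = "matrix",
    pairs = "matrix",
    k = "numeric",
    r0 = "numeric",
    cutoff = "numeric"
  )
)

setValidity("ToyPotential", function(object) {
  if (ncol(object@pairs) != 2L) return("pairs must have two columns")
  if (nrow(object@pairs) < 1L) return("pair list is empty")
  if (length(object@k) != nrow(object@pairs) ||
      length(object@r0) != nrow(object@pairs))
    return("k and r0 must have one entry per pair")
  if (any(object@k < 0)) return("spring constants must be non-negative")
  TRUE
})

#' Essential-dynamics driven trajectory
#'
#' Result of [edDrive()]: the recorded frames plus the per-step projection
#' series and energies.
#'
#' @slot trajectory [ConformationEnsemble-class] of recorded frames (the
#'   initial structure is frame 1).
#' @slot projections numeric, projection onto the driving eigenvector after
#'   every step (length \code{steps + 1}, including the start).
#' @slot energies numeric, potential energy at each recorded frame.
#' @slot frameSteps integer, the step index of each recorded frame (0 = start).
#' @slot config the [edConfig()] list used.
#' @exportClass EDTrajectory
setClass("EDTrajectory",
  slots = c(
    trajectory = "ConformationEnsemble",
    projections = "numeric",
    energies = "numeric",
    frameSteps = "integer",
    config = "list"
  )
)

#' Three-parameter logistic fit of a concentration-response experiment
#'
#' Unweighted least-squares fit of
#' \deqn{y = basal + (E_{max} - basal) / (1 + 10^{-(x + pEC_{50})})}
#' over \eqn{x = \log_{10}} concentration (M), with the Hill slope fixed at 1.
#'
#' @slot basal lower asymptote (nM cAMP).
#' @slot emax upper asymptote (nM cAMP); always \code{>= basal}.
#' @slot pec50 \eqn{-\log_{10} EC_{50}} (M).
#' @slot se named numeric: standard errors for \code{basal}, \code{emax},
#'   \code{pec50} (from the fit covariance; \code{NA} when unidentifiable).
#' @slot sigma residual standard deviation (nM).
#' @slot converged logical; \code{FALSE} when the optimiser failed or the
#'   curve is unidentifiable (never an exception).
#' @slot noCurve logical; \code{TRUE} when the fitted span is below three
#'   residual standard deviations ("N.C." rule) and the fit should be
#'   excluded from relative-activity comparisons.
#' @slot n number of observations.
#' @exportClass LogisticFit
setClass("LogisticFit",
  slots = c(
    basal = "numeric", emax = "numeric", pec50 = "numeric",
    se = "numeric", sigma = "numeric",
    converged = "logical", noCurve = "logical", n = "integer"
  )
)

setValidity("LogisticFit", function(object) {
  if (isTRUE(object@converged)) {
    if (object@emax < object@basal - 1e-9) return("emax must be >= basal")
    if (!is.finite(object@pec50)) return("pec50 must be finite when converged")
  }
  if (any(object@se < 0, na.rm = TRUE)) return("standard errors must be >= 0")
  TRUE
})

#' Cell-surface expression summary
#'
#' Background-corrected ELISA signal expressed as a percentage of the same
#' experiment's wild type, summarised as mean +/- SE across experiments.
#'
#' @slot percentOfWT mean percentage of wild type.
#' @slot se standard error of the percentage across experiments.
#' @slot n number of experiments.
#' @slot perExperiment per-experiment percentages.
#' @slot flagged TRUE when any per-experiment corrected signal was negative
#'   (background exceeded signal; allowed but flagged).
#' @exportClass ExpressionSummary
setClass("ExpressionSummary",
  slots = c(
    percentOfWT = "numeric", se = "numeric", n = "integer",
    perExperiment = "numeric", flagged = "logical"
  )
)

setValidity("ExpressionSummary", function(object) {
  if (object@se < 0) return("se must be >= 0")
  TRUE
})

#' Expression-corrected difference in log relative activity
#'
#' The headline pharmacology statistic. Per receptor, the log relative
#' activity is \eqn{\log RA = \log_{10}(E_{max}) + pEC_{50}} (Emax in nM over
#' EC50 in M; the unit constant cancels in differences). The mutant value is
#' corrected for cell-surface expression by subtracting
#' \eqn{\log_{10}(expression fraction)}, and
#' \deqn{\Delta\log RA = \log RA_{WT} - (\log RA_{mut} -
#'   \log_{10}(f_{expr}))}
#' so that positive values mean an impaired mutant. The standard error is the
#' quadrature of the pEC50 SEs, the delta-method SEs of log10(Emax) and the
#' delta-method SE of log10(expression fraction).
#'
#' @slot logRAWt,logRAMut log RA for wild type and (uncorrected) mutant.
#' @slot delta the expression-corrected difference (log10 units).
#' @slot se the SE used for the confidence interval (propagated in
#'   from-summary mode; across-experiment in per-experiment mode).
#' @slot sePropagated quadrature SE from component SEs (NA when unavailable).
#' @slot seAcross across-experiment SEM of per-experiment deltas (NA in
#'   from-summary mode).
#' @slot ciLow,ciHigh confidence bounds (\code{delta +/- ciMultiplier * se}).
#' @slot significant TRUE iff the CI excludes zero.
#' @slot mode \code{"summary"} or \code{"per-experiment"}.
#' @slot nExperiments number of experiment pairs used (0 in summary mode).
#' @slot perExperiment per-experiment deltas (empty in summary mode).
#' @exportClass DeltaLogRA
setClass("DeltaLogRA",
  slots = c(
    logRAWt = "numeric", logRAMut = "numeric",
    delta = "numeric", se = "numeric",
    sePropagated = "numeric", seAcross = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    significant = "logical", mode = "character",
    nExperiments = "integer", perExperiment = "numeric"
  )
)

setValidity("DeltaLogRA", function(object) {
  if (is.finite(object@delta)) {
    if (object@ciLow > object@delta + 1e-12 ||
        object@ciHigh < object@delta - 1e-12)
      return("delta must lie within [ciLow, ciHigh]")
    sig <- (object@ciLow > 0) || (object@ciHigh < 0)
    if (!identical(sig, object@significant))
      return("significant flag must equal (CI excludes 0)")
  }
  TRUE
})

#' One-site competition-binding fit
#'
#' Fit of \eqn{y = bottom + (top - bottom)/(1 + 10^{x + pIC_{50}})} over
#' \eqn{x = \log_{10}} unlabelled-ligand concentration (M).
#'
#' @slot top,bottom curve asymptotes (counts).
#' @slot pic50 \eqn{-\log_{10} IC_{50}} (M).
#' @slot span \code{top - bottom}, proportional to specific binding.
#' @slot se named numeric: SEs for top, bottom, pic50 and span (span SE by
#'   the delta method from the fit covariance).
#' @slot converged logical.
#' @exportClass CompetitionFit
setClass("CompetitionFit",
  slots = c(
    top = "numeric", bottom = "numeric", pic50 = "numeric",
    span = "numeric", se = "numeric", converged = "logical"
  )
)

setValidity("CompetitionFit", function(object) {
  if (isTRUE(object@converged) && object@span < -1e-9)
    return("span must be >= 0")
  TRUE
})

#' Specific binding of a mutant relative to wild type
#'
#' Ratio of competition-curve spans, with a delta-method 95\% CI.
#'
#' @slot wtFit,mutFit the underlying [CompetitionFit-class] objects.
#' @slot percentBoundVsWT 100 * span_mut / span_wt.
#' @slot se SE of the percentage (ratio delta method).
#' @slot ciLow,ciHigh confidence bounds on the percentage.
#' @exportClass BindingResult
setClass("BindingResult",
  slots = c(
    wtFit = "CompetitionFit", mutFit = "CompetitionFit",
    percentBoundVsWT = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric"
  )
)

setValidity("BindingResult", function(object) {
  if (is.finite(object@percentBoundVsWT) && object@percentBoundVsWT < 0)
    return("percentBoundVsWT must be >= 0")
  TRUE
})
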