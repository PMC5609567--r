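#' Configuration for essential-dynamics driving
#'
#' @param eigenvector unit-norm driving vector (length \code{3 * n_atoms},
#'   row-wise x,y,z flattening as produced by [essentialSubspace()]).
#' @param increment projection increment per step, Angstrom (negative values
#'   drive the reverse, active-to-inactive, transition). Alternatively give
#'   \code{incrementNm} (nm), which is converted (1 nm = 10 Angstrom).
#' @param steps number of simulation steps.
#' @param incrementNm optional increment in nm (overrides \code{increment}).
#' @param kT thermal energy in the potential's energy units (default 0.002, small
#'   against the default network stiffness so driven endpoints are reached
#'   with little thermal blur).
#' @param gamma friction coefficient of the overdamped Langevin update
#'   (default 1).
#' @param dt time step (default 0.01; the update is
#'   \code{x <- x - dt/gamma * grad + sqrt(2 kT dt / gamma) * noise}).
#' @param stride record a frame every \code{stride} steps (default 100; the
#'   initial structure is always frame 1).
#' @param nReplicates replicate count for [edDriveReplicates()] (default 10).
#' @param seed integer seed; replicate r uses \code{seed + r - 1}.
#' @param constraint \code{"reset"} (hard per-step projection reset, the
#'   default) or \code{"restraint"} (stiff harmonic restraint on the
#'   projection, spring \code{restraintK}).
#' @param restraintK restraint spring constant (energy / Angstrom^2).
#' @return a list of class \code{edConfig}.
#' @export
edConfig <- function(eigenvector, increment = 1.2e-5, steps = 1000L,
                     incrementNm = NULL, kT = 0.002, gamma = 1, dt = 0.01,
                     stride = 100L, nReplicates = 10L, seed = 1L,
                     constraint = c("reset", "restraint"),
                     restraintK = 50) {
  if (!is.null(incrementNm)) increment <- incrementNm * 10
  if (!is.finite(increment)) stop("increment must be finite")
  if (abs(sum(eigenvector^2) - 1) > 1e-8)
    stop("eigenvector must have unit norm (to 1e-8)")
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  cfg <- list(eigenvector = eigenvector, increment = increment,
              steps = as.integer(steps), kT = kT, gamma = gamma, dt = dt,
              stride = as.integer(stride),
              nReplicates = as.integer(nReplicates), seed = as.integer(seed),
              constraint = match.arg(constraint), restraintK = restraintK)
  class(cfg) <- "edConfig"
  cfg
}

#' Drive a structure along an eigenvector in fixed increments
#'
#' Essential-dynamics biased sampling: at every step an overdamped Langevin
#' update under the toy potential is applied, then the projection of the
#' coordinates onto the driving eigenvector is constrained to
#' \code{start_projection + step * increment} by correcting the positions
#' along the eigenvector only. After \code{steps} steps the projection has
#' advanced by exactly \code{steps * increment} (to floating-point
#' precision), driving the system from one endpoint of the reaction
#' coordinate to the other. Negative increments drive the reverse
#' transition.
#'
#' @param start starting coordinates (\code{n x 3} matrix or a single-frame
#'   [ConformationEnsemble-class]).
#' @param config an [edConfig()].
#' @param potential a [ToyPotential-class] compatible with \code{start}.
#' @param atoms optional atom table for the output trajectory (taken from
#'   \code{start} when it is an ensemble).
#' @return an [EDTrajectory-class].
#' @export
edDrive <- function(start, config, potential, atoms = NULL) {
  stopifnot(inherits(config, "edConfig"), is(potential, "ToyPotential"))
  if (is(start, "ConformationEnsemble")) {
    if (is.null(atoms)) atoms <- atomTable(start)
    start <- frameCoords(start, 1L)
  }
  x <- as.matrix(start)
  n <- nrow(x)
  v <- config$eigenvector
  if (length(v) != 3L * n)
    stop("eigenvector dimension does not match the structure")
  if (!is.null(config$seed)) set.seed(config$seed)
  vmat <- matrix(v, n, 3, byrow = TRUE)
  proj <- function(m) sum(m * vmat)
  p0 <- proj(x)
  steps <- config$steps
  amp <- sqrt(2 * config$kT * config$dt / config$gamma)
  record <- unique(c(0L, seq_len(steps)[seq_len(steps) %% config$stride == 0L],
                     steps))
  frames <- array(NA_real_, dim = c(n, 3, length(record)))
  energies <- numeric(length(record))
  projections <- numeric(steps + 1L)
  projections[1] <- p0
  fi <- 1L
  frames[, , 1] <- x; energies[1] <- potentialEnergy(potential, x)
  for (s in seq_len(steps)) {
    g <- potentialGradient(potential, x)
    x <- x - (config$dt / config$gamma) * g
    if (amp > 0) x <- x + amp * matrix(rnorm(3 * n), n, 3)
    target <- p0 + s * config$increment
    if (config$constraint == "reset") {
      x <- x + (target - proj(x)) * vmat
    } else {
      # stiff harmonic restraint: one implicit-Euler relaxation toward target
      pull <- config$restraintK * (target - proj(x)) /
        (config$gamma / config$dt + config$restraintK)
      x <- x + pull * vmat
    }
    projections[s + 1L] <- proj(x)
    if (s %in% record) {
      fi <- fi + 1L
      frames[, , fi] <- x
      energies[fi] <- potentialEnergy(potential, x)
    }
  }
  if (is.null(atoms))
    atoms <- data.frame(resno = seq_len(n), resname = "ALA",
                        helix = "loop", wootten = "", chain = "A")
  traj <- ConformationEnsemble(frames, atoms, provenance = "transition")
  new("EDTrajectory", trajectory = traj, projections = projections,
      energies = energies, frameSteps = as.integer(record),
      config = unclass(config)[setdiff(names(config), "eigenvector")] |>
        c(list(eigenvector = v)))
}

setMethod("show", "EDTrajectory", function(object) {
  p <- object@projections
  cat(sprintf(
    "EDTrajectory: %d recorded frames over %d steps\n  projection %.3f -> %.3f A, final energy %.4g\n",
    nFrames(object@trajectory), length(p) - 1L, p[1], p[length(p)],
    object@energies[length(object@energies)]))
})

#' Run replicate ED simulations
#'
#' Repeats [edDrive()] \code{nReplicates} times with seeds
#' \code{seed, seed + 1, ...}, mirroring the protocol of running the driven
#' transition several times and combining the replicates by best score.
#'
#' @inheritParams edDrive
#' @return list of [EDTrajectory-class] objects.
#' @export
edDriveReplicates <- function(start, config, potential, atoms = NULL) {
  lapply(seq_len(config$nReplicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    edDrive(start, cfg, potential, atoms = atoms)
  })
}

#' Combine replicate trajectories by best score
#'
#' Frame t of the consensus is the replicate frame at t with the minimal
#' score; ties are broken in favour of the lowest replicate index.
#'
#' @param replicates list of [EDTrajectory-class] or
#'   [ConformationEnsemble-class] objects with equal frame counts and atom
#'   ordering.
#' @param scorer function(coords matrix) -> scalar, lower is better. Default
#'   scores with [energyScorer()] when the replicates are
#'   [EDTrajectory-class] objects driven under the same potential is not
#'   known here, so \code{scorer} is required.
#' @return list with \code{trajectory} (the consensus
#'   [ConformationEnsemble-class]), \code{chosen} (replicate index per
#'   frame) and \code{scores} (matrix frame x replicate).
#' @export
combineBestScore <- function(replicates, scorer) {
  stopifnot(length(replicates) >= 1L, is.function(scorer))
  ens <- lapply(replicates, function(r)
    if (is(r, "EDTrajectory")) r@trajectory else r)
  nf <- vapply(ens, nFrames, integer(1))
  if (length(unique(nf)) != 1L)
    stop("replicates must have equal frame counts")
  scores <- vapply(ens, function(e)
    vapply(seq_len(nFrames(e)), function(f) scorer(frameCoords(e, f)),
           numeric(1)),
    numeric(nf[1]))
  scores <- matrix(scores, nrow = nf[1])
  chosen <- apply(scores, 1, which.min)   # which.min takes the first minimum
  coords <- array(NA_real_, dim = c(nAtoms(ens[[1]]), 3, nf[1]))
  for (f in seq_len(nf[1]))
    coords[, , f] <- frameCoords(ens[[chosen[f]]], f)
  list(trajectory = ConformationEnsemble(coords, atomTable(ens[[1]]),
                                         provenance = "transition"),
       chosen = as.integer(chosen), scores = scores)
}

#' Score structures by toy-potential energy
#'
#' Convenience scorer for [combineBestScore()].
#'
#' @param potential a [ToyPotential-class].
#' @return function(coords) -> energy.
#' @export
energyScorer <- function(potential) {
  force(potential)
  function(x) potentialEnergy(potential, x)
}
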