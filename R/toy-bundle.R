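# CLR-like residue ranges for the seven toy helices. Chosen so that the
# residues named in the wet-lab analysis (V190, I218, Y227, N305, L345,
# H374, ...) fall on the helix they occupy in the receptor, making metric
# outputs read like the published tables.
# 36 residues per helix = 10 exact turns at 100 deg/residue, so each
# 18-residue half covers 5 full turns and its principal axis is exactly the
# helix axis (no truncation bias in bend-angle fits).
.helixRanges <- list(
  TM1 = 133:168, TM2 = 170:205, TM3 = 206:241, TM4 = 243:278,
  TM5 = 280:315, TM6 = 318:353, TM7 = 355:390
)

# Named residues carried on the toy bundle: residue name + class-B label.
.labelMap <- data.frame(
  resno = c(148L, 177L, 183L, 184L, 190L, 218L, 227L, 230L, 233L, 295L,
            298L, 302L, 305L, 341L, 345L, 348L, 349L, 374L, 383L),
  resname = c("GLY", "HIS", "SER", "PHE", "VAL", "ILE", "TYR", "MET", "GLU",
              "HIS", "ILE", "LEU", "ASN", "LEU", "LEU", "GLU", "PHE", "HIS",
              "ILE"),
  wootten = c("", "2.50b", "", "2.57b", "2.63b", "", "3.44b", "3.47b",
              "3.50b", "5.40b", "5.43b", "5.47b", "5.50b", "6.45b", "6.49b",
              "6.52b", "6.53b", "7.47b", "7.56b"),
  stringsAsFactors = FALSE
)

#' Specification of an idealised seven-helix bundle
#'
#' Ideal alpha-helix geometry (rise 1.5 Angstrom/residue, helix radius
#' 2.3 Angstrom, 100 degrees twist/residue) on seven vertical axes placed on
#' a circle. The activation transition is a rigid pivot of TM5 and TM6 about
#' the TM3 axis, optionally with an extra kink of the cytoplasmic half of
#' TM6.
#'
#' @param bundleRadius radius (Angstrom) of the circle on which the helix
#'   axes sit. The default 9 Angstrom packs adjacent helices tightly enough
#'   that tens of interhelical Calpha pairs sit below the 5 Angstrom contact
#'   cutoff, as in a packed TM bundle.
#' @param helixRadius,risePerResidue,twistPerResidue ideal helix geometry.
#' @param pivotHelices helices moved by the activation pivot.
#' @param pivotAboutHelix the helix whose axis is the pivot (TM3).
#' @param kinkResidue TM6 residue at which the optional cytoplasmic kink is
#'   applied (the cytoplasmic half is the lower-numbered half).
#' @param helixRanges named list of residue-number ranges, one per helix
#'   (each at least 8 residues); the default is the seven CLR-like TM
#'   helices of 36 residues each.
#' @return a list of class \code{bundleSpec}.
#' @export
bundleSpec <- function(bundleRadius = 9, helixRadius = 2.3,
                       risePerResidue = 1.5, twistPerResidue = 100,
                       pivotHelices = c("TM5", "TM6"),
                       pivotAboutHelix = "TM3",
                       kinkResidue = 336L,
                       helixRanges = .helixRanges) {
  spec <- list(bundleRadius = bundleRadius, helixRadius = helixRadius,
               risePerResidue = risePerResidue,
               twistPerResidue = twistPerResidue,
               pivotHelices = pivotHelices,
               pivotAboutHelix = pivotAboutHelix,
               kinkResidue = as.integer(kinkResidue),
               helixRanges = helixRanges)
  class(spec) <- "bundleSpec"
  spec
}

# axis base position (x, y) of helix h for a given spec
.axisBase <- function(spec, h) {
  az <- 2 * pi * (h - 1) / length(spec$helixRanges)
  spec$bundleRadius * c(cos(az), sin(az))
}

#' Build the inactive toy bundle
#'
#' Deterministic ideal-helix Calpha coordinates for the seven-helix bundle
#' described by a [bundleSpec()]. Residues named in the label map carry their
#' residue names and class-B labels; helices are assigned chains A-G.
#'
#' @param spec a [bundleSpec()].
#' @return a single-frame [ConformationEnsemble-class] with provenance
#'   \code{"inactive"}.
#' @examples
#' b <- buildBundle()
#' nAtoms(b)
#' @export
buildBundle <- function(spec = bundleSpec()) {
  stopifnot(inherits(spec, "bundleSpec"))
  if (any(vapply(spec$helixRanges, length, integer(1)) < 8L))
    stop("each helix needs at least 8 residues")
  bases <- t(vapply(seq_along(spec$helixRanges),
                    function(h) .axisBase(spec, h), numeric(2)))
  dd <- as.matrix(dist(bases))
  if (any(dd[upper.tri(dd)] < 4))
    stop("helix axes closer than 4 Angstrom: bundle would overlap")
  coords <- NULL
  atoms <- NULL
  for (h in seq_along(spec$helixRanges)) {
    rng <- spec$helixRanges[[h]]
    j <- seq_along(rng) - 1L
    theta <- (j * spec$twistPerResidue) * pi / 180
    xy <- .axisBase(spec, h)
    xyz <- cbind(xy[1] + spec$helixRadius * cos(theta),
                 xy[2] + spec$helixRadius * sin(theta),
                 j * spec$risePerResidue)
    coords <- rbind(coords, xyz)
    atoms <- rbind(atoms, data.frame(
      resno = rng, resname = "ALA",
      helix = names(spec$helixRanges)[h], wootten = "",
      chain = LETTERS[h], stringsAsFactors = FALSE))
  }
  m <- match(.labelMap$resno, atoms$resno)
  ok <- !is.na(m)
  atoms$resname[m[ok]] <- .labelMap$resname[ok]
  atoms$wootten[m[ok]] <- .labelMap$wootten[ok]
  ens <- ConformationEnsemble(coords, atoms, provenance = "inactive")
  attr(ens, "spec") <- spec
  ens
}

# rotate points about a vertical axis through (cx, cy) by angle degrees
.rotateAboutVertical <- function(xyz, cx, cy, angleDeg) {
  a <- angleDeg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rel <- sweep(xyz[, 1:2, drop = FALSE], 2, c(cx, cy))
  cbind(sweep(rel %*% t(R), 2, c(cx, cy), "+"), xyz[, 3])
}

#' Apply the activation pivot (and optional TM6 kink)
#'
#' TM5 and TM6 are rigidly rotated about the TM3 helix axis by the pivot
#' angle, in the direction that separates TM6 from TM7 and brings TM5
#' toward TM4 (opening the cytoplasmic G-protein face between TM3/5/6/7);
#' all other helices are unchanged. Optionally the cytoplasmic (lower-numbered) half of TM6 is
#' additionally kinked by rotating it about a horizontal axis through the
#' kink residue. The ground-truth contact changes implied by the move are
#' recorded alongside, computed by direct distance counting on the two
#' noiseless structures.
#'
#' @param bundle the inactive structure from [buildBundle()].
#' @param pivotAngle degrees in \code{[0, 90]}.
#' @param kinkAngle degrees; additional TM6 cytoplasmic kink (default 0).
#' @param contactCutoff Angstrom used for the recorded ground-truth contact
#'   lists (default 5, the persistent-contact cutoff).
#' @return list with \code{structure} (single-frame active
#'   [ConformationEnsemble-class]), \code{broken} and \code{formed}
#'   (data.frames of residue pairs present only in the inactive or only in
#'   the active structure), and the angles used.
#' @export
applyActivationPivot <- function(bundle, pivotAngle, kinkAngle = 0,
                                 contactCutoff = 5) {
  stopifnot(is(bundle, "ConformationEnsemble"))
  if (pivotAngle < 0 || pivotAngle > 90)
    stop("pivotAngle must be in [0, 90] degrees")
  spec <- attr(bundle, "spec")
  if (is.null(spec)) spec <- bundleSpec()
  atoms <- atomTable(bundle)
  xyz <- frameCoords(bundle, 1L)
  hPivot <- match(spec$pivotAboutHelix, names(spec$helixRanges))
  ax <- .axisBase(spec, hPivot)
  move <- atoms$helix %in% spec$pivotHelices
  out <- xyz
  # positive pivot = clockwise seen from the extracellular side: TM6 moves
  # away from TM7 while TM5 approaches TM4
  out[move, ] <- .rotateAboutVertical(xyz[move, , drop = FALSE],
                                      ax[1], ax[2], -pivotAngle)
  if (kinkAngle != 0) {
    tm6 <- atoms$helix == "TM6"
    cyt <- tm6 & atoms$resno < spec$kinkResidue
    if (sum(cyt) < 4L || sum(tm6 & !cyt) < 4L)
      stop("kink residue leaves fewer than 4 residues on one side of TM6")
    hinge <- out[atoms$resno == spec$kinkResidue, ]
    # horizontal kink axis: tangential to the bundle at the (pivoted) TM6 axis
    radial <- c(hinge[1], hinge[2], 0)
    radial <- radial / sqrt(sum(radial^2))
    axis <- c(-radial[2], radial[1], 0)
    kinked <- .rotateAboutAxis(out[cyt, , drop = FALSE], hinge, axis,
                               kinkAngle)
    # orient the kink so the cytoplasmic end swings outward, away from the
    # bundle core (as when the G-protein pocket opens)
    endIdx <- which.min(atoms$resno[cyt])
    if (sum(kinked[endIdx, 1:2]^2) < sum(out[cyt, ][endIdx, 1:2]^2))
      kinked <- .rotateAboutAxis(out[cyt, , drop = FALSE], hinge, axis,
                                 -kinkAngle)
    out[cyt, ] <- kinked
  }
  active <- ConformationEnsemble(out, atoms, provenance = "active")
  attr(active, "spec") <- spec
  ci <- .contactSet(xyz, atoms, contactCutoff)
  ca <- .contactSet(out, atoms, contactCutoff)
  key <- function(d) paste(d$resno1, d$resno2)
  broken <- ci[!(key(ci) %in% key(ca)), , drop = FALSE]
  formed <- ca[!(key(ca) %in% key(ci)), , drop = FALSE]
  rownames(broken) <- rownames(formed) <- NULL
  list(structure = active, broken = broken, formed = formed,
       pivotAngle = pivotAngle, kinkAngle = kinkAngle)
}

# Rodrigues rotation of points about an axis through `origin`.
.rotateAboutAxis <- function(xyz, origin, axis, angleDeg) {
  a <- angleDeg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  rel <- sweep(xyz, 2, origin)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  sweep(rel %*% t(R), 2, origin, "+")
}

# Brute-force single-structure contact list (|i-j| > 2 in sequence).
.contactSet <- function(xyz, atoms, cutoff) {
  d <- as.matrix(dist(xyz))
  sep <- abs(outer(atoms$resno, atoms$resno, "-"))
  hit <- which(d < cutoff & sep > 2 & upper.tri(d), arr.ind = TRUE)
  data.frame(resno1 = atoms$resno[hit[, 1]], resno2 = atoms$resno[hit[, 2]],
             helix1 = atoms$helix[hit[, 1]], helix2 = atoms$helix[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Sample a noisy ensemble about a structure
#'
#' Adds i.i.d. isotropic Gaussian displacements (per atom, per frame) to a
#' reference conformation.
#'
#' @param structure a single-frame [ConformationEnsemble-class] (or any
#'   ensemble, whose first frame is used).
#' @param sigma per-coordinate displacement SD in Angstrom (so the expected
#'   per-atom RMSF is \code{sigma * sqrt(3)}).
#' @param nFrames number of frames to draw.
#' @param seed integer seed (sets the RNG; same seed gives an identical
#'   ensemble).
#' @return a [ConformationEnsemble-class] with the structure's provenance.
#' @export
sampleEnsemble <- function(structure, sigma, nFrames, seed = NULL) {
  stopifnot(is(structure, "ConformationEnsemble"), sigma >= 0, nFrames >= 1)
  if (!is.null(seed)) set.seed(seed)
  base <- frameCoords(structure, 1L)
  n <- nrow(base)
  coords <- array(NA_real_, dim = c(n, 3, nFrames))
  for (f in seq_len(nFrames))
    coords[, , f] <- base + matrix(rnorm(n * 3, sd = sigma), n, 3)
  ConformationEnsemble(coords, atomTable(structure),
                       provenance = provenance(structure))
}
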