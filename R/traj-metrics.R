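#' Per-frame Calpha distance between two residues
#'
#' Monitors an interhelical distance over a trajectory, e.g. TM2-TM3
#' (V190-I218) or TM1-TM7 (G148-H374).
#'
#' @param ensemble a [ConformationEnsemble-class].
#' @param resnoA,resnoB residue numbers (primary sequence); must differ and
#'   both be present.
#' @return numeric vector of per-frame distances (Angstrom) with attributes
#'   \code{mean} and \code{sd}.
#' @export
distanceSeries <- function(ensemble, resnoA, resnoB) {
  stopifnot(is(ensemble, "ConformationEnsemble"))
  if (resnoA == resnoB) stop("the two residues must differ")
  atoms <- atomTable(ensemble)
  ia <- .atomIndex(atoms, resnoA)
  ib <- .atomIndex(atoms, resnoB)
  dd <- ensemble@coords[ia, , , drop = FALSE] -
        ensemble@coords[ib, , , drop = FALSE]
  d <- as.numeric(sqrt(apply(dd^2, 3, sum)))
  attr(d, "mean") <- mean(d)
  attr(d, "sd") <- if (length(d) > 1L) sd(d) else 0
  d
}

# occupancy (fraction of frames with distance < cutoff) for every eligible
# pair of one simulation; returns list(pairs matrix, occupancy vector)
.contactOccupancy <- function(ensemble, cutoff, minSeqSep) {
  atoms <- atomTable(ensemble)
  n <- nAtoms(ensemble)
  sep <- abs(outer(atoms$resno, atoms$resno, "-"))
  eligible <- upper.tri(sep) & sep > minSeqSep - 1L
  idx <- which(eligible, arr.ind = TRUE)
  count <- numeric(nrow(idx))
  for (f in seq_len(nFrames(ensemble))) {
    d <- as.matrix(dist(ensemble@coords[, , f]))
    count <- count + (d[idx] < cutoff)
  }
  list(pairs = idx, occupancy = count / nFrames(ensemble))
}

#' Persistent residue contacts across one or more simulations
#'
#' A residue pair is persistent when its Calpha-Calpha distance is below
#' \code{cutoff} in strictly more than \code{persistence} of the frames of
#' \emph{every} supplied simulation (the "<5 Angstrom in more than 80\% of
#' frames in all simulations" criterion). Pairs within two positions in
#' sequence are excluded as trivial backbone contacts.
#'
#' @param ensembles a [ConformationEnsemble-class] or a list of them (the
#'   separate simulations), all over the same atom table.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @param persistence occupancy threshold in (0, 1] (default 0.8; strict
#'   inequality).
#' @param minSeqSep minimum sequence separation |i - j| to count a pair
#'   (default 3, i.e. pairs with |i - j| <= 2 are excluded).
#' @return data.frame with residue numbers, names, helix ids, class-B labels
#'   and one occupancy column per simulation, ordered by helix then residue.
#' @export
persistentContacts <- function(ensembles, cutoff = 5, persistence = 0.8,
                               minSeqSep = 3L) {
  if (is(ensembles, "ConformationEnsemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1L, cutoff > 0,
            persistence > 0, persistence <= 1)
  atoms <- atomTable(ensembles[[1]])
  for (e in ensembles[-1]) {
    if (!identical(atomTable(e)$resno, atoms$resno))
      stop("all simulations must share the same atom table")
  }
  occ <- lapply(ensembles, .contactOccupancy, cutoff = cutoff,
                minSeqSep = minSeqSep)
  occMat <- do.call(cbind, lapply(occ, `[[`, "occupancy"))
  keep <- rowSums(occMat > persistence) == length(ensembles)
  idx <- occ[[1]]$pairs[keep, , drop = FALSE]
  out <- data.frame(
    resno1 = atoms$resno[idx[, 1]], resno2 = atoms$resno[idx[, 2]],
    resname1 = atoms$resname[idx[, 1]], resname2 = atoms$resname[idx[, 2]],
    helix1 = atoms$helix[idx[, 1]], helix2 = atoms$helix[idx[, 2]],
    wootten1 = atoms$wootten[idx[, 1]], wootten2 = atoms$wootten[idx[, 2]],
    stringsAsFactors = FALSE)
  occCols <- as.data.frame(occMat[keep, , drop = FALSE])
  names(occCols) <- paste0("occupancy_sim", seq_along(ensembles))
  out <- cbind(out, occCols)
  out <- out[order(out$helix1, out$resno1, out$resno2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contact rearrangements between the inactive and active states
#'
#' Classifies persistent contacts as present in the inactive state only, the
#' active state only, or shared — the table of residue rearrangements upon
#' activation and opening of the G protein binding pocket.
#'
#' @param inactive,active ensembles (or lists of ensembles) over the same
#'   atom table.
#' @inheritParams persistentContacts
#' @return data.frame with columns \code{residue_1}, \code{residue_2}
#'   (display labels such as \code{"L345/6.49b"}), the underlying residue
#'   numbers/helices, and \code{conformation} in
#'   \code{c("Inactive", "Active", "Shared")}; ordered by helix then residue.
#' @export
rearrangementTable <- function(inactive, active, cutoff = 5,
                               persistence = 0.8, minSeqSep = 3L) {
  ci <- persistentContacts(inactive, cutoff, persistence, minSeqSep)
  ca <- persistentContacts(active, cutoff, persistence, minSeqSep)
  key <- function(d) paste(d$resno1, d$resno2)
  shared <- intersect(key(ci), key(ca))
  lab <- function(d, state) {
    if (nrow(d) == 0L) return(NULL)
    data.frame(
      residue_1 = .displayLabel(d$resname1, d$resno1, d$wootten1),
      residue_2 = .displayLabel(d$resname2, d$resno2, d$wootten2),
      resno1 = d$resno1, resno2 = d$resno2,
      helix1 = d$helix1, helix2 = d$helix2,
      conformation = state, stringsAsFactors = FALSE)
  }
  out <- rbind(
    lab(ci[!(key(ci) %in% shared), , drop = FALSE], "Inactive"),
    lab(ca[!(key(ca) %in% shared), , drop = FALSE], "Active"),
    lab(ci[key(ci) %in% shared, , drop = FALSE], "Shared"))
  if (is.null(out))
    out <- data.frame(residue_1 = character(), residue_2 = character(),
                      resno1 = integer(), resno2 = integer(),
                      helix1 = character(), helix2 = character(),
                      conformation = character(), stringsAsFactors = FALSE)
  out <- out[order(out$helix1, out$resno1, out$resno2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.displayLabel <- function(resname, resno, wootten) {
  one <- .aa3to1[resname]
  one[is.na(one)] <- "X"
  paste0(one, resno, ifelse(nzchar(wootten), paste0("/", wootten), ""))
}

#' Helix bend angle across a split residue
#'
#' Fits a least-squares axis (first principal axis) to each half of a helix
#' in every frame and reports the angle between the two axes, in degrees in
#' [0, 180]. Reported as the per-frame series plus mean, SD and maximum over
#' frames, the convention used for TM6 bending during activation.
#'
#' @param ensemble a [ConformationEnsemble-class].
#' @param helix helix id to analyse (e.g. \code{"TM6"}).
#' @param splitResno residue number at the split; the N-terminal half is
#'   \code{resno <= splitResno}. At least 4 residues are required on each
#'   side.
#' @return list with \code{angles} (degrees, per frame), \code{mean},
#'   \code{sd}, \code{max}.
#' @export
helixBendAngle <- function(ensemble, helix, splitResno) {
  stopifnot(is(ensemble, "ConformationEnsemble"))
  atoms <- atomTable(ensemble)
  sel <- atoms$helix == helix
  if (!any(sel)) stop(sprintf("no atoms annotated as helix %s", helix))
  resno <- atoms$resno[sel]
  lower <- sel & atoms$resno <= splitResno
  upper <- sel & atoms$resno > splitResno
  if (sum(lower) < 4L || sum(upper) < 4L)
    stop("at least 4 residues are required on each side of the split")
  ang <- vapply(seq_len(nFrames(ensemble)), function(f) {
    xyz <- ensemble@coords[, , f]
    a1 <- .helixAxis(xyz[lower, , drop = FALSE])
    a2 <- .helixAxis(xyz[upper, , drop = FALSE])
    acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
  }, numeric(1))
  list(angles = ang, mean = mean(ang),
       sd = if (length(ang) > 1L) sd(ang) else 0, max = max(ang))
}

# first principal axis of a set of points, oriented from first to last point
.helixAxis <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(c0, nu = 0, nv = 1)$v[, 1]
  if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
  v
}

#' Representative frame of an ensemble
#'
#' Frames are aligned to the iteratively converged ensemble mean and the
#' index of the frame with the lowest RMSD to the mean is returned (ties go
#' to the lowest index). This is the "structure with the lowest RMSD to the
#' average structure" convention for choosing a frame to display.
#'
#' @param ensemble a [ConformationEnsemble-class].
#' @return integer frame index (1-based).
#' @export
representativeFrame <- function(ensemble) {
  stopifnot(is(ensemble, "ConformationEnsemble"), nFrames(ensemble) >= 1L)
  if (nFrames(ensemble) == 1L) return(1L)
  al <- .iterativeMeanAlign(ensemble@coords)
  r <- vapply(seq_len(dim(al$coords)[3]), function(f)
    sqrt(mean(rowSums((al$coords[, , f] - al$mean)^2))), numeric(1))
  which.min(r)   # first minimum on ties
}
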