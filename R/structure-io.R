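#' Read a structure or trajectory (multi-MODEL PDB or XYZ)
#'
#' PDB files are parsed with \pkg{bio3d}; Calpha records are extracted and
#' multi-MODEL files become multi-frame ensembles. Chains A-G are mapped
#' back to helices TM1-TM7 (the convention used by [writeStructure()]);
#' other chains are annotated \code{"loop"}. The plain XYZ dialect written
#' by [writeStructure()] (one block per frame: atom count, comment, then
#' \code{resno x y z} lines) is supported as a fast fallback. An optional
#' annotation table can replace the reconstructed one (e.g. to restore
#' class-B labels, which neither format can carry).
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"xyz"} or \code{"auto"} (by extension).
#' @param annotation optional atom table (see [ConformationEnsemble()]);
#'   must match the file's atom count and residue numbers.
#' @param provenance provenance tag for the result (default
#'   \code{"synthetic"}).
#' @return a [ConformationEnsemble-class] (coordinates in Angstrom).
#' @export
readStructure <- function(path, format = c("auto", "pdb", "xyz"),
                          annotation = NULL, provenance = "synthetic") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ens <- if (format == "pdb") .readPdbEnsemble(path, provenance)
         else .readXyzEnsemble(path, provenance)
  if (!is.null(annotation)) {
    annotation <- .completeAtomTable(annotation)
    if (nrow(annotation) != nAtoms(ens) ||
        !identical(annotation$resno, atomTable(ens)$resno))
      stop("annotation table does not match the file's atoms")
    ens@atoms <- annotation
  }
  ens
}

.chainHelixMap <- setNames(paste0("TM", 1:7), LETTERS[1:7])

.readPdbEnsemble <- function(path, provenance) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- pdb$atom$elety == "CA"
  if (!any(ca)) stop("no Calpha atoms found in the PDB file")
  at <- pdb$atom[ca, ]
  xyzIdx <- bio3d::atom2xyz(which(ca))
  xyz <- pdb$xyz[, xyzIdx, drop = FALSE]     # frames x 3n
  n <- sum(ca)
  coords <- array(NA_real_, dim = c(n, 3, nrow(xyz)))
  for (f in seq_len(nrow(xyz)))
    coords[, , f] <- matrix(xyz[f, ], n, 3, byrow = TRUE)
  helix <- unname(.chainHelixMap[as.character(at$chain)])
  helix[is.na(helix)] <- "loop"
  atoms <- data.frame(resno = at$resno, resname = at$resid,
                      helix = helix, wootten = "",
                      chain = as.character(at$chain),
                      stringsAsFactors = FALSE)
  ConformationEnsemble(coords, atoms, provenance = provenance)
}

.readXyzEnsemble <- function(path, provenance) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); resno <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("parse error at line %d: expected atom count", i))
    if (i + 1L + n > length(lines))
      stop(sprintf("parse error at line %d: truncated frame", i))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad))
      stop(sprintf("parse error at line %d: expected 'resno x y z'",
                   i + 1L + bad[1]))
    m <- t(vapply(parts,
                  function(p) suppressWarnings(as.numeric(p[1:4])),
                  numeric(4)))
    if (any(!is.finite(m)))
      stop(sprintf("parse error near line %d: non-numeric field", i + 2L))
    if (is.null(resno)) resno <- as.integer(m[, 1])
    else if (!identical(as.integer(m[, 1]), resno) || nrow(m) != length(resno))
      stop(sprintf("parse error at line %d: atom mismatch between frames", i))
    frames[[length(frames) + 1L]] <- m[, 2:4, drop = FALSE]
    i <- i + 2L + n
  }
  if (length(frames) == 0L) stop("no frames found in XYZ file")
  coords <- array(unlist(frames), dim = c(length(resno), 3, length(frames)))
  ConformationEnsemble(coords, data.frame(resno = resno),
                       provenance = provenance)
}

#' Write a structure or trajectory
#'
#' Multi-MODEL PDB (via \pkg{bio3d}; helices TM1-TM7 become chains A-G, PDB
#' coordinate precision is 1e-3 Angstrom) or the plain XYZ dialect described
#' in [readStructure()].
#'
#' @param ensemble a [ConformationEnsemble-class].
#' @param path output path.
#' @param format \code{"pdb"}, \code{"xyz"} or \code{"auto"} (by extension).
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(ensemble, path, format = c("auto", "pdb", "xyz")) {
  stopifnot(is(ensemble, "ConformationEnsemble"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  atoms <- atomTable(ensemble)
  if (format == "pdb") {
    helixChain <- setNames(names(.chainHelixMap), .chainHelixMap)
    chain <- unname(helixChain[atoms$helix])
    chain[is.na(chain)] <- substr(atoms$chain[is.na(chain)], 1, 1)
    xyz <- t(apply(ensemble@coords, 3, function(m) as.numeric(t(m))))
    xyz <- matrix(xyz, nrow = nFrames(ensemble))
    bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                     resid = atoms$resname, elety = rep("CA", nrow(atoms)),
                     chain = chain)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(nFrames(ensemble))) {
      m <- frameCoords(ensemble, f)
      writeLines(as.character(nrow(m)), con)
      writeLines(sprintf("frame %d (%s)", f, provenance(ensemble)), con)
      writeLines(sprintf("%d %.6f %.6f %.6f", atoms$resno,
                         m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' Write result tables as CSV
#'
#' Deterministic column order, plain CSV, no row names; re-reading with
#' [utils::read.csv()] reproduces the values. A rearrangement table keeps
#' the \code{residue_1}, \code{residue_2}, \code{conformation} column
#' structure.
#'
#' @param table a data.frame (e.g. from [rearrangementTable()] or
#'   [deltaLogRATable()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsCsv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write results as JSON
#'
#' @param x a list or data.frame of results.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Tabulate Delta log(RA) results
#'
#' One row per comparison, mirroring the printed alanine-scan tables
#' (expression percentage, pEC50 +/- SE, Emax +/- SE, Delta log(RA) +/- SE
#' and the CI-excludes-zero significance flag).
#'
#' @param results named list of [DeltaLogRA-class] objects (names are the
#'   mutant labels).
#' @return data.frame.
#' @export
deltaLogRATable <- function(results) {
  stopifnot(length(results) >= 1L)
  do.call(rbind, lapply(names(results), function(nm) {
    d <- results[[nm]]
    data.frame(mutant = nm, delta_log_ra = d@delta, se = d@se,
               ci95_low = d@ciLow, ci95_high = d@ciHigh,
               significant = d@significant, mode = d@mode,
               stringsAsFactors = FALSE)
  }))
}
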