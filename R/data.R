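#' Published alanine-scan summary statistics for CLR-RAMP receptors
#'
#' A curated subset of the published summary pharmacology for CLR
#' transmembrane alanine substitutions assayed in Cos7 cells: cell-surface
#' expression (percent of WT +/- SEM from ELISA), pEC50 and Emax (nM cAMP)
#' means +/- SEM for the paired wild-type and mutant receptors, the printed
#' expression-corrected Delta log(RA) +/- SEM, and the experiment counts,
#' for selected mutants at the CGRP receptor (CLR/RAMP1, agonists CGRP and
#' AM) and the AM2 receptor (CLR/RAMP3, agonist AM). These printed summary
#' values are the inputs to the from-summary mode of
#' [deltaLogRAFromSummary()]; recomputing the statistic from them
#' reproduces the printed column.
#'
#' @param row optional mutant label (plus \code{ramp}, \code{ligand}) to
#'   select a single row.
#' @param ramp,ligand optional filters.
#' @return data.frame.
#' @examples
#' scan <- clrAlanineScan()
#' r <- clrAlanineScan("N305A", ramp = "RAMP1", ligand = "CGRP")
#' deltaLogRAFromSummary(r$wt_pec50, r$wt_emax_nM, r$mut_pec50,
#'                       r$mut_emax_nM, r$cse_pct)
#' @export
clrAlanineScan <- function(row = NULL, ramp = NULL, ligand = NULL) {
  path <- system.file("extdata", "clr_alanine_scan_summary.csv",
                      package = "rampkit", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(ramp)) d <- d[d$ramp == ramp, , drop = FALSE]
  if (!is.null(ligand)) d <- d[d$ligand == ligand, , drop = FALSE]
  if (!is.null(row)) d <- d[d$mutant == row, , drop = FALSE]
  rownames(d) <- NULL
  d
}
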