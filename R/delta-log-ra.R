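.LN10 <- log(10)

# core arithmetic shared by both modes: all inputs scalar
.deltaCore <- function(wtPec50, wtEmax, mutPec50, mutEmax, exprFraction,
                       wtPec50SE, wtEmaxSE, mutPec50SE, mutEmaxSE,
                       exprFractionSE) {
  logRAWt <- log10(wtEmax) + wtPec50
  logRAMut <- log10(mutEmax) + mutPec50
  delta <- logRAWt - (logRAMut - log10(exprFraction))
  se <- sqrt(wtPec50SE^2 + mutPec50SE^2 +
             (wtEmaxSE / (wtEmax * .LN10))^2 +
             (mutEmaxSE / (mutEmax * .LN10))^2 +
             ((exprFractionSE / exprFraction) / .LN10)^2)
  list(logRAWt = logRAWt, logRAMut = logRAMut, delta = delta, se = se)
}

.newDeltaLogRA <- function(core, se, ciMultiplier, mode,
                           sePropagated = NA_real_, seAcross = NA_real_,
                           nExperiments = 0L, perExperiment = numeric(0)) {
  ciLow <- core$delta - ciMultiplier * se
  ciHigh <- core$delta + ciMultiplier * se
  new("DeltaLogRA",
      logRAWt = core$logRAWt, logRAMut = core$logRAMut,
      delta = core$delta, se = se,
      sePropagated = sePropagated, seAcross = seAcross,
      ciLow = ciLow, ciHigh = ciHigh,
      significant = (ciLow > 0) || (ciHigh < 0),
      mode = mode, nExperiments = as.integer(nExperiments),
      perExperiment = perExperiment)
}

#' Expression-corrected difference in log relative activity (summary mode)
#'
#' Computes \eqn{\Delta\log RA} from summary statistics (means and SEMs of
#' pEC50 and Emax plus the cell-surface expression percentage), the form in
#' which alanine-scan pharmacology tables are printed. Per receptor,
#' \eqn{\log RA = \log_{10}(E_{max}) + pEC_{50}} (Emax in nM over EC50 in M;
#' the unit constant cancels in the difference). The mutant value is
#' corrected by subtracting \eqn{\log_{10}} of the expression fraction, and
#' \deqn{\Delta\log RA = \log RA_{WT} - (\log RA_{mut} - \log_{10} f)}
#' so positive values mean an impaired mutant (sign convention: a severely
#' impaired mutant such as N305A gives about +2.7; the gain-of-function
#' H374A/AM combination gives a negative value). Errors from curve fitting
#' and expression are propagated in quadrature:
#' \deqn{SE^2 = SE_{pWT}^2 + SE_{pmut}^2 +
#'   \left(\frac{SE_{EWT}}{E_{WT}\ln 10}\right)^2 +
#'   \left(\frac{SE_{Emut}}{E_{mut}\ln 10}\right)^2 +
#'   \left(\frac{SE_f / f}{\ln 10}\right)^2}
#' and the CI is \code{delta +/- ciMultiplier * SE}; the mutant is called
#' significantly different when the CI excludes zero.
#'
#' @param wtPec50,mutPec50 pEC50 means.
#' @param wtEmax,mutEmax Emax means (nM); must be positive.
#' @param expressionPercent mutant cell-surface expression as percent of WT
#'   (must be positive).
#' @param wtPec50SE,mutPec50SE,wtEmaxSE,mutEmaxSE,expressionSE component
#'   standard errors (default 0).
#' @param ciMultiplier normal-theory multiplier for the CI (default 1.96;
#'   supply e.g. \code{qt(0.975, df)} for a t-based interval). Ignored when
#'   \code{componentDf} is given.
#' @param componentDf optional vector of degrees of freedom for the five SE
#'   components, in the order (WT pEC50, mut pEC50, WT Emax, mut Emax,
#'   expression). When supplied, the CI multiplier is
#'   \code{qt(0.975, df_eff)} with the Welch-Satterthwaite effective
#'   \code{df_eff} of the combined variance — the calibrated choice when the
#'   component SEs are across-experiment SEMs from a handful of experiments.
#' @return a [DeltaLogRA-class].
#' @examples
#' # severely impaired mutant: printed summary values give ~2.67
#' deltaLogRAFromSummary(10.08, 31.16, 7.60, 19.35, 95.5)
#' @export
deltaLogRAFromSummary <- function(wtPec50, wtEmax, mutPec50, mutEmax,
                                  expressionPercent,
                                  wtPec50SE = 0, wtEmaxSE = 0,
                                  mutPec50SE = 0, mutEmaxSE = 0,
                                  expressionSE = 0, ciMultiplier = 1.96,
                                  componentDf = NULL) {
  if (!is.finite(expressionPercent) || expressionPercent <= 0)
    stop("expressionPercent must be positive")
  if (!all(is.finite(c(wtPec50, mutPec50))) ||
      !all(is.finite(c(wtEmax, mutEmax))) || wtEmax <= 0 || mutEmax <= 0)
    stop("pEC50 values must be finite and Emax values positive")
  core <- .deltaCore(wtPec50, wtEmax, mutPec50, mutEmax,
                     expressionPercent / 100,
                     wtPec50SE, wtEmaxSE, mutPec50SE, mutEmaxSE,
                     expressionSE / 100)
  if (!is.null(componentDf)) {
    v <- c(wtPec50SE^2, mutPec50SE^2,
           (wtEmaxSE / (wtEmax * .LN10))^2,
           (mutEmaxSE / (mutEmax * .LN10))^2,
           (((expressionSE / 100) / (expressionPercent / 100)) / .LN10)^2)
    componentDf <- pmax(rep_len(componentDf, 5L), 1L)
    use <- v > 0
    if (any(use)) {
      dfEff <- sum(v[use])^2 / sum(v[use]^2 / componentDf[use])
      ciMultiplier <- stats::qt(0.975, dfEff)
    }
  }
  .newDeltaLogRA(core, core$se, ciMultiplier, mode = "summary",
                 sePropagated = core$se)
}

#' Expression-corrected difference in log relative activity (per-experiment)
#'
#' Pairs wild-type and mutant fits experiment by experiment (the paired
#' plate design), computes a per-experiment expression-corrected delta using
#' the pooled expression percentage, and reports the mean with its
#' across-experiment SEM combined in quadrature with the expression SE. A
#' propagated SE computed from the across-experiment SEMs of pEC50 and Emax
#' (the summary route) is carried alongside for comparison.
#'
#' Pairs where either fit failed or was flagged N.C. are dropped.
#'
#' @param wtFits,mutFits lists of [LogisticFit-class] of equal length, paired
#'   by position.
#' @param expression an [ExpressionSummary-class], or a single percentage.
#' @param ciMultiplier CI multiplier (default 1.96).
#' @return a [DeltaLogRA-class] with \code{mode = "per-experiment"}.
#' @export
deltaLogRAFromFits <- function(wtFits, mutFits, expression,
                               ciMultiplier = 1.96) {
  if (length(wtFits) != length(mutFits))
    stop("wtFits and mutFits must be paired lists of equal length")
  if (is(expression, "ExpressionSummary")) {
    exprPct <- expression@percentOfWT; exprSE <- expression@se
  } else {
    exprPct <- as.numeric(expression); exprSE <- 0
  }
  if (!is.finite(exprPct) || exprPct <= 0)
    stop("expression percentage must be positive")
  ok <- vapply(seq_along(wtFits), function(i) {
    w <- wtFits[[i]]; m <- mutFits[[i]]
    w@converged && m@converged && !w@noCurve && !m@noCurve
  }, logical(1))
  if (!any(ok)) {
    # all pairs unusable (unconverged or N.C.): unavailable result
    return(new("DeltaLogRA",
               logRAWt = NA_real_, logRAMut = NA_real_, delta = NA_real_,
               se = NA_real_, sePropagated = NA_real_, seAcross = NA_real_,
               ciLow = NA_real_, ciHigh = NA_real_, significant = FALSE,
               mode = "per-experiment", nExperiments = 0L,
               perExperiment = numeric(0)))
  }
  f <- exprPct / 100
  per <- vapply(which(ok), function(i) {
    w <- wtFits[[i]]; m <- mutFits[[i]]
    (log10(w@emax) + w@pec50) - (log10(m@emax) + m@pec50 - log10(f))
  }, numeric(1))
  nUsed <- length(per)
  seAcrossRaw <- if (nUsed > 1L) sd(per) / sqrt(nUsed) else 0
  seLogF <- (exprSE / exprPct) / .LN10
  seAcross <- sqrt(seAcrossRaw^2 + seLogF^2)
  sw <- summariseFits(wtFits); sm <- summariseFits(mutFits)
  core <- .deltaCore(sw$pec50, sw$emax, sm$pec50, sm$emax, f,
                     sw$pec50SE, sw$emaxSE, sm$pec50SE, sm$emaxSE,
                     exprSE / 100)
  core$delta <- mean(per)
  core$logRAWt <- mean(vapply(wtFits[ok], function(x)
    log10(x@emax) + x@pec50, numeric(1)))
  core$logRAMut <- mean(vapply(mutFits[ok], function(x)
    log10(x@emax) + x@pec50, numeric(1)))
  .newDeltaLogRA(core, seAcross, ciMultiplier, mode = "per-experiment",
                 sePropagated = core$se, seAcross = seAcross,
                 nExperiments = nUsed, perExperiment = per)
}

setMethod("show", "DeltaLogRA", function(object) {
  cat(sprintf(
    "DeltaLogRA (%s mode): %.3f +/- %.3f  [95%% CI %.3f, %.3f]%s\n",
    object@mode, object@delta, object@se, object@ciLow, object@ciHigh,
    if (object@significant) "  *" else ""))
})

#' Fold change in potency between two pEC50 values
#'
#' \code{10^(mutPec50 - wtPec50)}; values above 1 mean the mutant is more
#' potent (e.g. pEC50 8.43 to 10.44 is a ~100-fold potency gain).
#'
#' @param wtPec50,mutPec50 finite pEC50 values.
#' @return fold change (ratio).
#' @examples
#' foldPotencyChange(8.43, 10.44)  # ~102
#' @export
foldPotencyChange <- function(wtPec50, mutPec50) {
  if (!all(is.finite(c(wtPec50, mutPec50))))
    stop("both pEC50 values must be finite")
  10^(mutPec50 - wtPec50)
}
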