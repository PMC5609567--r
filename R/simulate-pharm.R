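#' Ground truth for a synthetic alanine-scan pharmacology dataset
#'
#' Defines the true curve parameters, expression fraction, noise model and
#' experimental design emulated by [simulatePharmDataset()]. Defaults mirror
#' a typical transient-transfection cAMP assay: triplicate wells over eight
#' log-spaced agonist concentrations from 1 pM to 1 uM, five independent
#' experiments, wild-type pEC50 near 10 and Emax near 32 nM, expression near
#' 100\% of WT, multiplicative lognormal noise (sigma 0.15) on responses so
#' that variability grows with signal, Gaussian noise on ELISA ratios, and a
#' Gaussian day-to-day jitter (sigma 0.1 log units) on the true pEC50 of
#' each experiment to emulate transfection variation.
#'
#' @param wt,mut named numeric vectors with entries \code{pec50},
#'   \code{emax} (nM), \code{basal} (nM). The default mutant equals the
#'   wild type (a null effect).
#' @param expressionFraction true mutant expression as a fraction of WT.
#' @param nExperiments,nReplicates design (defaults 5 and 3).
#' @param concentrations molar concentration grid (default 8 points,
#'   1 pM to 1 uM).
#' @param sigmaResponse lognormal sigma on responses (default 0.15).
#' @param sigmaPec50Between SD of the per-experiment pEC50 jitter
#'   (default 0.1).
#' @param sigmaElisa Gaussian SD on ELISA well ratios (default 0.04).
#' @param elisaWtRatio,elisaBackgroundRatio true corrected/background ELISA
#'   ratio levels.
#' @param binding list with true \code{pic50}, \code{top}, \code{bottom} for
#'   the WT displacement curve, mutant \code{spanFraction} (mutant span as a
#'   fraction of WT), and \code{sigmaFraction} (Gaussian noise SD as a
#'   fraction of the WT span).
#' @return list of class \code{pharmTruth}.
#' @export
pharmTruth <- function(wt = c(pec50 = 10.0, emax = 32, basal = 2),
                       mut = wt,
                       expressionFraction = 1.0,
                       nExperiments = 5L, nReplicates = 3L,
                       concentrations = 10^seq(-12, -6, length.out = 8),
                       sigmaResponse = 0.15, sigmaPec50Between = 0.1,
                       sigmaElisa = 0.04,
                       elisaWtRatio = 0.5, elisaBackgroundRatio = 0.1,
                       binding = list(pic50 = 8.9, top = 2000, bottom = 200,
                                      spanFraction = 1.0,
                                      sigmaFraction = 0.05)) {
  stopifnot(sigmaResponse >= 0, sigmaPec50Between >= 0, sigmaElisa >= 0,
            wt[["emax"]] > wt[["basal"]], mut[["emax"]] > mut[["basal"]],
            all(concentrations > 0), length(concentrations) >= 4L,
            nExperiments >= 1L, nReplicates >= 1L,
            expressionFraction > 0)
  truth <- list(wt = wt, mut = mut,
                expressionFraction = expressionFraction,
                nExperiments = as.integer(nExperiments),
                nReplicates = as.integer(nReplicates),
                concentrations = sort(concentrations),
                sigmaResponse = sigmaResponse,
                sigmaPec50Between = sigmaPec50Between,
                sigmaElisa = sigmaElisa,
                elisaWtRatio = elisaWtRatio,
                elisaBackgroundRatio = elisaBackgroundRatio,
                binding = binding)
  class(truth) <- "pharmTruth"
  truth
}

#' The Delta log(RA) implied by a ground truth
#'
#' Plug-in value of the expression-corrected statistic at the true
#' parameters; the target that [recoveryReport()] measures recovery of.
#'
#' @param truth a [pharmTruth()].
#' @return scalar, log10 units.
#' @export
trueDeltaLogRA <- function(truth) {
  (log10(truth$wt[["emax"]]) + truth$wt[["pec50"]]) -
    (log10(truth$mut[["emax"]]) + truth$mut[["pec50"]] -
       log10(truth$expressionFraction))
}

#' Simulate a full synthetic pharmacology dataset
#'
#' Generates, reproducibly from one integer seed, the three tables consumed
#' by the pharmacology analyses: a long-format concentration-response table
#' for WT and mutant (triplicates times the concentration grid, per
#' experiment; responses are the true logistic multiplied by lognormal
#' noise), an ELISA plate table (wt / mut / background wells with Gaussian
#' ratio noise, mutant level set by the true expression fraction) and WT /
#' mutant displacement-binding tables.
#'
#' @param truth a [pharmTruth()].
#' @param seed integer seed.
#' @return list with \code{cre} (columns \code{receptor},
#'   \code{experiment_id}, \code{concentration_M}, \code{response_nM}),
#'   \code{elisa} (ELISA plate as for [normalizeElisa()]), \code{bindingWt}
#'   and \code{bindingMut} (as for [relativeBinding()]).
#' @export
simulatePharmDataset <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "pharmTruth"))
  set.seed(seed)
  conc <- truth$concentrations
  x <- log10(conc)
  simReceptor <- function(pars, label) {
    do.call(rbind, lapply(seq_len(truth$nExperiments), function(e) {
      p <- pars[["pec50"]] + rnorm(1, sd = truth$sigmaPec50Between)
      mu <- pars[["basal"]] +
        (pars[["emax"]] - pars[["basal"]]) * .logisticW(x, p)
      mu <- rep(mu, each = truth$nReplicates)
      noise <- exp(rnorm(length(mu), sd = truth$sigmaResponse) -
                     truth$sigmaResponse^2 / 2)   # mean-one lognormal
      data.frame(receptor = label, experiment_id = e,
                 concentration_M = rep(conc, each = truth$nReplicates),
                 response_nM = mu * noise, stringsAsFactors = FALSE)
    }))
  }
  cre <- rbind(simReceptor(truth$wt, "wt"), simReceptor(truth$mut, "mut"))
  # ELISA: 3 wells per role per experiment
  bg <- truth$elisaBackgroundRatio
  wtLevel <- truth$elisaWtRatio
  mutLevel <- bg + truth$expressionFraction * (wtLevel - bg)
  elisa <- do.call(rbind, lapply(seq_len(truth$nExperiments), function(e) {
    lev <- c(wt = wtLevel, mut = mutLevel, background = bg)
    do.call(rbind, lapply(names(lev), function(role) {
      data.frame(experiment_id = e, role = role,
                 A490 = lev[[role]] + rnorm(3, sd = truth$sigmaElisa),
                 A650 = 0, A595 = 1, stringsAsFactors = FALSE)
    }))
  }))
  # binding: one displacement series per receptor, triplicate wells per
  # concentration (as for the cAMP assays)
  b <- truth$binding
  bx <- rep(10^seq(-11, -6, length.out = 8), each = truth$nReplicates)
  simBinding <- function(spanFraction) {
    span <- (b$top - b$bottom) * spanFraction
    mu <- b$bottom + span / (1 + 10^(log10(bx) + b$pic50))
    data.frame(concentration_M = bx,
               counts = mu + rnorm(length(bx),
                                   sd = b$sigmaFraction * (b$top - b$bottom)),
               nonspecific = bx == max(bx))
  }
  list(cre = cre, elisa = elisa,
       bindingWt = simBinding(1.0), bindingMut = simBinding(b$spanFraction))
}

#' Analyse one simulated dataset with the standard pipeline
#'
#' Per-experiment logistic fits for WT and mutant, ELISA normalisation,
#' across-experiment summaries and the from-summary Delta log(RA) — the
#' same route applied to real plate data. The confidence interval uses the
#' Welch-Satterthwaite t multiplier (\code{componentDf} of
#' [deltaLogRAFromSummary()]), since all five SE components are SEMs over a
#' handful of experiments and a plain normal multiplier undercovers.
#'
#' @param sim output of [simulatePharmDataset()].
#' @return the [DeltaLogRA-class] for the simulated WT/mutant comparison.
#' @export
analysePharmDataset <- function(sim) {
  wtFits <- fitLogisticByExperiment(sim$cre[sim$cre$receptor == "wt", ])
  mutFits <- fitLogisticByExperiment(sim$cre[sim$cre$receptor == "mut", ])
  expr <- normalizeElisa(sim$elisa)
  sw <- summariseFits(wtFits); sm <- summariseFits(mutFits)
  if (sw$n == 0L || sm$n == 0L)
    stop("no usable fits in the simulated dataset")
  deltaLogRAFromSummary(sw$pec50, sw$emax, sm$pec50, sm$emax,
                        expr@percentOfWT,
                        wtPec50SE = sw$pec50SE, wtEmaxSE = sw$emaxSE,
                        mutPec50SE = sm$pec50SE, mutEmaxSE = sm$emaxSE,
                        expressionSE = expr@se,
                        componentDf = c(sw$n - 1L, sm$n - 1L, sw$n - 1L,
                                        sm$n - 1L, expr@n - 1L))
}

#' Monte-Carlo recovery diagnostics for the Delta log(RA) pipeline
#'
#' Repeats simulate-then-analyse \code{nRepeats} times and reports bias,
#' RMSE, 95\% CI coverage of the true delta, and the significance rate
#' (which, under a null truth with mutant identical to WT and expression
#' 100\%, is the false-positive rate).
#'
#' @param truth a [pharmTruth()].
#' @param nRepeats number of repeats (>= 100 for stable rates).
#' @param seed integer; repeat r uses seed \code{seed + r - 1}.
#' @return list with \code{trueDelta}, \code{estimates}, \code{bias},
#'   \code{rmse}, \code{coverage}, \code{significanceRate}, \code{nRepeats}.
#' @export
recoveryReport <- function(truth, nRepeats = 200L, seed = 1L) {
  stopifnot(nRepeats >= 1L)
  target <- trueDeltaLogRA(truth)
  est <- numeric(nRepeats); cover <- logical(nRepeats)
  sig <- logical(nRepeats)
  for (r in seq_len(nRepeats)) {
    sim <- simulatePharmDataset(truth, seed = seed + r - 1L)
    d <- analysePharmDataset(sim)
    est[r] <- d@delta
    cover[r] <- d@ciLow <= target && target <= d@ciHigh
    sig[r] <- d@significant
  }
  list(trueDelta = target, estimates = est,
       bias = mean(est) - target,
       rmse = sqrt(mean((est - target)^2)),
       coverage = mean(cover), significanceRate = mean(sig),
       nRepeats = as.integer(nRepeats))
}
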