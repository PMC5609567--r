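#' Normalise ELISA cell-surface expression to percent of wild type
#'
#' Per well, the expression signal is the ratio \code{(A490 - A650) / A595}
#' (peroxidase signal over cresyl-violet cell density). Within each
#' experiment the mean background ratio (vector-only wells) is subtracted
#' from the mean wild-type and mutant ratios, and the corrected mutant
#' signal is expressed as a percentage of the same experiment's wild type
#' (transient transfection varies day to day, so experiments are only
#' comparable after this within-experiment normalisation). The summary is
#' the mean +/- SE of the percentages across experiments.
#'
#' Negative corrected signals (background above signal) are allowed and the
#' result is flagged.
#'
#' @param plate data.frame with columns \code{experiment_id}, \code{role}
#'   (one of \code{"wt"}, \code{"mut"}, \code{"background"}), \code{A490},
#'   \code{A650}, \code{A595}; one row per well.
#' @return an [ExpressionSummary-class].
#' @examples
#' plate <- data.frame(
#'   experiment_id = 1, role = c("wt", "mut", "background"),
#'   A490 = c(0.60, 0.50, 0.20), A650 = c(0.10, 0.10, 0.10), A595 = 1)
#' normalizeElisa(plate)  # (0.4 - 0.1) / (0.5 - 0.1) = 75%
#' @export
normalizeElisa <- function(plate) {
  need <- c("experiment_id", "role", "A490", "A650", "A595")
  if (!all(need %in% names(plate)))
    stop(paste("plate must have columns:", paste(need, collapse = ", ")))
  if (any(!plate$role %in% c("wt", "mut", "background")))
    stop("role must be one of 'wt', 'mut', 'background'")
  if (any(!is.finite(plate$A595) | plate$A595 <= 0))
    stop("A595 must be positive for every well")
  plate$ratio <- (plate$A490 - plate$A650) / plate$A595
  perExp <- vapply(split(plate, plate$experiment_id), function(d) {
    bg <- mean(d$ratio[d$role == "background"])
    if (!is.finite(bg)) bg <- 0   # no background wells: no correction
    wt <- mean(d$ratio[d$role == "wt"]) - bg
    mu <- mean(d$ratio[d$role == "mut"]) - bg
    if (!is.finite(wt) || abs(wt) < 1e-12)
      stop("corrected wild-type signal is zero in an experiment")
    100 * mu / wt
  }, numeric(1))
  n <- length(perExp)
  new("ExpressionSummary",
      percentOfWT = mean(perExp),
      se = if (n > 1L) sd(perExp) / sqrt(n) else 0,
      n = as.integer(n), perExperiment = unname(perExp),
      flagged = any(perExp < 0))
}

setMethod("show", "ExpressionSummary", function(object) {
  cat(sprintf("ExpressionSummary: %.1f +/- %.1f %% of WT (n = %d)%s\n",
              object@percentOfWT, object@se, object@n,
              if (object@flagged) "  [negative corrected signal]" else ""))
})
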