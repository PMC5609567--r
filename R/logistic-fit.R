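# model weight w in y = basal + (emax - basal) * w, for x = log10(conc M)
.logisticW <- function(x, pec50) 1 / (1 + 10^(-(x + pec50)))

#' Fit a three-parameter logistic concentration-response curve
#'
#' Unweighted least squares of
#' \code{response = basal + (emax - basal) / (1 + 10^(-(log10(conc) + pec50)))}
#' with the Hill slope fixed at 1. The fit is exact profiled least squares:
#' for fixed pEC50 the model is linear in (basal, emax) and is solved
#' directly; the residual sum of squares is then minimised over pEC50 on
#' [4, 14] by a coarse grid followed by golden-section refinement. Standard
#' errors come from the Gauss-Newton covariance
#' \code{sigma^2 (J'J)^{-1}} at the optimum.
#'
#' Degenerate data (flat responses, an unidentifiable pEC50, or an inverted
#' span) give \code{converged = FALSE} rather than an error. A converged fit
#' whose span is below three residual standard deviations is flagged
#' \code{noCurve} ("N.C."), mirroring responses too weak to fit.
#'
#' @param concentration molar concentrations (strictly positive); at least
#'   4 distinct values.
#' @param response responses (nM cAMP), one per concentration entry
#'   (replicates appear as repeated concentrations); all finite.
#' @param pec50Bounds search bounds for pEC50 (default \code{c(4, 14)}).
#' @return a [LogisticFit-class].
#' @examples
#' conc <- 10^seq(-12, -6, length.out = 8)
#' y <- 30 / (1 + 10^(-(log10(conc) + 9)))
#' fitLogistic(conc, y)
#' @export
fitLogistic <- function(concentration, response, pec50Bounds = c(4, 14)) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response))
    stop("concentration and response must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and strictly positive")
  if (length(unique(concentration)) < 4L)
    stop("at least 4 distinct concentrations are required")
  if (any(!is.finite(response)))
    stop("all responses must be finite")
  x <- log10(concentration)
  n <- length(x)

  fail <- function() new("LogisticFit", basal = NA_real_, emax = NA_real_,
                         pec50 = NA_real_,
                         se = c(basal = NA_real_, emax = NA_real_,
                                pec50 = NA_real_),
                         sigma = NA_real_, converged = FALSE,
                         noCurve = TRUE, n = as.integer(n))

  # profiled RSS: solve the linear (basal, emax) subproblem at fixed p
  profile <- function(p) {
    w <- .logisticW(x, p)
    X <- cbind(1 - w, w)
    fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, response)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    b <- as.numeric(fit)
    rss <- sum((response - X %*% fit)^2)
    list(rss = rss, basal = b[1], emax = b[2], w = w)
  }
  grid <- seq(pec50Bounds[1], pec50Bounds[2], by = 0.25)
  rssGrid <- vapply(grid, function(p) profile(p)$rss, numeric(1))
  if (all(!is.finite(rssGrid))) return(fail())
  i <- which.min(rssGrid)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(function(p) profile(p)$rss, lower = lo, upper = hi,
                  tol = 1e-8)
  p <- opt$minimum
  pr <- profile(p)
  if (!is.finite(pr$rss)) return(fail())
  basal <- pr$basal; emax <- pr$emax
  span <- emax - basal
  dof <- max(1L, n - 3L)
  sigma <- sqrt(pr$rss / dof)
  if (span < 0) {
    # inverted "curve": report a flat fit, pEC50 unidentifiable
    mu <- mean(response)
    return(new("LogisticFit", basal = mu, emax = mu, pec50 = NA_real_,
               se = c(basal = sd(response) / sqrt(n),
                      emax = sd(response) / sqrt(n), pec50 = NA_real_),
               sigma = sd(response), converged = FALSE, noCurve = TRUE,
               n = as.integer(n)))
  }
  w <- pr$w
  J <- cbind(basal = 1 - w, emax = w,
             pec50 = span * log(10) * w * (1 - w))
  V <- tryCatch(sigma^2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(V)) c(basal = NA_real_, emax = NA_real_,
                          pec50 = NA_real_)
        else sqrt(pmax(0, diag(V)))
  names(se) <- c("basal", "emax", "pec50")
  # pEC50 pinned at a search bound means the midpoint is outside the
  # concentration window: treat as unidentifiable
  atBound <- p < pec50Bounds[1] + 1e-3 || p > pec50Bounds[2] - 1e-3
  noCurve <- span < 3 * sigma
  new("LogisticFit", basal = basal, emax = emax, pec50 = p, se = se,
      sigma = sigma, converged = !atBound, noCurve = noCurve || atBound,
      n = as.integer(n))
}

setMethod("show", "LogisticFit", function(object) {
  if (!object@converged) {
    cat("LogisticFit: not converged\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "LogisticFit: basal %.2f, Emax %.2f +/- %.2f nM, pEC50 %.2f +/- %.2f%s\n",
    object@basal, object@emax, object@se["emax"], object@pec50,
    object@se["pec50"], if (object@noCurve) "  [N.C.]" else ""))
})

#' Fit every experiment of a long-format concentration-response table
#'
#' @param data data.frame with columns \code{experiment_id},
#'   \code{concentration_M}, \code{response_nM} (the delimited-text dialect
#'   read by [utils::read.csv()]).
#' @param ... passed to [fitLogistic()].
#' @return named list of [LogisticFit-class], one per experiment.
#' @export
fitLogisticByExperiment <- function(data, ...) {
  need <- c("experiment_id", "concentration_M", "response_nM")
  if (!all(need %in% names(data)))
    stop(paste("data must have columns:", paste(need, collapse = ", ")))
  sp <- split(data, data$experiment_id)
  lapply(sp, function(d) fitLogistic(d$concentration_M, d$response_nM, ...))
}

#' Summarise logistic fits across experiments
#'
#' Mean and SEM of pEC50 and Emax over converged, non-N.C. fits — the
#' "mean +/- SEM of values from individual data sets" convention.
#'
#' @param fits list of [LogisticFit-class].
#' @return list with \code{pec50}, \code{pec50SE}, \code{emax},
#'   \code{emaxSE}, \code{n} (experiments used), \code{nExcluded}.
#' @export
summariseFits <- function(fits) {
  ok <- vapply(fits, function(f) f@converged && !f@noCurve, logical(1))
  used <- fits[ok]
  n <- length(used)
  if (n == 0L)
    return(list(pec50 = NA_real_, pec50SE = NA_real_, emax = NA_real_,
                emaxSE = NA_real_, n = 0L, nExcluded = length(fits)))
  p <- vapply(used, function(f) f@pec50, numeric(1))
  e <- vapply(used, function(f) f@emax, numeric(1))
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  list(pec50 = mean(p), pec50SE = sem(p), emax = mean(e), emaxSE = sem(e),
       n = n, nExcluded = sum(!ok))
}
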