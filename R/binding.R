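#' Fit a one-site competition (displacement) curve
#'
#' Least squares of
#' \code{counts = bottom + (top - bottom) / (1 + 10^(log10(conc) + pic50))}
#' over unlabelled-ligand concentration, using the same profiled scheme as
#' [fitLogistic()] (linear in top/bottom at fixed pIC50). Wells flagged
#' non-specific (top-concentration wells defining non-specific binding) are
#' included as ordinary observations at their concentration.
#'
#' @param concentration molar unlabelled-ligand concentrations (positive,
#'   at least 4 distinct).
#' @param counts bound counts.
#' @param pic50Bounds search bounds (default \code{c(5, 12)}).
#' @return a [CompetitionFit-class]; the \code{se} vector carries delta-method
#'   SEs for \code{top}, \code{bottom}, \code{pic50} and \code{span}
#'   (\code{var(span) = var(top) + var(bottom) - 2 cov(top, bottom)}).
#' @export
fitCompetition <- function(concentration, counts, pic50Bounds = c(5, 12)) {
  concentration <- as.numeric(concentration); counts <- as.numeric(counts)
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and strictly positive")
  if (length(unique(concentration)) < 4L)
    stop("at least 4 distinct displacement concentrations are required")
  x <- log10(concentration)
  n <- length(x)
  # fraction still bound decreases with concentration
  wOf <- function(p) 1 / (1 + 10^(x + p))
  profile <- function(p) {
    w <- wOf(p)
    X <- cbind(1 - w, w)    # columns: bottom, top
    fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, counts)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(rss = Inf))
    list(rss = sum((counts - X %*% fit)^2),
         bottom = fit[1], top = fit[2], w = w)
  }
  grid <- seq(pic50Bounds[1], pic50Bounds[2], by = 0.25)
  rssGrid <- vapply(grid, function(p) profile(p)$rss, numeric(1))
  i <- which.min(rssGrid)
  opt <- optimize(function(p) profile(p)$rss,
                  lower = grid[max(1L, i - 1L)],
                  upper = grid[min(length(grid), i + 1L)], tol = 1e-8)
  p <- opt$minimum
  pr <- profile(p)
  span <- pr$top - pr$bottom
  sigma <- sqrt(pr$rss / max(1L, n - 3L))
  conv <- is.finite(pr$rss) && span >= 0 &&
    p > pic50Bounds[1] + 1e-3 && p < pic50Bounds[2] - 1e-3
  w <- pr$w
  J <- cbind(bottom = 1 - w, top = w,
             pic50 = -span * .LN10 * w * (1 - w))
  V <- tryCatch(sigma^2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V)) {
    se <- c(top = NA_real_, bottom = NA_real_, pic50 = NA_real_,
            span = NA_real_)
  } else {
    se <- c(top = sqrt(max(0, V["top", "top"])),
            bottom = sqrt(max(0, V["bottom", "bottom"])),
            pic50 = sqrt(max(0, V["pic50", "pic50"])),
            span = sqrt(max(0, V["top", "top"] + V["bottom", "bottom"] -
                              2 * V["top", "bottom"])))
  }
  new("CompetitionFit", top = as.numeric(pr$top),
      bottom = as.numeric(pr$bottom), pic50 = p,
      span = max(0, span), se = se, converged = conv)
}

setMethod("show", "CompetitionFit", function(object) {
  cat(sprintf("CompetitionFit: pIC50 %.2f +/- %.2f, span %.1f +/- %.1f%s\n",
              object@pic50, object@se["pic50"], object@span,
              object@se["span"],
              if (object@converged) "" else "  [not converged]"))
})

#' Specific binding of a mutant relative to wild type
#'
#' With a radioligand used below its Kd, affinity changes show up most
#' sensitively as a loss of specific binding. Both displacement curves are
#' fitted with [fitCompetition()]; the mutant's specific binding is the
#' curve span expressed as a percentage of the wild-type span, with a 95\%
#' CI from the ratio delta method:
#' \code{SE(pct) = pct * sqrt((SE_sm/sm)^2 + (SE_sw/sw)^2)}.
#'
#' @param wt,mut data.frames with columns \code{concentration_M},
#'   \code{counts} (an optional logical \code{nonspecific} column marking the
#'   top-concentration wells is accepted and treated as ordinary data).
#' @param ciMultiplier CI multiplier (default 1.96).
#' @return a [BindingResult-class].
#' @export
relativeBinding <- function(wt, mut, ciMultiplier = 1.96) {
  fw <- fitCompetition(wt$concentration_M, wt$counts)
  fm <- fitCompetition(mut$concentration_M, mut$counts)
  if (fw@span <= 0) stop("wild-type span is zero: relative binding undefined")
  pct <- 100 * fm@span / fw@span
  relSE2 <- 0
  if (is.finite(fm@se["span"]) && fm@span > 0)
    relSE2 <- relSE2 + (fm@se[["span"]] / fm@span)^2
  if (is.finite(fw@se["span"]))
    relSE2 <- relSE2 + (fw@se[["span"]] / fw@span)^2
  se <- pct * sqrt(relSE2)
  new("BindingResult", wtFit = fw, mutFit = fm,
      percentBoundVsWT = pct, se = se,
      ciLow = pct - ciMultiplier * se, ciHigh = pct + ciMultiplier * se)
}

setMethod("show", "BindingResult", function(object) {
  cat(sprintf(
    "BindingResult: %.1f%% of WT specific binding [95%% CI %.1f, %.1f]\n",
    object@percentBoundVsWT, object@ciLow, object@ciHigh))
})
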