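#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of a mobile coordinate set onto a reference,
#' via SVD of the cross-covariance with the reflection corrected so that the
#' rotation determinant is +1.
#'
#' @param mobile,reference \code{n x 3} matrices, equal \code{n >= 3}.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{coords} (the transformed mobile set,
#'   \code{mobile \%*\% rotation} then shifted) and \code{rmsd} (Angstrom).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' mob <- ref %*% R + matrix(1:3, 10, 3, byrow = TRUE)
#' superpose(mob, ref)$rmsd  # ~0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be n x 3 matrices of equal size")
  if (nrow(mobile) < 3L) stop("at least 3 atoms are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)                 # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps centred mobile -> centred ref
  fitted <- A %*% t(R)
  fitted <- sweep(fitted, 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  list(rotation = t(R), translation = as.numeric(cr - cm %*% t(R)),
       coords = fitted, rmsd = rmsd)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b \code{n x 3} matrices.
#' @param fit if \code{TRUE} (default) superpose \code{a} onto \code{b} first.
#' @return RMSD in Angstrom.
#' @export
coordRMSD <- function(a, b, fit = TRUE) {
  if (fit) return(superpose(a, b)$rmsd)
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# Align every frame of a coords array onto a reference; returns the array.
.alignFrames <- function(coords, reference) {
  out <- coords
  for (f in seq_len(dim(coords)[3]))
    out[, , f] <- superpose(coords[, , f], reference)$coords
  out
}

# Iterative superposition onto the running mean until the mean moves by
# less than tol (Angstrom, RMS). Returns list(coords, mean).
.iterativeMeanAlign <- function(coords, tol = 1e-6, maxIter = 100L) {
  ref <- coords[, , 1]
  for (it in seq_len(maxIter)) {
    coords <- .alignFrames(coords, ref)
    m <- apply(coords, c(1, 2), mean)
    shift <- sqrt(mean((m - ref)^2))
    ref <- m
    if (shift < tol) break
  }
  list(coords = coords, mean = ref)
}
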