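#' Nonnegative least squares (Lawson-Hanson active set)
#'
#' Minimizes \eqn{\lVert A x - b \rVert_2} subject to \eqn{x \ge 0}.
#' Used as the bounded solver behind natural-abundance correction and
#' moiety deconvolution; weights are applied by row-scaling before the call.
#'
#' @param A numeric matrix (p x q), p >= 1.
#' @param b numeric vector of length p.
#' @param tol tolerance on the dual feasibility test.
#' @param max_iter iteration cap.
#' @return list with `x` (solution), `residual` (2-norm of `A x - b`),
#'   `passive` (indices of the active/positive set).
#' @export
nnls_solve <- function(A, b, tol = 1e-10, max_iter = NULL) {
  A <- as.matrix(A)
  p <- nrow(A); q <- ncol(A)
  stopifnot(length(b) == p, q >= 1L)
  if (is.null(max_iter)) max_iter <- 3L * q + 30L
  x <- numeric(q)
  passive <- rep(FALSE, q)
  w <- drop(crossprod(A, b - A %*% x))
  it <- 0L
  scale <- max(abs(w), 1)
  while (any(!passive) && any(w[!passive] > tol * scale) && it < max_iter) {
    it <- it + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(q)
      z[P] <- tryCatch(
        qr.coef(qr(A[, P, drop = FALSE]), b),
        error = function(e) rep(NA_real_, length(P))
      )
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      # step back along the segment x -> z until the first coefficient hits 0
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)), passive = which(passive))
}
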