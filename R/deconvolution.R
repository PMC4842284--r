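#' Build the convolution equation system for moiety deconvolution
#'
#' A molecule's MID is the convolution (Cauchy product) of the MIDs of its
#' independent moieties. Given an observed parent pattern of length p and a
#' known moiety vector of length m, the unknown complementary moiety has
#' q = p - m + 1 isotopomers and satisfies `C x = parent`, where column k of
#' the p x q design matrix `C` is the known vector shifted down by k.
#'
#' @param parent numeric observation vector (MID or raw intensities),
#'   length p.
#' @param known_moiety numeric vector of the known moiety (normalized to
#'   unit sum internally), length m <= p.
#' @param weights optional positive weights, length p. Default
#'   `1 / max(obs, eps)` with `eps = 1e-3 * max(parent)`, i.e. variance
#'   proportional to intensity as is standard for spectral counts.
#' @return list of class `convolution_system`: `C` (design matrix),
#'   `observation`, `weights`, `p`, `q`.
#' @export
build_convolution_system <- function(parent, known_moiety, weights = NULL) {
  stopifnot(is.numeric(parent), is.numeric(known_moiety))
  p <- length(parent); m <- length(known_moiety)
  if (p < m) {
    stop(sprintf("parent vector (length %d) shorter than known moiety (length %d)",
                 p, m))
  }
  known <- known_moiety / sum(known_moiety)
  q <- p - m + 1L
  C <- matrix(0, p, q)
  for (k in seq_len(q)) C[k:(k + m - 1L), k] <- known
  if (is.null(weights)) {
    eps <- 1e-3 * max(parent)
    weights <- 1 / pmax(parent, eps)
  }
  stopifnot(length(weights) == p, all(weights > 0))
  structure(list(C = C, observation = as.numeric(parent),
                 weights = as.numeric(weights), p = p, q = q),
            class = "convolution_system")
}

#' Solve a convolution system for the unknown moiety MID
#'
#' Minimizes \eqn{\sum_i w_i (obs_i - (Cx)_i)^2} subject to \eqn{x \ge 0}
#' (weighted nonnegative least squares via row scaling), then renormalizes
#' the solution to a unit-sum MID. Per-coefficient standard errors come
#' from the unconstrained normal equations on the active set.
#'
#' @param sys a [build_convolution_system()] result.
#' @return numeric MID of the unknown moiety with attributes `residual`
#'   (weighted residual 2-norm), `coefficients` (unnormalized solution),
#'   `stderr` (per-coefficient standard errors, `NA` where inestimable).
#' @export
solve_complementary_mid <- function(sys) {
  stopifnot(inherits(sys, "convolution_system"))
  sw <- sqrt(sys$weights)
  A <- sys$C * sw
  b <- sys$observation * sw
  if (qr(A)$rank < sys$q) {
    stop("rank-deficient design: use a longer parent observation vector")
  }
  fit <- nnls_solve(A, b)
  x <- fit$x
  if (sum(x) <= 0) stop("degenerate solution: all coefficients zero")
  se <- rep(NA_real_, sys$q)
  dof <- sys$p - length(fit$passive)
  if (length(fit$passive) && dof > 0) {
    Ap <- A[, fit$passive, drop = FALSE]
    sigma2 <- fit$residual^2 / dof
    covm <- tryCatch(solve(crossprod(Ap)) * sigma2, error = function(e) NULL)
    if (!is.null(covm)) se[fit$passive] <- sqrt(pmax(diag(covm), 0))
  }
  out <- x / sum(x)
  attr(out, "residual") <- fit$residual
  attr(out, "coefficients") <- x
  attr(out, "stderr") <- se / sum(x)
  out
}

#' Deconvolve a moiety MID from a parent/sub-fragment pair
#'
#' Recovers the MID of the moiety by which two fragments of the same
#' compound differ (e.g. the acetyl moiety from the NAA 2TMS pair
#' m/z 304 = [M-CH3]+ and m/z 245 = [M-CH3-CH3CONH2]+). When both fragments
#' carry raw spectral intensities, the system is populated with the raw
#' intensities (known-moiety column = sub-fragment intensities normalized
#' to unit sum) and the solved moiety MID is corrected post hoc for natural
#' isotope abundance using `moiety_formula`. Otherwise the corrected MIDs
#' are used and no further correction is applied.
#'
#' @param parent_mid,sub_mid corrected MIDs of the parent and sub-fragment.
#' @param parent_raw,sub_raw optional raw intensity vectors.
#' @param moiety_formula [elemental_formula()] of the moiety (used only on
#'   the raw-intensity path).
#' @param table isotope table for the correction.
#' @param weights optional explicit weights for the solve.
#' @return moiety MID with attributes of [solve_complementary_mid()] plus
#'   `path` (`"raw_intensities"` or `"corrected_mids"`).
#' @export
deconvolve_moiety <- function(parent_mid = NULL, sub_mid = NULL,
                              parent_raw = NULL, sub_raw = NULL,
                              moiety_formula = NULL,
                              table = default_isotope_table(),
                              weights = NULL) {
  use_raw <- !is.null(parent_raw) && !is.null(sub_raw)
  if (use_raw) {
    sys <- build_convolution_system(parent_raw, sub_raw, weights)
    sol <- solve_complementary_mid(sys)
    if (!is.null(moiety_formula)) {
      corrected <- correct_natural_abundance(as.numeric(sol), moiety_formula,
                                             table)
      attributes(corrected) <- c(attributes(corrected),
                                 attributes(sol)[c("residual", "coefficients",
                                                   "stderr")])
      sol <- corrected
    }
    attr(sol, "path") <- "raw_intensities"
    return(sol)
  }
  if (is.null(parent_mid) || is.null(sub_mid)) {
    stop("data error: need either raw intensities or corrected MIDs for both fragments")
  }
  sys <- build_convolution_system(parent_mid, sub_mid, weights)
  sol <- solve_complementary_mid(sys)
  attr(sol, "path") <- "corrected_mids"
  sol
}
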