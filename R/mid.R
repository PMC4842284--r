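#' Normalize a raw abundance vector into a mass isotopomer distribution
#'
#' A mass isotopomer distribution (MID) is the vector of relative abundances
#' of the isotopologues M0..Mn of one mass-spectrometric fragment. Small
#' negative entries can arise as artifacts of natural-abundance correction;
#' they are clamped to zero before the vector is rescaled to unit sum.
#'
#' @param raw numeric vector of length >= 1, raw (possibly slightly negative)
#'   abundances in M0..Mn order.
#' @return numeric vector of the same length summing to 1 (within 1e-6).
#' @examples
#' normalize_mid(c(2, 2))                 # 0.5 0.5
#' normalize_mid(c(0.98, -0.01, 0.03))    # negatives clamped, then rescaled
#' @export
normalize_mid <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1L) {
    stop("`raw` must be a numeric vector of length >= 1")
  }
  if (anyNA(raw)) stop("`raw` contains missing values")
  x <- pmax(raw, 0)
  s <- sum(x)
  if (s <= 0) stop("degenerate input: all abundances are zero or negative")
  x / s
}

#' Validate a MID vector
#'
#' Checks length, missing values, the small-negative tolerance used for
#' correction artifacts, and (optionally) unit sum.
#'
#' @param mid numeric vector.
#' @param normalized require sum within `tol` of 1.
#' @param min_abundance most negative entry allowed (default -0.02,
#'   correction artifacts only).
#' @param tol unit-sum tolerance.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_mid <- function(mid, normalized = FALSE, min_abundance = -0.02,
                         tol = 1e-6) {
  if (!is.numeric(mid) || length(mid) < 1L) stop("MID must have length >= 1")
  if (anyNA(mid)) stop("MID contains missing values")
  if (any(mid < min_abundance)) {
    stop(sprintf("MID abundance below %.3g (got %.4g)", min_abundance, min(mid)))
  }
  if (normalized && abs(sum(mid) - 1) > tol) {
    stop(sprintf("MID does not sum to 1 (sum = %.8f)", sum(mid)))
  }
  invisible(TRUE)
}

#' Fractional enrichment of a MID
#'
#' The labeled fraction of the pool, 1 - M0.
#'
#' @param mid MID vector.
#' @return scalar in `[0, 1]` for a valid MID.
#' @export
fractional_enrichment <- function(mid) {
  validate_mid(mid)
  1 - mid[[1L]]
}

# Zero-pad a list of numeric vectors on the right to a common length.
pad_mids <- function(mids, len = max(lengths(mids))) {
  lapply(mids, function(m) c(m, rep(0, len - length(m))))
}
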