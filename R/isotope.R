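#' Convolve two mass isotopomer distributions
#'
#' The MID of a molecule composed of two independent moieties is the
#' convolution (Cauchy product) of the moiety MIDs:
#' \eqn{c_j = \sum_k a_k b_{j-k}}.
#'
#' @param a,b numeric MID vectors.
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_mids(c(0.5, 0.5), c(0.5, 0.5))  # 0.25 0.50 0.25
#' @export
convolve_mids <- function(a, b) {
  validate_mid(a, min_abundance = -Inf)
  validate_mid(b, min_abundance = -Inf)
  out <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a)) {
    idx <- k:(k + length(b) - 1L)
    out[idx] <- out[idx] + a[[k]] * b
  }
  out
}

#' Default isotope abundance table
#'
#' Natural abundances of the heavy isotopes relevant to GC-MS analysis of
#' trimethylsilyl (TMS) derivatives; silicon matters because each TMS group
#' contributes one Si and three C. Each element maps to a named numeric
#' vector of isotope abundances indexed by nominal mass shift ("0", "1", ...),
#' summing to 1.
#'
#' @return named list, element symbol -> abundance vector by mass shift.
#' @export
default_isotope_table <- function() {
  tab <- list(
    C  = c(`1` = 0.0107),
    H  = c(`1` = 0.000115),
    N  = c(`1` = 0.00364),
    O  = c(`1` = 0.00038, `2` = 0.00205),
    Si = c(`1` = 0.04685, `2` = 0.03092),
    S  = c(`1` = 0.0075, `2` = 0.0425),
    P  = numeric(0)
  )
  lapply(tab, function(heavy) {
    shifts <- as.integer(names(heavy))
    out <- numeric(if (length(shifts)) max(shifts) + 1L else 1L)
    out[1L] <- 1 - sum(heavy)
    if (length(shifts)) out[shifts + 1L] <- heavy
    out
  })
}

#' Read an isotope table override from a YAML config file
#'
#' The file maps element symbols to lists of `{shift, abundance}` entries;
#' elements not listed fall back to [default_isotope_table()].
#'
#' @param path YAML file.
#' @return isotope table as in [default_isotope_table()].
#' @export
read_isotope_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  tab <- default_isotope_table()
  for (el in names(cfg)) {
    entries <- cfg[[el]]
    shifts <- vapply(entries, function(e) as.integer(e$shift), integer(1))
    ab <- vapply(entries, function(e) as.numeric(e$abundance), numeric(1))
    if (abs(sum(ab) - 1) > 1e-9) {
      stop(sprintf("isotope abundances for %s do not sum to 1", el))
    }
    v <- numeric(max(shifts) + 1L)
    v[shifts + 1L] <- ab
    tab[[el]] <- v
  }
  tab
}

#' Construct an elemental formula with tracer annotation
#'
#' @param counts either a named integer vector of atom counts
#'   (e.g. `c(C = 9, H = 21, N = 1, O = 4, Si = 2)`) or a Hill-notation
#'   string such as `"C9H21NO4Si2"`.
#' @param tracer_element element carrying the isotopic tracer (default `"C"`).
#' @param tracer_atoms number of backbone positions that can carry tracer
#'   label; defaults to all atoms of `tracer_element`. Must not exceed the
#'   count of `tracer_element`.
#' @return object of class `elemental_formula`: list with `counts`,
#'   `tracer_element`, `tracer_atoms`.
#' @export
elemental_formula <- function(counts, tracer_element = "C", tracer_atoms = NULL) {
  if (is.character(counts)) counts <- parse_hill_formula(counts)
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("atom counts must be nonnegative")
  n_tracer <- if (tracer_element %in% names(counts)) counts[[tracer_element]] else 0L
  if (is.null(tracer_atoms)) tracer_atoms <- n_tracer
  if (tracer_atoms > n_tracer) {
    stop(sprintf("tracer_atoms (%d) exceeds %s count (%d)",
                 tracer_atoms, tracer_element, n_tracer))
  }
  structure(list(counts = counts, tracer_element = tracer_element,
                 tracer_atoms = as.integer(tracer_atoms)),
            class = "elemental_formula")
}

#' Parse a Hill-notation formula string
#'
#' @param s string like `"C6H12O6"` or `"C2H3NO"`.
#' @return named integer vector of atom counts.
#' @export
parse_hill_formula <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop(sprintf("cannot parse formula '%s'", s))
  }
  els <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Z][a-z]?", "", toks)
  counts <- ifelse(nzchar(ns), as.integer(ns), 1L)
  tapply(counts, els, sum)[unique(els)]
}

format_hill_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

# Per-atom isotopologue distribution raised to the n-th power by repeated
# convolution; sizes here are tiny so no exponentiation tricks are needed.
atom_power <- function(dist, n) {
  out <- 1
  for (i in seq_len(n)) out <- convolve_mids(out, dist)
  out
}

#' Theoretical natural-abundance isotopologue envelope of a formula
#'
#' Convolution of the per-atom isotope distributions of every atom in the
#' formula, truncated where the cumulative tail falls below `tail_tol` and
#' renormalized. The tracer annotation is ignored here: the envelope covers
#' all atoms present in `formula$counts`.
#'
#' @param formula an [elemental_formula()].
#' @param table isotope table, see [default_isotope_table()].
#' @param tail_tol cumulative tail mass below which the envelope is cut.
#' @return MID vector of the natural isotopologue pattern.
#' @export
natural_abundance_envelope <- function(formula, table = default_isotope_table(),
                                       tail_tol = 1e-9) {
  counts <- formula$counts
  missing <- setdiff(names(counts), names(table))
  if (length(missing)) {
    stop(sprintf("element(s) not in isotope table: %s",
                 paste(missing, collapse = ", ")))
  }
  env <- 1
  for (el in names(counts)) {
    env <- convolve_mids(env, atom_power(table[[el]], counts[[el]]))
  }
  # drop the tail once the cumulative remainder is negligible
  tail_mass <- rev(cumsum(rev(env)))
  keep <- max(1L, which(tail_mass >= tail_tol))
  env <- env[seq_len(keep)]
  env / sum(env)
}

# Envelope of the non-tracer part of a fragment formula: all atoms except the
# tracer-capable backbone positions (which are what the corrected MID describes).
non_tracer_envelope <- function(formula, table, tail_tol = 1e-9) {
  counts <- formula$counts
  if (formula$tracer_atoms > 0L) {
    counts[[formula$tracer_element]] <-
      counts[[formula$tracer_element]] - formula$tracer_atoms
  }
  f2 <- formula
  f2$counts <- counts[counts > 0]
  natural_abundance_envelope(f2, table, tail_tol)
}

#' Correct a measured isotopologue pattern for natural isotope abundance
#'
#' Solves the lower-triangular convolution system `C x = measured`, where
#' column k of `C` is the natural-abundance envelope of the fragment's
#' non-tracer atoms shifted down by k. The number of unknowns is
#' `tracer_atoms + 1` (capped at the measured length). The solve is
#' nonnegative least squares, which is robust to the small negatives that
#' direct back-substitution amplifies in noisy data.
#'
#' @param measured numeric vector of measured relative isotopologue
#'   abundances (length >= 1).
#' @param formula an [elemental_formula()] describing the whole fragment ion,
#'   including derivatization atoms.
#' @param table isotope table.
#' @return corrected MID (length `tracer_atoms + 1`, clamped and
#'   renormalized), with attributes `residual` and `condition_number`.
#' @export
correct_natural_abundance <- function(measured, formula,
                                      table = default_isotope_table()) {
  if (!is.numeric(measured) || length(measured) < 1L) {
    stop("`measured` must have length >= 1")
  }
  env <- non_tracer_envelope(formula, table)
  p <- length(measured)
  q <- min(formula$tracer_atoms + 1L, p)
  C <- matrix(0, p, q)
  for (k in seq_len(q)) {
    idx <- k:min(p, k + length(env) - 1L)
    C[idx, k] <- env[seq_along(idx)]
  }
  kappa_c <- kappa(C, exact = TRUE)
  if (kappa_c > 1e8) {
    warning(sprintf("correction matrix ill-conditioned (kappa = %.3g)", kappa_c))
  }
  fit <- nnls_solve(C, measured)
  out <- normalize_mid(fit$x)
  attr(out, "residual") <- fit$residual
  attr(out, "condition_number") <- kappa_c
  out
}
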