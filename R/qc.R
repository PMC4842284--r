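#' QC thresholds for fragment and compound acceptance
#'
#' Defaults follow the acceptance criteria used for non-targeted MID
#' analysis: a compound is kept when, in at least one experimental
#' condition, at least two of its fragments have MID determination
#' R^2 > 0.98, total absolute abundance below 1.05, monoisotopic abundance
#' 0.45 < M0 < 1, and fractional enrichment 1 - M0 >= 0.05. Because the
#' maximal MID length is unknown in non-targeted mode, trailing abundances
#' below 0.01 are treated as noise and removed.
#'
#' @param min_r2 minimal MID determination quality (exclusive).
#' @param max_abs_sum maximal allowed sum of absolute abundances (exclusive);
#'   evaluated on the MID as read, before any clamping, since it exists to
#'   catch correction artifacts.
#' @param m0_lower,m0_upper open interval for the M0 abundance.
#' @param min_enrichment minimal fractional enrichment `1 - M0` (inclusive).
#' @param trailing_noise threshold below which trailing abundances are noise.
#' @param min_passing_fragments fragments that must pass in one condition.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_r2 = 0.98, max_abs_sum = 1.05, m0_lower = 0.45,
                          m0_upper = 1.0, min_enrichment = 0.05,
                          trailing_noise = 0.01, min_passing_fragments = 2L) {
  stopifnot(min_r2 > 0, min_r2 <= 1, m0_lower >= 0, m0_lower < m0_upper,
            m0_upper <= 1, min_passing_fragments >= 1L)
  structure(list(min_r2 = min_r2, max_abs_sum = max_abs_sum,
                 m0_lower = m0_lower, m0_upper = m0_upper,
                 min_enrichment = min_enrichment,
                 trailing_noise = trailing_noise,
                 min_passing_fragments = as.integer(min_passing_fragments)),
            class = "qc_thresholds")
}

#' Remove trailing noise from a MID
#'
#' Strips the maximal run of final entries each below `threshold` and
#' renormalizes the remainder. At least one entry is always retained, and
#' the leading entry is never removed.
#'
#' @param mid MID vector.
#' @param threshold noise threshold (default 0.01).
#' @return shortened, renormalized MID.
#' @examples
#' strip_trailing_noise(c(0.7, 0.25, 0.04, 0.005, 0.005))
#' @export
strip_trailing_noise <- function(mid, threshold = 0.01) {
  validate_mid(mid)
  keep <- length(mid)
  while (keep > 1L && mid[[keep]] < threshold) keep <- keep - 1L
  if (keep == length(mid)) return(mid)
  normalize_mid(mid[seq_len(keep)])
}

#' Test one fragment against the QC criteria
#'
#' @param mid MID vector as read (pre-clamping).
#' @param r2 MID determination quality; `NA`/`NULL` fails the r2 criterion.
#' @param thresholds a [qc_thresholds()].
#' @return list with `pass` (all four criteria) and `flags`, a named logical
#'   vector (`r2`, `abs_sum`, `m0_range`, `enrichment`) plus `r2_missing`.
#' @export
fragment_passes_qc <- function(mid, r2, thresholds = qc_thresholds()) {
  validate_mid(mid)
  t <- thresholds
  r2_missing <- is.null(r2) || is.na(r2)
  m0 <- mid[[1L]]
  flags <- c(
    r2 = !r2_missing && r2 > t$min_r2,
    abs_sum = sum(abs(mid)) < t$max_abs_sum,
    m0_range = m0 > t$m0_lower && m0 < t$m0_upper,
    enrichment = (1 - m0) >= t$min_enrichment
  )
  list(pass = all(flags), flags = flags, r2_missing = r2_missing)
}

#' QC-filter a labeling dataset
#'
#' Keeps a compound if and only if, in at least one (condition, tracer)
#' slice, at least `min_passing_fragments` of its fragments pass the
#' per-fragment QC on the replicate-mean MID. Compounds matching the
#' exclusion list are removed as contaminants regardless of QC. Trailing
#' noise is stripped from every retained MID.
#'
#' @param ds a [labeling_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @param exclusion_list character vector of contaminant ids/name substrings
#'   (see [read_exclusion_list()]).
#' @return list with `dataset` (filtered [labeling_dataset()]) and `report`:
#'   a `data.table` of one row per input compound with `compound_id`,
#'   `retained`, `reason` (`"ok"`, `"contaminant"`, or
#'   `"insufficient_fragments"`) and `max_passing_fragments`.
#' @export
filter_dataset <- function(ds, thresholds = qc_thresholds(),
                           exclusion_list = character(0)) {
  stopifnot(inherits(ds, "labeling_dataset"))
  dt <- ds$data
  compounds <- unique(dt[, c("compound_id", "compound_name"), with = FALSE],
                      by = "compound_id")
  contaminant <- matches_exclusion(compounds$compound_id,
                                   compounds$compound_name, exclusion_list) |
    vapply(compounds$compound_id,
           function(id) any(dt$is_contaminant[dt$compound_id == id]),
           logical(1))

  # passing-fragment count per compound within each (condition, tracer) slice
  max_pass <- vapply(compounds$compound_id, function(id) {
    sub <- dt[dt$compound_id == id, ]
    slices <- split(sub, list(sub$condition, sub$tracer), drop = TRUE)
    best <- 0L
    for (sl in slices) {
      by_frag <- split(sl, sl$fragment_mz)
      n_pass <- sum(vapply(by_frag, function(fr) {
        m <- normalize_raw_mean(fr$mid)
        r2 <- mean(fr$r2, na.rm = TRUE)
        fragment_passes_qc(m, if (is.nan(r2)) NA_real_ else r2, thresholds)$pass
      }, logical(1)))
      best <- max(best, n_pass)
    }
    best
  }, integer(1))

  retained <- !contaminant & max_pass >= thresholds$min_passing_fragments
  reason <- ifelse(contaminant, "contaminant",
                   ifelse(retained, "ok", "insufficient_fragments"))
  report <- data.table::data.table(
    compound_id = compounds$compound_id,
    compound_name = compounds$compound_name,
    retained = retained, reason = reason,
    max_passing_fragments = max_pass
  )
  keep <- dt[dt$compound_id %in% compounds$compound_id[retained], ]
  keep$mid <- lapply(keep$mid, function(m) {
    strip_trailing_noise(normalize_mid(m), thresholds$trailing_noise)
  })
  out <- labeling_dataset(keep,
                          conditions = intersect(ds$conditions,
                                                 unique(keep$condition)),
                          tracers = intersect(ds$tracers, unique(keep$tracer)))
  list(dataset = out, report = report[])
}

# Mean of replicate MIDs without clamping: the abs-sum QC criterion must see
# correction artifacts (small negatives) as read.
normalize_raw_mean <- function(mids) {
  padded <- pad_mids(mids)
  m <- Reduce(`+`, padded) / length(padded)
  m / sum(m)
}
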