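#' Read a canonical MID table (TSV)
#'
#' The canonical table is tab-separated with columns `condition`, `tracer`,
#' `replicate`, `compound_id`, `compound_name`, `retention_index`,
#' `derivative`, `fragment_mz`, `formula`, `r2`, `n_isotopomers`,
#' `M0 ... Mk` (corrected relative abundances, mandatory) and optionally
#' `I0 ... Ik` (raw intensities, blank allowed). `n_isotopomers` gives the
#' MID length of each row; trailing M columns beyond it are ignored.
#'
#' @param path file path.
#' @param expected_tracers optional character vector; tracer labels outside
#'   it trigger a warning (never an error).
#' @param exclusion_list optional character vector of contaminant ids/names
#'   (see [read_exclusion_list()]); matching rows are flagged
#'   `is_contaminant` but not removed.
#' @return a [labeling_dataset()].
#' @export
read_mid_table <- function(path, expected_tracers = NULL, exclusion_list = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("", "NA"))
  mandatory <- c("condition", "tracer", "replicate", "compound_id",
                 "compound_name", "retention_index", "derivative",
                 "fragment_mz", "formula", "r2", "n_isotopomers", "M0")
  miss <- setdiff(mandatory, names(dt))
  if (length(miss)) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  m_cols <- grep("^M[0-9]+$", names(dt), value = TRUE)
  m_cols <- m_cols[order(as.integer(sub("^M", "", m_cols)))]
  i_cols <- grep("^I[0-9]+$", names(dt), value = TRUE)
  i_cols <- i_cols[order(as.integer(sub("^I", "", i_cols)))]

  n <- nrow(dt)
  mids <- vector("list", n)
  raws <- rep(list(numeric(0)), n)
  if (n > 0L) {
    M <- as.matrix(dt[, m_cols, with = FALSE])
    RW <- if (length(i_cols)) as.matrix(dt[, i_cols, with = FALSE]) else NULL
    for (r in seq_len(n)) {
      k <- as.integer(dt$n_isotopomers[[r]])
      if (is.na(k) || k < 1L || k > length(m_cols)) {
        stop(sprintf("data error in row %d: n_isotopomers = %s out of range",
                     r, dt$n_isotopomers[[r]]))
      }
      mid <- as.numeric(M[r, seq_len(k)])
      if (anyNA(mid)) {
        stop(sprintf("data error in row %d: missing abundance within M0..M%d",
                     r, k - 1L))
      }
      s <- sum(mid)
      if (s < 0.8 || s > 1.2) {
        stop(sprintf("data error in row %d: abundances sum to %.4f (outside [0.8, 1.2])",
                     r, s))
      }
      mids[[r]] <- mid
      if (!is.null(RW)) {
        rv <- as.numeric(RW[r, ])
        rv <- rv[!is.na(rv)]
        if (length(rv) >= k) raws[[r]] <- rv
      }
    }
  }
  if (!is.null(expected_tracers)) {
    unknown <- setdiff(unique(dt$tracer), expected_tracers)
    if (length(unknown)) {
      warning(sprintf("unknown tracer label(s): %s",
                      paste(unknown, collapse = ", ")))
    }
  }
  core <- dt[, c("condition", "tracer", "replicate", "compound_id",
                 "compound_name", "retention_index", "derivative",
                 "fragment_mz", "formula", "r2"), with = FALSE]
  core$mid <- mids
  core$raw <- raws
  core$is_contaminant <- if (is.null(exclusion_list)) FALSE else {
    matches_exclusion(core$compound_id, core$compound_name, exclusion_list)
  }
  labeling_dataset(core)
}

#' Write a labeling dataset as a canonical MID table (TSV)
#'
#' Column order is fixed; floats are serialized at 6 significant digits.
#'
#' @param ds a [labeling_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(ds, path) {
  stopifnot(inherits(ds, "labeling_dataset"))
  dt <- ds$data
  kmax <- if (nrow(dt)) max(lengths(dt$mid)) else 1L
  have_raw <- nrow(dt) > 0L && any(lengths(dt$raw) > 0L)
  rmax <- if (have_raw) max(lengths(dt$raw)) else kmax
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6g", x))
  out <- data.table::data.table(
    condition = dt$condition, tracer = dt$tracer, replicate = dt$replicate,
    compound_id = dt$compound_id, compound_name = dt$compound_name,
    retention_index = fmt(dt$retention_index), derivative = dt$derivative,
    fragment_mz = dt$fragment_mz, formula = dt$formula, r2 = fmt(dt$r2),
    n_isotopomers = lengths(dt$mid)
  )
  for (j in seq_len(kmax)) {
    out[[paste0("M", j - 1L)]] <- vapply(dt$mid, function(m) {
      if (length(m) >= j) sprintf("%.6g", m[[j]]) else ""
    }, character(1))
  }
  for (j in seq_len(rmax)) {
    out[[paste0("I", j - 1L)]] <- vapply(dt$raw, function(v) {
      if (length(v) >= j) sprintf("%.6g", v[[j]]) else ""
    }, character(1))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a contaminant exclusion list
#'
#' Plain text, one compound id or compound name per line; blank lines and
#' `#` comments are ignored. Matching is exact on `compound_id` or
#' case-insensitive substring on `compound_name` (siloxane naming varies
#' between libraries).
#'
#' @param path file path.
#' @return character vector of patterns.
#' @export
read_exclusion_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

matches_exclusion <- function(compound_id, compound_name, exclusion) {
  if (!length(exclusion)) return(rep(FALSE, length(compound_id)))
  hit <- compound_id %in% exclusion
  name_lc <- tolower(ifelse(is.na(compound_name), "", compound_name))
  for (pat in tolower(exclusion)) {
    hit <- hit | (nzchar(name_lc) & grepl(pat, name_lc, fixed = TRUE))
  }
  hit
}
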