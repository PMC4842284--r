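#' Labeling dataset container
#'
#' The unit all pipeline stages consume: per-fragment MID measurements of
#' compounds across experimental conditions, tracers, and replicates. Backed
#' by a `data.table` in long format with one row per
#' (condition, tracer, replicate, compound_id, fragment_mz).
#'
#' Columns: `condition`, `tracer`, `replicate` (integer), `compound_id`,
#' `compound_name`, `retention_index`, `derivative`, `fragment_mz` (integer
#' nominal m/z), `formula` (Hill notation or `NA`), `r2` (MID determination
#' quality), `mid` (list column of numeric MID vectors, natural-abundance
#' corrected), `raw` (list column of raw intensity vectors or `NULL`),
#' `is_contaminant` (logical).
#'
#' @param data data.frame/data.table with at least `condition`, `tracer`,
#'   `replicate`, `compound_id`, `fragment_mz`, `mid`; missing metadata
#'   columns are filled with `NA`.
#' @param conditions optional ordered condition labels; defaults to first
#'   encountered order.
#' @param tracers optional tracer labels; defaults to those present.
#' @return object of class `labeling_dataset`.
#' @export
labeling_dataset <- function(data, conditions = NULL, tracers = NULL) {
  dt <- data.table::as.data.table(data)
  required <- c("condition", "tracer", "replicate", "compound_id",
                "fragment_mz", "mid")
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  defaults <- list(compound_name = NA_character_, retention_index = NA_real_,
                   derivative = NA_character_, formula = NA_character_,
                   r2 = NA_real_, is_contaminant = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(dt)) {
      dt[[col]] <- rep(defaults[[col]], length.out = nrow(dt))
    }
  }
  # absent raw intensities are empty vectors, never NULL: a NULL inside a
  # data.table list column is indistinguishable from column deletion
  if (!"raw" %in% names(dt)) {
    dt[["raw"]] <- rep(list(numeric(0)), length.out = nrow(dt))
  } else {
    dt[["raw"]] <- lapply(dt$raw, function(v) if (is.null(v)) numeric(0) else v)
  }
  dt$replicate <- as.integer(dt$replicate)
  dt$fragment_mz <- as.integer(dt$fragment_mz)
  if (!is.list(dt$mid)) stop("`mid` must be a list column of numeric vectors")
  key_cols <- c("condition", "tracer", "replicate", "compound_id", "fragment_mz")
  dup <- duplicated(dt, by = key_cols)
  if (any(dup)) {
    k <- dt[which(dup)[1L], key_cols, with = FALSE]
    stop(sprintf("duplicate measurement for key (%s)",
                 paste(unlist(lapply(k, as.character)), collapse = ", ")))
  }
  if (is.null(conditions)) conditions <- unique(dt$condition)
  if (is.null(tracers)) tracers <- unique(dt$tracer)
  data.table::setcolorder(dt, c(key_cols[1:4], "compound_name",
                                "retention_index", "derivative", "fragment_mz",
                                "formula", "r2", "mid", "raw", "is_contaminant"))
  structure(list(data = dt, conditions = conditions, tracers = tracers),
            class = "labeling_dataset")
}

#' @export
print.labeling_dataset <- function(x, ...) {
  dt <- x$data
  cat(sprintf(paste0("<labeling_dataset> %d measurements | %d compounds | ",
                     "%d conditions x %d tracers\n"),
              nrow(dt), length(unique(dt$compound_id)),
              length(x$conditions), length(x$tracers)))
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("tracers:   ", paste(x$tracers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.labeling_dataset <- function(x, ...) {
  sprintf("<labeling_dataset: %d rows>", nrow(x$data))
}

#' Subset a labeling dataset
#'
#' @param ds a [labeling_dataset()].
#' @param condition,tracer optional labels to keep (vectors allowed).
#' @return a new `labeling_dataset` restricted to the requested slice;
#'   condition/tracer ordering of the parent is preserved.
#' @export
dataset_slice <- function(ds, condition = NULL, tracer = NULL) {
  stopifnot(inherits(ds, "labeling_dataset"))
  # copy arguments before `[` so they cannot collide with column names
  want_cond <- condition; want_tracer <- tracer
  dt <- ds$data
  if (!is.null(want_cond)) dt <- dt[dt$condition %in% want_cond, ]
  if (!is.null(want_tracer)) dt <- dt[dt$tracer %in% want_tracer, ]
  labeling_dataset(dt,
                   conditions = intersect(ds$conditions, unique(dt$condition)),
                   tracers = intersect(ds$tracers, unique(dt$tracer)))
}

#' Replicate-mean MIDs per condition
#'
#' Stages that need a single MID per (condition, tracer, compound, fragment)
#' use the arithmetic mean of the replicate MIDs (zero-padded to a common
#' length), renormalized to unit sum. `r2` is averaged over replicates.
#'
#' @param ds a [labeling_dataset()].
#' @param tracer tracer label to restrict to (required: MIDs under different
#'   tracers are not comparable).
#' @return `data.table` with columns `condition`, `compound_id`,
#'   `compound_name`, `derivative`, `fragment_mz`, `r2`, `n_replicates`,
#'   `mid` (list column).
#' @export
condition_means <- function(ds, tracer) {
  stopifnot(inherits(ds, "labeling_dataset"))
  want_tracer <- tracer
  dt <- ds$data[ds$data$tracer == want_tracer, ]
  if (!nrow(dt)) {
    stop(sprintf("no measurements for tracer '%s'", tracer))
  }
  out <- dt[, {
    padded <- pad_mids(mid)
    m <- Reduce(`+`, padded) / length(padded)
    list(compound_name = compound_name[[1L]],
         derivative = derivative[[1L]],
         formula = formula[[1L]],
         r2 = mean(r2, na.rm = TRUE),
         n_replicates = .N,
         mid = list(normalize_mid(m)))
  }, by = c("condition", "compound_id", "fragment_mz")]
  out$r2[is.nan(out$r2)] <- NA_real_
  out[]
}
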