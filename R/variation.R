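#' Heaviest fragment common to all conditions where a compound occurs
#'
#' Cross-condition variation must compare like with like, so the largest
#' fragment m/z that was measured (with qualifying R^2) in every condition
#' in which the compound was detected is used.
#'
#' @param means `data.table` from [condition_means()], restricted to one
#'   compound.
#' @param min_r2 minimal R^2 for a fragment to qualify (`NA` r2 never
#'   qualifies when `min_r2 > 0`; pass `min_r2 = 0` to accept any).
#' @return integer fragment m/z, or `NA_integer_` when no common fragment
#'   exists.
#' @export
heaviest_common_fragment <- function(means, min_r2 = 0) {
  stopifnot(nrow(means) >= 1L)
  ok <- means[is.na(means$r2) & min_r2 <= 0 |
                (!is.na(means$r2) & means$r2 > min_r2), ]
  conds <- unique(means$condition)
  if (!nrow(ok)) return(NA_integer_)
  counts <- tapply(ok$condition, ok$fragment_mz,
                   function(x) length(unique(x)))
  common <- as.integer(names(counts)[counts == length(conds)])
  if (!length(common)) NA_integer_ else max(common)
}

#' Cross-condition variation score of a set of MIDs
#'
#' For each isotopomer index j, the population standard deviation
#' \eqn{\sigma_j = \sqrt{(1/n) \sum_i (\bar p_j - p_{j,i})^2}} of the
#' relative abundance across the n per-condition MIDs; the score is
#' \eqn{\max_j \sigma_j}. Vectors are zero-padded to a common length
#' (a missing heavy isotopomer is an observed ~0 abundance).
#'
#' @param mids list of numeric MID vectors, one per condition (n >= 2).
#' @return list with `score` (max sigma), `sigma` (per-index SDs) and
#'   `argmax` (1-based isotopomer index of the maximum, i.e. M[argmax-1]).
#' @examples
#' variation_score(list(c(1, 0), c(0.9, 0.1), c(0.8, 0.2)))$score  # 0.08165
#' @export
variation_score <- function(mids) {
  if (!is.list(mids) || length(mids) < 2L) {
    stop("need at least two per-condition MIDs")
  }
  P <- do.call(rbind, pad_mids(mids))
  n <- nrow(P)
  sigma <- sqrt(colMeans(sweep(P, 2, colMeans(P))^2))
  list(score = max(sigma), sigma = sigma, argmax = which.max(sigma))
}

#' Rank compounds by cross-condition MID variation
#'
#' Flags putative metabolic flux changes: since MIDs at isotopic steady
#' state are a function of flux ratios only, a change in relative mass
#' isotopomer abundance across conditions implies a flux change. Per
#' compound, replicate-mean MIDs are computed per condition, the heaviest
#' common fragment is selected, and the compound is scored by
#' [variation_score()]. Compounds isotopically enriched in fewer than
#' `min_conditions` conditions and unlabeled compounds are skipped. When
#' several derivatives of the same named metabolite qualify, only the
#' highest-scoring one is kept (unidentified compounds are never merged).
#'
#' @param ds QC-filtered [labeling_dataset()].
#' @param tracer tracer label.
#' @param min_conditions minimal number of conditions with isotopic
#'   enrichment (default 3).
#' @param top_k number of top-ranked compounds to return (`Inf` for all).
#' @param min_r2 fragment qualification threshold for
#'   [heaviest_common_fragment()].
#' @param min_enrichment enrichment defining "labeled in this condition".
#' @return `data.table` ordered by decreasing score: `compound_id`,
#'   `compound_name`, `fragment_mz`, `score`, `argmax_isotopomer` (0-based
#'   index of the most varying isotopomer), `n_conditions`, plus a list
#'   column `sigma`. Compounds excluded from ranking are reported in the
#'   `excluded` attribute with reasons.
#' @export
rank_by_variation <- function(ds, tracer, min_conditions = 3L, top_k = 5L,
                              min_r2 = 0, min_enrichment = 0.05) {
  means <- condition_means(ds, tracer)
  excluded <- list()
  rows <- list()
  for (id in unique(means$compound_id)) {
    cm <- means[means$compound_id == id, ]
    # enriched = labeled: detection without enrichment does not count
    enr_conds <- unique(cm$condition[
      vapply(cm$mid, fractional_enrichment, numeric(1)) >= min_enrichment])
    if (length(enr_conds) < min_conditions) {
      excluded[[id]] <- if (length(enr_conds) == 0L) "unlabeled"
                        else "too_few_conditions"
      next
    }
    cme <- cm[cm$condition %in% enr_conds, ]
    frag <- heaviest_common_fragment(cme, min_r2 = min_r2)
    if (is.na(frag)) {
      excluded[[id]] <- "no_common_fragment"
      next
    }
    sub <- cme[cme$fragment_mz == frag, ]
    vs <- variation_score(sub$mid)
    rows[[id]] <- data.table::data.table(
      compound_id = id, compound_name = sub$compound_name[[1L]],
      fragment_mz = frag, score = vs$score,
      argmax_isotopomer = vs$argmax - 1L,
      n_conditions = nrow(sub), sigma = list(vs$sigma)
    )
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(compound_id = character(0),
                           compound_name = character(0),
                           fragment_mz = integer(0), score = numeric(0),
                           argmax_isotopomer = integer(0),
                           n_conditions = integer(0), sigma = list())
  data.table::setorderv(out, c("score", "compound_id"), order = c(-1L, 1L))
  out <- dedupe_derivatives(out)
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  data.table::setattr(out, "excluded", excluded)
  out[]
}

# Keep only the best-scoring derivative per named metabolite; rows with no
# name (unidentified, typically named by retention index downstream) are
# never merged. Assumes `out` is already sorted by decreasing score.
dedupe_derivatives <- function(out) {
  named <- !is.na(out$compound_name) & nzchar(out$compound_name)
  drop <- named & duplicated(ifelse(named, out$compound_name, NA))
  out[!drop, ]
}
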