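#' Global alignment of two MID vectors
#'
#' Needleman-Wunsch alignment minimizing the sum of absolute abundance
#' differences over matched positions plus `gap_penalty` per gap. Gains or
#' losses of labeled fragments shift MIDs along the mass axis; the alignment
#' lets such shifted vectors be compared position-by-position. The traceback
#' tie-break is fixed (match, then gap in `a`, then gap in `b`) so results
#' are deterministic.
#'
#' @param a,b numeric MID vectors.
#' @param gap_penalty cost per gap (default 0.4).
#' @return list of class `mid_alignment`: `a_aligned`, `b_aligned`
#'   (equal-length, `NA` marks a gap), `cost`, `gap_count`.
#' @export
align_mid_vectors <- function(a, b, gap_penalty = 0.4) {
  validate_mid(a); validate_mid(b)
  n <- length(a); m <- length(b)
  eps <- 1e-12
  # canberra_term under the gap-as-zero convention: the secondary objective
  # that selects, among cost-optimal alignments, the one a distance reader
  # expects (pure shifts align shift-wise and score 0)
  cterm <- function(x, y) {
    d <- abs(x) + abs(y)
    if (d > 0) abs(x - y) / d else 0
  }
  D <- matrix(0, n + 1L, m + 1L)   # primary: alignment cost
  S <- matrix(0, n + 1L, m + 1L)   # secondary: canberra sum along the path
  MV <- matrix(0L, n + 1L, m + 1L) # traceback move: 1 match, 2 up, 3 left
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0L && j == 0L) next
      cand_cost <- rep(Inf, 3); cand_sec <- rep(Inf, 3)
      if (i > 0L && j > 0L) {
        cand_cost[1] <- D[i, j] + abs(a[[i]] - b[[j]])
        cand_sec[1] <- S[i, j] + cterm(a[[i]], b[[j]])
      }
      if (i > 0L) {  # a_i against a gap
        cand_cost[2] <- D[i, j + 1L] + gap_penalty
        cand_sec[2] <- S[i, j + 1L] + cterm(a[[i]], 0)
      }
      if (j > 0L) {  # b_j against a gap
        cand_cost[3] <- D[i + 1L, j] + gap_penalty
        cand_sec[3] <- S[i + 1L, j] + cterm(0, b[[j]])
      }
      best_cost <- min(cand_cost)
      tied <- which(cand_cost <= best_cost + eps)
      pick <- tied[which.min(cand_sec[tied])]
      D[i + 1L, j + 1L] <- best_cost
      S[i + 1L, j + 1L] <- cand_sec[pick]
      MV[i + 1L, j + 1L] <- pick
    }
  }
  i <- n; j <- m
  a_al <- numeric(0); b_al <- numeric(0)
  while (i > 0L || j > 0L) {
    mv <- MV[i + 1L, j + 1L]
    if (mv == 1L) {
      a_al <- c(a[[i]], a_al); b_al <- c(b[[j]], b_al)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      a_al <- c(a[[i]], a_al); b_al <- c(NA_real_, b_al)
      i <- i - 1L
    } else {
      a_al <- c(NA_real_, a_al); b_al <- c(b[[j]], b_al)
      j <- j - 1L
    }
  }
  structure(list(a_aligned = a_al, b_aligned = b_al,
                 cost = D[n + 1L, m + 1L],
                 gap_count = sum(is.na(a_al)) + sum(is.na(b_al))),
            class = "mid_alignment")
}

#' Normalized Canberra distance between two MID vectors
#'
#' The vectors are globally aligned first ([align_mid_vectors()]); the
#' Canberra distance \eqn{d = \sum_i |A_i - B_i| / (|A_i| + |B_i|)} is then
#' computed over aligned positions and normalized by the sum of the
#' dimensions of the input vectors:
#' \eqn{d^{norm} = d / (\dim A + \dim B)}.
#'
#' Under the default convention a gap contributes a 0-valued abundance and
#' the 0/0 term counts as 0, so a pure index shift (gain/loss of a labeled
#' fragment) has distance exactly 0. `gap_terms = "drop"` excludes gap
#' positions from the sum instead.
#'
#' @param a,b numeric MID vectors.
#' @param gap_penalty alignment gap penalty.
#' @param gap_terms `"zero"` (default) or `"drop"`.
#' @return normalized distance in `[0, 1]`.
#' @examples
#' mid_distance(c(1, 0), c(0, 1))        # 0: pure shift
#' mid_distance(c(1, 0), c(0.5, 0.5))    # 0.333333
#' @export
mid_distance <- function(a, b, gap_penalty = 0.4,
                         gap_terms = c("zero", "drop")) {
  gap_terms <- match.arg(gap_terms)
  al <- align_mid_vectors(a, b, gap_penalty)
  A <- al$a_aligned; B <- al$b_aligned
  if (gap_terms == "drop") {
    keep <- !is.na(A) & !is.na(B)
    A <- A[keep]; B <- B[keep]
  } else {
    A[is.na(A)] <- 0; B[is.na(B)] <- 0
  }
  denom <- abs(A) + abs(B)
  terms <- ifelse(denom > 0, abs(A - B) / denom, 0)
  sum(terms) / (length(a) + length(b))
}

#' Pairwise MID distance matrix for one condition and tracer
#'
#' Per compound, the heaviest fragment with R^2 above `min_r2` is selected
#' from the replicate-mean MIDs; compounds with no qualifying fragment are
#' excluded (and listed). All pairwise normalized Canberra distances are
#' computed within the slice; distances across tracers are never mixed.
#'
#' @param ds QC-filtered [labeling_dataset()].
#' @param condition,tracer slice labels.
#' @param min_r2 fragment qualification threshold (default 0.95, exclusive).
#' @param gap_penalty,gap_terms passed to [mid_distance()].
#' @return object of class `mid_distance_matrix`: list with `distances`
#'   (symmetric matrix, 0 diagonal), `compound_ids`, `compound_names`,
#'   `fragment_mz` (per compound), `mids`, `excluded`, `condition`, `tracer`.
#' @export
pairwise_distances <- function(ds, condition, tracer, min_r2 = 0.95,
                               gap_penalty = 0.4,
                               gap_terms = c("zero", "drop")) {
  gap_terms <- match.arg(gap_terms)
  want_cond <- condition
  means <- condition_means(ds, tracer)
  means <- means[means$condition == want_cond, ]
  sel <- list(); names_map <- list(); frag_map <- list(); excluded <- character(0)
  for (id in unique(means$compound_id)) {
    cm <- means[means$compound_id == id, ]
    ok <- cm[!is.na(cm$r2) & cm$r2 > min_r2, ]
    if (!nrow(ok)) { excluded <- c(excluded, id); next }
    best <- ok[which.max(ok$fragment_mz), ]
    sel[[id]] <- best$mid[[1L]]
    frag_map[[id]] <- best$fragment_mz
    names_map[[id]] <- best$compound_name
  }
  ids <- sort(names(sel))
  k <- length(ids)
  Dm <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- mid_distance(sel[[ids[i]]], sel[[ids[j]]], gap_penalty, gap_terms)
        Dm[i, j] <- d; Dm[j, i] <- d
      }
    }
  }
  structure(list(distances = Dm, compound_ids = ids,
                 compound_names = unlist(names_map[ids], use.names = TRUE),
                 fragment_mz = unlist(frag_map[ids], use.names = TRUE),
                 mids = sel[ids], excluded = excluded,
                 condition = condition, tracer = tracer),
            class = "mid_distance_matrix")
}

#' @export
print.mid_distance_matrix <- function(x, ...) {
  cat(sprintf("<mid_distance_matrix> %d compounds | condition %s | tracer %s\n",
              length(x$compound_ids), x$condition, x$tracer))
  if (length(x$excluded)) {
    cat("excluded (no qualifying fragment):",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a MID similarity network with cross-condition overlay
#'
#' An edge connects two compounds in every condition whose normalized
#' distance is at or below the cutoff; the per-condition networks are
#' overlaid into one graph whose edges carry the supporting condition set.
#' Edges supported by multiple conditions are more likely to reflect true
#' metabolic adjacency.
#'
#' @param matrices named list of [pairwise_distances()] results, one per
#'   condition (names default to each matrix's `condition`).
#' @param cutoff distance cutoff (> 0); the cutoff is data-dependent and
#'   therefore has no default.
#' @param keep_isolated keep nodes without any edge (default `FALSE`).
#' @return object of class `similarity_network`: list with `nodes`
#'   (character), `edges` (`data.table`: `source`, `target`, `distance` =
#'   minimum supporting distance, `conditions` semicolon-joined, and a list
#'   column `condition_distances`).
#' @export
build_similarity_network <- function(matrices, cutoff, keep_isolated = FALSE) {
  stopifnot(cutoff > 0)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices)))) {
    names(matrices) <- vapply(matrices, function(m) m$condition, character(1))
  }
  acc <- new.env(parent = emptyenv())
  all_nodes <- character(0)
  for (cond in names(matrices)) {
    dm <- matrices[[cond]]
    ids <- dm$compound_ids
    all_nodes <- union(all_nodes, ids)
    k <- length(ids)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- dm$distances[i, j]
        if (d <= cutoff) {
          key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
          prev <- if (!is.null(acc[[key]])) acc[[key]] else numeric(0)
          prev[[cond]] <- d
          acc[[key]] <- prev
        }
      }
    }
  }
  keys <- ls(acc)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.table::data.table(
      source = vapply(parts, `[[`, character(1), 1L),
      target = vapply(parts, `[[`, character(1), 2L),
      distance = vapply(keys, function(k) min(acc[[k]]), numeric(1)),
      conditions = vapply(keys, function(k)
        paste(sort(names(acc[[k]])), collapse = ";"), character(1)),
      condition_distances = lapply(keys, function(k) acc[[k]])
    )
    data.table::setorderv(edges, c("source", "target"))
  } else {
    edges <- data.table::data.table(
      source = character(0), target = character(0), distance = numeric(0),
      conditions = character(0), condition_distances = list())
  }
  nodes <- if (keep_isolated) sort(all_nodes) else
    sort(unique(c(edges$source, edges$target)))
  structure(list(nodes = nodes, edges = edges[]), class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Nearest neighbors of a compound in a distance matrix
#'
#' Returns the `k` most MID-similar compounds, ascending by distance with
#' ties broken by compound id. When several derivatives of the same named
#' metabolite occur, only the nearest one is reported.
#'
#' @param dm a [pairwise_distances()] result.
#' @param compound_id query compound.
#' @param k number of neighbors (clipped to the matrix size).
#' @return `data.table` with `compound_id`, `compound_name`, `distance`.
#' @export
nearest_neighbors <- function(dm, compound_id, k = 3L) {
  stopifnot(inherits(dm, "mid_distance_matrix"))
  if (!compound_id %in% dm$compound_ids) {
    stop(sprintf("unknown compound '%s'", compound_id))
  }
  others <- setdiff(dm$compound_ids, compound_id)
  d <- dm$distances[compound_id, others]
  ord <- order(d, others)
  res <- data.table::data.table(
    compound_id = others[ord],
    compound_name = unname(dm$compound_names[others[ord]]),
    distance = unname(d[ord])
  )
  named <- !is.na(res$compound_name) & nzchar(res$compound_name)
  drop <- named & duplicated(ifelse(named, res$compound_name, NA))
  res <- res[!drop, ]
  utils::head(res, min(k, nrow(res)))
}

#' Convert a similarity network to an igraph object
#'
#' @param net a [build_similarity_network()] result.
#' @return undirected `igraph` graph with `distance` and `conditions` edge
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "distance", "conditions"), with = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g
}

#' Write a similarity network to GraphML
#'
#' @param net a [build_similarity_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a similarity network as a flat edge-list TSV
#'
#' Columns: `source`, `target`, `distance`, `conditions` (semicolon-joined).
#'
#' @param net a [build_similarity_network()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  out <- net$edges[, c("source", "target", "distance", "conditions"),
                   with = FALSE]
  out$distance <- sprintf("%.6g", out$distance)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
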