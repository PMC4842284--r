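# Independent oracles and fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths.

# Exhaustive global alignment cost by recursive enumeration (lengths <= ~6).
brute_force_alignment_cost <- function(a, b, gap = 0.4) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- Inf
    if (i > 0L && j > 0L) best <- min(best, rec(i - 1L, j - 1L) + abs(a[i] - b[j]))
    if (i > 0L) best <- min(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- min(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(a), length(b))
}

# Direct evaluation of the per-isotopomer population SD and its maximum.
sigma_oracle <- function(mids) {
  len <- max(lengths(mids))
  P <- t(vapply(mids, function(m) c(m, rep(0, len - length(m))), numeric(len)))
  n <- nrow(P)
  sigma <- numeric(len)
  for (j in seq_len(len)) {
    pbar <- sum(P[, j]) / n
    sigma[j] <- sqrt(sum((pbar - P[, j])^2) / n)
  }
  list(score = max(sigma), sigma = sigma)
}

# Random unit-sum MID of length k.
random_mid <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# Long-format rows for one fragment measurement, for building toy datasets.
mid_row <- function(condition, tracer, replicate, compound_id, fragment_mz,
                    mid, r2 = 0.99, compound_name = NA_character_,
                    raw = NULL, derivative = NA_character_) {
  data.table::data.table(
    condition = condition, tracer = tracer, replicate = as.integer(replicate),
    compound_id = compound_id, compound_name = compound_name,
    retention_index = NA_real_, derivative = derivative,
    fragment_mz = as.integer(fragment_mz), formula = NA_character_,
    r2 = r2, mid = list(mid), raw = list(raw), is_contaminant = FALSE)
}

toy_dataset <- function(rows) {
  labeling_dataset(data.table::rbindlist(rows))
}

# Ten crafted rows with designed per-row QC outcomes: keep1 passes twice in
# condition A, drop1 has a single passing fragment everywhere, contam is a
# siloxane with perfect QC, drop2 never clears the enrichment threshold.
make_qc_dataset <- function() {
  good <- c(0.6, 0.3, 0.1)
  unlab <- c(0.98, 0.01, 0.01)
  rows <- list(
    mid_row("A", "t", 1, "keep1", 100, good, r2 = 0.99),
    mid_row("A", "t", 1, "keep1", 200, good, r2 = 0.995),
    mid_row("B", "t", 1, "keep1", 100, unlab, r2 = 0.90),
    mid_row("A", "t", 1, "drop1", 100, good, r2 = 0.99),
    mid_row("A", "t", 1, "drop1", 200, good, r2 = 0.50),
    mid_row("B", "t", 1, "drop1", 100, good, r2 = 0.99),
    mid_row("A", "t", 1, "contam", 100, good, r2 = 0.999,
            compound_name = "Hexamethylcyclotrisiloxane"),
    mid_row("A", "t", 1, "contam", 200, good, r2 = 0.999,
            compound_name = "Hexamethylcyclotrisiloxane"),
    mid_row("A", "t", 1, "drop2", 100, unlab, r2 = 0.999),
    mid_row("A", "t", 1, "drop2", 200, unlab, r2 = 0.999))
  toy_dataset(rows)
}

# Linear chain of `len` transfer steps, each step diluting with an unlabeled
# pool, fed by a source with the given labeling. Used for pathway-recovery
# and nearest-neighbor ground truth.
linear_pathway_model <- function(prefix, source_spec, dilutions,
                                 n_atoms = 3L) {
  len <- length(dilutions)
  cps <- stats::setNames(as.list(rep(n_atoms, len + 2L)),
                         c(paste0(prefix, "S"), paste0(prefix, "U"),
                           paste0(prefix, seq_len(len))))
  rx <- list(); mixing <- list()
  up <- paste0(prefix, "S")
  for (i in seq_len(len)) {
    this <- paste0(prefix, i)
    main_id <- paste0(prefix, "main", i)
    dil_id <- paste0(prefix, "dil", i)
    rx[[length(rx) + 1L]] <- list(
      id = main_id, product = this,
      substrates = list(list(compound = up, atoms = seq_len(n_atoms),
                             to = seq_len(n_atoms))))
    rx[[length(rx) + 1L]] <- list(
      id = dil_id, product = this,
      substrates = list(list(compound = paste0(prefix, "U"),
                             atoms = seq_len(n_atoms), to = seq_len(n_atoms))))
    mixing[[this]] <- stats::setNames(c(1 - dilutions[i], dilutions[i]),
                                      c(main_id, dil_id))
    up <- this
  }
  sources <- stats::setNames(
    list(source_spec, list(labeled_positions = integer(0), fraction = 0)),
    c(paste0(prefix, "S"), paste0(prefix, "U")))
  compile_model(list(compounds = cps, reactions = rx, mixing = mixing,
                     sources = sources))
}

# Two parallel 4-compound pathways with distinct source labeling, merged
# into one model so a single simulated dataset covers both. Partial
# positional purity keeps every isotopomer solidly populated (Canberra
# terms on structural zeros would otherwise be pure noise ratios), and a
# modest 5% exchange dilution per step keeps within-pathway MIDs similar.
parallel_pathways_model <- function() {
  specA <- list(labeled_positions = 1:3, fraction = 0.7, purity = 0.8)
  specB <- list(labeled_positions = 1:3, fraction = 0.65, purity = 0.45)
  a <- linear_pathway_model("A", specA, dilutions = rep(0.05, 4))
  b <- linear_pathway_model("B", specB, dilutions = rep(0.05, 4))
  spec <- list(
    compounds = c(as.list(a$compounds), as.list(b$compounds)),
    reactions = c(unname(a$reactions), unname(b$reactions)),
    mixing = c(a$mixing, b$mixing),
    sources = list(
      AS = specA, AU = list(labeled_positions = integer(0), fraction = 0),
      BS = specB, BU = list(labeled_positions = integer(0), fraction = 0))
  )
  compile_model(spec)
}
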