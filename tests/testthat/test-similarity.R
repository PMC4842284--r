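test_that("alignment reproduces the worked examples", {
  al0 <- align_mid_vectors(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(al0$cost, 0)
  expect_equal(al0$gap_count, 0L)
  # one leading gap in a beats the gapless cost of 0.9
  al1 <- align_mid_vectors(c(0.5, 0.5), c(0, 0.5, 0.5))
  expect_equal(al1$cost, 0.4)
  expect_equal(al1$a_aligned, c(NA, 0.5, 0.5))
  # pure shift: a as (gap, 1, 0) against (0, 1, gap)
  al2 <- align_mid_vectors(c(1, 0), c(0, 1))
  expect_equal(al2$cost, 0.8)
  expect_equal(al2$a_aligned, c(NA, 1, 0))
  expect_equal(al2$b_aligned, c(0, 1, NA))
})

test_that("alignment cost equals exhaustive enumeration (200+ random pairs)", {
  set.seed(41)
  for (i in 1:200) {
    a <- random_mid(sample(1:5, 1))
    b <- random_mid(sample(1:5, 1))
    al <- align_mid_vectors(a, b)
    expect_equal(al$cost, brute_force_alignment_cost(a, b), tolerance = 1e-12)
    # removing gaps recovers the originals
    expect_equal(al$a_aligned[!is.na(al$a_aligned)], a)
    expect_equal(al$b_aligned[!is.na(al$b_aligned)], b)
  }
})

test_that("mid_distance satisfies the distance axioms", {
  set.seed(43)
  expect_equal(mid_distance(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)), 0)
  expect_equal(mid_distance(c(1, 0), c(0, 1)), 0)
  expect_equal(mid_distance(c(1, 0), c(0.5, 0.5)), 1.3333333 / 4,
               tolerance = 1e-6)
  for (i in 1:100) {
    a <- random_mid(sample(1:6, 1))
    b <- random_mid(sample(1:6, 1))
    d <- mid_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, mid_distance(b, a), tolerance = 1e-12)
    expect_equal(mid_distance(a, a), 0, tolerance = 1e-12)
    # pure shifts are free under the gap-as-zero convention
    expect_equal(mid_distance(a, c(0, a)), 0, tolerance = 1e-12)
  }
})

test_that("the drop-gap-terms convention is available and differs", {
  a <- c(0.6, 0.4); b <- c(0.1, 0.6, 0.3)
  expect_false(isTRUE(all.equal(mid_distance(a, b),
                                mid_distance(a, b, gap_terms = "drop"))))
})

test_that("pairwise_distances selects heaviest qualifying fragment", {
  set.seed(47)
  m1 <- c(0.5, 0.3, 0.2)
  rows <- list(
    mid_row("A", "t", 1, "x", 100, m1, r2 = 0.99),
    mid_row("A", "t", 1, "x", 200, c(0.4, 0.4, 0.2), r2 = 0.99),
    mid_row("A", "t", 1, "y", 150, m1, r2 = 0.99),
    # z's only fragment has r2 below the threshold -> excluded
    mid_row("A", "t", 1, "z", 180, m1, r2 = 0.90),
    mid_row("A", "t", 1, "w", 120, c(0.8, 0.1, 0.1), r2 = 0.99))
  dm <- pairwise_distances(toy_dataset(rows), "A", "t", min_r2 = 0.95)
  expect_setequal(dm$compound_ids, c("x", "y", "w"))
  expect_equal(dm$excluded, "z")
  expect_equal(unname(dm$fragment_mz[["x"]]), 200L)
  # matrix entries agree with direct mid_distance of the selected MIDs
  expect_equal(dm$distances["x", "y"],
               mid_distance(c(0.4, 0.4, 0.2), m1), tolerance = 1e-12)
  expect_equal(dm$distances["y", "w"],
               mid_distance(m1, c(0.8, 0.1, 0.1)), tolerance = 1e-12)
  expect_equal(diag(dm$distances), rep(0, 3), ignore_attr = TRUE)
  expect_equal(dm$distances, t(dm$distances))
})

test_that("similarity network applies the cutoff and overlays conditions", {
  mk <- function(cond, mids) {
    rows <- lapply(names(mids), function(id)
      mid_row(cond, "t", 1, id, 100, mids[[id]], r2 = 0.99))
    pairwise_distances(toy_dataset(rows), cond, "t")
  }
  mids1 <- list(a = c(0.5, 0.5), b = c(0.52, 0.48), c = c(0.9, 0.1))
  mids2 <- list(a = c(0.6, 0.4), b = c(0.61, 0.39), c = c(0.1, 0.9))
  m_glc <- mk("glc_cond", mids1)
  m_gln <- mk("gln_cond", mids2)
  cutoff <- 0.05
  net <- build_similarity_network(list(glc_cond = m_glc, gln_cond = m_gln),
                                  cutoff)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$source, "a")
  expect_equal(net$edges$target, "b")
  expect_equal(net$edges$conditions, "glc_cond;gln_cond")
  expect_lte(net$edges$distance, cutoff)
  # overlay edges are exactly the union of per-condition edge sets
  e1 <- build_similarity_network(list(glc_cond = m_glc), cutoff)$edges
  e2 <- build_similarity_network(list(gln_cond = m_gln), cutoff)$edges
  both <- unique(rbind(e1[, c("source", "target")],
                       e2[, c("source", "target")]))
  expect_equal(net$edges[, c("source", "target")], both)
  # all distances above cutoff -> empty network
  empty <- build_similarity_network(list(glc_cond = m_glc), cutoff = 1e-6)
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$nodes, 0L)
})

test_that("network exports write GraphML and edge-list TSV", {
  rows <- list(mid_row("A", "t", 1, "a", 100, c(0.5, 0.5)),
               mid_row("A", "t", 1, "b", 100, c(0.5, 0.5)),
               mid_row("A", "t", 1, "c", 100, c(0.9, 0.1)))
  dm <- pairwise_distances(toy_dataset(rows), "A", "t")
  net <- build_similarity_network(list(A = dm), cutoff = 0.01)
  gpath <- withr::local_tempfile(fileext = ".graphml")
  epath <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(net, gpath)
  write_network_edges(net, epath)
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::gsize(g), 1L)
  edges <- data.table::fread(epath)
  expect_equal(names(edges), c("source", "target", "distance", "conditions"))
  expect_equal(edges$distance, 0)
})

test_that("nearest_neighbors orders, deduplicates derivatives, and errors", {
  rows <- list(
    mid_row("A", "t", 1, "q", 100, c(0.5, 0.5)),
    mid_row("A", "t", 1, "twin", 100, c(0.5, 0.5)),
    mid_row("A", "t", 1, "glu2", 100, c(0.55, 0.45),
            compound_name = "glutamate"),
    mid_row("A", "t", 1, "glu3", 100, c(0.56, 0.44),
            compound_name = "glutamate"),
    mid_row("A", "t", 1, "far", 100, c(0.95, 0.05)))
  dm <- pairwise_distances(toy_dataset(rows), "A", "t")
  nn <- nearest_neighbors(dm, "q", k = 1)
  expect_equal(nn$compound_id, "twin")
  expect_equal(nn$distance, 0)
  all_nn <- nearest_neighbors(dm, "q", k = 10)
  expect_equal(sum(all_nn$compound_name == "glutamate", na.rm = TRUE), 1L)
  expect_true(all(diff(all_nn$distance) >= 0))
  expect_error(nearest_neighbors(dm, "nope"), "unknown compound")
})

test_that("pathway structure is recoverable from simulated MIDs", {
  model <- parallel_pathways_model()
  sim <- generate_dataset(model, conditions = list(base = list()),
                          noise_sd = 0.01, replicates = 3L, seed = 21L)
  dm <- pairwise_distances(sim$dataset, "base", "tracer1", min_r2 = 0.95)
  ids <- dm$compound_ids
  a_ids <- grep("^A", ids, value = TRUE)
  b_ids <- grep("^B", ids, value = TRUE)
  within <- c(dm$distances[a_ids, a_ids][upper.tri(diag(length(a_ids)))],
              dm$distances[b_ids, b_ids][upper.tri(diag(length(b_ids)))])
  between <- as.vector(dm$distances[a_ids, b_ids])
  expect_lt(mean(within), mean(between))
  # direct precursor appears in the top-3 neighbors along a linear pathway
  nn <- nearest_neighbors(dm, "A3", k = 3)
  expect_true("A2" %in% nn$compound_id)
})
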