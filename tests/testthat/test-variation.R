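test_that("variation_score matches direct formula evaluation", {
  expect_equal(variation_score(list(c(1, 0), c(1, 0), c(1, 0)))$score, 0)
  # population SD of {1, 0.9, 0.8} is sqrt(0.02 / 3) = 0.081650
  vs <- variation_score(list(c(1, 0), c(0.9, 0.1), c(0.8, 0.2)))
  expect_equal(vs$sigma, rep(sqrt(0.02 / 3), 2), tolerance = 1e-12)
  expect_equal(vs$score, sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(variation_score(list(c(1, 0), c(0, 1)))$score, 0.5)
  expect_error(variation_score(list(c(1, 0))), "at least two")
})

test_that("variation_score equals the independent oracle on random input", {
  set.seed(13)
  for (i in 1:50) {
    mids <- replicate(sample(2:6, 1), random_mid(sample(2:6, 1)),
                      simplify = FALSE)
    got <- variation_score(mids)
    want <- sigma_oracle(mids)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-12)
    # permutation invariance of the condition order
    perm <- sample(mids)
    expect_equal(variation_score(perm)$score, got$score, tolerance = 1e-12)
  }
})

test_that("score is zero iff all per-condition MIDs are identical", {
  set.seed(17)
  m <- random_mid(4)
  expect_lt(variation_score(list(m, m, m))$score, 1e-12)
  m2 <- m; m2[2] <- m2[2] + 1e-6; m2[1] <- m2[1] - 1e-6
  expect_gt(variation_score(list(m, m2, m))$score, 1e-12)
})

test_that("heaviest_common_fragment follows the rule set", {
  cm <- function(cond, mz, r2 = 0.99) data.table::data.table(
    condition = cond, compound_id = "x", fragment_mz = as.integer(mz),
    r2 = r2, mid = list(c(0.5, 0.5)))
  # 245 in all five conditions, 304 only in four -> 245
  tab <- data.table::rbindlist(c(
    lapply(paste0("c", 1:5), cm, mz = 245),
    lapply(paste0("c", 1:4), cm, mz = 304)))
  expect_equal(heaviest_common_fragment(tab), 245L)
  # both everywhere -> the heavier wins
  tab2 <- data.table::rbindlist(c(
    lapply(paste0("c", 1:5), cm, mz = 245),
    lapply(paste0("c", 1:5), cm, mz = 304)))
  expect_equal(heaviest_common_fragment(tab2), 304L)
  # disjoint fragments per condition -> none
  tab3 <- data.table::rbindlist(list(cm("c1", 245), cm("c2", 304)))
  expect_true(is.na(heaviest_common_fragment(tab3)))
  # an unqualifying r2 removes a fragment from consideration
  tab4 <- data.table::rbindlist(c(
    lapply(paste0("c", 1:5), cm, mz = 245),
    lapply(paste0("c", 1:4), cm, mz = 304),
    list(cm("c5", 304, r2 = 0.5))))
  expect_equal(heaviest_common_fragment(tab4, min_r2 = 0.95), 245L)
})

test_that("identical conditions give all-zero scores ordered by compound id", {
  set.seed(23)
  mids <- list(b = random_mid(3), a = random_mid(3), c = random_mid(3))
  rows <- list()
  for (id in names(mids)) for (cond in paste0("c", 1:3)) {
    rows[[length(rows) + 1L]] <- mid_row(cond, "t", 1, id, 100, mids[[id]])
  }
  rk <- rank_by_variation(toy_dataset(rows), "t", min_conditions = 3,
                          top_k = Inf, min_enrichment = 0)
  expect_equal(rk$score, rep(0, 3), tolerance = 1e-12)
  expect_equal(rk$compound_id, c("a", "b", "c"))
})

test_that("compounds below the condition minimum or unlabeled are excluded", {
  rows <- list()
  for (cond in paste0("c", 1:5)) {
    rows[[length(rows) + 1L]] <- mid_row(cond, "t", 1, "always", 100,
                                         c(0.6, 0.4))
    rows[[length(rows) + 1L]] <- mid_row(cond, "t", 1, "unlab", 100,
                                         c(0.99, 0.01))
  }
  for (cond in paste0("c", 1:2)) {
    rows[[length(rows) + 1L]] <- mid_row(cond, "t", 1, "rare", 100,
                                         c(0.5, 0.5))
  }
  rk <- rank_by_variation(toy_dataset(rows), "t", min_conditions = 3,
                          top_k = Inf)
  expect_equal(rk$compound_id, "always")
  excl <- attr(rk, "excluded")
  expect_equal(excl$rare, "too_few_conditions")
  expect_equal(excl$unlab, "unlabeled")
})

test_that("only the best-scoring derivative of a named metabolite is kept", {
  set.seed(29)
  rows <- list()
  for (cond in paste0("c", 1:3)) {
    shift <- switch(cond, c1 = 0, c2 = 0.1, c3 = 0.2)
    rows[[length(rows) + 1L]] <- mid_row(
      cond, "t", 1, "glu_2tms", 100, c(0.6 - shift, 0.4 + shift),
      compound_name = "glutamate", derivative = "2TMS")
    rows[[length(rows) + 1L]] <- mid_row(
      cond, "t", 1, "glu_3tms", 100, c(0.6 - shift / 2, 0.4 + shift / 2),
      compound_name = "glutamate", derivative = "3TMS")
    rows[[length(rows) + 1L]] <- mid_row(
      cond, "t", 1, sprintf("unk%s", cond), 100, c(0.5, 0.5))
    rows[[length(rows) + 1L]] <- mid_row(
      cond, "t", 1, "unknown_a", 100, c(0.7 - shift, 0.3 + shift))
    rows[[length(rows) + 1L]] <- mid_row(
      cond, "t", 1, "unknown_b", 100, c(0.7 - shift, 0.3 + shift))
  }
  rk <- rank_by_variation(toy_dataset(rows), "t", min_conditions = 3,
                          top_k = Inf)
  expect_equal(sum(rk$compound_name == "glutamate", na.rm = TRUE), 1L)
  expect_equal(rk$compound_id[rk$compound_name == "glutamate" &
                                !is.na(rk$compound_name)], "glu_2tms")
  # unnamed compounds are never merged
  expect_true(all(c("unknown_a", "unknown_b") %in% rk$compound_id))
})

test_that("a swept mixing node ranks first and responds monotonically", {
  em <- example_model()
  base <- 0.9
  deltas <- c(0, 0.1, 0.2, 0.4)
  scores <- vapply(deltas, function(d) {
    conds <- list(base = list(ACA = c(pdh = base, ac_exchange = 1 - base)),
                  pert = list(ACA = c(pdh = base - d,
                                      ac_exchange = 1 - base + d)))
    sim <- generate_dataset(em$model, conditions = conds,
                            tracers = em$tracers["glc12"], noise_sd = 0,
                            replicates = 1L, seed = 4L)
    rk <- rank_by_variation(sim$dataset, "glc12", min_conditions = 2,
                            top_k = Inf)
    rk$score[rk$compound_id == "ACA"]
  }, numeric(1))
  expect_equal(scores[[1L]], 0, tolerance = 1e-12)
  expect_true(all(diff(scores) > 0))
  # full five-condition sweep: the product of the perturbed node ranks first
  sim <- generate_dataset(em$model, conditions = pdh_sweep_conditions(),
                          tracers = em$tracers["glc12"], noise_sd = 0.01,
                          replicates = 3L, seed = 9L)
  rk <- rank_by_variation(filter_dataset(sim$dataset)$dataset, "glc12",
                          min_conditions = 3, top_k = 5)
  expect_equal(rk$compound_id[[1L]], "ACA")
})
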