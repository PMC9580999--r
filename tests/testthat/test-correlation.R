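make_pair_df <- function(a, b) data.frame(protein_a = a, protein_b = b,
                                          stringsAsFactors = FALSE)

test_that("Spearman handles monotone, antitone and tied inputs", {
  v <- rbind(X = c(1, 2, 3, 4), Y = c(2, 4, 6, 8),
             Z = c(8, 6, 4, 2), W = c(1, 1, 3, 4))
  colnames(v) <- paste0("T0", 1:4)
  m <- abundance_matrix(v, rep("tumor", 4))
  pairs <- make_pair_df(c("X", "X", "X"), c("Y", "Z", "W"))
  corr <- pairwise_spearman(m, pairs, min_n = 3)
  rho <- setNames(corr$rho, corr$pair)
  expect_equal(unname(rho[pair_key("X", "Y")]), 1)
  expect_equal(unname(rho[pair_key("X", "Z")]), -1)
  # tie-corrected value: Pearson on mid-ranks [1,2,3,4] vs [1.5,1.5,3,4]
  expect_equal(unname(rho[pair_key("X", "W")]), 0.9486833,
               tolerance = 1e-6)
  expect_equal(unname(rho[pair_key("X", "W")]),
               oracle_spearman(c(1, 2, 3, 4), c(1, 1, 3, 4)))
})

test_that("Spearman equals Pearson on mid-ranks for random tied vectors", {
  set.seed(202)
  v <- matrix(sample(1:8, 400, replace = TRUE), 2, 200,
              dimnames = list(c("A", "B"), sprintf("T%03d", 1:200)))
  m <- abundance_matrix(v, rep("tumor", 200))
  for (i in 1:25) {
    idx <- sample(200, 30)
    sub <- abundance_matrix(v[, idx, drop = FALSE], rep("tumor", 30))
    got <- pairwise_spearman(sub, make_pair_df("A", "B"), min_n = 5)$rho
    expect_equal(got, oracle_spearman(v["A", idx], v["B", idx]),
                 tolerance = 1e-12)
  }
})

test_that("pair symmetry and monotone-transform invariance hold", {
  set.seed(11)
  v <- matrix(rnorm(60), 3, 20,
              dimnames = list(c("A", "B", "C"), sprintf("T%02d", 1:20)))
  m <- abundance_matrix(v, rep("tumor", 20))
  ab <- pairwise_spearman(m, make_pair_df("A", "B"), min_n = 5)$rho
  ba <- pairwise_spearman(m, make_pair_df("B", "A"), min_n = 5)$rho
  expect_identical(ab, ba)
  v2 <- v; v2["A", ] <- exp(v["A", ])  # strictly monotone transform
  m2 <- abundance_matrix(v2, rep("tumor", 20))
  expect_equal(pairwise_spearman(m2, make_pair_df("A", "B"), min_n = 5)$rho,
               ab)
})

test_that("pairs below min_n complete observations are omitted and counted", {
  v <- matrix(rnorm(40), 2, 20,
              dimnames = list(c("A", "B"), sprintf("T%02d", 1:20)))
  v["A", 1:15] <- NA
  m <- abundance_matrix(v, rep("tumor", 20))
  corr <- pairwise_spearman(m, make_pair_df("A", "B"), min_n = 10)
  expect_identical(nrow(corr), 0L)
  expect_identical(attr(corr, "n_omitted"), 1L)
  expect_error(pairwise_spearman(m, make_pair_df(character(0),
                                                 character(0))),
               "empty pair list")
})

test_that("pooling keeps one observation per pair and cohort", {
  t1 <- data.frame(pair = c("A|B", "C|D"), rho = c(0.5, 0.1))
  t2 <- data.frame(pair = c("A|B"), rho = c(0.7))
  t3 <- data.frame(pair = c("A|B", "C|D"), rho = c(0.6, 0.2))
  class(t1) <- class(t2) <- class(t3) <- c("CorrelationTable", "data.frame")
  groups <- data.frame(pair = c("A|B", "C|D"),
                       group = c("same_complex", "different_complex"))
  pooled <- pool_across_cohorts(list(t1, t2, t3), groups)
  expect_identical(sort(pooled$same_complex), c(0.5, 0.6, 0.7))
  expect_identical(sort(pooled$different_complex), c(0.1, 0.2))
  expect_identical(sum(lengths(pooled)), nrow(t1) + nrow(t2) + nrow(t3))
  # single cohort: pooled distribution equals the cohort's values
  single <- pool_across_cohorts(t1, groups)
  expect_identical(single$same_complex, 0.5)
})

test_that("group comparison separates distinct distributions", {
  sep <- compare_correlation_groups(rep(0.6, 50), rep(0, 50),
                                    "same", "diff")
  expect_lt(sep$p, 1e-15)
  expect_identical(sep$direction, "same > diff")
  same <- compare_correlation_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_error(compare_correlation_groups(numeric(0), 1), "non-empty")
})

test_that("catalog pair groups label shared-complex pairs", {
  catalog <- complex_catalog(list(C1 = c("A", "B", "C"), C2 = c("C", "D")))
  groups <- catalog_pair_groups(catalog)
  lab <- setNames(groups$group, groups$pair)
  expect_identical(unname(lab[pair_key("A", "B")]), "same_complex")
  expect_identical(unname(lab[pair_key("C", "D")]), "same_complex")
  expect_identical(unname(lab[pair_key("A", "D")]), "different_complex")
  # pairs in several complexes appear exactly once
  expect_false(anyDuplicated(groups$pair) > 0)
  # restriction to quantified proteins
  g2 <- catalog_pair_groups(catalog, proteins = c("A", "B", "C"))
  expect_false(any(grepl("D", g2$pair)))
})
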