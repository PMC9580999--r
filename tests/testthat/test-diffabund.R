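test_that("small-sample rank-sum p-values match exhaustive enumeration", {
  # the canonical extreme case: complete separation of 3 vs 3
  v <- matrix(c(5, 6, 7, 1, 2, 3,
                1, 5, 2, 4, 3, 6), nrow = 2, byrow = TRUE)
  m <- make_toy_matrix(v, 3, 3)
  res <- test_differential_abundance(m)
  expect_equal(res$p[1], 0.1)
  expect_equal(res$p[1], oracle_ranksum_p(c(5, 6, 7), c(1, 2, 3)))
  # randomized cases, group sizes <= 6, unique values so the exact path runs
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    vals <- sample(seq_len(50), n1 + n2)
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    mm <- make_toy_matrix(matrix(c(x, y, x, y), nrow = 2, byrow = TRUE),
                          n1, n2)
    got <- test_differential_abundance(mm)$p[1]
    expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("log2fc is the difference of group medians", {
  v <- matrix(c(6, 7, 8, 2, 3, 4), nrow = 1)
  m <- make_toy_matrix(v, 3, 3)
  expect_equal(test_differential_abundance(m)$log2fc, 4)
})

test_that("identical groups give p = 1 and an unchanged call", {
  v <- matrix(rep(c(1, 2, 3), 2), nrow = 1)
  m <- make_toy_matrix(v, 3, 3)
  res <- test_differential_abundance(m)
  expect_equal(res$p, 1)
  expect_identical(res$call, "unchanged")
})

test_that("Bonferroni uses the tested-protein count and skips the rest", {
  set.seed(1)
  v <- matrix(rnorm(50), 5, 10)
  v[5, 1:4] <- NA  # only 1 tumor value left -> skipped
  m <- make_toy_matrix(v, 5, 5)
  res <- test_differential_abundance(m, min_per_group = 3)
  expect_identical(attr(res, "skipped"), "G05")
  expect_identical(attr(res, "n_tested"), 4L)
  expect_equal(res$p_adj, pmin(1, res$p * 4))
  expect_true(all(res$p_adj >= res$p))
})

test_that("calls use a strict fold-change and inclusive p threshold", {
  res <- structure(
    data.frame(protein = c("A", "B", "C"),
               log2fc = c(1.0, 1.5, -2),
               p = c(1e-4, 1e-3, 1e-5),
               p_adj = c(0.01, 0.05, 0.001),
               n_tumor_used = 5L, n_normal_used = 5L),
    class = c("DifferentialResult", "data.frame"))
  out <- call_differential(res)
  expect_identical(out$call, c("unchanged", "up", "down"))
  expect_error(call_differential(res, lfc_threshold = 0), "positive")
})

test_that("the paired signed-rank switch uses the pairing map", {
  v <- matrix(c(5, 7, 9, 12, 1, 2, 3, 4), nrow = 1)
  colnames(v) <- c(paste0("T0", 1:4), paste0("N0", 1:4))
  rownames(v) <- "G01"
  m <- abundance_matrix(v, rep(c("tumor", "normal"), each = 4),
                        pairing = setNames(paste0("N0", 1:4),
                                           paste0("T0", 1:4)))
  res <- test_differential_abundance(m, paired = TRUE)
  # all 4 differences positive and distinct: exact two-sided
  # signed-rank p = 2/16
  expect_equal(res$p, 0.125)
  no_pairing <- abundance_matrix(v, rep(c("tumor", "normal"), each = 4))
  expect_error(test_differential_abundance(no_pairing, paired = TRUE),
               "pairing")
})

test_that("dispersion comparison detects shifted SDs and degenerate ties", {
  # constant tumor values -> zero tumor SDs
  v <- cbind(matrix(5, 3, 4), matrix(rnorm(12), 3, 4))
  m <- make_toy_matrix(v, 4, 4)
  d <- compare_dispersion(m)
  expect_equal(d$mean_sd_tumor, 0)
  # planted SD shift across 500 proteins
  set.seed(33)
  n <- 500
  tum <- matrix(rnorm(n * 10, sd = rep(runif(n, 2, 3), 10)), n, 10)
  nor <- matrix(rnorm(n * 10, sd = rep(runif(n, 1, 2), 10)), n, 10)
  m2 <- make_toy_matrix(cbind(tum, nor), 10, 10)
  d2 <- compare_dispersion(m2)
  expect_lt(d2$p, 1e-10)
  expect_gt(d2$mean_sd_tumor, d2$mean_sd_normal)
  # identical matrices in both groups: statistic 0, p = 1
  same <- matrix(rnorm(30), 3, 10)
  m3 <- make_toy_matrix(cbind(same, same), 10, 10)
  d3 <- compare_dispersion(m3)
  expect_equal(d3$statistic, 0)
  expect_equal(d3$p, 1)
})
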