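make_universe <- function(n) sprintf("U%04d", seq_len(n))

test_that("the chi-square statistic matches the hand formula", {
  # rows member/non-member, cols DA/notDA: [[10,90],[30,70]]
  universe <- make_universe(200)
  members <- universe[1:100]
  da <- c(universe[1:10], universe[101:130])
  res <- association_test(da, members, universe)
  expect_identical(res$table["member", "da"], 10L)
  expect_identical(res$table["non_member", "da"], 30L)
  expect_equal(res$statistic, 12.5)
  expect_equal(res$statistic, oracle_chisq_stat(res$table))
  expect_equal(res$p, stats::pchisq(12.5, 1, lower.tail = FALSE))
  expect_identical(res$direction, "depleted")
  # random tables agree with the oracle too
  set.seed(55)
  for (i in 1:10) {
    da_i <- sample(universe, sample(40:120, 1))
    res_i <- association_test(da_i, members, universe)
    expect_equal(res_i$statistic, oracle_chisq_stat(res_i$table),
                 tolerance = 1e-12)
  }
})

test_that("zero margins are hard errors and Yates shrinks the statistic", {
  universe <- make_universe(100)
  members <- universe[1:40]
  expect_error(association_test(character(0), members, universe), "margin")
  expect_error(association_test(universe[1:5], universe, universe), "margin")
  res <- association_test(universe[1:20], members, universe)
  res_y <- association_test(universe[1:20], members, universe, yates = TRUE)
  expect_lt(res_y$statistic, res$statistic)
})

test_that("direction follows the sign of observed minus expected", {
  universe <- make_universe(100)
  members <- universe[1:50]
  enriched <- association_test(universe[1:20], members, universe)
  expect_identical(enriched$direction, "enriched")
  depleted <- association_test(universe[51:70], members, universe)
  expect_identical(depleted$direction, "depleted")
})

test_that("matched background preserves the abundance-bin histogram", {
  set.seed(12)
  universe <- make_universe(500)
  abundance <- setNames(rnorm(500, 20, 3), universe)
  members <- sample(universe, 120)
  bg <- build_matched_background(members, universe, abundance,
                                 n_bins = 10, seed = 4)
  expect_length(bg, length(members))
  expect_length(intersect(bg, members), 0)
  bins <- attr(bg, "bins")
  expect_identical(table(bins[members]), table(bins[bg]))
  # abundance distributions of members and background are close (KS)
  ks <- suppressWarnings(stats::ks.test(abundance[members], abundance[bg]))
  expect_gt(ks$p.value, 0.01)
})

test_that("matched background honors degenerate binning cases", {
  universe <- make_universe(100)
  # identical abundance everywhere: a single bin, draw from non-members
  flat <- setNames(rep(1, 100), universe)
  bg <- build_matched_background(universe[1:30], universe, flat, seed = 2)
  expect_length(bg, 30)
  expect_length(intersect(bg, universe[1:30]), 0)
  # members concentrated in the top of the distribution stay there
  abundance <- setNames(seq_len(100), universe)
  top_members <- universe[91:95]
  bg_top <- build_matched_background(top_members, universe, abundance,
                                     n_bins = 10, seed = 3)
  expect_true(all(abundance[bg_top] > 90))
  # a bin with more members than non-members is an error naming the bin
  expect_error(build_matched_background(universe[91:100], universe,
                                        abundance, n_bins = 10, seed = 1),
               "bin")
})

test_that("the matched association test restricts to members plus background", {
  set.seed(9)
  universe <- make_universe(400)
  abundance <- setNames(rnorm(400, 20, 2), universe)
  members <- sample(universe, 100)
  da <- sample(universe, 60)
  res <- matched_association_test(da, members, universe, abundance,
                                  seed = 7)
  expect_identical(res$background_kind, "abundance_matched")
  expect_identical(sum(res$table), 200L)
  rep_res <- matched_association_test(da, members, universe, abundance,
                                      seed = 7, replicates = 5)
  expect_length(attr(rep_res, "replicate_p"), 5)
})

test_that("directional association reports untestable directions", {
  res <- structure(
    data.frame(protein = make_universe(100),
               log2fc = c(rep(-3, 20), rep(0, 80)),
               p = 1e-6, p_adj = c(rep(1e-4, 20), rep(1, 80)),
               n_tumor_used = 5L, n_normal_used = 5L),
    class = c("DifferentialResult", "data.frame"))
  res <- call_differential(res)
  out <- directional_association(res, make_universe(100)[1:50],
                                 make_universe(100))
  expect_s3_class(out$down, "AssociationResult")
  expect_s3_class(out$up, "NotTestable")
})

test_that("a planted membership depletion is detected as depleted", {
  set.seed(77)
  universe <- make_universe(2000)
  members <- universe[1:400]
  hits <- 0
  for (i in 1:50) {
    da <- draw_da_weighted(universe, members, 200, 0.5)
    res <- association_test(da, members, universe)
    if (res$p <= 0.05 && res$direction == "depleted") hits <- hits + 1
  }
  expect_gt(hits / 50, 0.8)
})
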