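test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 300, n_complexes = 10, seed = 11)
  a <- generate_complex_catalog(cfg)
  b <- generate_complex_catalog(cfg)
  expect_identical(a, b)
  ca <- generate_cohort(a$catalog, cfg)
  cb <- generate_cohort(b$catalog, cfg)
  expect_identical(ca$matrix$values, cb$matrix$values)
  sa <- generate_structural_stoichiometry(a$catalog, cfg)
  sb <- generate_structural_stoichiometry(a$catalog, cfg)
  expect_identical(sa, sb)
  ia <- generate_interactome(a$catalog, cfg)
  ib <- generate_interactome(a$catalog, cfg)
  expect_identical(ia$interactions$pair, ib$interactions$pair)
  expect_identical(ia$truth, ib$truth)
})

test_that("catalog generation respects size and overlap settings", {
  cfg <- sim_config(n_proteins = 1000, n_complexes = 30,
                    complex_size_range = c(3, 6),
                    complex_membership_overlap_prob = 0, seed = 3)
  res <- generate_complex_catalog(cfg)
  expect_length(res$catalog, 30)
  expect_true(all(lengths(res$catalog) >= 3 & lengths(res$catalog) <= 6))
  # no overlap: every protein in at most one complex, so all co-occurrence
  # Jaccards are 1
  expect_lte(max(table(unlist(res$catalog))), 1L)
  jac <- cooccurrence_jaccard(res$catalog)
  expect_true(all(jac$jaccard == 1))
  # with overlap, shared membership produces Jaccards strictly below 1
  cfg2 <- sim_config(n_proteins = 1000, n_complexes = 30,
                     complex_membership_overlap_prob = 0.3, seed = 3)
  jac2 <- cooccurrence_jaccard(generate_complex_catalog(cfg2)$catalog)
  expect_true(any(jac2$jaccard < 1))
  expect_error(
    generate_complex_catalog(sim_config(n_proteins = 20,
                                        frac_complex_proteins = 0.2,
                                        complex_size_range = c(3, 6),
                                        seed = 1)),
    "pool")
})

test_that("differential planting follows the selection model", {
  cfg <- sim_config(n_proteins = 1000, n_complexes = 10,
                    frac_differential = 0.1, depletion_odds_ratio = 1,
                    missing_rate = 0, seed = 5)
  cat0 <- generate_complex_catalog(cfg)
  coh <- generate_cohort(cat0$catalog, cfg)
  n_da <- sum(coh$truth$is_differential)
  # Binomial(1000, 0.1): bounds at +-1e-6 tail
  expect_gte(n_da, qbinom(1e-6, 1000, 0.1))
  expect_lte(n_da, qbinom(1 - 1e-6, 1000, 0.1))
  expect_false(anyNA(coh$matrix$values))
  expect_true(all(abs(coh$truth$planted_lfc[coh$truth$is_differential]) > 0))
  # ~90% of planted effects point down by default
  expect_gt(mean(coh$truth$direction[coh$truth$is_differential] == -1), 0.8)
  audit_ground_truth(cat0$catalog, coh)
})

test_that("missingness rate is honored", {
  cfg <- sim_config(n_proteins = 500, n_complexes = 10,
                    missing_rate = 0.1, seed = 9)
  coh <- generate_cohort(generate_complex_catalog(cfg)$catalog, cfg)
  rate <- mean(is.na(coh$matrix$values))
  expect_gt(rate, 0.08); expect_lt(rate, 0.12)
})

test_that("realized within-complex Spearman tracks the target", {
  # overlap 0 isolates the one-factor-per-complex calibration; proteins
  # shared between complexes deliberately split their loading and dilute
  # pair correlations
  cfg <- sim_config(n_proteins = 600, n_complexes = 30,
                    complex_size_range = c(4, 4), n_tumor = 100,
                    n_normal = 3, within_complex_rho = 0.6,
                    complex_membership_overlap_prob = 0,
                    frac_differential = 0, seed = 21)
  cat0 <- generate_complex_catalog(cfg)
  coh <- generate_cohort(cat0$catalog, cfg)
  groups <- catalog_pair_groups(cat0$catalog, max_different = 0)
  corr <- pairwise_spearman(coh$matrix, groups, min_n = 10)
  expect_gt(nrow(corr), 100)
  expect_lt(abs(mean(corr$rho) - 0.6), 0.05)
})

test_that("infeasible correlation targets are rejected", {
  cfg <- sim_config(n_proteins = 300, n_complexes = 10,
                    within_complex_rho = 0.9, baseline_rho = 0.5, seed = 2)
  cat0 <- generate_complex_catalog(cfg)
  expect_error(generate_cohort(cat0$catalog, cfg), "infeasible")
})

test_that("stoichiometry generator controls parity and conflicts", {
  cfg_even <- sim_config(n_proteins = 500, n_complexes = 40,
                         frac_even_pairs = 1, parity_conflict_frac = 0,
                         seed = 13)
  cat0 <- generate_complex_catalog(cfg_even)
  sto <- generate_structural_stoichiometry(cat0$catalog, cfg_even)
  parity <- classify_stoichiometric_parity(sto$table)
  expect_true(all(parity$parity == "even"))
  # conflict fraction ~0.2 of complexes -> a matching share of mixed pairs
  cfg_mix <- sim_config(n_proteins = 2000, n_complexes = 100,
                        frac_even_pairs = 0.5, parity_conflict_frac = 0.2,
                        seed = 13)
  cat1 <- generate_complex_catalog(cfg_mix)
  sto1 <- generate_structural_stoichiometry(cat1$catalog, cfg_mix)
  mixed_frac <- mean(sto1$truth$parity == "mixed")
  expect_gt(mixed_frac, 0.10); expect_lt(mixed_frac, 0.32)
  audit_ground_truth(cat1$catalog,
                     generate_cohort(cat1$catalog, cfg_mix), sto1)
})

test_that("interactome planting pins the downstream class boundaries", {
  cfg <- sim_config(n_proteins = 600, n_complexes = 25,
                    detect_both_prob = 1, competitive_frac = 0.5,
                    interface_overlap = 0.5, seed = 17)
  cat0 <- generate_complex_catalog(cfg)
  res <- generate_interactome(cat0$catalog, cfg)
  # detection prob both = 1: every bait-in-both interaction is general
  ctx <- classify_context(res$interactions)
  truth_ctx <- res$truth$context
  expect_true(all(ctx$context[truth_ctx$label == "general"] == "general"))
  expect_false(any(ctx$context == "context_specific"))
  # planted competitive triples have Jaccard >= 0.1, cooperative are disjoint
  tc <- res$truth$competition
  expect_true(all(tc$jaccard[tc$label == "competitive"] >= 0.1))
  expect_true(all(tc$jaccard[tc$label == "cooperative"] == 0))
  # classifier recovers every planted label
  comp <- classify_competition(res$interactions, threshold = 0.1)
  m <- merge(comp, tc, by = "pair")
  expect_gt(nrow(m), 20)
  expect_identical(m$competition, m$label)
})

test_that("the seed is mandatory and probabilities validated", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(frac_differential = 1.5, seed = 1), "probabilities")
  expect_error(sim_config(n_tumor = 2, seed = 1), ">= 3")
})
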