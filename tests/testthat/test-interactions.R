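test_that("stoichiometric parity follows chain-count equality per structure", {
  st <- stoichiometry_table(
    structure_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S4", "S4"),
    protein = c("A", "B", "C", "D", "E", "F", "E", "F"),
    chain_count = c(2, 2, 3, 1, 1, 1, 2, 1))
  parity <- classify_stoichiometric_parity(st)
  lab <- setNames(parity$parity, parity$pair)
  expect_identical(unname(lab[pair_key("A", "B")]), "even")    # 2:2
  expect_identical(unname(lab[pair_key("C", "D")]), "uneven")  # 3:1
  expect_identical(unname(lab[pair_key("E", "F")]), "mixed")   # 1:1 then 2:1
  expect_identical(parity$n_structures[parity$pair == pair_key("E", "F")],
                   2L)
})

test_that("co-occurrence Jaccard counts shared and total complexes", {
  catalog <- complex_catalog(list(
    c1 = c("A", "X1"), c2 = c("A", "B"), c3 = c("A", "B"),
    c4 = c("B", "X2"), c5 = c("Y", "Z")))
  jac <- cooccurrence_jaccard(catalog)
  j <- setNames(jac$jaccard, jac$pair)
  # A in {c1,c2,c3}, B in {c2,c3,c4}: 2 shared of 4 total
  expect_equal(unname(j[pair_key("A", "B")]), 0.5)
  # Y and Z co-occur in exactly one complex, their only one
  expect_equal(unname(j[pair_key("Y", "Z")]), 1)
  # pairs never found together are not emitted
  expect_false(pair_key("A", "Y") %in% jac$pair)
})

test_that("co-occurrence Jaccard matches a brute-force recount", {
  cfg <- sim_config(n_proteins = 2000, n_complexes = 200,
                    complex_membership_overlap_prob = 0.3, seed = 8)
  catalog <- generate_complex_catalog(cfg)$catalog
  jac <- cooccurrence_jaccard(catalog)
  prot2cx <- lapply(setNames(nm = catalog_proteins(catalog)), function(p)
    names(catalog)[vapply(catalog, function(mem) p %in% mem, logical(1))])
  for (i in sample(nrow(jac), 200)) {
    parts <- split_pair_key(jac$pair[i])
    expect_equal(jac$jaccard[i],
                 oracle_set_jaccard(prot2cx[[parts$protein_a]],
                                    prot2cx[[parts$protein_b]]))
  }
})

test_that("context classification needs the bait in both cell lines", {
  ix <- interaction_set(
    c("A", "C", "E"), c("B", "D", "F"),
    cell_lines_detected = list(c("293T", "HCT116"), "293T", "293T"),
    bait_cell_lines = list(c("293T", "HCT116"), c("293T", "HCT116"),
                           "293T"))
  ctx <- classify_context(ix)
  lab <- setNames(ctx$context, ctx$pair)
  expect_identical(unname(lab[pair_key("A", "B")]), "general")
  expect_identical(unname(lab[pair_key("C", "D")]), "context_specific")
  expect_identical(unname(lab[pair_key("E", "F")]), "unknown")
})

test_that("interface Jaccard follows set arithmetic with empty-set rules", {
  expect_equal(interface_jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(interface_jaccard(1:5, 1:5), 1)
  expect_equal(interface_jaccard(1:3, 4:6), 0)
  expect_equal(interface_jaccard(integer(0), 1:3), 0)
  expect_error(interface_jaccard(integer(0), integer(0)), "undefined")
  set.seed(61)
  for (i in 1:50) {
    a <- sample(1:40, sample(1:15, 1))
    b <- sample(1:40, sample(1:15, 1))
    expect_equal(interface_jaccard(a, b), oracle_set_jaccard(a, b))
  }
})

competition_fixture <- function() {
  # A and B share partners C (overlap 0.05) and D (overlap 0.3); E's
  # interaction with C lacks interface data on the C side and is filtered.
  interaction_set(
    protein_a = c("A", "B", "A", "B", "C"),
    protein_b = c("C", "C", "D", "D", "E"),
    interface_a = list(1:8, 1:8, 1:8, 1:8, 1:8),
    interface_b = list(1:10, c(10L, 11:20), 1:6, c(4:10), NA_integer_))
}

test_that("competition takes the best common partner and the 0.1 boundary", {
  comp <- classify_competition(competition_fixture(), threshold = 0.1)
  row <- comp[comp$pair == pair_key("A", "B"), ]
  expect_equal(row$competition_jaccard, 0.3)  # max(0.05, 0.3)
  expect_identical(row$best_partner, "D")
  expect_identical(row$competition, "competitive")
  # E never appears: its interface data is one-sided
  expect_false(any(grepl("E", comp$pair)))
  # a score of exactly the threshold is competitive (inclusive rule)
  ix <- interaction_set(c("A", "B"), c("C", "C"),
                        interface_a = list(1:5, 1:5),
                        interface_b = list(1:5, c(5L, 6:10)))
  at_boundary <- classify_competition(ix, threshold = 0.1)
  expect_equal(at_boundary$competition_jaccard, 0.1)
  expect_identical(at_boundary$competition, "competitive")
  # disjoint sites on the only partner: cooperative
  ix2 <- interaction_set(c("A", "B"), c("C", "C"),
                         interface_a = list(1:5, 1:5),
                         interface_b = list(1:5, 6:10))
  expect_identical(classify_competition(ix2)$competition, "cooperative")
})

test_that("competition classification is invariant to row order", {
  ix <- competition_fixture()
  perm <- ix[c(4, 1, 5, 3, 2), ]
  class(perm) <- class(ix)
  attr(perm, "cell_lines") <- attr(ix, "cell_lines")
  a <- classify_competition(ix)
  b <- classify_competition(perm)
  a <- a[order(a$pair), ]; b <- b[order(b$pair), ]
  expect_equal(a$competition_jaccard, b$competition_jaccard)
  expect_identical(a$competition, b$competition)
})

test_that("stability curation keeps human heterodimers and flags conflicts", {
  t1 <- data.frame(protein_a = c("A", "C", "E", "G"),
                   protein_b = c("B", "D", "F", "H"),
                   stability_label = c("transient", "permanent",
                                       "transient", "transient"),
                   species = c("human", "human", "yeast", "human"),
                   composition = c("heterodimer", "heterodimer",
                                   "heterodimer", "homodimer"))
  t2 <- data.frame(protein_a = c("B", "C"), protein_b = c("A", "D"),
                   stability_label = c("transient", "transient"),
                   species = "human", composition = "heterodimer")
  expect_warning(out <- curate_stability_labels(list(t1, t2)),
                 "conflicting")
  lab <- setNames(out$stability, out$pair)
  expect_identical(unname(lab[pair_key("A", "B")]), "transient")  # dedup
  expect_identical(unname(lab[pair_key("C", "D")]), "unknown")    # conflict
  expect_false(pair_key("E", "F") %in% out$pair)  # non-human dropped
  expect_false(pair_key("G", "H") %in% out$pair)  # homodimer dropped
})

test_that("pair annotation merges the five classes with unknown defaults", {
  ann <- annotate_pairs(
    parity = data.frame(pair = "A|B", parity = "even"),
    cooccurrence = data.frame(pair = c("A|B", "C|D"),
                              jaccard = c(0.5, 1)),
    stability = data.frame(pair = "C|D", stability = "permanent"))
  expect_identical(nrow(ann), 2L)
  ab <- ann[ann$pair == "A|B", ]
  expect_identical(ab$stoich_parity, "even")
  expect_identical(ab$stability, "unknown")
  expect_identical(ab$context, "unknown")
  cd <- ann[ann$pair == "C|D", ]
  expect_identical(cd$stoich_parity, "unknown")
  expect_identical(cd$stability, "permanent")
  expect_true(is.na(cd$competition_jaccard))
})
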