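## Synthetic cohort generator. Emits every input the pipeline consumes --
## paired tumor/normal abundances with planted within-complex co-regulation
## and planted differential effects, a complex catalog with overlapping
## membership, chain-count tables with controllable parity, an interactome
## with interface residues, detection flags and stability labels -- together
## with the ground truth, so each downstream stage has a recovery test.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with validated
#' defaults. Defaults describe a mid-sized tumor proteomics study: 2,000
#' quantified proteins of which a fifth sit in 50 complexes of size 3-6,
#' 30 tumor / 30 matched normal samples, a within-complex Spearman target of
#' 0.6 against an uncorrelated background, 10% differentially abundant
#' proteins with membership-depleted selection (odds ratio 0.5), planted
#' |log2 fold changes| around 2 of which 90% are down-regulated, and unit
#' between-sample noise on the log2 scale.
#'
#' @param n_proteins Number of quantified proteins.
#' @param n_complexes Number of complexes in the catalog.
#' @param complex_size_range Integer vector `c(min, max)` of complex sizes.
#' @param complex_membership_overlap_prob Probability that a member slot is
#'   filled by a protein already used in another complex (creates shared
#'   subunits, so co-occurrence Jaccard spans (0, 1]).
#' @param frac_complex_proteins Fraction of proteins eligible for complex
#'   membership.
#' @param n_tumor,n_normal Samples per group (>= 3 each).
#' @param within_complex_rho Target pairwise Spearman correlation between
#'   co-members across tumor samples, in [0, 1).
#' @param baseline_rho Background correlation between any two proteins
#'   (global latent factor), in [0, 1).
#' @param frac_differential Fraction of proteins receiving a planted tumor
#'   shift when the membership odds ratio is 1.
#' @param depletion_odds_ratio Odds of a complex member being selected for
#'   differential abundance relative to a non-member (0.5 = depleted).
#' @param lfc_mean,lfc_sd Planted effect sizes: the shift is
#'   `sign * |N(lfc_mean, lfc_sd)|` on the log2 scale.
#' @param frac_down Fraction of planted effects that are down-regulations.
#' @param noise_sd Marginal between-sample standard deviation of log2
#'   abundance.
#' @param missing_rate Completely-at-random missingness rate.
#' @param frac_even_pairs Fraction of structures with equal chain counts for
#'   all members (even parity).
#' @param parity_conflict_frac Fraction of complexes given a second structure
#'   of opposite parity, so their pairs become "mixed" downstream.
#' @param planted_slope_map Named numeric vector mapping a chain-count ratio
#'   `"hi:lo"` to the generative slope with which the higher-copy protein
#'   follows the lower-copy one. The default is stoichiometric scaling
#'   (slope = hi/lo).
#' @param regression_noise_sd Residual noise around planted pair regressions.
#' @param detect_both_prob Probability an interaction (with bait targeted in
#'   both cell lines) is detected in both lines (general) rather than one.
#' @param bait_both_prob Probability the bait of an interaction was targeted
#'   in both cell lines.
#' @param competitive_frac Fraction of planted shared-partner pairs with
#'   overlapping interfaces (competitive); the rest are disjoint
#'   (cooperative).
#' @param interface_overlap Target interface Jaccard for planted competitive
#'   pairs.
#' @param stability_label_frac Fraction of interactions given a curated
#'   stability label.
#' @param transient_share Fraction of stability labels that are transient
#'   (the curated literature sets are transient-heavy).
#' @param seed Mandatory integer seed; every generator derives its stream
#'   from it.
#' @return A validated list of class `"SimulationConfig"`.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_complexes = 50,
                       complex_size_range = c(3L, 6L),
                       complex_membership_overlap_prob = 0.1,
                       frac_complex_proteins = 0.2,
                       n_tumor = 30, n_normal = 30,
                       within_complex_rho = 0.6,
                       baseline_rho = 0,
                       frac_differential = 0.1,
                       depletion_odds_ratio = 0.5,
                       lfc_mean = 2, lfc_sd = 0.5,
                       frac_down = 0.9,
                       noise_sd = 1,
                       missing_rate = 0,
                       frac_even_pairs = 0.5,
                       parity_conflict_frac = 0.2,
                       planted_slope_map = NULL,
                       regression_noise_sd = 0.1,
                       detect_both_prob = 0.5,
                       bait_both_prob = 0.8,
                       competitive_frac = 0.5,
                       interface_overlap = 0.5,
                       stability_label_frac = 0.1,
                       transient_share = 58 / 67,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  probs <- c(complex_membership_overlap_prob, frac_complex_proteins,
             frac_differential, frac_down, missing_rate, frac_even_pairs,
             parity_conflict_frac, detect_both_prob, bait_both_prob,
             competitive_frac, interface_overlap, stability_label_frac,
             transient_share)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (within_complex_rho < -1 || within_complex_rho > 1)
    stop("within_complex_rho must be in [-1, 1]")
  if (n_tumor < 3 || n_normal < 3) stop("n_tumor and n_normal must be >= 3")
  if (length(complex_size_range) != 2 || complex_size_range[1] < 2 ||
      complex_size_range[1] > complex_size_range[2])
    stop("complex_size_range must be c(min >= 2, max >= min)")
  if (noise_sd <= 0 || lfc_sd < 0 || regression_noise_sd < 0)
    stop("scale parameters must be positive")
  if (depletion_odds_ratio < 0) stop("depletion_odds_ratio must be >= 0")
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              complex_membership_overlap_prob = complex_membership_overlap_prob,
              frac_complex_proteins = frac_complex_proteins,
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              within_complex_rho = within_complex_rho,
              baseline_rho = baseline_rho,
              frac_differential = frac_differential,
              depletion_odds_ratio = depletion_odds_ratio,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd, frac_down = frac_down,
              noise_sd = noise_sd, missing_rate = missing_rate,
              frac_even_pairs = frac_even_pairs,
              parity_conflict_frac = parity_conflict_frac,
              planted_slope_map = planted_slope_map,
              regression_noise_sd = regression_noise_sd,
              detect_both_prob = detect_both_prob,
              bait_both_prob = bait_both_prob,
              competitive_frac = competitive_frac,
              interface_overlap = interface_overlap,
              stability_label_frac = stability_label_frac,
              transient_share = transient_share,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' Each generator and pipeline stage draws from its own stream so that adding
#' a stage never perturbs another stage's randomness. The derived value stays
#' below 2^31.
#'
#' @param seed Integer master seed.
#' @param tag Character stage tag.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Convert a target Spearman correlation to the implied Pearson correlation
#' of the Gaussian latent-factor model
#'
#' For a bivariate Gaussian with Pearson correlation r, the population
#' Spearman correlation is (6/pi) asin(r/2); inverting gives the factor
#' correlation needed to realize a Spearman target under the generator's
#' latent-factor model.
#'
#' @param rho_s Target Spearman correlation in [-1, 1].
#' @return The implied Pearson correlation `2 sin(pi rho_s / 6)`.
#' @export
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

protein_names <- function(n) sprintf("P%04d", seq_len(n))

#' Generate a complex catalog with overlapping membership
#'
#' Complexes draw their members from a pool of
#' `frac_complex_proteins * n_proteins` proteins; with probability
#' `complex_membership_overlap_prob` a member slot reuses a protein already
#' placed in an earlier complex, which makes co-occurrence Jaccard values
#' span (0, 1].
#'
#' @param cfg A [sim_config()].
#' @return List with elements `catalog` (a [complex_catalog()]) and `truth`
#'   (data frame `protein`, `is_complex_member` over all proteins).
#' @export
generate_complex_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  pool_size <- floor(cfg$frac_complex_proteins * cfg$n_proteins)
  if (pool_size < cfg$complex_size_range[2])
    stop("complex-protein pool (", pool_size,
         ") smaller than the largest complex size (",
         cfg$complex_size_range[2], ")")
  set.seed(derive_seed(cfg$seed, "catalog"))
  all_proteins <- protein_names(cfg$n_proteins)
  pool <- sample(all_proteins, pool_size)
  used <- character(0)
  unused <- pool
  members <- vector("list", cfg$n_complexes)
  names(members) <- sprintf("CPX%03d", seq_len(cfg$n_complexes))
  size_choices <- seq(cfg$complex_size_range[1], cfg$complex_size_range[2])
  for (j in seq_len(cfg$n_complexes)) {
    size <- size_choices[sample.int(length(size_choices), 1L)]
    mem <- character(0)
    for (s in seq_len(size)) {
      reuse_pool <- setdiff(used, mem)
      take_used <- (length(reuse_pool) > 0 &&
                      stats::runif(1) < cfg$complex_membership_overlap_prob) ||
        length(unused) == 0
      if (take_used && length(reuse_pool) > 0) {
        mem <- c(mem, sample(reuse_pool, 1L))
      } else {
        mem <- c(mem, unused[1L])
        used <- c(used, unused[1L])
        unused <- unused[-1L]
      }
    }
    members[[j]] <- mem
  }
  catalog <- complex_catalog(members, provenance = "synthetic")
  truth <- data.frame(protein = all_proteins,
                      is_complex_member = all_proteins %in% unlist(members),
                      stringsAsFactors = FALSE)
  list(catalog = catalog, truth = truth)
}

#' Generate a paired tumor/normal cohort with planted structure
#'
#' Log2 abundances follow a Gaussian latent-factor model: each complex has
#' one factor per sample, and a member with loading shared across the complex
#' realizes the target within-complex Spearman correlation (via
#' [spearman_to_pearson()]); proteins in several complexes split their
#' loading across factors so the marginal variance stays at `noise_sd^2`. A
#' subset of proteins, selected with membership-dependent odds
#' (`depletion_odds_ratio`), receives an additive tumor shift of
#' `sign * |N(lfc_mean, lfc_sd)|`; `frac_down` of the shifts point down.
#' Cells are then blanked completely at random at `missing_rate`.
#'
#' @param catalog A `ComplexCatalog` (typically from
#'   [generate_complex_catalog()]).
#' @param cfg A [sim_config()].
#' @return List with elements `matrix` (an [abundance_matrix()] with paired
#'   samples) and `truth` (data frame `protein`, `is_complex_member`,
#'   `is_differential`, `direction`, `planted_lfc`).
#' @export
generate_cohort <- function(catalog, cfg) {
  stopifnot(inherits(catalog, "ComplexCatalog"),
            inherits(cfg, "SimulationConfig"))
  if (cfg$within_complex_rho < 0 || cfg$baseline_rho < 0)
    stop("latent-factor planting requires nonnegative correlation targets")
  r_within <- spearman_to_pearson(cfg$within_complex_rho)
  r_base <- spearman_to_pearson(cfg$baseline_rho)
  if (r_within + r_base >= 1 + 1e-12)
    stop("infeasible rho combination: factor variance share ",
         signif(r_within + r_base, 4), " >= 1")
  set.seed(derive_seed(cfg$seed, "cohort"))
  proteins <- protein_names(cfg$n_proteins)
  n_samp <- cfg$n_tumor + cfg$n_normal
  membership <- lapply(stats::setNames(proteins, proteins),
                       function(p) character(0))
  for (cx in names(catalog))
    for (p in catalog[[cx]])
      membership[[p]] <- c(membership[[p]], cx)
  baseline <- stats::rnorm(cfg$n_proteins, mean = 20, sd = 2.5)
  factors <- matrix(stats::rnorm(length(catalog) * n_samp),
                    nrow = length(catalog), dimnames = list(names(catalog)))
  gfac <- stats::rnorm(n_samp)
  values <- matrix(NA_real_, cfg$n_proteins, n_samp,
                   dimnames = list(proteins, NULL))
  for (i in seq_len(cfg$n_proteins)) {
    cxs <- membership[[proteins[i]]]
    k <- length(cxs)
    fac_part <- if (k > 0)
      sqrt(r_within / k) * colSums(factors[cxs, , drop = FALSE])
    else 0
    shared_var <- (if (k > 0) r_within else 0) + r_base
    z <- sqrt(r_base) * gfac + fac_part +
      sqrt(1 - shared_var) * stats::rnorm(n_samp)
    values[i, ] <- baseline[i] + cfg$noise_sd * z
  }
  is_member <- proteins %in% unlist(catalog)
  odds_nm <- cfg$frac_differential / (1 - cfg$frac_differential)
  odds_m <- cfg$depletion_odds_ratio * odds_nm
  p_sel <- ifelse(is_member, odds_m / (1 + odds_m), odds_nm / (1 + odds_nm))
  is_da <- stats::runif(cfg$n_proteins) < p_sel
  direction <- integer(cfg$n_proteins)
  direction[is_da] <- ifelse(stats::runif(sum(is_da)) < cfg$frac_down, -1L, 1L)
  planted <- direction * abs(stats::rnorm(cfg$n_proteins, cfg$lfc_mean,
                                          cfg$lfc_sd))
  planted[!is_da] <- 0
  tumor_cols <- seq_len(cfg$n_tumor)
  values[, tumor_cols] <- values[, tumor_cols] + planted
  if (cfg$missing_rate > 0) {
    blank <- stats::runif(length(values)) < cfg$missing_rate
    values[blank] <- NA_real_
  }
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_normal))
  colnames(values) <- c(tumor_ids, normal_ids)
  n_pair <- min(cfg$n_tumor, cfg$n_normal)
  pairing <- stats::setNames(normal_ids[seq_len(n_pair)],
                             tumor_ids[seq_len(n_pair)])
  group <- c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal))
  truth <- data.frame(protein = proteins, is_complex_member = is_member,
                      is_differential = is_da, direction = direction,
                      planted_lfc = planted, stringsAsFactors = FALSE)
  list(matrix = abundance_matrix(values, group, pairing), truth = truth)
}

#' Generate chain-count structures with controlled parity
#'
#' Each catalog complex yields one structure: with probability
#' `frac_even_pairs` all members get the same chain count (even parity,
#' count drawn from 1/2/4), otherwise members get distinct counts
#' (1, 2, 3, ...), so every co-member pair is uneven. A
#' `parity_conflict_frac` fraction of complexes additionally emits a second
#' structure of the opposite parity, so their pairs are later classified
#' "mixed" and excluded.
#'
#' @param catalog A `ComplexCatalog`.
#' @param cfg A [sim_config()].
#' @return List with elements `table` (a [stoichiometry_table()]) and
#'   `truth` (data frame `pair`, `parity` for all co-structure pairs).
#' @export
generate_structural_stoichiometry <- function(catalog, cfg) {
  stopifnot(inherits(catalog, "ComplexCatalog"),
            inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "stoichiometry"))
  rows <- list()
  pair_parities <- list()
  add_structure <- function(sid, members, even) {
    counts <- if (even) rep(sample(c(1L, 2L, 4L), 1L), length(members))
      else sample(seq_along(members))
    rows[[length(rows) + 1L]] <<- data.frame(
      structure_id = sid, protein = members, chain_count = counts,
      stringsAsFactors = FALSE)
    for (ij in utils::combn(seq_along(members), 2L, simplify = FALSE)) {
      key <- pair_key(members[ij[1]], members[ij[2]])
      lab <- if (counts[ij[1]] == counts[ij[2]]) "even" else "uneven"
      pair_parities[[key]] <<- c(pair_parities[[key]], lab)
    }
  }
  for (cx in names(catalog)) {
    even <- stats::runif(1) < cfg$frac_even_pairs
    add_structure(paste0("S_", cx), catalog[[cx]], even)
    if (stats::runif(1) < cfg$parity_conflict_frac)
      add_structure(paste0("S_", cx, "_alt"), catalog[[cx]], !even)
  }
  tab <- do.call(rbind, rows)
  truth <- data.frame(
    pair = names(pair_parities),
    parity = vapply(pair_parities, function(x)
      if (length(unique(x)) > 1) "mixed" else x[1], ""),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(table = stoichiometry_table(tab$structure_id, tab$protein,
                                   tab$chain_count),
       truth = truth)
}

## Residue sets for planted shared-partner pairs: competitive partners share
## a common block sized so pairwise Jaccard hits the configured overlap;
## cooperative partners get disjoint blocks.
planted_interface_sets <- function(n_partners, competitive, overlap,
                                   offset = 0L) {
  site_size <- 20L
  shared <- max(1L, round(2 * site_size * overlap / (1 + overlap)))
  sets <- vector("list", n_partners)
  for (i in seq_len(n_partners)) {
    if (competitive[i]) {
      sets[[i]] <- c(offset + seq_len(shared),
                     offset + 1000L + seq_len(site_size - shared) +
                       i * site_size)
    } else {
      sets[[i]] <- offset + 5000L + i * site_size + seq_len(site_size)
    }
  }
  sets
}

#' Generate a synthetic interactome with interfaces, detection flags and
#' stability labels
#'
#' Emits one hub per complex: the first member is the shared partner and
#' every other member interacts with it. Partner interfaces on the hub are
#' planted so that a `competitive_frac` fraction of partner pairs overlap at
#' the configured Jaccard (competitive) while the rest are disjoint
#' (cooperative). Cross-complex random interactions (without interface data)
#' are added, baits are targeted in both cell lines with probability
#' `bait_both_prob`, detection lands in both lines with probability
#' `detect_both_prob` (else in one), and a `stability_label_frac` subset is
#' labeled transient/permanent.
#'
#' @param catalog A `ComplexCatalog`.
#' @param cfg A [sim_config()].
#' @return List with elements `interactions` (an [interaction_set()]) and
#'   `truth` (data frames `context` (pair, label), `competition`
#'   (partner-pair, jaccard, label), `stability` (pair, label)).
#' @export
generate_interactome <- function(catalog, cfg) {
  stopifnot(inherits(catalog, "ComplexCatalog"),
            inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "interactome"))
  cl <- c("293T", "HCT116")
  pa <- pb <- character(0)
  iface_a <- iface_b <- list()
  existing <- character(0)
  # sites actually stored per hub: hub -> partner -> residue set (the first
  # complex to plant a (hub, partner) interaction wins, as in the emitted
  # interaction rows)
  hub_sites <- list()
  for (cx_i in seq_along(catalog)) {
    cx <- names(catalog)[cx_i]
    members <- catalog[[cx]]
    hub <- members[1]
    partners <- setdiff(members[-1], hub)
    if (!length(partners)) next
    competitive <- stats::runif(length(partners)) < cfg$competitive_frac
    sets <- planted_interface_sets(length(partners), competitive,
                                   cfg$interface_overlap,
                                   offset = cx_i * 100000L)
    for (i in seq_along(partners)) {
      key <- pair_key(hub, partners[i])
      if (key %in% existing) next
      existing <- c(existing, key)
      pa <- c(pa, hub); pb <- c(pb, partners[i])
      # interface on the hub side carries the planted set; the site on the
      # partner side is generic but unique per interaction, so no spurious
      # binding-site overlap arises through non-hub common partners
      hub_site <- sets[[i]]
      partner_site <- cx_i * 100000L + 90000L + i * 10L + seq_len(10L)
      # rows are passed hub-first; interaction_set() canonicalizes the pair
      # and swaps the interface sides along with it
      iface_a <- c(iface_a, list(hub_site))
      iface_b <- c(iface_b, list(partner_site))
      if (is.null(hub_sites[[hub]])) hub_sites[[hub]] <- list()
      hub_sites[[hub]][[partners[i]]] <- hub_site
    }
  }
  # true competition labels: best (max) binding-site Jaccard over all hubs a
  # partner pair shares, from the stored sets
  comp_best <- list()
  for (hub in names(hub_sites)) {
    partners <- names(hub_sites[[hub]])
    if (length(partners) < 2) next
    for (ij in utils::combn(length(partners), 2L, simplify = FALSE)) {
      s1 <- hub_sites[[hub]][[partners[ij[1]]]]
      s2 <- hub_sites[[hub]][[partners[ij[2]]]]
      jac <- length(intersect(s1, s2)) / length(union(s1, s2))
      key <- pair_key(partners[ij[1]], partners[ij[2]])
      if (is.null(comp_best[[key]]) || jac > comp_best[[key]])
        comp_best[[key]] <- jac
    }
  }
  comp_rows <- if (length(comp_best)) {
    jac <- unlist(comp_best)
    list(data.frame(pair = names(comp_best), jaccard = unname(jac),
                    label = ifelse(jac >= 0.1, "competitive", "cooperative"),
                    stringsAsFactors = FALSE))
  } else list()
  # cross-complex random interactions without interface data
  all_members <- catalog_proteins(catalog)
  n_random <- max(10L, length(pa) %/% 2L)
  tries <- 0L
  while (n_random > 0 && tries < 1000L) {
    cand <- sample(all_members, 2L)
    key <- pair_key(cand[1], cand[2])
    tries <- tries + 1L
    if (key %in% existing) next
    pa <- c(pa, cand[1]); pb <- c(pb, cand[2])
    iface_a <- c(iface_a, list(NA_integer_))
    iface_b <- c(iface_b, list(NA_integer_))
    existing <- c(existing, key)
    n_random <- n_random - 1L
  }
  n <- length(pa)
  bait_both <- stats::runif(n) < cfg$bait_both_prob
  bait <- lapply(seq_len(n), function(i)
    if (bait_both[i]) cl else sample(cl, 1L))
  detected <- vector("list", n)
  context <- rep("unknown", n)
  for (i in seq_len(n)) {
    if (bait_both[i]) {
      if (stats::runif(1) < cfg$detect_both_prob) {
        detected[[i]] <- cl
        context[i] <- "general"
      } else {
        detected[[i]] <- sample(cl, 1L)
        context[i] <- "context_specific"
      }
    } else {
      detected[[i]] <- bait[[i]]
    }
  }
  stability <- rep("unlabeled", n)
  labeled <- which(stats::runif(n) < cfg$stability_label_frac)
  stability[labeled] <- ifelse(stats::runif(length(labeled)) <
                                 cfg$transient_share,
                               "transient", "permanent")
  keys <- pair_key(pa, pb)
  ix <- interaction_set(pa, pb, cell_lines_detected = detected,
                        bait_cell_lines = bait,
                        interface_a = iface_a, interface_b = iface_b,
                        stability_label = stability, cell_lines = cl)
  truth <- list(
    context = data.frame(pair = keys, label = context,
                         stringsAsFactors = FALSE),
    competition = if (length(comp_rows)) do.call(rbind, comp_rows)
      else data.frame(pair = character(0), jaccard = numeric(0),
                      label = character(0)),
    stability = data.frame(pair = keys, label = stability,
                           stringsAsFactors = FALSE))
  list(interactions = ix, truth = truth)
}

#' Generate tumor abundances with planted pair-regression slopes
#'
#' For each structure, the lowest-copy member drives the rest: member j
#' follows `x_j = mu_j + beta_j (x_lo - mu_lo) + noise`, with `beta_j` looked
#' up in `planted_slope_map` by the chain-count ratio `count_j:count_lo`
#' (default: stoichiometric scaling, `beta_j = count_j / count_lo`). The
#' generative slope between any two members is then the ratio of their betas,
#' recorded as ground truth.
#'
#' @param st A `StoichiometryTable`.
#' @param cfg A [sim_config()]; `n_tumor` sets the sample count.
#' @return List with elements `matrix` (tumor-only [abundance_matrix()]) and
#'   `truth` (data frame `pair`, `slope`: generative slope of the
#'   higher-copy on the lower-copy protein).
#' @export
generate_stoichiometric_abundances <- function(st, cfg) {
  stopifnot(inherits(st, "StoichiometryTable"),
            inherits(cfg, "SimulationConfig"))
  set.seed(derive_seed(cfg$seed, "stoich-abund"))
  n <- cfg$n_tumor
  proteins <- unique(st$protein)
  baseline <- stats::setNames(stats::rnorm(length(proteins), 20, 2.5),
                              proteins)
  values <- matrix(NA_real_, length(proteins), n,
                   dimnames = list(proteins,
                                   sprintf("T%03d", seq_len(n))))
  slope_for_ratio <- function(hi, lo) {
    key <- paste0(hi, ":", lo)
    if (!is.null(cfg$planted_slope_map) &&
        key %in% names(cfg$planted_slope_map))
      return(unname(cfg$planted_slope_map[key]))
    hi / lo
  }
  truth <- list()
  origin <- stats::setNames(rep(NA_character_, length(proteins)), proteins)
  for (sid in unique(st$structure_id)) {
    sub <- st[st$structure_id == sid, ]
    sub <- sub[order(sub$chain_count, sub$protein), ]
    lo <- sub$protein[1]
    if (is.na(origin[lo])) {
      values[lo, ] <- baseline[lo] + stats::rnorm(n)
      origin[lo] <- sid
    }
    driver <- values[lo, ] - baseline[lo]
    betas <- stats::setNames(rep(1, nrow(sub)), sub$protein)
    for (i in seq_len(nrow(sub))[-1]) {
      p <- sub$protein[i]
      betas[p] <- slope_for_ratio(sub$chain_count[i], sub$chain_count[1])
      if (is.na(origin[p])) {
        values[p, ] <- baseline[p] + betas[p] * driver +
          stats::rnorm(n, sd = cfg$regression_noise_sd)
        origin[p] <- sid
      }
    }
    # truth is only recorded where both members were generated off this
    # structure's driver (shared proteins keep their first-structure values)
    gen_here <- sub$protein[origin[sub$protein] == sid | sub$protein == lo]
    for (ij in utils::combn(seq_len(nrow(sub)), 2L, simplify = FALSE)) {
      p1 <- sub$protein[ij[1]]; p2 <- sub$protein[ij[2]]
      if (!(p1 %in% gen_here && p2 %in% gen_here)) next
      key <- pair_key(p1, p2)
      if (key %in% names(truth)) next
      # slope of the higher-copy member on the lower-copy one
      truth[[key]] <- betas[p2] / betas[p1]
    }
  }
  truth_df <- data.frame(pair = names(truth),
                         slope = unname(unlist(truth)),
                         stringsAsFactors = FALSE)
  m <- abundance_matrix(values, rep("tumor", n))
  list(matrix = m, truth = truth_df)
}

#' Audit consistency between ground truth and emitted tables
#'
#' Checks that the truth tables produced by the generators agree with the
#' emitted artifacts: membership flags match the catalog, planted effects are
#' nonzero exactly for truth-flagged differential proteins, and parity truth
#' re-derives from the chain-count table.
#'
#' @param catalog A `ComplexCatalog`.
#' @param cohort Output of [generate_cohort()].
#' @param stoich Optional output of [generate_structural_stoichiometry()].
#' @return `TRUE` invisibly; inconsistencies are errors.
#' @export
audit_ground_truth <- function(catalog, cohort, stoich = NULL) {
  truth <- cohort$truth
  members <- catalog_proteins(catalog)
  if (!identical(truth$is_complex_member, truth$protein %in% members))
    stop("membership flags inconsistent with catalog")
  if (!identical(truth$is_differential, truth$planted_lfc != 0))
    stop("differential flags inconsistent with planted effects")
  if (!identical(sign(truth$planted_lfc), as.numeric(truth$direction)))
    stop("directions inconsistent with planted effects")
  if (!is.null(stoich)) {
    recomputed <- classify_stoichiometric_parity(stoich$table)
    m <- merge(stoich$truth, recomputed, by = "pair")
    if (!all(m$parity.x == m$parity.y))
      stop("parity truth inconsistent with chain-count table")
  }
  invisible(TRUE)
}
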