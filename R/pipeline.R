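## End-to-end orchestration: simulate (or read) inputs, then preprocess ->
## differential abundance -> membership association -> co-abundance
## correlation -> pair classification -> slope comparison, with one master
## seed and a reproducibility manifest.

default_stages <- c("simulate", "preprocess", "diffabund", "enrich",
                    "correlate", "classify", "slopes")

#' Run the full analysis pipeline
#'
#' Executes the requested stages in their fixed order. Inputs come either
#' from the synthetic-data generators (`config$simulate`, a list of
#' [sim_config()] arguments) or from files (`config$inputs` with elements
#' `abundance`, `sample_sheet`, and optionally `catalog`, `stoichiometry`
#' and `interactions`). One master seed drives every stage through
#' [derive_seed()], so a config plus a seed reproduces the output bundle
#' byte for byte.
#'
#' @param config A list with `seed` (integer), `out_dir` (path), one of
#'   `simulate`/`inputs`, optionally `stages` (subset of
#'   simulate/preprocess/diffabund/enrich/correlate/classify/slopes) and
#'   `params` (overrides: `min_fraction`, `merge_duplicates`, `min_corr_n`,
#'   `n_bins`, `competition_threshold`, `lfc_threshold`, `alpha`,
#'   `max_different_pairs`, `cohort`).
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage plus the manifest; all result tables are written as TSV to
#'   `config$out_dir` along with `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  stages <- if (is.null(config$stages)) default_stages else config$stages
  bad <- setdiff(stages, default_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- default_stages[default_stages %in% stages]
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config must name 'inputs' or contain a 'simulate' block")
  p <- utils::modifyList(
    list(min_fraction = 0.5, merge_duplicates = TRUE, min_corr_n = 10,
         n_bins = 10, competition_threshold = 0.1, lfc_threshold = 1,
         alpha = 0.05, max_different_pairs = 2000, cohort = "cohort"),
    if (is.null(config$params)) list() else config$params)
  seed <- as.integer(config$seed)
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", config$out_dir)
  state <- list()
  tables <- list()
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' needs '", what,
           "' from an earlier stage or from inputs")
    state[[what]]
  }

  if ("simulate" %in% stages) {
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    cat_res <- generate_complex_catalog(cfg)
    coh <- generate_cohort(cat_res$catalog, cfg)
    sto <- generate_structural_stoichiometry(cat_res$catalog, cfg)
    ixr <- generate_interactome(cat_res$catalog, cfg)
    state$matrix <- coh$matrix
    state$catalog <- cat_res$catalog
    state$stoichiometry <- sto$table
    state$interactions <- ixr$interactions
    state$truth <- list(protein = coh$truth, parity = sto$truth,
                        interactome = ixr$truth)
    tables$truth_proteins <- coh$truth
    tables$truth_parity <- sto$truth
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (!is.null(inp$abundance))
      state$matrix <- read_abundance_matrix(inp$abundance, inp$sample_sheet)
    if (!is.null(inp$catalog))
      state$catalog <- read_complex_catalog(inp$catalog)
    if (!is.null(inp$stoichiometry))
      state$stoichiometry <- read_stoichiometry_table(inp$stoichiometry)
    if (!is.null(inp$interactions))
      state$interactions <- read_interaction_tables(inp$interactions)
  }

  if ("preprocess" %in% stages) {
    m <- need("matrix", "preprocess")
    if (p$merge_duplicates && has_duplicate_symbols(m))
      m <- merge_duplicate_symbols(m)
    state$matrix <- filter_low_coverage(m, min_fraction = p$min_fraction)
  }

  if ("diffabund" %in% stages) {
    m <- need("matrix", "diffabund")
    da <- test_differential_abundance(m)
    da <- call_differential(da, lfc_threshold = p$lfc_threshold,
                            alpha = p$alpha)
    state$differential <- da
    tables$differential_abundance <- as.data.frame(da)
    disp <- compare_dispersion(m)
    tables$dispersion_summary <- data.frame(
      mean_sd_tumor = disp$mean_sd_tumor,
      mean_sd_normal = disp$mean_sd_normal,
      statistic = disp$statistic, p = disp$p)
  }

  if ("enrich" %in% stages) {
    da <- need("differential", "enrich")
    m <- need("matrix", "enrich")
    catalog <- need("catalog", "enrich")
    universe <- da$protein
    members <- intersect(catalog_proteins(catalog), universe)
    da_set <- da$protein[da$call != "unchanged"]
    as_row <- function(res, label) {
      if (inherits(res, "NotTestable"))
        return(data.frame(test = label, statistic = NA_real_, p = NA_real_,
                          observed = NA_integer_, expected = NA_real_,
                          direction = res$reason))
      data.frame(test = label, statistic = res$statistic, p = res$p,
                 observed = res$table["member", "da"],
                 expected = res$expected["member", "da"],
                 direction = res$direction)
    }
    overall <- tryCatch(association_test(da_set, members, universe),
                        error = function(e)
                          structure(list(direction = "all",
                                         reason = conditionMessage(e)),
                                    class = "NotTestable"))
    matched <- tryCatch(matched_association_test(
      da_set, members, universe, abundance_summary(m, "normal"),
      n_bins = p$n_bins, seed = derive_seed(seed, "background")),
      error = function(e)
        structure(list(direction = "matched",
                       reason = conditionMessage(e)),
                  class = "NotTestable"))
    dir_res <- directional_association(da, members, universe)
    state$association <- list(overall = overall, matched = matched,
                              up = dir_res$up, down = dir_res$down)
    tables$association_summary <- rbind(
      as_row(overall, "all_universe"), as_row(matched, "matched"),
      as_row(dir_res$up, "up"), as_row(dir_res$down, "down"))
  }

  if ("correlate" %in% stages) {
    m <- need("matrix", "correlate")
    catalog <- need("catalog", "correlate")
    groups <- catalog_pair_groups(catalog, rownames(m$values),
                                  max_different = p$max_different_pairs,
                                  seed = derive_seed(seed, "pairs"))
    corr <- pairwise_spearman(m, groups, min_n = p$min_corr_n,
                              cohort = p$cohort)
    pooled <- pool_across_cohorts(corr, groups)
    state$correlations <- corr
    state$pair_groups <- groups
    tables$correlations <- as.data.frame(corr)
    if (all(c("same_complex", "different_complex") %in% names(pooled))) {
      cmp <- compare_correlation_groups(pooled$same_complex,
                                        pooled$different_complex,
                                        "same_complex", "different_complex")
      state$correlation_comparison <- cmp
      tables$correlation_comparison <- data.frame(
        group_a = cmp$name_a, group_b = cmp$name_b, n_a = cmp$n_a,
        n_b = cmp$n_b, median_a = cmp$median_a, median_b = cmp$median_b,
        p = cmp$p, direction = cmp$direction)
    }
  }

  if ("classify" %in% stages) {
    catalog <- need("catalog", "classify")
    parity <- if (!is.null(state$stoichiometry))
      classify_stoichiometric_parity(state$stoichiometry) else NULL
    cooc <- cooccurrence_jaccard(catalog)
    ctx <- comp <- stab <- NULL
    if (!is.null(state$interactions)) {
      ix <- state$interactions
      ctx <- classify_context(ix)
      comp <- classify_competition(ix,
                                   threshold = p$competition_threshold)
      stab <- data.frame(pair = ix$pair, stability = ix$stability_label,
                         stringsAsFactors = FALSE)
      stab$stability[stab$stability == "unlabeled"] <- "unknown"
    }
    ann <- annotate_pairs(parity = parity, cooccurrence = cooc,
                          context = ctx, competition = comp,
                          stability = stab)
    state$annotation <- ann
    tables$pair_annotation <- as.data.frame(ann)
  }

  if ("slopes" %in% stages) {
    m <- need("matrix", "slopes")
    sto <- need("stoichiometry", "slopes")
    parity <- classify_stoichiometric_parity(sto)
    assignments <- assign_dependent(parity, sto)
    reg <- pair_regressions(m, assignments,
                            correlations = state$correlations)
    cmp <- compare_slopes(reg)
    state$regressions <- reg
    state$slope_comparison <- cmp
    tables$pair_regressions <- as.data.frame(reg)
    slope_row <- function(r, stratum) {
      if (inherits(r, "NotTestable"))
        return(data.frame(stratum = stratum, n_even = 0L, n_uneven = 0L,
                          median_even = NA_real_, median_uneven = NA_real_,
                          p = NA_real_, direction = r$reason))
      data.frame(stratum = stratum, n_even = r$n_a, n_uneven = r$n_b,
                 median_even = r$median_a, median_uneven = r$median_b,
                 p = r$p, direction = r$direction)
    }
    tables$slope_comparison <- rbind(slope_row(cmp$positive, "positive"),
                                     slope_row(cmp$negative, "negative"))
  }

  if (!is.null(state$matrix) && "simulate" %in% stages) {
    write_abundance_matrix(state$matrix,
                           file.path(config$out_dir, "abundance.tsv"),
                           file.path(config$out_dir, "samples.tsv"))
    write_complex_catalog(state$catalog,
                          file.path(config$out_dir, "catalog.tsv"))
    write_stoichiometry_table(state$stoichiometry,
                              file.path(config$out_dir, "stoichiometry.tsv"))
    write_interaction_set(state$interactions,
                          file.path(config$out_dir, "interactions.tsv"))
  }
  manifest <- write_results(
    tables, config$out_dir,
    inputs = if (is.null(config$inputs)) list(mode = "simulate")
      else config$inputs,
    params = c(p, list(stages = stages,
                       simulate = config$simulate)),
    seed = seed)
  state$manifest <- manifest
  invisible(state)
}
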