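## All-pairs Spearman co-abundance across tumor samples, cross-cohort
## pooling without averaging, and rank-sum comparisons between pair groups.

#' Spearman correlation for protein pairs across tumor samples
#'
#' For each requested pair, computes the tie-corrected Spearman correlation
#' over pairwise-complete tumor observations. Pairs with fewer than `min_n`
#' complete observations are omitted (their count is in attribute
#' `n_omitted`).
#'
#' @param m An `AbundanceMatrix`; only tumor samples are used.
#' @param pairs Data frame with columns `protein_a`, `protein_b`, or a
#'   character vector of [pair_key()] keys.
#' @param min_n Minimum pairwise-complete observations.
#' @param cohort Cohort label recorded on every row.
#' @return Data frame of class `"CorrelationTable"` with columns `pair`,
#'   `protein_a`, `protein_b`, `cohort`, `rho`, `n_samples_used`.
#' @export
pairwise_spearman <- function(m, pairs, min_n = 10, cohort = "cohort") {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (is.character(pairs)) pairs <- split_pair_key(pairs)
  if (!nrow(pairs)) stop("empty pair list")
  key <- pair_key(pairs$protein_a, pairs$protein_b)
  dup <- duplicated(key)
  pairs <- pairs[!dup, , drop = FALSE]
  key <- key[!dup]
  tum <- tumor_values(m)
  missing_prot <- setdiff(unique(c(pairs$protein_a, pairs$protein_b)),
                          rownames(tum))
  if (length(missing_prot))
    stop("pairs reference proteins absent from the matrix: ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  n <- nrow(pairs)
  rho <- rep(NA_real_, n)
  used <- integer(n)
  for (i in seq_len(n)) {
    x <- tum[pairs$protein_a[i], ]
    y <- tum[pairs$protein_b[i], ]
    ok <- !is.na(x) & !is.na(y)
    used[i] <- sum(ok)
    if (used[i] < min_n) next
    rho[i] <- stats::cor(x[ok], y[ok], method = "spearman")
  }
  keep <- !is.na(rho)
  out <- data.frame(pair = key[keep],
                    protein_a = pairs$protein_a[keep],
                    protein_b = pairs$protein_b[keep],
                    cohort = rep(cohort, sum(keep)), rho = rho[keep],
                    n_samples_used = used[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("CorrelationTable", "data.frame")
  attr(out, "n_omitted") <- sum(!keep)
  out
}

#' Enumerate protein pairs covered by a complex catalog
#'
#' All unordered pairs among catalog proteins present in `proteins`, labeled
#' `same_complex` when the two proteins share at least one complex and
#' `different_complex` otherwise. Pairs occurring in several complexes appear
#' once. For large catalogs the different-complex side can be subsampled.
#'
#' @param catalog A `ComplexCatalog`.
#' @param proteins Character vector restricting the pair universe (typically
#'   the quantified proteins); `NULL` for all catalog proteins.
#' @param max_different Cap on the number of different-complex pairs; a
#'   deterministic subsample (by `seed`) is taken beyond it. `Inf` disables
#'   the cap.
#' @param seed Seed for the subsample.
#' @return Data frame with columns `pair`, `protein_a`, `protein_b`,
#'   `group`.
#' @export
catalog_pair_groups <- function(catalog, proteins = NULL,
                                max_different = Inf, seed = 1L) {
  stopifnot(inherits(catalog, "ComplexCatalog"))
  prots <- catalog_proteins(catalog)
  if (!is.null(proteins)) prots <- intersect(prots, proteins)
  if (length(prots) < 2) stop("fewer than 2 catalog proteins available")
  same <- unique(unlist(lapply(catalog, function(mem) {
    mem <- intersect(mem, prots)
    if (length(mem) < 2) return(character(0))
    cmb <- utils::combn(sort(mem), 2L)
    pair_key(cmb[1, ], cmb[2, ])
  })))
  cmb <- utils::combn(sort(prots), 2L)
  all_keys <- pair_key(cmb[1, ], cmb[2, ])
  diff <- setdiff(all_keys, same)
  if (is.finite(max_different) && length(diff) > max_different) {
    set.seed(seed)
    diff <- sample(diff, max_different)
  }
  keys <- c(same, diff)
  parts <- split_pair_key(keys)
  data.frame(pair = keys, protein_a = parts$protein_a,
             protein_b = parts$protein_b,
             group = c(rep("same_complex", length(same)),
                       rep("different_complex", length(diff))),
             stringsAsFactors = FALSE)
}

#' Pool per-cohort correlations into per-group value distributions
#'
#' Every (pair, cohort) correlation contributes one observation to its
#' group's pooled distribution; values are never averaged within a pair, so
#' a pair measured in three cohorts contributes three values.
#'
#' @param tables List of `CorrelationTable`s (one per cohort) or a single
#'   table.
#' @param pair_groups Data frame with columns `pair` and `group` assigning
#'   each pair to a group; pairs without an assignment are dropped.
#' @return Named list of numeric vectors, one per group.
#' @export
pool_across_cohorts <- function(tables, pair_groups) {
  if (inherits(tables, "CorrelationTable")) tables <- list(tables)
  if (!length(tables)) stop("at least one cohort table is required")
  combined <- do.call(rbind, lapply(tables, function(t)
    as.data.frame(t)[, c("pair", "rho")]))
  grp <- pair_groups$group[match(combined$pair, pair_groups$pair)]
  keep <- !is.na(grp)
  split(combined$rho[keep], grp[keep])
}

#' Compare two pooled correlation distributions
#'
#' Two-sided Wilcoxon rank-sum test between the pooled correlation values of
#' two pair groups, with group medians and the effect direction.
#'
#' @param values_a,values_b Numeric vectors of correlations.
#' @param name_a,name_b Group names for reporting.
#' @return List of class `"GroupComparison"`: `p`, `median_a`, `median_b`,
#'   `direction` (`"<name_a> > <name_b>"` or the reverse, `"equal"` at
#'   identical medians), `n_a`, `n_b`, `name_a`, `name_b`.
#' @export
compare_correlation_groups <- function(values_a, values_b,
                                       name_a = "group_a",
                                       name_b = "group_b") {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  p <- wilcox_p_value(values_a, values_b)
  med_a <- stats::median(values_a); med_b <- stats::median(values_b)
  direction <- if (med_a > med_b) paste(name_a, ">", name_b)
    else if (med_a < med_b) paste(name_b, ">", name_a) else "equal"
  structure(list(p = p, median_a = med_a, median_b = med_b,
                 direction = direction, n_a = length(values_a),
                 n_b = length(values_b), name_a = name_a, name_b = name_b),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d, median %.3f) vs %s (n=%d, median %.3f): p = %.3g, %s\n",
    x$name_a, x$n_a, x$median_a, x$name_b, x$n_b, x$median_b, x$p,
    x$direction))
  invisible(x)
}
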