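## Association between differential abundance and complex membership:
## a 2x2 chi-square test plus the abundance-matched background construction
## that removes abundance as a confounder.

#' Chi-square association between a protein set and complex membership
#'
#' Pearson chi-square (no continuity correction by default) on the 2x2 table
#' membership x differential status over a protein universe. The expected
#' count of the differential-and-member cell is reported so depletion versus
#' enrichment is explicit.
#'
#' @param da_set Character vector of differentially abundant proteins
#'   (subset of `universe`).
#' @param member_set Character vector of complex members (subset of
#'   `universe`).
#' @param universe Character vector of all quantified proteins.
#' @param yates Apply the Yates continuity correction (off by default; the
#'   uncorrected statistic is the plain hand formula and expected counts in
#'   realistic uses are large).
#' @param background_kind Label recorded on the result.
#' @return List of class `"AssociationResult"`: `table` (2x2 observed
#'   counts, rows member/non_member, cols da/not_da), `expected`,
#'   `statistic`, `p`, `direction` (`"enriched"`/`"depleted"` by the sign of
#'   observed minus expected in the member-and-da cell), `background_kind`.
#' @export
association_test <- function(da_set, member_set, universe, yates = FALSE,
                             background_kind = "all_non_tested_universe") {
  universe <- unique(universe)
  da_set <- unique(da_set); member_set <- unique(member_set)
  if (!all(da_set %in% universe) || !all(member_set %in% universe))
    stop("da_set and member_set must be subsets of the universe")
  is_da <- universe %in% da_set
  is_mem <- universe %in% member_set
  tab <- matrix(c(sum(is_mem & is_da), sum(!is_mem & is_da),
                  sum(is_mem & !is_da), sum(!is_mem & !is_da)),
                nrow = 2, byrow = FALSE,
                dimnames = list(c("member", "non_member"),
                                c("da", "not_da")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test undefined: a table margin is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  direction <- if (tab["member", "da"] < ct$expected["member", "da"])
    "depleted" else "enriched"
  structure(list(table = tab, expected = ct$expected,
                 statistic = unname(ct$statistic), p = ct$p.value,
                 direction = direction, background_kind = background_kind),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf(
    "Association (%s): chi2 = %.3f, p = %.3g, member-and-da observed %d vs expected %.1f (%s)\n",
    x$background_kind, x$statistic, x$p, x$table["member", "da"],
    x$expected["member", "da"], x$direction))
  invisible(x)
}

#' Per-protein abundance summary for matched-background binning
#'
#' @param m An `AbundanceMatrix`.
#' @param samples Which samples to summarize over: `"normal"` (default),
#'   `"tumor"` or `"all"`.
#' @return Named numeric vector of per-protein median log2 abundances.
#' @export
abundance_summary <- function(m, samples = c("normal", "tumor", "all")) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  samples <- match.arg(samples)
  v <- switch(samples, all = m$values, tumor = tumor_values(m),
              normal = normal_values(m))
  apply(v, 1, stats::median, na.rm = TRUE)
}

#' Draw an abundance-matched non-member background set
#'
#' Bins the universe into `n_bins` equal-frequency abundance bins and
#' replaces each complex member with a distinct non-member drawn (without
#' replacement) from the same bin, so the background matches the members'
#' abundance-bin histogram exactly and is disjoint from the member set.
#'
#' @param member_set Character vector of member proteins.
#' @param universe Character vector of all quantified proteins.
#' @param abundance Named numeric vector giving one abundance summary per
#'   universe protein (see [abundance_summary()]).
#' @param n_bins Number of equal-frequency bins.
#' @param seed Integer seed for the draw.
#' @return Character vector of background proteins, `|member_set|` long,
#'   with a `bins` attribute giving each universe protein's bin.
#' @export
build_matched_background <- function(member_set, universe, abundance,
                                     n_bins = 10, seed = 1L) {
  universe <- unique(universe)
  member_set <- unique(member_set)
  if (!all(member_set %in% universe))
    stop("member_set must be a subset of the universe")
  if (!all(universe %in% names(abundance)))
    stop("abundance summary missing for some universe proteins")
  a <- abundance[universe]
  breaks <- unique(stats::quantile(a, probs = seq(0, 1, length.out = n_bins + 1),
                                   na.rm = TRUE, names = FALSE))
  bins <- if (length(breaks) < 2) rep(1L, length(a))
    else as.integer(cut(a, breaks = breaks, include.lowest = TRUE))
  names(bins) <- universe
  set.seed(seed)
  background <- character(0)
  for (b in sort(unique(bins[member_set]))) {
    mem_b <- member_set[bins[member_set] == b]
    pool <- setdiff(universe[bins == b], member_set)
    if (length(pool) < length(mem_b))
      stop("bin ", b, " has ", length(mem_b), " members but only ",
           length(pool), " non-members to draw from")
    background <- c(background, sample(pool, length(mem_b)))
  }
  attr(background, "bins") <- bins
  background
}

#' Association test against an abundance-matched background
#'
#' Repeats the membership association with the universe restricted to the
#' members plus a matched background from [build_matched_background()], so
#' that abundance differences between complex and non-complex proteins
#' cannot drive the association. With `replicates > 1` the draw is repeated
#' and the replicate with the median p-value is reported (the per-replicate
#' p-values are attached).
#'
#' @inheritParams build_matched_background
#' @param da_set Differentially abundant proteins.
#' @param yates Continuity correction, as in [association_test()].
#' @param replicates Number of background draws.
#' @return An `AssociationResult` (with attribute `replicate_p` when
#'   `replicates > 1`).
#' @export
matched_association_test <- function(da_set, member_set, universe, abundance,
                                     n_bins = 10, seed = 1L, yates = FALSE,
                                     replicates = 1L) {
  run_one <- function(s) {
    bg <- build_matched_background(member_set, universe, abundance,
                                   n_bins = n_bins, seed = s)
    restricted <- c(member_set, bg)
    association_test(intersect(da_set, restricted), member_set, restricted,
                     yates = yates, background_kind = "abundance_matched")
  }
  if (replicates <= 1L) return(run_one(seed))
  seeds <- seed + seq_len(replicates) - 1L
  results <- lapply(seeds, run_one)
  ps <- vapply(results, `[[`, 0, "p")
  pick <- order(ps)[ceiling(replicates / 2)]
  out <- results[[pick]]
  attr(out, "replicate_p") <- ps
  out
}

#' Run the membership association separately for up- and down-regulated
#' proteins
#'
#' @param result A `DifferentialResult` with calls.
#' @param member_set,universe As in [association_test()].
#' @param yates Continuity correction flag.
#' @return List with elements `up` and `down`; each an `AssociationResult`,
#'   or a list of class `"NotTestable"` with the margin error message when
#'   that direction has no calls (or the test is otherwise undefined).
#' @export
directional_association <- function(result, member_set, universe,
                                    yates = FALSE) {
  stopifnot(inherits(result, "DifferentialResult"))
  run_dir <- function(dir) {
    da <- result$protein[result$call == dir]
    tryCatch(association_test(da, member_set, universe, yates = yates),
             error = function(e)
               structure(list(direction = dir, reason = conditionMessage(e)),
                         class = "NotTestable"))
  }
  list(up = run_dir("up"), down = run_dir("down"))
}

#' @export
print.NotTestable <- function(x, ...) {
  cat(sprintf("Not testable (%s): %s\n", x$direction, x$reason))
  invisible(x)
}
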