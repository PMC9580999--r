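#' Filter proteins quantified in too few samples
#'
#' Removes proteins quantified in less than `min_fraction` of the samples
#' (tumor and normal pooled); a protein observed in exactly the threshold
#' fraction is retained, i.e. the rule is strictly "less than".
#'
#' @param m An `AbundanceMatrix`.
#' @param min_fraction Required fraction of non-missing samples, in (0, 1].
#' @param samples Which samples count towards coverage: `"all"` (default),
#'   `"tumor"` or `"normal"`.
#' @return The filtered `AbundanceMatrix`. Removing every protein is an
#'   error.
#' @export
filter_low_coverage <- function(m, min_fraction = 0.5,
                                samples = c("all", "tumor", "normal")) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  samples <- match.arg(samples)
  v <- switch(samples, all = m$values, tumor = tumor_values(m),
              normal = normal_values(m))
  frac <- rowMeans(!is.na(v))
  keep <- !(frac < min_fraction)
  if (!any(keep)) stop("coverage filter removed every protein")
  abundance_matrix(m$values[keep, , drop = FALSE], m$group, m$pairing)
}

#' Merge rows sharing a protein symbol
#'
#' Rows mapped to the same gene symbol are collapsed to their per-sample mean
#' over the available (non-missing) values; a merged cell is missing only if
#' it is missing in all contributing rows. Row order of the first occurrence
#' of each symbol is preserved.
#'
#' @param m An `AbundanceMatrix`.
#' @return An `AbundanceMatrix` with unique protein symbols.
#' @export
merge_duplicate_symbols <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  syms <- rownames(m$values)
  if (!anyDuplicated(syms)) return(m)
  first <- !duplicated(syms)
  merged <- rowsum(ifelse(is.na(m$values), 0, m$values), syms,
                   reorder = FALSE)
  counts <- rowsum((!is.na(m$values)) + 0, syms, reorder = FALSE)
  out <- merged / counts
  out[counts == 0] <- NA_real_
  out <- out[match(syms[first], rownames(out)), , drop = FALSE]
  abundance_matrix(out, m$group, m$pairing)
}

#' Quantile-normalize spectral counts and log-transform
#'
#' Columns are quantile-normalized to the mean empirical distribution (ties
#' receive the average of the tied reference quantiles), then transformed as
#' `log2(x + 1)`; replicate columns of the same specimen are averaged
#' afterwards. Intended for label-free spectral-count cohorts that arrive as
#' raw counts rather than log ratios.
#'
#' @param counts Nonnegative numeric matrix (proteins x samples).
#' @param group Group labels as for [abundance_matrix()].
#' @param replicate_map Optional named character vector mapping column names
#'   to specimen identifiers; columns sharing a specimen are averaged and the
#'   column is renamed to the specimen. Group labels must agree within a
#'   specimen.
#' @return An `AbundanceMatrix` of log2 normalized abundances.
#' @export
normalize_spectral_counts <- function(counts, group, replicate_map = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (any(counts < 0, na.rm = TRUE)) stop("negative spectral counts")
  normed <- limma::normalizeQuantiles(counts, ties = TRUE)
  logged <- log2(normed + 1)
  if (!is.null(names(group))) group <- group[colnames(counts)]
  names(group) <- colnames(counts)
  if (!is.null(replicate_map)) {
    spec <- replicate_map[colnames(logged)]
    if (anyNA(spec)) stop("replicate_map must cover every column")
    grp_by_spec <- tapply(group, spec, unique)
    if (any(lengths(grp_by_spec) > 1))
      stop("replicates of one specimen must share a group label")
    agg <- t(rowsum(t(ifelse(is.na(logged), 0, logged)), spec,
                    reorder = FALSE))
    cnt <- t(rowsum(t((!is.na(logged)) + 0), spec, reorder = FALSE))
    logged <- agg / cnt
    logged[cnt == 0] <- NA_real_
    rownames(logged) <- rownames(counts)
    group <- vapply(colnames(logged), function(s) grp_by_spec[[s]][1], "")
  }
  abundance_matrix(logged, group)
}
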