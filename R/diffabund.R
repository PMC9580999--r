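## Tumor-vs-normal differential abundance: per-protein Wilcoxon rank tests,
## Bonferroni correction, and a median-difference log2 fold change.

# Rank-sum / signed-rank p-value with the package's exactness policy: exact
# null distribution when both groups have <= `exact_limit` values and no
# ties, normal approximation with tie and continuity correction otherwise.
# Degenerate inputs whose rank variance is zero get p = 1.
wilcox_p_value <- function(x, y, paired = FALSE, exact_limit = 12L) {
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- if (paired) {
    d <- x - y
    any(d == 0) || anyDuplicated(abs(d)) > 0
  } else anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_limit && length(y) <= exact_limit
  p <- suppressWarnings(stats::wilcox.test(
    x, y, paired = paired, exact = exact, correct = TRUE,
    alternative = "two.sided")$p.value)
  if (is.na(p)) 1 else min(1, p)
}

#' Test per-protein differential abundance between tumor and normal samples
#'
#' For each protein with at least `min_per_group` non-missing values in both
#' groups, computes a two-sided Wilcoxon rank-sum p-value (signed-rank over
#' complete matched pairs when `paired = TRUE`), the log2 fold change as the
#' difference of group medians, and Bonferroni-adjusted p-values with the
#' correction factor equal to the number of proteins actually tested.
#' Under-observed proteins are skipped and reported via the `skipped`
#' attribute. Calls are assigned with the default thresholds of
#' [call_differential()].
#'
#' @param m An `AbundanceMatrix`.
#' @param paired Use the signed-rank test on matched pairs (requires a
#'   pairing map) instead of the default rank-sum test on the two groups.
#' @param min_per_group Minimum non-missing values per group (complete pairs
#'   when `paired`).
#' @return A data frame of class `"DifferentialResult"` with columns
#'   `protein`, `log2fc`, `p`, `p_adj`, `call`, `n_tumor_used`,
#'   `n_normal_used`, and attributes `skipped` (protein symbols) and
#'   `n_tested`.
#' @export
test_differential_abundance <- function(m, paired = FALSE,
                                        min_per_group = 3L) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (has_duplicate_symbols(m))
    stop("duplicate protein symbols; run merge_duplicate_symbols first")
  if (paired && is.null(m$pairing))
    stop("paired test requested but the matrix has no pairing map")
  tum <- tumor_values(m)
  nor <- normal_values(m)
  proteins <- rownames(m$values)
  rows <- vector("list", length(proteins))
  skipped <- character(0)
  for (i in seq_along(proteins)) {
    x <- tum[i, ]; y <- nor[i, ]
    if (paired) {
      xp <- tum[i, names(m$pairing)]
      yp <- nor[i, m$pairing]
      ok <- !is.na(xp) & !is.na(yp)
      if (sum(ok) < min_per_group) { skipped <- c(skipped, proteins[i]); next }
      p <- wilcox_p_value(xp[ok], yp[ok], paired = TRUE)
      n_t <- n_n <- sum(ok)
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < min_per_group || length(y) < min_per_group) {
        skipped <- c(skipped, proteins[i]); next
      }
      p <- wilcox_p_value(x, y, paired = FALSE)
      n_t <- length(x); n_n <- length(y)
    }
    rows[[i]] <- data.frame(
      protein = proteins[i],
      log2fc = stats::median(tum[i, ], na.rm = TRUE) -
        stats::median(nor[i, ], na.rm = TRUE),
      p = p, n_tumor_used = n_t, n_normal_used = n_n,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || !nrow(res)) stop("no protein passed the coverage rule")
  m_tested <- nrow(res)
  res$p_adj <- pmin(1, res$p * m_tested)
  res <- res[, c("protein", "log2fc", "p", "p_adj",
                 "n_tumor_used", "n_normal_used")]
  rownames(res) <- NULL
  class(res) <- c("DifferentialResult", "data.frame")
  attr(res, "skipped") <- skipped
  attr(res, "n_tested") <- m_tested
  call_differential(res)
}

#' Assign up/down/unchanged calls to a differential result
#'
#' A protein is called `up` when `log2fc` strictly exceeds `lfc_threshold`
#' and the adjusted p-value is at most `alpha` (the p cutoff is inclusive,
#' the fold-change cutoff strict); `down` mirrors this below
#' `-lfc_threshold`; everything else is `unchanged`.
#'
#' @param result A `DifferentialResult`.
#' @param lfc_threshold Positive log2 fold-change threshold (strict).
#' @param alpha Adjusted-p threshold (inclusive).
#' @return The result with its `call` column (re)computed.
#' @export
call_differential <- function(result, lfc_threshold = 1, alpha = 0.05) {
  stopifnot(inherits(result, "DifferentialResult") ||
              is.data.frame(result))
  if (lfc_threshold <= 0 || alpha <= 0) stop("thresholds must be positive")
  call <- rep("unchanged", nrow(result))
  sig <- result$p_adj <= alpha
  call[sig & result$log2fc > lfc_threshold] <- "up"
  call[sig & result$log2fc < -lfc_threshold] <- "down"
  result$call <- call
  if (!inherits(result, "DifferentialResult"))
    class(result) <- c("DifferentialResult", "data.frame")
  result
}

#' Compare abundance dispersion between tumor and normal samples
#'
#' Computes each protein's standard deviation separately across tumor and
#' across normal samples (proteins need at least two non-missing values in a
#' group to contribute there), then compares the two SD distributions across
#' proteins with a two-sided t-test.
#'
#' @param m An `AbundanceMatrix`.
#' @return List of class `"DispersionComparison"`: `sd_tumor`, `sd_normal`
#'   (named vectors), `mean_sd_tumor`, `mean_sd_normal`, `statistic`, `p`.
#' @export
compare_dispersion <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (sum(m$group == "tumor") < 2 || sum(m$group == "normal") < 2)
    stop("need at least 2 samples per group")
  row_sd <- function(v) apply(v, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::sd(x)
  })
  sd_t <- row_sd(tumor_values(m))
  sd_n <- row_sd(normal_values(m))
  ok <- !is.na(sd_t) & !is.na(sd_n)
  if (sum(ok) < 2) stop("fewer than 2 proteins with SDs in both groups")
  if (stats::sd(sd_t[ok]) == 0 && stats::sd(sd_n[ok]) == 0 &&
      mean(sd_t[ok]) == mean(sd_n[ok])) {
    statistic <- 0; p <- 1
  } else {
    tt <- stats::t.test(sd_t[ok], sd_n[ok])
    statistic <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(sd_tumor = sd_t[ok], sd_normal = sd_n[ok],
                 mean_sd_tumor = mean(sd_t[ok]),
                 mean_sd_normal = mean(sd_n[ok]),
                 statistic = statistic, p = p),
            class = "DispersionComparison")
}

#' @export
print.DispersionComparison <- function(x, ...) {
  cat(sprintf(
    "Dispersion comparison over %d proteins: mean SD tumor %.3f vs normal %.3f (t = %.2f, p = %.3g)\n",
    length(x$sd_tumor), x$mean_sd_tumor, x$mean_sd_normal, x$statistic, x$p))
  invisible(x)
}
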