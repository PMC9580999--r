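## Pairwise OLS of co-structure protein abundances with the copy-number
## dependent-variable rule, and the even-vs-uneven slope comparison
## stratified by correlation sign.

#' Ordinary least squares for one protein pair
#'
#' Fits `y ~ x` over complete paired observations and returns the slope,
#' intercept and the two-sided t-test p-value for the slope coefficient.
#'
#' @param x_values Independent-variable abundances.
#' @param y_values Dependent-variable abundances.
#' @return List with `slope`, `intercept`, `coef_p`, `n`.
#' @export
fit_pair_regression <- function(x_values, y_values) {
  ok <- !is.na(x_values) & !is.na(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  if (length(x) < 3) stop("need at least 3 complete paired observations")
  if (stats::var(x) == 0)
    stop("independent variable has zero variance")
  fit <- stats::lm(y ~ x)
  # a perfect fit triggers a harmless precision warning in summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  coef_p <- if (nrow(sm) < 2 || is.na(sm["x", 4])) 1 else sm["x", 4]
  list(slope = unname(stats::coef(fit)["x"]),
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       coef_p = coef_p, n = length(x))
}

#' Assign the dependent protein of each pair
#'
#' For uneven pairs the dependent variable is the protein with the smaller
#' chain count (taken from the first structure resolving both proteins);
#' for even pairs the lexicographically first protein. Mixed-parity pairs
#' are excluded.
#'
#' @param parity Output of [classify_stoichiometric_parity()].
#' @param st The `StoichiometryTable` the parity was derived from.
#' @return `parity` restricted to non-mixed pairs, with columns
#'   `dependent_protein` and `independent_protein` added.
#' @export
assign_dependent <- function(parity, st) {
  stopifnot(inherits(st, "StoichiometryTable"))
  parity <- parity[parity$parity != "mixed", , drop = FALSE]
  parts <- split_pair_key(parity$pair)
  dep <- character(nrow(parity))
  for (i in seq_len(nrow(parity))) {
    a <- parts$protein_a[i]; b <- parts$protein_b[i]
    if (parity$parity[i] == "even") {
      dep[i] <- a  # keys are lexicographically ordered
      next
    }
    sa <- st[st$protein == a, c("structure_id", "chain_count")]
    sb <- st[st$protein == b, c("structure_id", "chain_count")]
    shared <- intersect(sa$structure_id, sb$structure_id)
    ca <- sa$chain_count[match(shared[1], sa$structure_id)]
    cb <- sb$chain_count[match(shared[1], sb$structure_id)]
    dep[i] <- if (ca < cb) a else b
  }
  parity$dependent_protein <- dep
  parity$independent_protein <- ifelse(dep == parts$protein_a,
                                       parts$protein_b, parts$protein_a)
  parity
}

#' Fit per-pair regressions across tumor samples
#'
#' Regresses each pair's dependent protein on its independent protein over
#' pairwise-complete tumor observations, and joins the Spearman sign from a
#' correlation table of the same cohort. The `retained` flag marks pairs
#' whose slope coefficient is significant at `coef_alpha`; pairs with
#' correlation exactly zero get `rho_sign = "zero"` and are excluded from
#' the stratified comparison.
#'
#' @param m An `AbundanceMatrix` (tumor samples are used).
#' @param assignments Output of [assign_dependent()].
#' @param correlations A `CorrelationTable` for the same cohort (or `NULL`
#'   to compute Spearman on the spot).
#' @param coef_alpha Significance threshold on the slope p-value (strict).
#' @param min_n Minimum complete observations per pair.
#' @return Data frame of class `"PairRegression"` with columns `pair`,
#'   `dependent_protein`, `parity`, `slope`, `intercept`, `coef_p`, `n`,
#'   `rho`, `rho_sign`, `retained`.
#' @export
pair_regressions <- function(m, assignments, correlations = NULL,
                             coef_alpha = 0.05, min_n = 3L) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  tum <- tumor_values(m)
  rows <- list()
  for (i in seq_len(nrow(assignments))) {
    dep <- assignments$dependent_protein[i]
    ind <- assignments$independent_protein[i]
    if (!(dep %in% rownames(tum)) || !(ind %in% rownames(tum))) next
    x <- tum[ind, ]; y <- tum[dep, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n || stats::var(x[ok]) == 0) next
    fit <- fit_pair_regression(x, y)
    rho <- if (!is.null(correlations)) {
      j <- match(assignments$pair[i], correlations$pair)
      if (is.na(j)) NA_real_ else correlations$rho[j]
    } else stats::cor(x[ok], y[ok], method = "spearman")
    if (is.na(rho)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pair = assignments$pair[i], dependent_protein = dep,
      parity = assignments$parity[i], slope = fit$slope,
      intercept = fit$intercept, coef_p = fit$coef_p, n = fit$n,
      rho = rho,
      rho_sign = if (rho > 0) "positive" else if (rho < 0) "negative"
        else "zero",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no pair could be fitted")
  out$retained <- out$coef_p < coef_alpha
  rownames(out) <- NULL
  class(out) <- c("PairRegression", "data.frame")
  out
}

#' Compare regression slopes between even and uneven pairs
#'
#' Restricts to pairs with a significant slope coefficient, then within the
#' positively correlated stratum and within the negatively correlated
#' stratum separately runs a two-sided Wilcoxon rank-sum test of the slopes,
#' even versus uneven.
#'
#' @param regressions A `PairRegression` data frame.
#' @return List with elements `positive` and `negative`; each a
#'   `GroupComparison` (even vs uneven) or a `"NotTestable"` record when a
#'   stratum lacks one of the parity groups.
#' @export
compare_slopes <- function(regressions) {
  stopifnot(is.data.frame(regressions))
  kept <- regressions[regressions$retained &
                        regressions$rho_sign != "zero", , drop = FALSE]
  run_stratum <- function(sgn) {
    sub <- kept[kept$rho_sign == sgn, , drop = FALSE]
    even <- sub$slope[sub$parity == "even"]
    uneven <- sub$slope[sub$parity == "uneven"]
    if (!length(even) || !length(uneven))
      return(structure(list(direction = sgn,
                            reason = "a parity group is empty"),
                       class = "NotTestable"))
    compare_correlation_groups(even, uneven, "even", "uneven")
  }
  list(positive = run_stratum("positive"),
       negative = run_stratum("negative"))
}
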