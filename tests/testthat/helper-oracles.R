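# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, naive set arithmetic, closed
# forms) and never call the implementation paths they check.

# Exhaustive two-sided rank-sum p-value: enumerate every assignment of the
# pooled ranks to group 1 and compare the Mann-Whitney U statistic of the
# observed assignment against the full null distribution.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(length(pooled), n1), 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs))
  min(1, p)
}

# Uncorrected 2x2 chi-square by the hand formula n(ad-bc)^2 / (r1 r2 c1 c2).
oracle_chisq_stat <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  n * (a * d - b * c)^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# Spearman as Pearson on mid-ranks.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

oracle_set_jaccard <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

# Weighted differential-protein draw: members carry `odds_ratio` times the
# selection odds of non-members, n_da proteins drawn without replacement.
draw_da_weighted <- function(universe, members, n_da, odds_ratio) {
  w <- ifelse(universe %in% members, odds_ratio, 1)
  sample(universe, n_da, prob = w)
}

# Small paired tumor/normal matrix fixture.
make_toy_matrix <- function(values, n_tumor, n_normal,
                            proteins = sprintf("G%02d", seq_len(nrow(values)))) {
  colnames(values) <- c(sprintf("T%02d", seq_len(n_tumor)),
                        sprintf("N%02d", seq_len(n_normal)))
  rownames(values) <- proteins
  abundance_matrix(values,
                   c(rep("tumor", n_tumor), rep("normal", n_normal)))
}
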