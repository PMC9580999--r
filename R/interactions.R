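## The five protein-pair classifications: stoichiometric parity from chain
## counts, complex co-occurrence Jaccard, context-specific vs general
## detection, competitive vs cooperative binding from interface overlap on
## shared partners, and curated transient/permanent labels. Each pair is
## annotated independently per class.

#' Classify co-structure pairs by stoichiometric parity
#'
#' Within each structure, a pair of proteins is even when their chain counts
#' are equal (1:1, 2:2, 4:4) and uneven otherwise (2:1, 3:1, 3:2). A pair
#' resolved in several structures keeps the label only when it is consistent
#' across all of them; pairs that are sometimes even and sometimes uneven
#' are labeled `mixed` and are excluded from parity-based comparisons.
#'
#' @param st A `StoichiometryTable`.
#' @return Data frame with columns `pair`, `parity` (`even`/`uneven`/
#'   `mixed`), `n_structures`.
#' @export
classify_stoichiometric_parity <- function(st) {
  stopifnot(inherits(st, "StoichiometryTable"))
  acc <- new.env(parent = emptyenv())
  for (sid in unique(st$structure_id)) {
    sub <- st[st$structure_id == sid, ]
    if (nrow(sub) < 2) next
    for (ij in utils::combn(nrow(sub), 2L, simplify = FALSE)) {
      key <- pair_key(sub$protein[ij[1]], sub$protein[ij[2]])
      lab <- if (sub$chain_count[ij[1]] == sub$chain_count[ij[2]])
        "even" else "uneven"
      acc[[key]] <- c(acc[[key]], lab)
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(pair = character(0), parity = character(0),
                      n_structures = integer(0)))
  parity <- vapply(keys, function(k) {
    labs <- unique(acc[[k]])
    if (length(labs) > 1) "mixed" else labs
  }, "")
  data.frame(pair = keys, parity = unname(parity),
             n_structures = vapply(keys, function(k) length(acc[[k]]), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Co-occurrence Jaccard of protein pairs over a complex catalog
#'
#' For each pair found together in at least one complex, the number of
#' complexes containing both divided by the number of complexes containing
#' at least one — a co-membership frequency normalized for each protein's
#' overall tendency to sit in complexes.
#'
#' @param catalog A `ComplexCatalog`.
#' @return Data frame with columns `pair`, `jaccard`, `n_together`.
#' @export
cooccurrence_jaccard <- function(catalog) {
  stopifnot(inherits(catalog, "ComplexCatalog"))
  prot2cx <- list()
  for (cx in names(catalog))
    for (p in catalog[[cx]])
      prot2cx[[p]] <- c(prot2cx[[p]], cx)
  together <- new.env(parent = emptyenv())
  for (cx in names(catalog)) {
    mem <- sort(catalog[[cx]])
    if (length(mem) < 2) next
    cmb <- utils::combn(mem, 2L)
    for (k in pair_key(cmb[1, ], cmb[2, ]))
      together[[k]] <- TRUE
  }
  keys <- ls(together)
  parts <- split_pair_key(keys)
  jac <- numeric(length(keys))
  n_tog <- integer(length(keys))
  for (i in seq_along(keys)) {
    ca <- prot2cx[[parts$protein_a[i]]]
    cb <- prot2cx[[parts$protein_b[i]]]
    n_tog[i] <- length(intersect(ca, cb))
    jac[i] <- n_tog[i] / length(union(ca, cb))
  }
  data.frame(pair = keys, jaccard = jac, n_together = n_tog,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify interactions as general or context-specific
#'
#' Restricted to interactions whose bait was targeted in both cell lines,
#' an interaction is `general` when detected in both lines and
#' `context_specific` when detected in exactly one. Interactions whose bait
#' was targeted in only one line are `unknown` (excluded from comparisons).
#'
#' @param ix An `InteractionSet`.
#' @param cell_lines The two cell lines to compare (defaults to the set
#'   declared on `ix`).
#' @return Data frame with columns `pair`, `context`.
#' @export
classify_context <- function(ix, cell_lines = NULL) {
  stopifnot(inherits(ix, "InteractionSet"))
  if (is.null(cell_lines)) cell_lines <- attr(ix, "cell_lines")
  if (length(cell_lines) != 2) stop("exactly two cell lines are required")
  context <- vapply(seq_len(nrow(ix)), function(i) {
    bait <- ix$bait_cell_lines[[i]]
    if (!all(cell_lines %in% bait)) return("unknown")
    det <- intersect(ix$cell_lines_detected[[i]], cell_lines)
    if (length(det) == 2) "general"
    else if (length(det) == 1) "context_specific"
    else "unknown"
  }, "")
  data.frame(pair = ix$pair, context = context, stringsAsFactors = FALSE)
}

#' Jaccard overlap of two interface-residue sets
#'
#' `|A intersect B| / |A union B|` over residue indices. If exactly one set
#' is empty the overlap is 0; two empty sets leave the index undefined and
#' raise an error.
#'
#' @param site_a,site_b Integer vectors of residue indices.
#' @return The Jaccard index in [0, 1].
#' @export
interface_jaccard <- function(site_a, site_b) {
  site_a <- unique(site_a[!is.na(site_a)])
  site_b <- unique(site_b[!is.na(site_b)])
  if (!length(site_a) && !length(site_b))
    stop("interface Jaccard undefined for two empty residue sets")
  if (!length(site_a) || !length(site_b)) return(0)
  length(intersect(site_a, site_b)) / length(union(site_a, site_b))
}

# Interactions with interface data on both sides, unrolled to one row per
# (protein, partner) direction with the residue set on the *partner* side --
# i.e. protein's binding site on the partner.
two_sided_interface_edges <- function(ix) {
  has_both <- vapply(seq_len(nrow(ix)), function(i)
    !anyNA(ix$interface_a[[i]]) && !anyNA(ix$interface_b[[i]]), logical(1))
  idx <- which(has_both)
  if (!length(idx))
    return(data.frame(protein = character(0), partner = character(0)))
  edges <- data.frame(
    protein = c(ix$protein_a[idx], ix$protein_b[idx]),
    partner = c(ix$protein_b[idx], ix$protein_a[idx]),
    stringsAsFactors = FALSE)
  # the site of protein_a sits on protein_b, i.e. interface_b, and vice versa
  edges$site_on_partner <- c(ix$interface_b[idx], ix$interface_a[idx])
  edges
}

#' Classify shared-partner pairs as competitive or cooperative
#'
#' Interactions lacking interface data on either side are filtered out
#' first. For every pair of proteins sharing at least one common partner
#' (with their binding sites on that partner known), the binding similarity
#' is the interface Jaccard of the two sites; with several common partners
#' the highest Jaccard counts. Pairs at or above `threshold` are
#' `competitive`, the rest `cooperative`.
#'
#' @param ix An `InteractionSet`.
#' @param threshold Jaccard threshold (inclusive on the competitive side).
#' @return Data frame with columns `pair`, `competition`,
#'   `competition_jaccard`, `best_partner`.
#' @export
classify_competition <- function(ix, threshold = 0.1) {
  stopifnot(inherits(ix, "InteractionSet"))
  edges <- two_sided_interface_edges(ix)
  if (!nrow(edges))
    return(data.frame(pair = character(0), competition = character(0),
                      competition_jaccard = numeric(0),
                      best_partner = character(0)))
  out <- list()
  for (partner in unique(edges$partner)) {
    sub <- edges[edges$partner == partner, ]
    if (nrow(sub) < 2) next
    for (ij in utils::combn(nrow(sub), 2L, simplify = FALSE)) {
      a <- sub$protein[ij[1]]; b <- sub$protein[ij[2]]
      if (a == b) next
      jac <- interface_jaccard(sub$site_on_partner[[ij[1]]],
                               sub$site_on_partner[[ij[2]]])
      key <- pair_key(a, b)
      prev <- out[[key]]
      if (is.null(prev) || jac > prev$jac)
        out[[key]] <- list(jac = jac, partner = partner)
    }
  }
  if (!length(out))
    return(data.frame(pair = character(0), competition = character(0),
                      competition_jaccard = numeric(0),
                      best_partner = character(0)))
  keys <- names(out)
  jac <- vapply(out, function(x) x$jac, 0)
  data.frame(pair = keys,
             competition = ifelse(jac >= threshold, "competitive",
                                  "cooperative"),
             competition_jaccard = unname(jac),
             best_partner = vapply(out, function(x) x$partner, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Curate transient/permanent labels from raw literature tables
#'
#' Keeps human heterodimers, deduplicates unordered pairs across sources,
#' and resolves conflicting labels for the same pair to `unknown` with a
#' warning.
#'
#' @param tables List of data frames with columns `protein_a`, `protein_b`,
#'   `stability_label` (`transient`/`permanent`), `species`, `composition`
#'   (`heterodimer`/`homodimer`/...).
#' @return Data frame with columns `pair`, `stability`.
#' @export
curate_stability_labels <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  raw <- do.call(rbind, lapply(tables, function(t)
    t[, c("protein_a", "protein_b", "stability_label", "species",
          "composition")]))
  raw <- raw[raw$species == "human" & raw$composition == "heterodimer" &
               raw$protein_a != raw$protein_b, , drop = FALSE]
  if (!nrow(raw))
    return(data.frame(pair = character(0), stability = character(0)))
  raw$pair <- pair_key(raw$protein_a, raw$protein_b)
  labels <- tapply(raw$stability_label, raw$pair,
                   function(x) unique(as.character(x)))
  conflicted <- names(labels)[lengths(labels) > 1]
  if (length(conflicted))
    warning("conflicting stability labels set to unknown for: ",
            paste(conflicted, collapse = ", "))
  stability <- vapply(labels, function(x)
    if (length(x) > 1) "unknown" else x, "")
  data.frame(pair = names(stability), stability = unname(stability),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the per-pair annotation table
#'
#' Full outer merge of the five classification outputs on the canonical pair
#' key; classes missing for a pair are `unknown` (`NA` for the numeric
#' Jaccard columns).
#'
#' @param parity Output of [classify_stoichiometric_parity()] (or `NULL`).
#' @param cooccurrence Output of [cooccurrence_jaccard()] (or `NULL`).
#' @param context Output of [classify_context()] (or `NULL`).
#' @param competition Output of [classify_competition()] (or `NULL`).
#' @param stability Output of [curate_stability_labels()] (or `NULL`).
#' @return Data frame of class `"PairAnnotation"` with columns `pair`,
#'   `stoich_parity`, `cooccurrence_jaccard`, `context`, `competition`,
#'   `competition_jaccard`, `stability`.
#' @export
annotate_pairs <- function(parity = NULL, cooccurrence = NULL,
                           context = NULL, competition = NULL,
                           stability = NULL) {
  keys <- unique(c(if (!is.null(parity)) parity$pair,
                   if (!is.null(cooccurrence)) cooccurrence$pair,
                   if (!is.null(context)) context$pair,
                   if (!is.null(competition)) competition$pair,
                   if (!is.null(stability)) stability$pair))
  if (!length(keys)) stop("no pairs to annotate")
  out <- data.frame(pair = sort(keys), stringsAsFactors = FALSE)
  pull <- function(tab, col, default) {
    if (is.null(tab)) return(rep(default, nrow(out)))
    v <- tab[[col]][match(out$pair, tab$pair)]
    if (is.character(default)) v[is.na(v)] <- default
    v
  }
  out$stoich_parity <- pull(parity, "parity", "unknown")
  out$cooccurrence_jaccard <- pull(cooccurrence, "jaccard", NA_real_)
  out$context <- pull(context, "context", "unknown")
  out$competition <- pull(competition, "competition", "unknown")
  out$competition_jaccard <- pull(competition, "competition_jaccard",
                                  NA_real_)
  out$stability <- pull(stability, "stability", "unknown")
  class(out) <- c("PairAnnotation", "data.frame")
  out
}
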