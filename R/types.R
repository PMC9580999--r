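#' Construct an abundance matrix with sample annotation
#'
#' The central data container of the package: a proteins-by-samples matrix of
#' log2 abundances together with a tumor/normal label per sample and an
#' optional tumor-to-normal pairing map. Missing quantifications are stored as
#' `NA`, never as zero.
#'
#' @param values Numeric matrix, rows = proteins (rownames are gene symbols),
#'   columns = samples (colnames are sample identifiers). Duplicate row
#'   symbols are tolerated at construction (they arise in raw exports and are
#'   resolved by [merge_duplicate_symbols()]); duplicate column identifiers
#'   are an error.
#' @param group Character vector of length `ncol(values)` (or named by sample
#'   identifier) with values `"tumor"` or `"normal"`.
#' @param pairing Optional named character vector mapping tumor sample
#'   identifiers (names) to their matched normal sample identifiers (values).
#'   Must be a bijection between a subset of the tumor samples and a subset of
#'   the normal samples.
#' @return An object of class `"AbundanceMatrix"`: a list with elements
#'   `values`, `group` (named by sample) and `pairing`.
#' @seealso [read_abundance_matrix()], [merge_duplicate_symbols()]
#' @export
abundance_matrix <- function(values, group, pairing = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  samples <- colnames(values)
  if (!is.null(names(group))) {
    missing_grp <- setdiff(samples, names(group))
    if (length(missing_grp))
      stop("samples missing from group annotation: ",
           paste(missing_grp, collapse = ", "))
    group <- group[samples]
  } else {
    if (length(group) != length(samples))
      stop("'group' must have one label per sample")
    names(group) <- samples
  }
  group <- as.character(group)
  names(group) <- samples
  bad <- setdiff(unique(group), c("tumor", "normal"))
  if (length(bad))
    stop("group labels must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  if (!is.null(pairing)) {
    if (is.null(names(pairing)))
      stop("'pairing' must be named by tumor sample identifier")
    if (!all(names(pairing) %in% samples[group == "tumor"]))
      stop("pairing names must be tumor samples")
    if (!all(pairing %in% samples[group == "normal"]))
      stop("pairing values must be normal samples")
    if (anyDuplicated(names(pairing)) || anyDuplicated(pairing))
      stop("pairing must be a bijection (no duplicated samples)")
  }
  structure(list(values = values, group = group, pairing = pairing),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (has_duplicate_symbols(x))
    cat("  note: duplicate protein symbols present (run merge_duplicate_symbols)\n")
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

#' Test for duplicate protein symbols
#'
#' @param m An `AbundanceMatrix`.
#' @return `TRUE` if two or more rows share a protein symbol.
#' @export
has_duplicate_symbols <- function(m) {
  anyDuplicated(rownames(m$values)) > 0
}

#' Subset the tumor columns of an abundance matrix
#'
#' @param m An `AbundanceMatrix`.
#' @return Numeric matrix restricted to tumor samples.
#' @export
tumor_values <- function(m) m$values[, m$group == "tumor", drop = FALSE]

#' Subset the normal columns of an abundance matrix
#'
#' @param m An `AbundanceMatrix`.
#' @return Numeric matrix restricted to normal samples.
#' @export
normal_values <- function(m) m$values[, m$group == "normal", drop = FALSE]

#' Construct a complex catalog
#'
#' A catalog maps complex identifiers to member sets of protein symbols, in
#' the style of CORUM. Complexes with fewer than two distinct members are not
#' representable (a complex is by definition multimeric here).
#'
#' @param members Named list; each element a character vector of member gene
#'   symbols. Duplicates within a complex are removed.
#' @param provenance Character tag recording where the catalog came from.
#' @return An object of class `"ComplexCatalog"`: the named list of member
#'   sets with a `provenance` attribute.
#' @export
complex_catalog <- function(members, provenance = "unspecified") {
  if (!is.list(members) || is.null(names(members)) ||
      anyDuplicated(names(members)))
    stop("'members' must be a list uniquely named by complex identifier")
  members <- lapply(members, function(x) unique(trimws(as.character(x))))
  sizes <- lengths(members)
  if (any(sizes < 2))
    stop("complexes with <2 distinct members: ",
         paste(names(members)[sizes < 2], collapse = ", "))
  structure(members, class = "ComplexCatalog", provenance = provenance)
}

#' @export
print.ComplexCatalog <- function(x, ...) {
  cat(sprintf("ComplexCatalog: %d complexes, %d distinct proteins (provenance: %s)\n",
              length(x), length(unique(unlist(x))), attr(x, "provenance")))
  invisible(x)
}

#' All proteins appearing in a complex catalog
#'
#' @param catalog A `ComplexCatalog`.
#' @return Character vector of distinct member symbols, sorted.
#' @export
catalog_proteins <- function(catalog) sort(unique(unlist(catalog)))

#' Construct a stoichiometry table
#'
#' Records, per resolved structure and protein, how many chains of that
#' protein the structure contains. Chain-count ratios between co-resolved
#' proteins define the stoichiometric parity used by
#' [classify_stoichiometric_parity()].
#'
#' @param structure_id Character vector of structure identifiers.
#' @param protein Character vector of gene symbols.
#' @param chain_count Positive integer vector of chain counts.
#' @return Data frame of class `"StoichiometryTable"` with the three columns.
#' @export
stoichiometry_table <- function(structure_id, protein, chain_count) {
  structure_id <- as.character(structure_id)
  protein <- as.character(protein)
  if (!length(structure_id) ||
      length(protein) != length(structure_id) ||
      length(chain_count) != length(structure_id))
    stop("columns must be non-empty and of equal length")
  if (any(is.na(chain_count)) || any(chain_count < 1) ||
      any(chain_count != round(chain_count)))
    stop("chain_count must be positive integers")
  df <- data.frame(structure_id = structure_id, protein = protein,
                   chain_count = as.integer(chain_count),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("structure_id", "protein")]))
    stop("(structure_id, protein) rows must be unique")
  class(df) <- c("StoichiometryTable", "data.frame")
  df
}

#' Canonical unordered pair keys
#'
#' Protein pairs are keyed by the lexicographically ordered pair of symbols so
#' that (A, B) and (B, A) address the same record everywhere in the package.
#'
#' @param a,b Character vectors of protein symbols (recycled to equal length).
#' @return Character vector of keys `"<first>|<second>"`.
#' @export
pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) stop("self-pairs are not valid pair keys")
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Split canonical pair keys back into symbols
#'
#' @param key Character vector of keys produced by [pair_key()].
#' @return Data frame with columns `protein_a` and `protein_b`
#'   (lexicographically ordered).
#' @export
split_pair_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(protein_a = vapply(parts, `[`, "", 1L),
             protein_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct an interaction set
#'
#' Binary protein interactions with optional per-cell-line detection and bait
#' flags, optional interface-residue sets on either side, and an optional
#' stability label. Pairs are canonicalized with [pair_key()]; each unordered
#' pair appears at most once.
#'
#' @param protein_a,protein_b Character vectors of interacting symbols
#'   (self-interactions are rejected).
#' @param cell_lines_detected List of character vectors (which declared cell
#'   lines detected the interaction), or `NULL`.
#' @param bait_cell_lines List of character vectors (in which cell lines the
#'   bait protein of this interaction was targeted), or `NULL`.
#' @param interface_a,interface_b Lists of integer vectors of interface
#'   residue indices (on protein_a / protein_b side after canonical
#'   reordering), or `NULL`. `NA` entries mean "no interface data".
#' @param stability_label Character vector in `{"transient", "permanent",
#'   "unlabeled"}`, or `NULL` (all unlabeled).
#' @param cell_lines Character vector declaring the universe of cell lines.
#' @return Data frame of class `"InteractionSet"` with list-columns for the
#'   set-valued fields and a `cell_lines` attribute.
#' @export
interaction_set <- function(protein_a, protein_b,
                            cell_lines_detected = NULL,
                            bait_cell_lines = NULL,
                            interface_a = NULL, interface_b = NULL,
                            stability_label = NULL,
                            cell_lines = c("293T", "HCT116")) {
  protein_a <- as.character(protein_a); protein_b <- as.character(protein_b)
  n <- length(protein_a)
  if (length(protein_b) != n) stop("protein columns must have equal length")
  if (any(protein_a == protein_b)) stop("self-interactions are not allowed")
  swap <- protein_a > protein_b
  empty_sets <- function(proto) rep(list(proto), n)
  if (is.null(cell_lines_detected)) cell_lines_detected <- empty_sets(character(0))
  if (is.null(bait_cell_lines)) bait_cell_lines <- empty_sets(character(0))
  if (is.null(interface_a)) interface_a <- empty_sets(NA_integer_)
  if (is.null(interface_b)) interface_b <- empty_sets(NA_integer_)
  if (is.null(stability_label)) stability_label <- rep("unlabeled", n)
  if (any(swap)) {
    tmp <- protein_a[swap]; protein_a[swap] <- protein_b[swap]; protein_b[swap] <- tmp
    tmpi <- interface_a[swap]; interface_a[swap] <- interface_b[swap]
    interface_b[swap] <- tmpi
  }
  check_iface <- function(s) {
    lapply(s, function(r) {
      if (length(r) == 1 && is.na(r[1])) return(NA_integer_)
      r <- sort(unique(as.integer(r)))
      if (any(r < 1)) stop("residue indices must be positive integers")
      r
    })
  }
  interface_a <- check_iface(interface_a)
  interface_b <- check_iface(interface_b)
  bad <- setdiff(unlist(cell_lines_detected), cell_lines)
  if (length(bad))
    stop("undeclared cell lines in detection flags: ", paste(bad, collapse = ", "))
  stopifnot(all(stability_label %in% c("transient", "permanent", "unlabeled")))
  key <- pair_key(protein_a, protein_b)
  if (anyDuplicated(key))
    stop("duplicate unordered pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df <- data.frame(pair = key, protein_a = protein_a, protein_b = protein_b,
                   stability_label = stability_label, stringsAsFactors = FALSE)
  df$cell_lines_detected <- cell_lines_detected
  df$bait_cell_lines <- bait_cell_lines
  df$interface_a <- interface_a
  df$interface_b <- interface_b
  attr(df, "cell_lines") <- cell_lines
  class(df) <- c("InteractionSet", "data.frame")
  df
}

#' @export
print.InteractionSet <- function(x, ...) {
  cat(sprintf("InteractionSet: %d interactions, %d proteins; cell lines: %s\n",
              nrow(x), length(unique(c(x$protein_a, x$protein_b))),
              paste(attr(x, "cell_lines"), collapse = ", ")))
  with_if <- sum(vapply(seq_len(nrow(x)), function(i)
    !anyNA(x$interface_a[[i]]) && !anyNA(x$interface_b[[i]]), logical(1)))
  cat(sprintf("  with two-sided interface data: %d; stability labels: %d\n",
              with_if, sum(x$stability_label != "unlabeled")))
  invisible(x)
}
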