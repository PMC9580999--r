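## Tabular I/O. Everything is TSV with "NA" as the missing token, so one
## parser path serves all four table kinds; writers and readers round-trip.

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = NA, comment.char = "")
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
}

#' Read an abundance matrix with its sample sheet
#'
#' The matrix file is TSV with a `protein` first column and one column per
#' sample; the sample sheet is TSV with columns `sample_id`, `group`
#' (tumor/normal) and optionally `paired_normal` (the matched normal sample
#' of a tumor sample; empty or NA where unmatched). Cells "NA" parse as
#' missing values, not zero; row and column order is preserved. Duplicate
#' protein symbols are accepted (and flagged for
#' [merge_duplicate_symbols()]); duplicate sample identifiers are an error,
#' as is a matrix sample absent from the sheet.
#'
#' @param path Path to the matrix TSV.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, sample_sheet) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifier in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  tab <- read_tsv_strict(path)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1]])
  colnames(values) <- samples
  sheet <- read_tsv_strict(sample_sheet)
  if (!all(c("sample_id", "group") %in% names(sheet)))
    stop("sample sheet must have 'sample_id' and 'group' columns")
  missing_samples <- setdiff(samples, sheet$sample_id)
  if (length(missing_samples))
    stop("samples in matrix absent from sample sheet: ",
         paste(missing_samples, collapse = ", "))
  sheet <- sheet[match(samples, sheet$sample_id), ]
  group <- sheet$group
  names(group) <- sheet$sample_id
  pairing <- NULL
  if ("paired_normal" %in% names(sheet)) {
    has_pair <- !is.na(sheet$paired_normal) & nzchar(sheet$paired_normal)
    if (any(has_pair)) {
      pairing <- sheet$paired_normal[has_pair]
      names(pairing) <- sheet$sample_id[has_pair]
    }
  }
  abundance_matrix(values, group, pairing)
}

#' Write an abundance matrix and its sample sheet
#'
#' Inverse of [read_abundance_matrix()]; values are written in full precision
#' so that write-then-read reproduces the matrix exactly.
#'
#' @param m An `AbundanceMatrix`.
#' @param path,sample_sheet Output paths for the matrix and sheet TSVs.
#' @return Invisibly, `m`.
#' @export
write_abundance_matrix <- function(m, path, sample_sheet) {
  df <- data.frame(protein = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  write_tsv_plain(df, path)
  paired <- rep(NA_character_, ncol(m$values))
  if (!is.null(m$pairing))
    paired[match(names(m$pairing), colnames(m$values))] <- m$pairing
  sheet <- data.frame(sample_id = colnames(m$values),
                      group = unname(m$group),
                      paired_normal = paired, stringsAsFactors = FALSE)
  write_tsv_plain(sheet, sample_sheet)
  invisible(m)
}

#' Read a complex catalog
#'
#' TSV with columns `complex_id` and `subunits` (semicolon-separated gene
#' symbols). Subunit strings are split, trimmed and deduplicated per complex;
#' complexes left with fewer than two distinct subunits are skipped with a
#' warning (their count is available as attribute `n_skipped`).
#'
#' @param path Path to the TSV.
#' @param provenance Provenance tag stored on the catalog.
#' @return A [complex_catalog()].
#' @export
read_complex_catalog <- function(path, provenance = basename(path)) {
  tab <- read_tsv_strict(path)
  if (!all(c("complex_id", "subunits") %in% names(tab)))
    stop("catalog must have 'complex_id' and 'subunits' columns")
  members <- lapply(strsplit(as.character(tab$subunits), ";", fixed = TRUE),
                    function(x) unique(trimws(x[nzchar(trimws(x))])))
  names(members) <- as.character(tab$complex_id)
  singleton <- lengths(members) < 2
  if (any(singleton)) {
    warning(sum(singleton), " complex(es) with <2 distinct subunits skipped: ",
            paste(names(members)[singleton], collapse = ", "))
    members <- members[!singleton]
  }
  out <- complex_catalog(members, provenance = provenance)
  attr(out, "n_skipped") <- sum(singleton)
  out
}

#' Write a complex catalog
#'
#' @param catalog A `ComplexCatalog`.
#' @param path Output TSV path.
#' @return Invisibly, `catalog`.
#' @export
write_complex_catalog <- function(catalog, path) {
  df <- data.frame(complex_id = names(catalog),
                   subunits = vapply(catalog, paste, "", collapse = ";"),
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(catalog)
}

#' Read a stoichiometry table
#'
#' TSV with columns `structure_id`, `protein`, `chain_count`.
#'
#' @param path Path to the TSV.
#' @return A [stoichiometry_table()].
#' @export
read_stoichiometry_table <- function(path) {
  tab <- read_tsv_strict(path)
  if (!all(c("structure_id", "protein", "chain_count") %in% names(tab)))
    stop("stoichiometry table must have structure_id, protein, chain_count")
  stoichiometry_table(tab$structure_id, tab$protein, tab$chain_count)
}

#' Write a stoichiometry table
#'
#' @param st A `StoichiometryTable`.
#' @param path Output TSV path.
#' @return Invisibly, `st`.
#' @export
write_stoichiometry_table <- function(st, path) {
  write_tsv_plain(as.data.frame(st), path)
  invisible(st)
}

parse_residue_list <- function(s, row_label) {
  if (is.na(s) || !nzchar(s)) return(NA_integer_)
  parts <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  vals <- suppressWarnings(as.integer(parts))
  if (anyNA(vals) || any(as.character(vals) != parts))
    stop("non-integer residue index in row ", row_label, ": '", s, "'")
  sort(unique(vals))
}

#' Read and merge interaction tables into one interaction set
#'
#' Three sources, merged on the unordered protein pair: an interactions TSV
#' (`protein_a`, `protein_b`, optional `cell_lines_detected` and
#' `bait_cell_lines` as comma-separated lists), an interface TSV
#' (`protein_a`, `protein_b`, `residues_a`, `residues_b` as comma-separated
#' positive integers), and a stability TSV (`protein_a`, `protein_b`,
#' `stability_label`). The interactions file may itself carry any of the
#' optional columns, so a merged set written by [write_interaction_set()]
#' round-trips through the `interactions` slot alone. A pair labeled both
#' transient and permanent becomes `unlabeled` with a warning; a non-integer
#' residue entry is a hard error naming the offending row.
#'
#' @param paths Named list with elements `interactions` (required),
#'   `interfaces` and `stability` (optional paths).
#' @param cell_lines Declared universe of cell lines.
#' @return An [interaction_set()].
#' @export
read_interaction_tables <- function(paths,
                                    cell_lines = c("293T", "HCT116")) {
  if (is.character(paths)) paths <- list(interactions = paths)
  if (is.null(paths$interactions)) stop("an 'interactions' path is required")
  ints <- read_tsv_strict(paths$interactions)
  split_cl <- function(col) {
    if (is.null(col)) return(NULL)
    lapply(as.character(col), function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  }
  key <- pair_key(ints$protein_a, ints$protein_b)
  if (anyDuplicated(key))
    stop("duplicate unordered pairs in interactions file: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  swap <- ints$protein_a > ints$protein_b
  rec <- list(
    protein_a = ifelse(swap, ints$protein_b, ints$protein_a),
    protein_b = ifelse(swap, ints$protein_a, ints$protein_b),
    detected = split_cl(ints$cell_lines_detected),
    bait = split_cl(ints$bait_cell_lines),
    iface_a = rep(list(NA_integer_), nrow(ints)),
    iface_b = rep(list(NA_integer_), nrow(ints)),
    stability = if (!is.null(ints$stability_label))
      ifelse(is.na(ints$stability_label), "unlabeled", ints$stability_label)
      else rep("unlabeled", nrow(ints)))
  if (!is.null(ints$residues_a)) {
    ra <- lapply(seq_len(nrow(ints)), function(i)
      parse_residue_list(as.character(ints$residues_a[i]), i))
    rb <- lapply(seq_len(nrow(ints)), function(i)
      parse_residue_list(as.character(ints$residues_b[i]), i))
    rec$iface_a <- ra
    rec$iface_b <- rb
    rec$iface_a[swap] <- rb[swap]
    rec$iface_b[swap] <- ra[swap]
  }
  names(rec$iface_a) <- names(rec$iface_b) <- NULL
  idx <- seq_along(key)
  names(idx) <- key
  if (!is.null(paths$interfaces)) {
    ifc <- read_tsv_strict(paths$interfaces)
    for (i in seq_len(nrow(ifc))) {
      a <- ifc$protein_a[i]; b <- ifc$protein_b[i]
      ra <- parse_residue_list(as.character(ifc$residues_a[i]), i)
      rb <- parse_residue_list(as.character(ifc$residues_b[i]), i)
      if (a > b) { tmp <- ra; ra <- rb; rb <- tmp }
      j <- idx[pair_key(a, b)]
      if (is.na(j)) next  # interface rows for undetected pairs are ignored
      rec$iface_a[[j]] <- ra
      rec$iface_b[[j]] <- rb
    }
  }
  if (!is.null(paths$stability)) {
    stb <- read_tsv_strict(paths$stability)
    for (i in seq_len(nrow(stb))) {
      j <- idx[pair_key(stb$protein_a[i], stb$protein_b[i])]
      if (is.na(j)) next
      lab <- stb$stability_label[i]
      cur <- rec$stability[j]
      if (cur == "unlabeled") {
        rec$stability[j] <- lab
      } else if (cur != lab) {
        warning("conflicting stability labels for pair ",
                pair_key(stb$protein_a[i], stb$protein_b[i]),
                "; set to unlabeled")
        rec$stability[j] <- "unlabeled"
      }
    }
  }
  interaction_set(rec$protein_a, rec$protein_b,
                  cell_lines_detected = rec$detected,
                  bait_cell_lines = rec$bait,
                  interface_a = rec$iface_a, interface_b = rec$iface_b,
                  stability_label = rec$stability, cell_lines = cell_lines)
}

#' Write an interaction set as a single merged TSV
#'
#' @param ix An `InteractionSet`.
#' @param path Output TSV path.
#' @return Invisibly, `ix`.
#' @export
write_interaction_set <- function(ix, path) {
  fmt_set <- function(col, sep) vapply(col, function(x) {
    if (length(x) == 1 && is.na(x[1])) NA_character_
    else paste(x, collapse = sep)
  }, "")
  df <- data.frame(protein_a = ix$protein_a, protein_b = ix$protein_b,
                   cell_lines_detected = fmt_set(ix$cell_lines_detected, ","),
                   bait_cell_lines = fmt_set(ix$bait_cell_lines, ","),
                   residues_a = fmt_set(ix$interface_a, ","),
                   residues_b = fmt_set(ix$interface_b, ","),
                   stability_label = ix$stability_label,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
  invisible(ix)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each table as `<name>.tsv` (fixed column order as given, numeric
#' columns at 6 significant digits, missing values as "NA") plus a
#' `manifest.json` recording the input descriptions, parameters, seed and
#' package version. Given identical tables and seed the output bytes are
#' identical — no timestamps are recorded.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param inputs Named list or character vector describing the inputs used.
#' @param params Named list of parameters to record.
#' @param seed The seed the run used.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(tables, out_dir, inputs = list(), params = list(),
                          seed = NULL) {
  if (!length(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to output directory: ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_plain(df, f)
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "coabundance",
    version = as.character(utils::packageVersion("coabundance")),
    seed = seed, inputs = inputs, params = params,
    tables = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
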