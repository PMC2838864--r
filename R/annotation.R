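#' Describe the column layout of a platform annotation file
#'
#' Affymetrix-style annotation files name their columns inconsistently across
#' platforms and releases. A dialect names the columns holding the probeset
#' identifier, the gene symbol, and (optionally) a negative-strand-matching
#' probeset (NSMP) indicator. NSMP status may instead be supplied as an
#' explicit identifier list (`nsmp_ids`), since public annotation files encode
#' strand evidence inconsistently; when both are given the union is flagged.
#'
#' @param probeset_col column holding the probeset identifier.
#' @param symbol_col column holding the gene symbol.
#' @param nsmp_col optional column holding a logical/0-1/yes-no NSMP flag.
#' @param nsmp_ids optional character vector of probeset ids to flag as NSMP.
#' @param sequence_col optional column holding the probeset target sequence.
#' @param unannotated_markers symbol values treated as "no annotation".
#' @return an object of class `annotation_dialect`.
#' @export
annotation_dialect <- function(probeset_col = "Probe Set ID",
                               symbol_col = "Gene Symbol",
                               nsmp_col = NULL,
                               nsmp_ids = NULL,
                               sequence_col = "Target Sequence",
                               unannotated_markers = c("---", "", "NA")) {
  structure(list(probeset_col = probeset_col,
                 symbol_col = symbol_col,
                 nsmp_col = nsmp_col,
                 nsmp_ids = nsmp_ids,
                 sequence_col = sequence_col,
                 unannotated_markers = unannotated_markers),
            class = "annotation_dialect")
}

#' Read a platform annotation file
#'
#' Parses a CSV/TSV platform annotation file (quoted fields allowed, comment
#' lines starting with `#` skipped) into one record per probeset. Rows whose
#' symbol is an unannotated marker (`---`, empty, `NA`) get `NA` as
#' `gene_symbol`. Multi-symbol cells such as `"A /// B"` are reduced to their
#' first symbol.
#'
#' @param path path to the annotation file.
#' @param dialect an [annotation_dialect()] describing the columns.
#' @return a data frame of class `probeset_annotation` with columns
#'   `probeset_id`, `gene_symbol` (`NA` when unannotated), `is_nsmp`, and
#'   `target_sequence` (`NA` when absent).
#' @export
read_annotation <- function(path, dialect = annotation_dialect()) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  for (col in c(dialect$probeset_col, dialect$symbol_col)) {
    if (!col %in% names(df)) {
      stopf("annotation file %s lacks required column '%s'", path, col)
    }
  }
  if (!is.null(dialect$nsmp_col) && !dialect$nsmp_col %in% names(df)) {
    stopf("annotation file %s lacks NSMP column '%s'", path, dialect$nsmp_col)
  }
  ids <- trimws(df[[dialect$probeset_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stopf("duplicate probeset ids in %s: %s", path,
          paste(utils::head(dup, 10), collapse = ", "))
  }
  sym <- trimws(df[[dialect$symbol_col]])
  sym[sym %in% dialect$unannotated_markers] <- NA_character_
  multi <- grepl("///", sym)
  if (any(multi, na.rm = TRUE)) {
    message(sum(multi, na.rm = TRUE),
            " multi-symbol annotation cells reduced to their first symbol")
    sym <- trimws(sub("\\s*///.*$", "", sym))
  }
  is_nsmp <- rep(FALSE, length(ids))
  if (!is.null(dialect$nsmp_col)) {
    raw <- tolower(trimws(df[[dialect$nsmp_col]]))
    is_nsmp <- raw %in% c("true", "t", "1", "yes", "y")
  }
  if (!is.null(dialect$nsmp_ids)) {
    is_nsmp <- is_nsmp | ids %in% dialect$nsmp_ids
  }
  seqs <- rep(NA_character_, length(ids))
  if (!is.null(dialect$sequence_col) && dialect$sequence_col %in% names(df)) {
    seqs <- trimws(df[[dialect$sequence_col]])
    seqs[seqs == ""] <- NA_character_
  }
  out <- data.frame(probeset_id = ids, gene_symbol = sym, is_nsmp = is_nsmp,
                    target_sequence = seqs, stringsAsFactors = FALSE)
  class(out) <- c("probeset_annotation", "data.frame")
  out
}

# guess the field separator from the first non-comment line
sniff_sep <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stopf("annotation file %s is empty", path)
    if (!startsWith(line, "#")) break
  }
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Group probesets by gene symbol
#'
#' Partitions annotated, non-NSMP probesets into per-gene groups. Genes with
#' at least two probesets are the ones eligible for isoform testing
#' downstream. Grouping is deterministic: probeset order within a group
#' follows the input record order, groups are sorted by gene symbol.
#'
#' @param records a `probeset_annotation` data frame.
#' @return a named list of character vectors (probeset ids per gene symbol).
#' @export
group_by_gene <- function(records) {
  keep <- !records$is_nsmp & !is.na(records$gene_symbol)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0) return(structure(list(), names = character(0)))
  groups <- split(r$probeset_id, r$gene_symbol)
  groups[order(names(groups))]
}

#' Summarize SplicerAV-relevant features of a platform
#'
#' Computes, over the raw annotation (NSMP flags are a filtering concern, not
#' an annotation one): the number of unique annotated genes, how many are
#' interrogated by multiple probesets, the fraction they represent, the mean
#' probeset count among those multi-probeset genes, and the unannotated and
#' total probeset counts.
#'
#' @param records a `probeset_annotation` data frame.
#' @return a list of class `platform_summary`.
#' @export
summarize_platform <- function(records) {
  sizes <- table(records$gene_symbol[!is.na(records$gene_symbol)])
  n_genes <- length(sizes)
  multi <- sizes[sizes >= 2]
  n_multi <- length(multi)
  if (n_genes == 0) {
    warnf("no annotated probesets; fraction of multi-probeset genes reported as 0")
    frac <- 0
  } else {
    frac <- n_multi / n_genes
  }
  avg <- if (n_multi > 0) mean(multi) else 0
  structure(list(n_unique_genes = n_genes,
                 n_multiprobeset_genes = n_multi,
                 fraction_multiprobeset = frac,
                 avg_probesets_per_multiprobeset_gene = avg,
                 n_unannotated_probesets = sum(is.na(records$gene_symbol)),
                 n_total_probesets = nrow(records)),
            class = "platform_summary")
}

#' @export
print.platform_summary <- function(x, ...) {
  cat("Platform summary\n")
  cat("  total probesets:          ", x$n_total_probesets, "\n")
  cat("  unannotated probesets:    ", x$n_unannotated_probesets, "\n")
  cat("  unique annotated genes:   ", x$n_unique_genes, "\n")
  cat("  genes w/ mult. probesets: ", x$n_multiprobeset_genes,
      sprintf(" (%.0f%%)", 100 * x$fraction_multiprobeset), "\n")
  cat("  avg probesets per multi-probeset gene: ",
      sprintf("%.2f", x$avg_probesets_per_multiprobeset_gene), "\n")
  invisible(x)
}

#' Write one gene's probeset target sequences as FASTA
#'
#' One FASTA entry per member probeset that carries a target sequence, header
#' equal to the probeset id, sequence written unchanged (case preserved). The
#' file is named after the sanitized gene symbol. When no member has a
#' sequence the gene is skipped with a message.
#'
#' @param gene_symbol the gene whose probesets to write.
#' @param probeset_ids member probeset ids (e.g. one element of
#'   [group_by_gene()]).
#' @param records a `probeset_annotation` data frame carrying
#'   `target_sequence`.
#' @param out_dir output directory (created if needed).
#' @return the path of the written file, or `NA` when skipped.
#' @export
write_gene_fasta <- function(gene_symbol, probeset_ids, records, out_dir) {
  idx <- match(probeset_ids, records$probeset_id)
  if (anyNA(idx)) stopf("probesets not found in annotation: %s",
                        paste(probeset_ids[is.na(idx)], collapse = ", "))
  seqs <- records$target_sequence[idx]
  has <- !is.na(seqs)
  if (!any(has)) {
    message("gene ", gene_symbol, ": no member probeset has a target sequence; skipped")
    return(NA_character_)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set <- Biostrings::BStringSet(seqs[has])
  names(set) <- probeset_ids[has]
  path <- file.path(out_dir, paste0(sanitize_filename(gene_symbol), ".fa"))
  Biostrings::writeXStringSet(set, path)
  path
}
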