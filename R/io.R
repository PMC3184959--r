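#' Construct a protein record
#'
#' The basic unit carried through the classification pipeline: an identifier,
#' an amino-acid sequence, and optional externally supplied feature
#' annotations (signal peptide, GPI-anchor signal, plastocyanin-like domain
#' intervals, N-glycosylation sites). Annotations left `NA`/`NULL` are later
#' filled by heuristics or by domain scanning.
#'
#' @param id unique identifier.
#' @param seq amino-acid sequence (20 standard letters plus `X`); lowercase
#'   input is uppercased.
#' @param sp_flag logical, signal peptide present (`NA` = unknown).
#' @param gas_flag logical, GPI-anchor signal present (`NA` = unknown).
#' @param pcld_intervals list of 1-based inclusive `c(start, end)` intervals
#'   of plastocyanin-like domains, or `NULL`.
#' @param nglyc_sites integer vector of 1-based N-glycosylation positions, or
#'   `NULL`.
#' @return an object of class `protein_record`.
#' @export
#' @examples
#' protein_record("p1", "MKAPSTGH")
protein_record <- function(id, seq, sp_flag = NA, gas_flag = NA,
                           pcld_intervals = NULL, nglyc_sites = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("empty sequence for '", id, "'")
  bad <- setdiff(unique(seq_chars(seq)), c(AA_STANDARD, "X"))
  if (length(bad))
    stop("non-standard residue(s) in '", id, "': ", paste(bad, collapse = ", "))
  if (!is.null(pcld_intervals)) {
    pcld_intervals <- lapply(pcld_intervals, check_interval, len = nchar(seq),
                             what = paste0("PCLD interval of '", id, "'"))
    if (length(pcld_intervals) > 1L) {
      ord <- order(vapply(pcld_intervals, `[`, integer(1L), 1L))
      pcld_intervals <- pcld_intervals[ord]
      ends <- vapply(pcld_intervals, `[`, integer(1L), 2L)
      starts <- vapply(pcld_intervals, `[`, integer(1L), 1L)
      if (any(starts[-1L] <= ends[-length(ends)]))
        stop("overlapping PCLD intervals for '", id, "'")
    }
  }
  structure(list(id = id, seq = seq,
                 sp_flag = sp_flag, gas_flag = gas_flag,
                 pcld_intervals = pcld_intervals,
                 nglyc_sites = nglyc_sites),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$seq), " aa)\n", sep = "")
  flags <- c(SP = x$sp_flag, GAS = x$gas_flag)
  cat("  flags:", paste(names(flags), ifelse(is.na(flags), "?", flags),
                        sep = "=", collapse = " "), "\n")
  if (length(x$pcld_intervals))
    cat("  PCLD:", paste(vapply(x$pcld_intervals,
                                function(i) paste(i, collapse = "-"),
                                character(1L)), collapse = ", "), "\n")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses with [Biostrings::readAAStringSet()], uppercases, and validates
#' residues against the 20 standard amino acids plus `X`. Identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @param nonstandard what to do with residues outside the standard 20 + `X`:
#'   `"error"` (default) rejects the file, `"mask"` maps them to `X`.
#' @return a list of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path, nonstandard = c("error", "mask")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(aa))
  if (nonstandard == "mask")
    seqs <- vapply(seqs, function(s) {
      gsub(paste0("[^", paste(AA_STANDARD, collapse = ""), "X]"), "X", s)
    }, character(1L), USE.NAMES = FALSE)
  mapply(protein_record, id = ids, seq = seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, `[[`, character(1L), "seq")
  ids <- vapply(records, `[[`, character(1L), "id")
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- ids
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Read a gene-coordinate table and assign per-chromosome ordinals
#'
#' Expects a TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (1-based inclusive base-pair coordinates). Each gene receives an ordinal
#' rank among all genes of its chromosome, sorted by ascending start (ties
#' broken by end, then `gene_id`). The tandem-duplication rule is defined on
#' these ordinals.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with the input columns plus `ordinal`, of class
#'   `c("gene_loci", "data.frame")`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  gene_loci(df[need])
}

#' Build a gene-locus table from a data frame
#'
#' Validates coordinates and strand and assigns per-chromosome ordinal ranks.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return a `gene_loci` data.frame with an `ordinal` column.
#' @export
gene_loci <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- df$start > df$end
  if (any(bad))
    stop("coordinate error (start > end) for: ",
         paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  df$ordinal <- NA_integer_
  for (ch in unique(df$chrom)) {
    idx <- which(df$chrom == ch)
    ord <- order(df$start[idx], df$end[idx], df$gene_id[idx])
    df$ordinal[idx[ord]] <- seq_along(idx)
  }
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' Attach external feature annotations to protein records
#'
#' Reads a TSV keyed by protein id with logical columns `sp` and `gas` and an
#' interval column `pcld` (format `"start-end"`, multiple intervals separated
#' by `";"`, empty for none). These carry the outputs of external predictors
#' (SignalP, Big-PI, InterProScan); proteins absent from the table keep their
#' flags unset. Rows naming unknown proteins are skipped with a warning.
#'
#' @param path path to the annotation TSV (columns `id`, `sp`, `gas`, `pcld`).
#' @param records list of [protein_record()] objects.
#' @return the updated list of records.
#' @export
read_annotation_table <- function(path, records) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) return(records)
  need <- c("id", "sp", "gas")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  ids <- vapply(records, `[[`, character(1L), "id")
  for (r in seq_len(nrow(df))) {
    i <- match(df$id[r], ids)
    if (is.na(i)) {
      warning("annotation row for unknown protein '", df$id[r], "' skipped")
      next
    }
    records[[i]]$sp_flag <- as.logical(df$sp[r])
    records[[i]]$gas_flag <- as.logical(df$gas[r])
    if ("pcld" %in% names(df) && nzchar(df$pcld[r])) {
      ivs <- lapply(strsplit(df$pcld[r], ";", fixed = TRUE)[[1L]],
                    parse_interval)
      rec <- records[[i]]
      records[[i]] <- protein_record(rec$id, rec$seq, rec$sp_flag,
                                     rec$gas_flag, pcld_intervals = ivs,
                                     nglyc_sites = rec$nglyc_sites)
    }
  }
  records
}

# "24-120" -> c(24L, 120L); rejects reversed intervals.
parse_interval <- function(txt) {
  parts <- as.integer(strsplit(trimws(txt), "-", fixed = TRUE)[[1L]])
  if (length(parts) != 2L || anyNA(parts))
    stop("malformed interval: '", txt, "'")
  if (parts[1L] > parts[2L])
    stop("malformed interval (start > end): '", txt, "'")
  parts
}

#' Construct an expression matrix with sample metadata
#'
#' @param values numeric matrix, genes x samples, finite and nonnegative;
#'   rownames are gene ids, colnames sample ids.
#' @param sample_meta data.frame with columns `sample_id`, `tissue`,
#'   `condition`, `replicate`; one row per column of `values`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and >= 0")
  need <- c("sample_id", "tissue", "condition", "replicate")
  miss <- setdiff(need, names(sample_meta))
  if (length(miss)) stop("sample_meta missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!setequal(colnames(values), sample_meta$sample_id) ||
      nrow(sample_meta) != ncol(values))
    stop("every sample must have exactly one metadata row")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  tissues:   ", paste(unique(x$sample_meta$tissue), collapse = ", "),
      "\n  conditions:", paste(unique(x$sample_meta$condition),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix and its sample sheet from TSV files
#'
#' @param path TSV whose first column is the gene id and whose header names
#'   the samples.
#' @param meta_path TSV sample sheet with columns `sample_id`, `tissue`,
#'   `condition`, `replicate`.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, meta_path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' Read a duplicated-segment block-pair table
#'
#' TSV with columns `pair_id`, `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#' `start_b`, `end_b` describing paired collinear chromosome blocks.
#'
#' @param path path to the TSV file.
#' @return a data.frame of block pairs.
#' @export
read_block_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("block table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$start_a > df$end_a) || any(df$start_b > df$end_b))
    stop("degenerate block (start > end)")
  df
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' All pcfam coordinates are 1-based inclusive; these helpers convert at the
#' I/O boundary for interoperability with BED-style tools.
#'
#' @param start,end interval bounds.
#' @return a length-2 integer vector.
#' @export
to_zero_based <- function(start, end) c(as.integer(start) - 1L,
                                        as.integer(end))

#' @rdname to_zero_based
#' @export
from_zero_based <- function(start, end) c(as.integer(start) + 1L,
                                          as.integer(end))
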