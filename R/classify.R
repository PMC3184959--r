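# Canonical synthetic plastocyanin-like domain (PCLD) used as alignment
# reference. 60 residues; copper-ligand columns carry H, C, H, M (positions
# 12, 25, 40, 45) and the two structural disulfide Cys sit at 6 and 52. The
# background alphabet is polar, Pro-free, and free of hydrophobic runs so the
# domain can never fake a glycomodule or an SP/GAS cassette, and each ligand
# residue differs from both neighbors so a ligand deletion maps to a unique
# gap column under global alignment.
REF_PCLD_SEQ <- paste0("GNTDKCEYQG", "SHNDEKRTGY", "NQSDCKGNET",
                       "DYKQGSNERH", "GTDKMNEQGY", "SCNDKRTGEN")
REF_LIGAND_COLUMNS <- c(12L, 25L, 40L, 45L)
REF_DISULFIDE_COLUMNS <- c(6L, 52L)

#' The packaged reference plastocyanin-like domain
#'
#' A 60-residue synthetic PCLD annotated with the four copper-ligand columns
#' (His, Cys, His, Met in the canonical uclacyanin arrangement) and the two
#' disulfide Cys columns. Query domains are aligned pairwise to this
#' reference and the ligand columns are read through the alignment.
#'
#' @return a list with `seq`, `ligand_columns`, `disulfide_columns`.
#' @export
reference_pcld <- function() {
  list(seq = REF_PCLD_SEQ,
       ligand_columns = REF_LIGAND_COLUMNS,
       disulfide_columns = REF_DISULFIDE_COLUMNS)
}

# Global pairwise alignment (BLOSUM62, affine gaps) of a query PCLD to the
# reference; shared by ligand extraction.
align_to_reference <- function(query, ref, gap_opening = 10, gap_extension = 0.5) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(ref$seq),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
}

#' Extract copper-ligand residues from a PCLD
#'
#' Globally aligns the query domain to the packaged reference
#' ([reference_pcld()]) with BLOSUM62 scoring and affine gaps, then maps the
#' four ligand columns and the two disulfide columns through the alignment.
#' A ligand column aligned to a gap yields `"-"` (absent).
#'
#' @param query_pcld amino-acid string of the candidate domain (>= 30 aa).
#' @param ref reference domain, as from [reference_pcld()].
#' @param score_floor minimum acceptable alignment score; below it a
#'   low-confidence error (condition class `pcfam_low_confidence`) is
#'   signalled. Default is 40% of the reference self-alignment score.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return a list with `ligands` (length-4 character, `"-"` = absent),
#'   `disulfide_ok` (both disulfide columns map to Cys), and `score`.
#' @export
extract_ligand_sites <- function(query_pcld, ref = reference_pcld(),
                                 score_floor = NULL,
                                 gap_opening = 10, gap_extension = 0.5) {
  if (nchar(query_pcld) < 30L) stop("query PCLD shorter than 30 residues")
  if (is.null(score_floor))
    score_floor <- 0.4 * Biostrings::score(
      align_to_reference(ref$seq, ref, gap_opening, gap_extension))
  aln <- align_to_reference(query_pcld, ref, gap_opening, gap_extension)
  sc <- Biostrings::score(aln)
  if (sc < score_floor) {
    cond <- structure(
      class = c("pcfam_low_confidence", "error", "condition"),
      list(message = sprintf(
        "alignment score %.1f below confidence floor %.1f", sc, score_floor),
        call = sys.call()))
    stop(cond)
  }
  qa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  ref_pos <- cumsum(sa != "-")
  pick <- function(col) {
    hit <- which(ref_pos == col & sa != "-")[1L]
    qa[hit]
  }
  ligands <- vapply(ref$ligand_columns, pick, character(1L))
  disulf <- vapply(ref$disulfide_columns, pick, character(1L))
  list(ligands = ligands, disulfide_ok = all(disulf == "C"), score = sc)
}

#' Assign a phytocyanin subfamily from the ligand tuple
#'
#' The complete copper-ligand set is His, Cys, His plus an axial Met
#' (uclacyanin-like, UCL) or Gln (stellacyanin-like, SCL). Any other tuple
#' lacks key residues for copper binding and is early-nodulin-like (ENODL).
#'
#' @param ligands length-4 character vector; `"-"` marks an absent (gapped)
#'   ligand column.
#' @return `"UCL"`, `"SCL"` or `"ENODL"`.
#' @export
classify_subfamily <- function(ligands) {
  stopifnot(length(ligands) == 4L)
  if (identical(unname(ligands), c("H", "C", "H", "M"))) return("UCL")
  if (identical(unname(ligands), c("H", "C", "H", "Q"))) return("SCL")
  "ENODL"
}

# domain-architecture truth table: (sp, n_pcld, alr, gas) -> type
ARCH_TABLE <- data.frame(
  sp = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
  n_pcld = c(1L, 1L, 1L, 1L, 1L, 2L),
  alr = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  gas = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
  type = c("I", "II", "III", "IV", "V", "VI"))

#' Classify protein architecture into the six phytocyanin types
#'
#' Type I: SP + PCLD + ALR + GAS; type II: as I without GAS; type III: as I
#' without ALR; type IV: SP + PCLD only; type V: bare PCLD; type VI: SP + two
#' PCLDs. Any other flag combination is `"UNCLASSIFIED"`.
#'
#' @param has_sp signal peptide present.
#' @param n_pcld number of plastocyanin-like domains (>= 1).
#' @param has_alr AGP-like region present.
#' @param has_gas GPI-anchor signal present.
#' @return one of `"I"`..`"VI"` or `"UNCLASSIFIED"`.
#' @export
classify_architecture <- function(has_sp, n_pcld, has_alr, has_gas) {
  if (n_pcld < 1L) stop("not a phytocyanin: no PCLD")
  hit <- ARCH_TABLE$sp == has_sp & ARCH_TABLE$n_pcld == n_pcld &
    ARCH_TABLE$alr == has_alr & ARCH_TABLE$gas == has_gas
  if (any(hit)) ARCH_TABLE$type[hit] else "UNCLASSIFIED"
}

#' Locate plastocyanin-like domains by scanning against the reference
#'
#' Repeated best local alignment (BLOSUM62, affine gaps) of the reference
#' domain against the protein; each hit above `score_floor` is recorded and
#' masked with `X` before searching for the next. Used when a protein has no
#' externally supplied PCLD intervals.
#'
#' @param seq amino-acid string.
#' @param ref reference domain.
#' @param score_floor minimum local alignment score to accept a domain;
#'   default 50% of the reference self-score.
#' @param max_domains search cutoff.
#' @return list of 1-based inclusive intervals, sorted by start (possibly
#'   empty).
#' @export
locate_pclds <- function(seq, ref = reference_pcld(), score_floor = NULL,
                         max_domains = 4L) {
  self <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(ref$seq),
    subject = Biostrings::AAString(ref$seq),
    substitutionMatrix = "BLOSUM62", type = "local",
    gapOpening = 10, gapExtension = 0.5)
  if (is.null(score_floor)) score_floor <- 0.5 * Biostrings::score(self)
  intervals <- list()
  masked <- seq
  for (k in seq_len(max_domains)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(masked),
      subject = Biostrings::AAString(ref$seq),
      substitutionMatrix = "BLOSUM62", type = "local",
      gapOpening = 10, gapExtension = 0.5)
    if (Biostrings::score(aln) < score_floor) break
    iv <- c(Biostrings::start(Biostrings::pattern(aln)),
            Biostrings::end(Biostrings::pattern(aln)))
    intervals[[length(intervals) + 1L]] <- as.integer(iv)
    substr(masked, iv[1L], iv[2L]) <- strrep("X", iv[2L] - iv[1L] + 1L)
  }
  if (length(intervals) > 1L)
    intervals <- intervals[order(vapply(intervals, `[`, integer(1L), 1L))]
  intervals
}

#' Classify one protein: subfamily, architecture type, chimeric-AGP status
#'
#' Pulls the pieces together: PCLD intervals are taken from the record or
#' located by scanning ([locate_pclds()]); SP and GAS come from annotation
#' flags when set, otherwise from the heuristics; the ligand tuple is read
#' from the first (N-terminal) domain; the ALR call masks all PCLDs, the SP
#' region (residues 1-25 when SP is present) and the GPI omega-region (last
#' 25 residues when GAS is present). Types I and II are chimeric AGPs.
#'
#' A low-confidence ligand alignment falls back to an ENODL call with a
#' warning rather than failing the protein.
#'
#' @param protein a [protein_record()].
#' @param ref reference domain, see [reference_pcld()].
#' @param min_dipeptides ALR threshold, see [call_alr()].
#' @return a one-row data.frame: `id`, `subfamily`, `arch_type`,
#'   `chimeric_agp`, `l1`..`l4`, `disulfide_ok`, `n_pcld`, `sp`, `alr`,
#'   `gas`, `alr_dipeptides`, `region_past`.
#' @export
classify_protein <- function(protein, ref = reference_pcld(),
                             min_dipeptides = 3L) {
  stopifnot(inherits(protein, "protein_record"))
  ivs <- protein$pcld_intervals
  if (is.null(ivs) || !length(ivs)) ivs <- locate_pclds(protein$seq, ref)
  if (!length(ivs))
    stop("no detectable PCLD in protein '", protein$id, "'")
  sp <- if (!is.na(protein$sp_flag)) protein$sp_flag
        else heuristic_sp(protein$seq)
  gas <- if (!is.na(protein$gas_flag)) protein$gas_flag
         else heuristic_gas(protein$seq)
  first <- ivs[[1L]]
  lig <- tryCatch(
    extract_ligand_sites(substr(protein$seq, first[1L], first[2L]), ref),
    pcfam_low_confidence = function(e) {
      warning("low-confidence PCLD alignment for '", protein$id,
              "'; assigning ENODL (", conditionMessage(e), ")")
      list(ligands = c("-", "-", "-", "-"), disulfide_ok = FALSE,
           score = NA_real_)
    })
  subfam <- classify_subfamily(lig$ligands)
  n <- nchar(protein$seq)
  excl <- ivs
  if (sp) excl <- c(excl, list(c(1L, min(25L, n))))
  if (gas) excl <- c(excl, list(c(max(1L, n - 24L), n)))
  alr <- call_alr(protein, excluded = excl, min_dipeptides = min_dipeptides)
  type <- classify_architecture(sp, length(ivs), alr$present, gas)
  data.frame(id = protein$id, subfamily = subfam, arch_type = type,
             chimeric_agp = type %in% c("I", "II"),
             l1 = lig$ligands[1L], l2 = lig$ligands[2L],
             l3 = lig$ligands[3L], l4 = lig$ligands[4L],
             disulfide_ok = lig$disulfide_ok, n_pcld = length(ivs),
             sp = sp, alr = alr$present, gas = gas,
             alr_dipeptides = alr$n_dipeptides,
             region_past = alr$region_past,
             stringsAsFactors = FALSE)
}

#' Classify a set of proteins
#'
#' @param records list of [protein_record()] objects.
#' @param ... passed to [classify_protein()].
#' @return a data.frame of class `c("pc_family", "data.frame")`, one row per
#'   protein.
#' @export
classify_family <- function(records, ...) {
  out <- do.call(rbind, lapply(records, classify_protein, ...))
  rownames(out) <- NULL
  class(out) <- c("pc_family", "data.frame")
  out
}

#' @export
print.pc_family <- function(x, ...) {
  cat("<pc_family> classification of", nrow(x), "proteins\n")
  show <- intersect(c("id", "subfamily", "arch_type", "chimeric_agp"),
                    names(x))
  print.data.frame(utils::head(as.data.frame(x)[show], 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' @method summary pc_family
#' @export
summary.pc_family <- function(object, ...) summarize_types(object)

#' Summarize classifications as a subfamily-by-type count table
#'
#' @param assignments a `pc_family` data.frame (or any data.frame with
#'   `subfamily` and `arch_type` columns).
#' @return an integer matrix of class `pc_type_summary`: rows are types
#'   I..VI plus UNCLASSIFIED, columns UCL/SCL/ENODL plus a `Total` column and
#'   a `Total` row.
#' @export
summarize_types <- function(assignments) {
  types <- c("I", "II", "III", "IV", "V", "VI", "UNCLASSIFIED")
  subs <- c("UCL", "SCL", "ENODL")
  m <- matrix(0L, nrow = length(types), ncol = length(subs),
              dimnames = list(types, subs))
  if (nrow(assignments)) {
    tb <- table(factor(assignments$arch_type, levels = types),
                factor(assignments$subfamily, levels = subs))
    m[] <- as.integer(tb)
  }
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  class(m) <- c("pc_type_summary", class(m))
  m
}

#' @export
print.pc_type_summary <- function(x, ...) {
  cat("Phytocyanin counts by architecture type and subfamily\n")
  y <- x
  class(y) <- "matrix"
  keep <- rowSums(y[, setdiff(colnames(y), "Total"), drop = FALSE]) > 0 |
    rownames(y) == "Total"
  print(y[keep, , drop = FALSE])
  invisible(x)
}

#' Percentage of family genes with expression evidence
#'
#' Simple reporting helper: `100 * n_with_evidence / n_total`, the figure
#' quoted when stating what share of a family has EST or full-length cDNA
#' support.
#'
#' @param n_with_evidence number of genes with at least one evidence record.
#' @param n_total family size.
#' @return a percentage.
#' @export
#' @examples
#' expressed_percent(38, 62) # 61.29032...
expressed_percent <- function(n_with_evidence, n_total) {
  stopifnot(n_total > 0, n_with_evidence >= 0, n_with_evidence <= n_total)
  100 * n_with_evidence / n_total
}
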