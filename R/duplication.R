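#' Find tandem-duplicate groups among family genes
#'
#' Two family genes on the same chromosome are tandem duplicates when they
#' are separated by at most `max_intervening` genes (of any family) in the
#' chromosome's gene order; groups are the transitive closure of that
#' relation, so a chain of near neighbors forms one group. Singletons are
#' never reported.
#'
#' @param loci a `gene_loci` data.frame (all genes, with ordinals), see
#'   [read_gene_table()] / [gene_loci()].
#' @param family_ids gene ids belonging to the family under study.
#' @param max_intervening maximum number of intervening genes (default 5).
#' @return a list of groups, each a list with `chrom` and `gene_ids`
#'   (ordered by ordinal).
#' @export
find_tandem_groups <- function(loci, family_ids, max_intervening = 5L) {
  miss <- setdiff(family_ids, loci$gene_id)
  if (length(miss))
    stop("family id(s) missing from loci: ", paste(miss, collapse = ", "))
  fam <- loci[loci$gene_id %in% family_ids, , drop = FALSE]
  groups <- list()
  for (ch in unique(fam$chrom)) {
    sub <- fam[fam$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    if (nrow(sub) < 2L) next
    # chain whenever the ordinal gap leaves <= max_intervening genes between
    new_run <- c(TRUE, diff(sub$ordinal) - 1L > max_intervening)
    run_id <- cumsum(new_run)
    for (g in split(seq_len(nrow(sub)), run_id)) {
      if (length(g) < 2L) next
      groups[[length(groups) + 1L]] <-
        list(chrom = ch, gene_ids = sub$gene_id[g])
    }
  }
  groups
}

#' Find segmental-duplicate gene pairs in collinear block pairs
#'
#' For each duplicated-segment block pair, family genes whose midpoint lies
#' in block A are paired with family genes in block B; a pair is collinear
#' (and reported) when the two genes' offsets from their respective block
#' starts differ by at most `max_offset` base pairs. A gene may participate
#' in pairs from several blocks.
#'
#' @param loci a `gene_loci` data.frame.
#' @param blocks data.frame of block pairs, see [read_block_table()].
#' @param family_ids family gene ids.
#' @param max_offset maximal collinear offset difference in bp (default
#'   500 kb).
#' @return a data.frame with columns `pair_id`, `gene_a`, `gene_b`,
#'   `offset_diff` (0 rows when none).
#' @export
find_segmental_pairs <- function(loci, blocks, family_ids,
                                 max_offset = 500000) {
  fam <- loci[loci$gene_id %in% family_ids, , drop = FALSE]
  fam$mid <- (fam$start + fam$end) / 2
  out <- data.frame(pair_id = character(), gene_a = character(),
                    gene_b = character(), offset_diff = numeric())
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    in_a <- fam$chrom == b$chrom_a & fam$mid >= b$start_a & fam$mid <= b$end_a
    in_b <- fam$chrom == b$chrom_b & fam$mid >= b$start_b & fam$mid <= b$end_b
    if (!any(in_a) || !any(in_b)) next
    for (i in which(in_a)) {
      off_a <- fam$mid[i] - b$start_a
      for (j in which(in_b)) {
        if (fam$gene_id[i] == fam$gene_id[j]) next
        off_b <- fam$mid[j] - b$start_b
        d <- abs(off_a - off_b)
        if (d <= max_offset)
          out <- rbind(out, data.frame(pair_id = as.character(b$pair_id),
                                       gene_a = fam$gene_id[i],
                                       gene_b = fam$gene_id[j],
                                       offset_diff = d))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Summarize duplication analysis
#'
#' Counts duplicated genes (union of tandem-group members and segmental-pair
#' members), tandem genes per chromosome, and the same-subfamily concordance
#' of each mechanism: the fraction of tandem groups whose members all share a
#' subfamily, and the fraction of segmental pairs joining genes of the same
#' subfamily.
#'
#' @param tandem groups from [find_tandem_groups()].
#' @param segmental pairs from [find_segmental_pairs()].
#' @param assignments optional `pc_family` data.frame supplying per-gene
#'   `subfamily`; concordance fractions are `NA` without it.
#' @return a list with `n_duplicated`, `n_tandem_genes`, `n_segmental_genes`,
#'   `tandem_by_chrom`, `tandem_concordance`, `segmental_concordance`.
#' @export
duplication_report <- function(tandem, segmental, assignments = NULL) {
  tandem_genes <- unique(unlist(lapply(tandem, `[[`, "gene_ids")))
  seg_genes <- unique(c(segmental$gene_a, segmental$gene_b))
  by_chrom <- table(unlist(lapply(tandem, function(g)
    rep(g$chrom, length(g$gene_ids)))))
  subfam_of <- function(ids) {
    if (is.null(assignments)) return(rep(NA_character_, length(ids)))
    assignments$subfamily[match(ids, assignments$id)]
  }
  tand_conc <- if (length(tandem) && !is.null(assignments)) {
    mean(vapply(tandem, function(g) {
      s <- subfam_of(g$gene_ids)
      length(unique(s)) == 1L
    }, logical(1L)))
  } else NA_real_
  seg_conc <- if (nrow(segmental) && !is.null(assignments)) {
    mean(subfam_of(segmental$gene_a) == subfam_of(segmental$gene_b))
  } else NA_real_
  list(n_duplicated = length(union(tandem_genes, seg_genes)),
       n_tandem_genes = length(tandem_genes),
       n_segmental_genes = length(seg_genes),
       tandem_by_chrom = by_chrom,
       tandem_concordance = tand_conc,
       segmental_concordance = seg_conc)
}
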