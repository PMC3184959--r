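# small helper: loci table with one gene per ordinal slot
slot_loci <- function(slots_by_chrom) {
  rows <- list()
  for (ch in names(slots_by_chrom)) {
    n <- slots_by_chrom[[ch]]
    rows[[ch]] <- data.frame(gene_id = sprintf("%s_g%02d", ch, seq_len(n)),
                             chrom = ch, start = seq_len(n) * 1000,
                             end = seq_len(n) * 1000 + 500, strand = "+")
  }
  gene_loci(do.call(rbind, rows))
}

test_that("tandem grouping honors the five-intervening-gene boundary", {
  loci <- slot_loci(list(chr1 = 20))
  # ordinals 4 and 10: exactly 5 intervening -> one group
  g <- find_tandem_groups(loci, c("chr1_g04", "chr1_g10"))
  expect_length(g, 1L)
  expect_setequal(g[[1]]$gene_ids, c("chr1_g04", "chr1_g10"))
  # ordinals 4 and 11: six intervening -> none
  expect_length(find_tandem_groups(loci, c("chr1_g04", "chr1_g11")), 0L)
  # chain 1,6,12 links transitively into one group of 3
  g3 <- find_tandem_groups(loci, c("chr1_g01", "chr1_g06", "chr1_g12"))
  expect_length(g3, 1L)
  expect_equal(g3[[1]]$gene_ids, c("chr1_g01", "chr1_g06", "chr1_g12"))
  # missing family id errors
  expect_error(find_tandem_groups(loci, "ghost"), "missing")
})

test_that("tandem grouping matches brute-force closure on random layouts", {
  set.seed(202)
  for (rep in 1:50) {
    n1 <- sample(20:120, 1)
    n2 <- sample(20:80, 1)
    loci <- slot_loci(list(chr1 = n1, chr2 = n2))
    fam <- sample(loci$gene_id, sample(4:min(25, n1 + n2), 1))
    got <- find_tandem_groups(loci, fam)
    got_canon <- lapply(got, function(g) sort(g$gene_ids))
    got_canon <- got_canon[order(vapply(got_canon, `[`, character(1), 1))]
    expect_equal(got_canon, oracle_tandem(loci, fam))
    # no singleton groups, ever
    expect_true(all(lengths(lapply(got, `[[`, "gene_ids")) >= 2L))
  }
})

test_that("segmental pairing applies the 500 kb collinear-offset rule", {
  loci <- gene_loci(data.frame(
    gene_id = c("a1", "b1", "b2", "c1"),
    chrom = c("chr1", "chr2", "chr2", "chr3"),
    start = c(1e6 + 10000, 2e6 + 20000, 2e6 + 700000, 5e6),
    end = c(1e6 + 11000, 2e6 + 21000, 2e6 + 701000, 5e6 + 1000),
    strand = "+"))
  blocks <- data.frame(pair_id = "blk1", chrom_a = "chr1", start_a = 1e6,
                       end_a = 2.5e6, chrom_b = "chr2", start_b = 2e6,
                       end_b = 3.5e6)
  # offsets 10.5 kb vs 20.5 kb: difference 10 kb -> pair
  p <- find_segmental_pairs(loci, blocks, c("a1", "b1"))
  expect_equal(nrow(p), 1L)
  expect_equal(p$gene_a, "a1")
  expect_equal(p$gene_b, "b1")
  # offsets differing by ~690 kb -> no pair
  expect_equal(nrow(find_segmental_pairs(loci, blocks, c("a1", "b2"))), 0L)
  # family gene in block A with no family partner in block B -> no pair
  expect_equal(nrow(find_segmental_pairs(loci, blocks, c("a1", "c1"))), 0L)
})

test_that("segmental pairing is symmetric under block swap", {
  lay <- gen_genome_layout(seed = 8)
  fwd <- find_segmental_pairs(lay$loci, lay$blocks, lay$family_ids)
  swapped <- lay$blocks
  names(swapped) <- c("pair_id", "chrom_b", "start_b", "end_b",
                      "chrom_a", "start_a", "end_a")
  rev <- find_segmental_pairs(lay$loci, swapped, lay$family_ids)
  expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                  paste(rev$gene_b, rev$gene_a))
  expect_equal(sort(fwd$offset_diff), sort(rev$offset_diff))
})

test_that("planted genome layouts are recovered exactly", {
  lay <- gen_genome_layout(seed = 4)
  groups <- find_tandem_groups(lay$loci, lay$family_ids)
  expect_equal(lapply(groups, `[[`, "gene_ids"), lay$truth$tandem)
  pairs <- find_segmental_pairs(lay$loci, lay$blocks, lay$family_ids)
  expect_equal(pairs[c("gene_a", "gene_b")], lay$truth$segmental,
               ignore_attr = TRUE)
  # a planted cluster with six intervening genes is not a tandem group
  lay6 <- gen_genome_layout(seed = 4, tandem_spec = list(
    list(chrom = 1L, size = 2L, gap = 6L)))
  expect_length(lay6$truth$tandem, 0L)
  expect_length(find_tandem_groups(lay6$loci, lay6$family_ids), 0L)
})

test_that("duplication reports count genes and subfamily concordance", {
  empty <- duplication_report(list(),
                              data.frame(gene_a = character(),
                                         gene_b = character()))
  expect_equal(empty$n_duplicated, 0L)
  lay <- gen_genome_layout(seed = 4)
  groups <- find_tandem_groups(lay$loci, lay$family_ids)
  pairs <- find_segmental_pairs(lay$loci, lay$blocks, lay$family_ids)
  # assignments: one segmental pair crosses subfamilies (UCL vs SCL),
  # mirroring a Met->Gln shuffle across a duplicated segment
  asg <- data.frame(id = lay$family_ids, subfamily = "UCL")
  asg$subfamily[asg$id == pairs$gene_b[1]] <- "SCL"
  rep <- duplication_report(groups, pairs, asg)
  expect_equal(rep$n_tandem_genes, 5L)  # planted 3-gene + 2-gene clusters
  expect_lt(rep$segmental_concordance, 1)
  expect_equal(rep$tandem_concordance, 1)
  expect_equal(rep$n_duplicated,
               length(union(unlist(lay$truth$tandem),
                            unlist(lay$truth$segmental))))
})
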