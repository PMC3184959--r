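# Cassette constants for the synthetic protein generator. Linker/background
# residues are polar and Pro-free so planted features are the only features:
# no accidental glycomodule, signal peptide or GPI tail can arise outside the
# cassettes that encode them.
SIM_POLAR <- c("G", "N", "D", "E", "Q", "K", "R", "S", "T")

# N-terminal signal-peptide cassette (25 aa): Met-Lys, a 12-residue
# hydrophobic core starting at position 3, then polar padding. Satisfies the
# heuristic_sp() rule by construction.
SIM_SP <- paste0("MK", "LALVLLVALLVF", "GNDEQKRSTGN")

# C-terminal GPI-anchor-signal cassette (25 aa): small-residue omega context
# up front, then a 12-residue hydrophobic tail reaching the C-terminus.
# Satisfies the heuristic_gas() rule by construction.
SIM_GAS <- paste0("SGNS", "DEQKRTGND", "LVLLVALLVLLV")

rand_linker <- function(len) paste(sample(SIM_POLAR, len, replace = TRUE),
                                   collapse = "")

# AGP-like region: n_units noncontiguous Ala-Pro dipeptides 4 residues apart,
# one Pro-rich region with a single glycomodule of size n_units.
sim_alr <- function(n_units) strrep("APSG", n_units)

# Mutate the reference PCLD for a target subfamily. UCL keeps the canonical
# H,C,H,M; SCL carries the axial Met->Gln swap; ENODL loses a random key
# residue by substitution or deletion.
sim_pcld <- function(subfamily) {
  ref <- reference_pcld()
  s <- seq_chars(ref$seq)
  if (subfamily == "SCL") {
    s[ref$ligand_columns[4L]] <- "Q"
  } else if (subfamily == "ENODL") {
    site <- sample(4L, 1L)
    col <- ref$ligand_columns[site]
    if (stats::runif(1) < 0.5) {
      s <- s[-col]                          # ligand column maps to a gap
    } else {
      s[col] <- c("R", "S", "R", "K")[site] # non-ligand substitution
    }
  } else if (subfamily != "UCL") {
    stop("unknown subfamily: ", subfamily)
  }
  paste(s, collapse = "")
}

#' Generate one synthetic phytocyanin with known ground truth
#'
#' Concatenates rule-satisfying cassettes according to the requested
#' architecture type: a signal peptide (types I-IV, VI), one or two copies of
#' the reference plastocyanin-like domain carrying the subfamily's ligand
#' residues, an AGP-like region of `n_glyco` noncontiguous Ala-Pro
#' dipeptides (types I-II), and a GPI-anchor-signal tail (types I, III).
#' Backgrounds are polar and Pro-free, so the classifier working from the
#' sequence alone must recover the planted labels.
#'
#' @param subfamily `"UCL"`, `"SCL"` or `"ENODL"`.
#' @param arch_type architecture type `"I"`..`"VI"`.
#' @param n_glyco number of glycomodule dipeptides planted in the ALR
#'   (default 8; only used for types I and II).
#' @param id identifier for the record.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream (used by [gen_family_fixture()]).
#' @return a list with `record` (a [protein_record()]) and `truth`
#'   (`subfamily`, `arch_type`, `chimeric_agp`).
#' @export
gen_pc_protein <- function(subfamily, arch_type, n_glyco = 8L,
                           id = paste0("syn_", subfamily, "_", arch_type),
                           seed = NULL) {
  if (!arch_type %in% c("I", "II", "III", "IV", "V", "VI"))
    stop("unknown architecture type: ", arch_type)
  build <- function() {
    pcld <- sim_pcld(subfamily)
    parts <- switch(arch_type,
      I   = c(SIM_SP, rand_linker(sample(8:16, 1L)), pcld,
              rand_linker(sample(8:16, 1L)), sim_alr(n_glyco), SIM_GAS),
      II  = c(SIM_SP, rand_linker(sample(8:16, 1L)), pcld,
              rand_linker(sample(8:16, 1L)), sim_alr(n_glyco),
              rand_linker(sample(10:16, 1L))),
      III = c(SIM_SP, rand_linker(sample(8:16, 1L)), pcld,
              rand_linker(sample(8:16, 1L)), SIM_GAS),
      IV  = c(SIM_SP, rand_linker(sample(8:16, 1L)), pcld,
              rand_linker(sample(10:20, 1L))),
      V   = c(rand_linker(sample(3:6, 1L)), pcld,
              rand_linker(sample(8:12, 1L))),
      VI  = c(SIM_SP, rand_linker(sample(8:16, 1L)), pcld,
              rand_linker(sample(8:16, 1L)), sim_pcld(subfamily),
              rand_linker(sample(10:16, 1L))))
    list(record = protein_record(id, paste(parts, collapse = "")),
         truth = list(subfamily = subfamily, arch_type = arch_type,
                      chimeric_agp = arch_type %in% c("I", "II")))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Default family composition: the rice subfamily-by-type cell counts
# (19/1/18 type I, 3/1/4 type III, 11/1/2 type IV, 2/0/0 type V; 62 total).
default_family_counts <- function() {
  m <- matrix(0L, nrow = 6L, ncol = 3L,
              dimnames = list(c("I", "II", "III", "IV", "V", "VI"),
                              c("UCL", "SCL", "ENODL")))
  m["I", ] <- c(19L, 1L, 18L)
  m["III", ] <- c(3L, 1L, 4L)
  m["IV", ] <- c(11L, 1L, 2L)
  m["V", ] <- c(2L, 0L, 0L)
  m
}

#' Generate a synthetic phytocyanin family fixture
#'
#' One protein per occupant of a subfamily-by-type count table; the default
#' table is the 62-member rice family composition. Identifiers follow the
#' field's convention (`OsUCL1`, `OsSCL1`, `OsENODL1`, ... numbered within
#' subfamily).
#'
#' @param counts integer matrix, rows `I`..`VI`, columns `UCL`, `SCL`,
#'   `ENODL`; default [default_family_counts()].
#' @param seed integer seed; the fixture is a deterministic function of
#'   `(counts, seed)`.
#' @param n_glyco glycomodule dipeptides planted per ALR-positive protein.
#' @return a list with `records` (list of [protein_record()]) and `truth`
#'   (data.frame `id`, `subfamily`, `arch_type`, `chimeric_agp`).
#' @export
gen_family_fixture <- function(counts = default_family_counts(), seed = 1L,
                               n_glyco = 8L) {
  stopifnot(all(counts >= 0))
  with_seed(seed, {
    records <- list()
    truth <- list()
    counter <- c(UCL = 0L, SCL = 0L, ENODL = 0L)
    for (subfam in colnames(counts)) {
      for (type in rownames(counts)) {
        k <- counts[type, subfam]
        if (k == 0L) next
        for (i in seq_len(k)) {
          counter[subfam] <- counter[subfam] + 1L
          id <- paste0("Os", subfam, counter[subfam])
          g <- gen_pc_protein(subfam, type, n_glyco = n_glyco, id = id)
          records[[length(records) + 1L]] <- g$record
          truth[[length(truth) + 1L]] <-
            data.frame(id = id, subfamily = subfam, arch_type = type,
                       chimeric_agp = g$truth$chimeric_agp)
        }
      }
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

#' Generate a synthetic genome layout with planted duplications
#'
#' Lays out background genes on regularly spaced slots, plants tandem
#' clusters of family genes with chosen intervening-gene gaps, adds isolated
#' family genes, and builds duplicated-segment block pairs carrying one
#' family gene each at chosen collinear offsets. The returned truth lists
#' exactly the tandem groups (clusters with gap <= 5 and size >= 2) and
#' segmental pairs (offset difference <= 500 kb) that the detection rules
#' must report.
#'
#' @param seed integer seed.
#' @param background_per_chrom background genes per chromosome.
#' @param tandem_spec list of `list(chrom =, size =, gap =)` planted
#'   clusters (`gap` = intervening genes between consecutive members).
#' @param n_lone_family isolated family genes (never in a group).
#' @param block_spec list of `list(offset_diff =)` block pairs; each plants
#'   one family gene per block with the given collinear offset difference in
#'   bp.
#' @return a list with `loci` (a `gene_loci` table), `blocks`, `family_ids`,
#'   and `truth` (`tandem` = list of id vectors, `segmental` = data.frame).
#' @export
gen_genome_layout <- function(seed = 1L,
                              background_per_chrom = 80L,
                              tandem_spec = list(
                                list(chrom = 1L, size = 3L, gap = 2L),
                                list(chrom = 2L, size = 2L, gap = 5L)),
                              n_lone_family = 2L,
                              block_spec = list(
                                list(offset_diff = 100000),
                                list(offset_diff = 600000))) {
  with_seed(seed, {
    slot_bp <- 10000
    gene_len <- 2000
    chroms <- c("chr1", "chr2")
    rows <- list()
    add_gene <- function(id, chrom, start) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = id, chrom = chrom, start = start,
        end = start + gene_len - 1L, strand = sample(c("+", "-"), 1L))
    }
    for (ci in seq_along(chroms))
      for (s in seq_len(background_per_chrom))
        add_gene(sprintf("bg%d_%03d", ci, s), chroms[ci], s * slot_bp)
    # family genes occupy background slots (replacing the background gene id
    # would change ordinals, so they sit between slots at +1/2 spacing is
    # wrong -- instead we convert chosen background genes to family genes)
    df <- do.call(rbind, rows)
    family_ids <- character()
    truth_tandem <- list()
    cursor <- c(5L, 5L)
    fam_counter <- 0L
    for (sp in tandem_spec) {
      ci <- sp$chrom
      slots <- cursor[ci] + cumsum(c(0L, rep(sp$gap + 1L, sp$size - 1L)))
      if (max(slots) > background_per_chrom - 10L)
        stop("tandem_spec does not fit on chromosome ", ci)
      ids <- character(sp$size)
      for (k in seq_along(slots)) {
        fam_counter <- fam_counter + 1L
        id <- sprintf("fam%02d", fam_counter)
        df$gene_id[df$chrom == chroms[ci] &
                     df$start == slots[k] * slot_bp] <- id
        ids[k] <- id
      }
      family_ids <- c(family_ids, ids)
      if (sp$gap <= 5L && sp$size >= 2L)
        truth_tandem[[length(truth_tandem) + 1L]] <- ids
      cursor[ci] <- max(slots) + 10L
    }
    for (l in seq_len(n_lone_family)) {
      ci <- 1L + (l %% 2L)
      if (cursor[ci] > background_per_chrom - 10L)
        stop("no room for lone family genes")
      fam_counter <- fam_counter + 1L
      id <- sprintf("fam%02d", fam_counter)
      df$gene_id[df$chrom == chroms[ci] &
                   df$start == cursor[ci] * slot_bp] <- id
      family_ids <- c(family_ids, id)
      cursor[ci] <- cursor[ci] + 10L
    }
    # block pairs live beyond the background slots; each block carries its
    # family gene plus filler genes so block genes are never ordinal-adjacent
    blocks <- list()
    truth_seg <- list()
    base <- (background_per_chrom + 50L) * slot_bp
    for (bi in seq_along(block_spec)) {
      width <- 1500000
      start_a <- base + (bi - 1L) * 2L * width
      start_b <- base + (bi - 1L) * 2L * width + width %/% 2L
      blocks[[bi]] <- data.frame(
        pair_id = sprintf("blk%02d", bi),
        chrom_a = "chr1", start_a = start_a, end_a = start_a + width,
        chrom_b = "chr2", start_b = start_b, end_b = start_b + width)
      off <- 200000
      fam_counter <- fam_counter + 1L
      id_a <- sprintf("fam%02d", fam_counter)
      add_gene2 <- function(id, chrom, start) {
        df <<- rbind(df, data.frame(gene_id = id, chrom = chrom,
                                    start = start, end = start + gene_len - 1L,
                                    strand = "+"))
      }
      add_gene2(id_a, "chr1", start_a + off)
      fam_counter <- fam_counter + 1L
      id_b <- sprintf("fam%02d", fam_counter)
      add_gene2(id_b, "chr2", start_b + off + block_spec[[bi]]$offset_diff)
      for (f in 1:7) {
        add_gene2(sprintf("blkbg%d_%d_a", bi, f), "chr1",
                  start_a + off + f * 60000)
        add_gene2(sprintf("blkbg%d_%d_b", bi, f), "chr2",
                  start_b + off + f * 60000)
      }
      family_ids <- c(family_ids, id_a, id_b)
      if (block_spec[[bi]]$offset_diff <= 500000)
        truth_seg[[length(truth_seg) + 1L]] <-
          data.frame(gene_a = id_a, gene_b = id_b)
    }
    truth_seg <- if (length(truth_seg)) do.call(rbind, truth_seg)
    else data.frame(gene_a = character(), gene_b = character())
    list(loci = gene_loci(df), blocks = do.call(rbind, blocks),
         family_ids = family_ids,
         truth = list(tandem = truth_tandem, segmental = truth_seg))
  })
}

#' Generate synthetic expression data with planted effects
#'
#' Emits the four expression inputs the digital-expression rules consume,
#' each with ground truth: a developmental [expression_matrix()] and a
#' stress-design matrix with log-normal noise, EST count profiles with
#' planted tissue-specific genes (one tissue carrying well over half the
#' mass), MPSS tag abundances drawn inside planted tier intervals away from
#' the 50/500 boundaries, and a qPCR plate (dilution series plus samples)
#' generated from known template quantities at a stated amplification
#' efficiency.
#'
#' @param seed integer seed.
#' @param n_genes number of genes.
#' @param tissues tissue labels for the developmental design.
#' @param n_rep replicates per tissue (developmental matrix).
#' @param n_specific genes planted as tissue-specific (EST + matrix).
#' @param stress_conditions treatment labels; every one gets `n_stress_rep`
#'   replicate arrays plus a shared control arm.
#' @param n_stress_rep replicates per stress arm (default 4).
#' @param n_up,n_down genes planted up-/down-regulated in every stress
#'   condition.
#' @param up_fold,down_fold planted linear fold changes (defaults 4 and
#'   0.25).
#' @param noise_sd log2-scale noise standard deviation (default 0.2).
#' @param efficiency qPCR amplification efficiency (default 2 = 100%).
#' @return a list with `dev` (expression_matrix), `stress`
#'   (expression_matrix), `est` (gene x tissue count matrix), `mpss` (gene x
#'   library tpm matrix), `qpcr` (list: `plate`, `dilution`, `amounts`,
#'   `reference_genes`), and `truth`.
#' @export
gen_expression_data <- function(seed = 1L, n_genes = 40L,
                                tissues = c("root", "leaf", "stem", "panicle"),
                                n_rep = 3L, n_specific = 4L,
                                stress_conditions = c("drought", "salt", "cold"),
                                n_stress_rep = 4L,
                                n_up = 3L, n_down = 3L,
                                up_fold = 4, down_fold = 0.25,
                                noise_sd = 0.2, efficiency = 2) {
  with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(n_genes))
    base_log2 <- stats::runif(n_genes, 6, 10)
    specific <- genes[seq_len(n_specific)]
    spec_tissue <- sample(tissues, n_specific, replace = TRUE)
    names(spec_tissue) <- specific

    # developmental matrix: tissues x replicates
    dev_meta <- expand.grid(replicate = seq_len(n_rep), tissue = tissues,
                            stringsAsFactors = FALSE)
    dev_meta$condition <- "none"
    dev_meta$sample_id <- paste0(dev_meta$tissue, "_r", dev_meta$replicate)
    dev <- matrix(0, n_genes, nrow(dev_meta),
                  dimnames = list(genes, dev_meta$sample_id))
    for (s in seq_len(nrow(dev_meta))) {
      mu <- base_log2
      boost <- names(spec_tissue)[spec_tissue == dev_meta$tissue[s]]
      mu[match(boost, genes)] <- mu[match(boost, genes)] + 3
      dev[, s] <- 2^(mu + stats::rnorm(n_genes, 0, noise_sd))
    }

    # stress matrix: control + each condition, n_stress_rep replicates
    up <- genes[n_specific + seq_len(n_up)]
    down <- genes[n_specific + n_up + seq_len(n_down)]
    st_meta <- expand.grid(replicate = seq_len(n_stress_rep),
                           condition = c("control", stress_conditions),
                           stringsAsFactors = FALSE)
    st_meta$tissue <- "seedling"
    st_meta$sample_id <- paste0(st_meta$condition, "_r", st_meta$replicate)
    st <- matrix(0, n_genes, nrow(st_meta),
                 dimnames = list(genes, st_meta$sample_id))
    for (s in seq_len(nrow(st_meta))) {
      mu <- base_log2
      if (st_meta$condition[s] != "control") {
        mu[match(up, genes)] <- mu[match(up, genes)] + log2(up_fold)
        mu[match(down, genes)] <- mu[match(down, genes)] + log2(down_fold)
      }
      st[, s] <- 2^(mu + stats::rnorm(n_genes, 0, noise_sd))
    }

    # EST counts: specific genes put 3/4 of their mass on one tissue
    est <- matrix(10L, n_genes, length(tissues),
                  dimnames = list(genes, tissues))
    for (g in specific) {
      est[g, ] <- 2L
      est[g, spec_tissue[g]] <- 30L  # well over half of the total
    }

    # MPSS: planted tiers, values drawn strictly inside tier intervals
    libs <- c("root14d", "leaf14d", "pollen", "ovary")
    tier <- sample(c("LOW", "MODERATE", "STRONG"), n_genes, replace = TRUE)
    names(tier) <- genes
    mpss <- matrix(0, n_genes, length(libs), dimnames = list(genes, libs))
    for (i in seq_len(n_genes)) {
      rng <- switch(tier[i], LOW = c(0, 45), MODERATE = c(55, 495),
                    STRONG = c(505, 5000))
      mpss[i, ] <- stats::runif(length(libs), rng[1L], rng[2L])
    }

    # qPCR: four reference genes at a common quantity scale, targets at
    # known relative levels; Ct from the standard-curve model
    amounts <- 10 * 3^(0:5)
    slope <- -1 / log10(efficiency)
    intercept <- 35
    refs <- paste0("HK", 1:4)
    targets <- genes[seq_len(3L)]
    samples <- c("root", "leaf", "panicle")
    rel_truth <- matrix(stats::runif(length(targets) * length(samples),
                                     0.25, 8),
                        length(targets), length(samples),
                        dimnames = list(targets, samples))
    plate <- list()
    for (smp in samples) {
      ref_q <- stats::runif(4L, 50, 200)
      names(ref_q) <- refs
      gm <- exp(mean(log(ref_q)))
      for (g in c(targets, refs)) {
        q <- if (g %in% refs) ref_q[g] else rel_truth[g, smp] * gm
        ct <- intercept + slope * log10(q)
        for (tr in 1:3)
          plate[[length(plate) + 1L]] <- data.frame(
            gene = g, sample = smp, bio_rep = 1L, tech_rep = tr, ct = ct)
      }
    }
    plate <- do.call(rbind, plate)
    dilution <- do.call(rbind, lapply(c(targets, refs), function(g)
      data.frame(gene = g, amount = amounts,
                 ct = intercept + slope * log10(amounts))))

    list(dev = expression_matrix(dev, dev_meta),
         stress = expression_matrix(st, st_meta),
         est = est, mpss = mpss,
         qpcr = list(plate = plate, dilution = dilution, amounts = amounts,
                     reference_genes = refs, slope = slope,
                     intercept = intercept),
         truth = list(specific = spec_tissue, up = up, down = down,
                      tier = tier, qpcr_relative = rel_truth))
  })
}
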