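# Independent brute-force oracles used to validate the optimized scanners.
# They share no code with the implementations: components are found by
# all-pairs adjacency and repeated closure rather than sorted chaining.

# components of an adjacency relation by repeated expansion
closure_components <- function(n, adjacent) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && adjacent(i, j) && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  comp
}

# Pro-rich regions by brute force: Pro positions grouped with gap <= 11
oracle_pro_regions <- function(seq, max_gap = 11L) {
  ch <- strsplit(seq, "")[[1]]
  pro <- which(ch == "P")
  if (length(pro) < 2L) return(list())
  comp <- closure_components(length(pro), function(i, j)
    abs(pro[i] - pro[j]) - 1L <= max_gap)
  out <- list()
  for (cc in unique(comp)) {
    g <- pro[comp == cc]
    if (length(g) >= 2L)
      out[[length(out) + 1L]] <- c(min(g), max(g))
  }
  out[order(vapply(out, `[`, numeric(1), 1))]
}

# glycomodule clusters by brute force inside a region
oracle_glycomodules <- function(seq, region_start, region_end,
                                max_start_gap = 13L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  cand <- integer()
  for (i in seq_len(max(0L, n - 1L))) {
    p <- i + 1L
    if (!(ch[i] %in% c("A", "S", "T"))) next
    if (ch[p] != "P") next
    if (p < region_start || p > region_end) next
    if (i < region_start - 1L || i > region_end) next
    left_p <- i >= 1L && ch[i] == "P"
    right_p <- p < n && ch[p + 1L] == "P"
    if (left_p || right_p) next
    cand <- c(cand, i)
  }
  if (length(cand) < 2L) return(list())
  # spacing rule as all-pairs adjacency + closure (equivalent to splitting
  # the sorted starts at gaps > max_start_gap, but derived independently)
  comp <- closure_components(length(cand), function(i, j)
    abs(cand[i] - cand[j]) <= max_start_gap)
  out <- list()
  for (cc in unique(comp)) {
    g <- sort(cand[comp == cc])
    if (length(g) >= 2L) out[[length(out) + 1L]] <- g
  }
  out[order(vapply(out, `[`, numeric(1), 1))]
}

# tandem groups by brute force: all-pairs rule + closure
oracle_tandem <- function(loci, family_ids, max_intervening = 5L) {
  fam <- loci[loci$gene_id %in% family_ids, , drop = FALSE]
  fam <- fam[order(fam$chrom, fam$ordinal), , drop = FALSE]
  n <- nrow(fam)
  if (n < 2L) return(list())
  comp <- closure_components(n, function(i, j)
    fam$chrom[i] == fam$chrom[j] &&
      abs(fam$ordinal[i] - fam$ordinal[j]) - 1L <= max_intervening)
  out <- list()
  for (cc in unique(comp)) {
    g <- fam$gene_id[comp == cc]
    if (length(g) >= 2L) out[[length(out) + 1L]] <- sort(g)
  }
  out[order(vapply(out, `[`, character(1), 1))]
}

# random amino-acid sequence biased toward P/A/S/T so glycomodule cases occur
random_biased_seq <- function(len) {
  paste(sample(c("P", "A", "S", "T", "G", "K", "E", "L"), len,
               replace = TRUE,
               prob = c(0.25, 0.15, 0.1, 0.1, 0.15, 0.1, 0.1, 0.05)),
        collapse = "")
}

# normalize pcfam glycomodule output to a list of sorted start vectors
mods_as_starts <- function(mods) {
  out <- lapply(mods, function(m) sort(m$starts))
  out[order(vapply(out, `[`, numeric(1), 1))]
}
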