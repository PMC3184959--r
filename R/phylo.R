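#' Read a protein multiple alignment from aligned FASTA
#'
#' Like [read_fasta()] but rows may contain the gap character `-` and all
#' rows must have equal length.
#'
#' @param path path to an aligned FASTA file.
#' @return a named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2L) stop("alignment needs >= 2 sequences")
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length")
  seqs
}

#' Pairwise p-distances with pairwise gap deletion
#'
#' For each pair of aligned sequences, columns where either row carries a
#' gap (`-` or `.`) are dropped and the distance is the proportion of the
#' remaining columns at which the residues differ.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (>= 2 taxa).
#' @return a symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
p_distance <- function(alignment) {
  if (length(alignment) < 2L) stop("need >= 2 taxa")
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-" | m == "."
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop("no comparable columns between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion with the standard
#' branch-length formulas. Ties in the Q-matrix are broken by the smallest
#' (row, column) index pair, making the output deterministic. Negative
#' branch-length estimates are clamped to zero and flagged via the
#' `negative_clamped` attribute. Two taxa yield a degenerate single-edge
#' tree.
#'
#' @param d symmetric distance matrix with taxa dimnames (zero diagonal).
#' @return an unrooted [ape::phylo] tree with branch lengths; attribute
#'   `negative_clamped` reports whether any estimate was clamped.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      0
    } else x
  }
  sub <- rownames(d)  # newick fragment per active node
  D <- unname(d)
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest index pair among minima (column-major scan of upper triangle)
    best <- c(NA_integer_, NA_integer_)
    qmin <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (Q[i, j] < qmin - 1e-12) {
          qmin <- Q[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], bi, sub[j], bj)
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], dnew),
               c(dnew, 0))
    sub <- c(sub[others], newfrag)
  }
  if (nrow(D) == 3L) {
    b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   sub[1L], b1, sub[2L], b2, sub[3L], b3)
  } else {
    half <- D[1, 2] / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", sub[1L], half, sub[2L], half)
  }
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data p-distance NJ tree, then resamples alignment columns
#' with replacement `n_reps` times, rebuilds a tree per replicate, and
#' annotates each internal split of the full tree with the percentage of
#' replicate trees containing it. Supports are written to the tree's node
#' labels (the root label stays empty).
#'
#' @param alignment named character vector of aligned sequences.
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer seed; same seed, same supports.
#' @return the full-data [ape::phylo] tree with `node.label` percentages and
#'   a `bootstrap` attribute holding the raw counts.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  full <- nj_tree(p_distance(alignment))
  ncol_aln <- unique(nchar(alignment))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      boot <- vapply(strsplit(alignment, "", fixed = TRUE),
                     function(ch) paste(ch[cols], collapse = ""),
                     character(1L))
      tryCatch(nj_tree(p_distance(boot)), error = function(e) NULL)
    })
  })
  reps <- reps[!vapply(reps, is.null, logical(1L))]
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps), 1L)
  lab <- as.character(support)
  lab[1L] <- ""  # root of the unrooted representation carries no split
  full$node.label <- lab
  attr(full, "bootstrap") <- counts
  attr(full, "n_reps") <- length(reps)
  full
}

#' Write a tree in Newick format
#'
#' Thin wrapper over [ape::write.tree()] retaining node labels (bootstrap
#' supports) and branch lengths.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
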