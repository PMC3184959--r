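#' Tissue-specific expression call from EST counts
#'
#' A gene is specifically expressed in the unique tissue whose EST count
#' contributes strictly more than half of the gene's total count; otherwise
#' (including a zero total) no tissue is returned.
#'
#' @param counts named nonnegative integer vector of EST counts per tissue.
#' @return the tissue label, or `NA_character_` when none qualifies.
#' @export
#' @examples
#' est_specific_tissue(c(root = 6, leaf = 2, stem = 2)) # "root"
#' est_specific_tissue(c(root = 5, leaf = 5))           # NA
est_specific_tissue <- function(counts) {
  if (any(counts < 0)) stop("negative EST counts")
  total <- sum(counts)
  if (total == 0) return(NA_character_)
  hit <- which(counts > total / 2)
  if (length(hit) == 1L) names(counts)[hit] else NA_character_
}

#' MPSS expression tier
#'
#' Bins a tags-per-million abundance into the three conventional tiers:
#' low (< 50 tpm), moderate (50-500 tpm, boundaries inclusive), strong
#' (> 500 tpm).
#'
#' @param tpm nonnegative numeric vector of tag abundances.
#' @return character vector of `"LOW"`, `"MODERATE"`, `"STRONG"`.
#' @export
mpss_tier <- function(tpm) {
  if (any(!is.finite(tpm)) || any(tpm < 0)) stop("tpm must be finite and >= 0")
  ifelse(tpm < 50, "LOW", ifelse(tpm <= 500, "MODERATE", "STRONG"))
}

#' Normalize a microarray signal matrix for cluster display
#'
#' Divides every absolute signal by the grand mean of the whole matrix and
#' takes log2 of the ratios. Zeros are floored at a pseudo-value before
#' division so the logs stay finite.
#'
#' @param em an [expression_matrix()] or plain nonnegative matrix.
#' @param pseudo floor for zero signals; default half the smallest positive
#'   value in the matrix.
#' @return a matrix of log2 ratios with the input dimnames.
#' @export
normalize_microarray <- function(em, pseudo = NULL) {
  values <- if (inherits(em, "expression_matrix")) em$values else em
  if (all(values == 0)) stop("all-zero matrix cannot be normalized")
  if (is.null(pseudo)) pseudo <- min(values[values > 0]) * 0.5
  values[values == 0] <- pseudo
  log2(values / mean(values))
}

#' Hierarchically cluster genes of a normalized matrix
#'
#' Agglomerative clustering with centered-correlation distance
#' (1 - Pearson correlation across samples) and average linkage, the classic
#' combination for expression heat maps. A zero-variance gene has no defined
#' correlation and is assigned the maximal distance (2) to every other gene.
#' Leaf order is deterministic for a given input order.
#'
#' @param normalized matrix of (log-ratio) values, genes in rows.
#' @return a list with `hclust` (the merge tree) and `leaf_order` (row
#'   indices in display order).
#' @export
cluster_genes <- function(normalized) {
  if (nrow(normalized) < 2L) stop("need at least 2 genes to cluster")
  sds <- apply(normalized, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(normalized)))
  d <- 1 - cc
  d[!is.finite(d)] <- 2
  flat <- which(sds == 0)
  d[flat, ] <- 2
  d[, flat] <- 2
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, leaf_order = hc$order)
}

#' Call differential expression under stress
#'
#' Per gene, the fold change is the ratio of linear-scale arm means
#' (condition over control) and the p-value comes from a two-sided Welch
#' t-test on log2 signals. A gene is `UP` when fold > `fc_hi` and
#' p < `alpha`, `DOWN` when fold < `fc_lo` and p < `alpha`, otherwise
#' `NONE`.
#'
#' @param em an [expression_matrix()].
#' @param condition condition label of the treatment arm (matched against
#'   `sample_meta$condition`).
#' @param control condition label of the control arm (default
#'   `"control"`).
#' @param fc_hi,fc_lo fold-change gates (defaults 2 and 0.5).
#' @param alpha significance level (default 0.05).
#' @param pseudo floor for zero signals before taking logs; default half the
#'   smallest positive value.
#' @return a data.frame with columns `gene_id`, `condition`, `fold_change`,
#'   `p_value`, `call`.
#' @export
call_stress_de <- function(em, condition, control = "control",
                           fc_hi = 2, fc_lo = 0.5, alpha = 0.05,
                           pseudo = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  trt <- em$sample_meta$condition == condition
  ctl <- em$sample_meta$condition == control
  if (sum(trt) < 2L || sum(ctl) < 2L)
    stop("need >= 2 replicates per arm")
  v <- em$values
  if (is.null(pseudo))
    pseudo <- if (any(v > 0)) min(v[v > 0]) * 0.5 else 1e-3
  v[v == 0] <- pseudo
  lv <- log2(v)
  rows <- lapply(seq_len(nrow(v)), function(i) {
    fold <- mean(v[i, trt]) / mean(v[i, ctl])
    p <- tryCatch(
      stats::t.test(lv[i, trt], lv[i, ctl], var.equal = FALSE)$p.value,
      error = function(e) 1)
    call <- if (fold > fc_hi && p < alpha) "UP"
            else if (fold < fc_lo && p < alpha) "DOWN"
            else "NONE"
    data.frame(gene_id = rownames(v)[i], condition = condition,
               fold_change = fold, p_value = p, call = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
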