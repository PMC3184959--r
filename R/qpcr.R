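#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10(template amount) over a dilution
#' series. With a three-fold series and 100% amplification efficiency the
#' Ct drops by log2(3) per step, giving the closed-form slope
#' -log2(3)/log10(3) = -ln(10)/ln(2) = -3.3219.
#'
#' @param cts Ct values, one per dilution point (NA = undetected, dropped).
#' @param amounts template amounts of the series, default the three-fold
#'   series 10, 30, 90, 270, 810, 2430.
#' @return a list with `slope`, `intercept`, `r_squared`, and `efficiency`
#'   (`10^(-1/slope) - 1`, the conventional per-cycle efficiency estimate).
#' @export
qpcr_standard_curve <- function(cts, amounts = c(10, 30, 90, 270, 810, 2430)) {
  stopifnot(length(cts) == length(amounts))
  ok <- !is.na(cts)
  cts <- cts[ok]
  amounts <- amounts[ok]
  if (length(cts) < 3L) stop("need at least 3 dilution points")
  ord <- order(amounts)
  if (any(diff(cts[ord]) > 0))
    warning("Ct not monotone decreasing with amount")
  fit <- stats::lm(cts ~ log10(amounts))
  slope <- unname(stats::coef(fit)[2L])
  ss_tot <- sum((cts - mean(cts))^2)
  if (ss_tot == 0) warning("degenerate standard curve: all Ct equal")
  r2 <- if (ss_tot == 0) NaN else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       efficiency = if (slope < 0) 10^(-1 / slope) - 1 else NA_real_)
}

#' Relative expression by the standard-curve method
#'
#' Technical replicates are averaged on the Ct scale; each Ct is converted
#' to a template quantity through the gene's standard curve
#' (`quantity = 10^((Ct - intercept)/slope)`); quantities are normalized by
#' the geometric mean of the reference (housekeeping) gene quantities in the
#' same sample; biological replicates are summarized as mean and sd.
#'
#' Samples in which any reference gene is undetected are flagged and
#' excluded from the summaries.
#'
#' @param plate data.frame with columns `gene`, `sample`, `bio_rep`,
#'   `tech_rep`, `ct` (`NA` = undetected).
#' @param curves named list of standard curves (one per gene) from
#'   [qpcr_standard_curve()].
#' @param reference_genes character vector of housekeeping gene names
#'   (conventionally four).
#' @return a list with `relative` (per gene / sample / biological replicate
#'   relative levels), `summary` (per gene / sample mean and sd over
#'   biological replicates), and `excluded_samples`.
#' @export
qpcr_relative_expression <- function(plate, curves, reference_genes) {
  need <- c("gene", "sample", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate missing column(s): ",
                         paste(miss, collapse = ", "))
  miss_curve <- setdiff(unique(plate$gene), names(curves))
  if (length(miss_curve)) stop("no standard curve for gene(s): ",
                               paste(miss_curve, collapse = ", "))
  # mean Ct over technical replicates (NA technical replicates dropped)
  agg <- stats::aggregate(ct ~ gene + sample + bio_rep, data = plate,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$quantity <- vapply(seq_len(nrow(agg)), function(i) {
    cu <- curves[[agg$gene[i]]]
    10^((agg$ct[i] - cu$intercept) / cu$slope)
  }, numeric(1L))
  # geometric mean of reference quantities per (sample, bio_rep)
  key <- interaction(agg$sample, agg$bio_rep, drop = TRUE)
  excluded <- character()
  norm <- rep(NA_real_, nrow(agg))
  for (k in levels(key)) {
    idx <- key == k
    refs <- agg$quantity[idx & agg$gene %in% reference_genes]
    if (length(refs) < length(reference_genes) || any(!is.finite(refs))) {
      excluded <- c(excluded, k)
      next
    }
    norm[idx] <- exp(mean(log(refs)))
  }
  agg$relative <- agg$quantity / norm
  targets <- agg[!(agg$gene %in% reference_genes) & !is.na(agg$relative), ]
  summ <- if (nrow(targets)) {
    s <- stats::aggregate(relative ~ gene + sample, data = targets,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x)))
    data.frame(gene = s$gene, sample = s$sample,
               mean = s$relative[, "mean"], sd = s$relative[, "sd"])
  } else {
    data.frame(gene = character(), sample = character(),
               mean = numeric(), sd = numeric())
  }
  list(relative = agg, summary = summ, excluded_samples = excluded)
}
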