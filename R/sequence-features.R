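#' PAST fraction of a sequence interval
#'
#' Fraction of Pro + Ala + Ser + Thr residues. A biased amino-acid
#' composition (>35% PAST) is a hallmark of arabinogalactan-protein core
#' backbones; the value is reported, not used as a hard gate.
#'
#' @param seq amino-acid string.
#' @param interval optional 1-based inclusive `c(start, end)` restricting the
#'   computation; default is the whole sequence.
#' @return a number in \[0, 1\].
#' @export
#' @examples
#' past_fraction("PAST")      # 1
#' past_fraction("APAPSPTPGG") # 0.8
past_fraction <- function(seq, interval = NULL) {
  if (!nzchar(seq)) stop("empty sequence")
  if (!is.null(interval)) {
    interval <- check_interval(interval, nchar(seq))
    seq <- substr(seq, interval[1L], interval[2L])
  }
  ch <- seq_chars(seq)
  sum(ch %in% c("P", "A", "S", "T")) / length(ch)
}

#' Find Pro-rich regions
#'
#' A Pro-rich region is a maximal run of Pro residues in which no more than
#' `max_gap` (default 11) non-Pro residues separate consecutive Pro. Runs
#' with fewer than two Pro are discarded. Region bounds are the first and
#' last Pro of the run. Pro residues inside `exclude` intervals do not
#' participate.
#'
#' @param seq amino-acid string.
#' @param max_gap maximum number of residues between consecutive Pro.
#' @param exclude optional list of 1-based inclusive intervals to mask.
#' @return a data.frame with columns `start`, `end`, `pro_count`,
#'   `past_fraction` (possibly 0 rows).
#' @export
find_pro_rich_regions <- function(seq, max_gap = 11L, exclude = NULL) {
  ch <- seq_chars(seq)
  pro <- which(ch == "P")
  if (!is.null(exclude) && length(exclude)) {
    for (iv in exclude) {
      iv <- check_interval(iv, nchar(seq), "excluded interval")
      pro <- pro[pro < iv[1L] | pro > iv[2L]]
    }
  }
  out <- data.frame(start = integer(), end = integer(),
                    pro_count = integer(), past_fraction = numeric())
  if (length(pro) < 2L) return(out)
  # chain Pro positions whenever the gap between consecutive ones <= max_gap
  breaks <- which(diff(pro) - 1L > max_gap)
  run_id <- cumsum(c(1L, seq_along(pro)[-1L] %in% (breaks + 1L)))
  for (g in split(pro, run_id)) {
    if (length(g) < 2L) next
    out <- rbind(out, data.frame(
      start = g[1L], end = g[length(g)], pro_count = length(g),
      past_fraction = past_fraction(seq, c(g[1L], g[length(g)]))))
  }
  rownames(out) <- NULL
  out
}

#' Find AG glycomodules within a Pro-rich region
#'
#' Scans for `[Ala/Ser/Thr]-Pro` dipeptides whose Pro lies inside the region
#' and is noncontiguous (not adjacent to another Pro), then groups kept
#' dipeptides into clusters whose consecutive start positions are at most
#' `max_start_gap` apart. Clusters of two or more dipeptides are putative
#' arabinosylation sites (AG glycomodules).
#'
#' @param seq amino-acid string.
#' @param region a one-row data.frame (or list) with `start` and `end`
#'   bounding a Pro-rich region, as from [find_pro_rich_regions()].
#' @param max_start_gap maximum spacing between consecutive member dipeptide
#'   starts (default 13, the 11-residue Pro spacing rule plus the dipeptide
#'   itself).
#' @return a list of glycomodules, each a list with `starts` (1-based
#'   dipeptide start positions) and `size`.
#' @export
find_glycomodules <- function(seq, region, max_start_gap = 13L) {
  check_interval(c(region$start, region$end), nchar(seq), "region")
  ch <- seq_chars(seq)
  n <- length(ch)
  # dipeptide start may sit one residue before the first Pro of the region
  lo <- max(1L, region$start - 1L)
  hi <- min(region$end, n - 1L)
  if (lo > hi) return(list())
  starts <- lo:hi
  keep <- ch[starts] %in% c("A", "S", "T") & ch[starts + 1L] == "P"
  # the member Pro (at start+1) must not touch another Pro
  p <- starts + 1L
  adj <- (p < n & ch[pmin(p + 1L, n)] == "P")
  keep <- keep & !adj & p >= region$start & p <= region$end
  starts <- starts[keep]
  if (length(starts) < 2L) return(list())
  breaks <- which(diff(starts) > max_start_gap)
  run_id <- cumsum(c(1L, seq_along(starts)[-1L] %in% (breaks + 1L)))
  mods <- lapply(split(starts, run_id), function(s)
    list(starts = as.integer(s), size = length(s)))
  unname(mods[vapply(mods, `[[`, integer(1L), "size") >= 2L])
}

#' Call an AGP-like region (ALR)
#'
#' Searches the protein outside `excluded` intervals (typically the
#' plastocyanin-like domain, the signal peptide, and the GPI omega-region)
#' for Pro-rich regions carrying AG glycomodules. The protein is called
#' ALR-positive when the total number of member dipeptides across qualifying
#' glycomodules reaches `min_dipeptides`.
#'
#' @param protein a [protein_record()] or plain amino-acid string.
#' @param excluded list of 1-based inclusive intervals to mask.
#' @param min_dipeptides minimum total glycomodule dipeptides for a positive
#'   call (default 3).
#' @return a list with `present` (logical), `glycomodules`, `regions`
#'   (qualifying Pro-rich regions), `n_dipeptides`, and `region_past` (PAST
#'   fraction over the union of qualifying regions; 0 when none).
#' @export
call_alr <- function(protein, excluded = list(), min_dipeptides = 3L) {
  seq <- if (inherits(protein, "protein_record")) protein$seq else protein
  if (!nzchar(seq)) stop("empty sequence")
  for (iv in excluded) check_interval(iv, nchar(seq), "excluded interval")
  regions <- find_pro_rich_regions(seq, exclude = excluded)
  mods <- list()
  keep_region <- logical(nrow(regions))
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      m <- find_glycomodules(seq, regions[i, ])
      if (length(m)) {
        keep_region[i] <- TRUE
        mods <- c(mods, m)
      }
    }
  }
  regions <- regions[keep_region, , drop = FALSE]
  n_dip <- sum(vapply(mods, `[[`, integer(1L), "size"))
  region_past <- if (nrow(regions)) {
    pos <- unlist(lapply(seq_len(nrow(regions)),
                         function(i) regions$start[i]:regions$end[i]))
    pos <- unique(pos)
    ch <- seq_chars(seq)[pos]
    sum(ch %in% c("P", "A", "S", "T")) / length(ch)
  } else 0
  list(present = n_dip >= min_dipeptides, glycomodules = mods,
       regions = regions, n_dipeptides = n_dip, region_past = region_past)
}

#' Toy signal-peptide and GPI-anchor-signal heuristics
#'
#' Simple pattern rules used only on synthetic sequences, standing in for
#' external predictors on real data (whose calls are supplied via annotation
#' tables instead). `heuristic_sp()` requires a hydrophobic stretch of at
#' least 8 residues from \{A,I,L,V,F,M,W\} starting within the first 6
#' positions and contained in residues 1-25. `heuristic_gas()` requires, in
#' the last 25 residues, a hydrophobic stretch of at least 10 ending within 3
#' residues of the C-terminus, plus a small residue \{S,A,G,N,C\} 10-20
#' positions upstream of the stretch start.
#'
#' @param seq amino-acid string of length >= 40.
#' @return a logical scalar.
#' @export
heuristic_sp <- function(seq) {
  if (nchar(seq) < 40L) stop("sequence shorter than 40 residues")
  ch <- seq_chars(substr(seq, 1L, 25L))
  runs <- hydrophobic_runs(ch)
  any(runs$length >= 8L & runs$start <= 6L)
}

#' @rdname heuristic_sp
#' @export
heuristic_gas <- function(seq) {
  n <- nchar(seq)
  if (n < 40L) stop("sequence shorter than 40 residues")
  offset <- n - 25L
  ch_all <- seq_chars(seq)
  ch <- ch_all[(offset + 1L):n]
  runs <- hydrophobic_runs(ch)
  for (i in seq_along(runs$start)) {
    if (runs$length[i] < 10L) next
    end_abs <- offset + runs$start[i] + runs$length[i] - 1L
    if (end_abs < n - 3L) next
    start_abs <- offset + runs$start[i]
    up <- (start_abs - 20L):(start_abs - 10L)
    up <- up[up >= 1L]
    if (length(up) && any(ch_all[up] %in% AA_SMALL)) return(TRUE)
  }
  FALSE
}

# Maximal runs of hydrophobic residues; returns start positions and lengths
# relative to the supplied character vector.
hydrophobic_runs <- function(ch) {
  r <- rle(ch %in% AA_HYDROPHOBIC)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], length = r$lengths[keep])
}

#' Per-protein sequence feature report
#'
#' Convenience wrapper producing one row per protein: whole-sequence PAST
#' fraction, number of Pro-rich regions, number of glycomodules and the ALR
#' call (computed outside the supplied excluded intervals, if any).
#'
#' @param records list of [protein_record()] objects.
#' @param excluded optional named list (by protein id) of interval lists to
#'   mask per protein.
#' @return a data.frame with columns `id`, `past_fraction`,
#'   `n_pro_rich_regions`, `n_glycomodules`, `alr_present`.
#' @export
feature_report <- function(records, excluded = list()) {
  rows <- lapply(records, function(rec) {
    exc <- excluded[[rec$id]]
    if (is.null(exc)) exc <- list()
    alr <- call_alr(rec, excluded = exc)
    data.frame(id = rec$id,
               past_fraction = past_fraction(rec$seq),
               n_pro_rich_regions = nrow(find_pro_rich_regions(rec$seq,
                                                               exclude = exc)),
               n_glycomodules = length(alr$glycomodules),
               alr_present = alr$present)
  })
  do.call(rbind, rows)
}
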