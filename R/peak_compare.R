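# Comparative occupancy analytics between two peak sets (wild-type vs
# DNA-binding-mutant factor): matched-region strength, motif copy-number
# stratification, positional profiles and WRE-Helper spacing.

.peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' All overlapping region pairs between two peak sets
#'
#' Every pair sharing at least `min_overlap` bases is reported; a peak may
#' appear in several pairs.  Order is deterministic (by position of the
#' first-set peak, then the second).
#'
#' @param peaks_a,peaks_b Peak `data.frame`s.
#' @param min_overlap Minimum shared bases (>= 1).
#' @return `data.frame` with columns `peak_id_a`, `peak_id_b`,
#'   `overlap_bp`, `score_a`, `score_b`.
#' @export
overlap_regions <- function(peaks_a, peaks_b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  gra <- .peaks_granges(peaks_a)
  grb <- .peaks_granges(peaks_b)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gra)[qi], IRanges::ranges(grb)[si]))
  ord <- order(peaks_a$chrom[qi], peaks_a$start[qi], peaks_b$start[si])
  data.frame(peak_id_a = peaks_a$peak_id[qi][ord],
             peak_id_b = peaks_b$peak_id[si][ord],
             overlap_bp = as.integer(ov[ord]),
             score_a = peaks_a$score[qi][ord],
             score_b = peaks_b$score[si][ord])
}

#' Keep each first-set peak's maximum-overlap partner
#'
#' Used for paired score tests, avoiding pseudo-replication when one peak
#' overlaps several in the other set.  Ties go to the earlier partner in
#' the deterministic pair order.
#'
#' @param pairs Output of [overlap_regions()].
#' @return One row per distinct `peak_id_a`.
#' @export
best_partner_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  ord <- order(match(pairs$peak_id_a, unique(pairs$peak_id_a)),
               -pairs$overlap_bp)
  out <- pairs[ord, , drop = FALSE]
  out <- out[!duplicated(out$peak_id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal overlap of top-ranked peaks
#'
#' Fraction of each set's top-ranked peaks (by score) overlapping at least
#' one peak of the *full* other set.
#'
#' @param peaks_a,peaks_b Peak `data.frame`s.
#' @param top_fraction Fraction of each set to rank-select (0, 1].
#' @return Named numeric vector `c(frac_a_in_b, frac_b_in_a)`.
#' @export
reciprocal_overlap_fraction <- function(peaks_a, peaks_b,
                                        top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            nrow(peaks_a) > 0L, nrow(peaks_b) > 0L)
  frac_in <- function(top, full) {
    hits <- GenomicRanges::countOverlaps(.peaks_granges(top),
                                         .peaks_granges(full))
    mean(hits > 0L)
  }
  ta <- top_peaks(peaks_a, max(1L, floor(top_fraction * nrow(peaks_a))))
  tb <- top_peaks(peaks_b, max(1L, floor(top_fraction * nrow(peaks_b))))
  c(frac_a_in_b = frac_in(ta, peaks_b), frac_b_in_a = frac_in(tb, peaks_a))
}

#' Classify matched-region strength and test the paired score difference
#'
#' A pair is `a_stronger` when `score_a / score_b >= ratio_threshold`,
#' `b_stronger` when `<= 1/ratio_threshold`, otherwise `similar`.  The
#' paired test (default Wilcoxon signed-rank on each first-set peak's
#' maximum-overlap partner) or the unpaired Mann-Whitney variant is
#' reported alongside.
#'
#' @param pairs Output of [overlap_regions()]; scores must be positive.
#' @param ratio_threshold Symmetric ratio band for `similar` (> 1).
#' @param test `"signed_rank"` (paired, default) or `"mann_whitney"`
#'   (unpaired, on the same deduplicated pairs).
#' @return List: `pairs` (input plus `class` column), `class_counts`,
#'   `p_value`, `statistic`, `n_tested`, `test`.
#' @export
classify_strength <- function(pairs, ratio_threshold = 1.5,
                              test = c("signed_rank", "mann_whitney")) {
  test <- match.arg(test)
  stopifnot(ratio_threshold > 1)
  if (any(pairs$score_a <= 0 | pairs$score_b <= 0)) {
    stop("peak scores must be positive for strength classification")
  }
  ratio <- pairs$score_a / pairs$score_b
  cls <- ifelse(ratio >= ratio_threshold, "a_stronger",
                ifelse(ratio <= 1 / ratio_threshold, "b_stronger",
                       "similar"))
  pairs$class <- cls
  dd <- best_partner_pairs(pairs)
  res <- if (test == "signed_rank") {
    wilcoxon_signed_rank_test(dd$score_a, dd$score_b)
  } else {
    mann_whitney_test(dd$score_a, dd$score_b)
  }
  list(pairs = pairs,
       class_counts = table(factor(cls, levels = c("a_stronger",
                                                   "b_stronger", "similar"))),
       p_value = res$p_value, statistic = res$statistic,
       n_tested = nrow(dd), test = test)
}

#' Default copy-number bins
#'
#' @return Named list of `c(lo, hi)` count ranges.
#' @export
default_copy_bins <- function() {
  list(`0` = c(0, 0), `1` = c(1, 1), `2-3` = c(2, 3), `4+` = c(4, Inf))
}

#' Stratify matched-region score differences by motif copy number
#'
#' Pairs (deduplicated to each first-set peak's best partner) are binned by
#' the motif count of the first-set peak; per-bin score-difference
#' summaries and between-bin Mann-Whitney p-values quantify whether higher
#' copy number tracks larger occupancy differences.
#'
#' @param pairs Output of [overlap_regions()].
#' @param profiles Profile table ([profile_peaks()]) covering the first-set
#'   peaks.
#' @param motif Motif name used for binning.
#' @param bins Named list of `c(lo, hi)` inclusive count ranges.
#' @return List: `summary` (`data.frame` bin / n / median_diff /
#'   mean_diff), `tests` (`data.frame` bin_a / bin_b / p_value; bins with
#'   fewer than 2 pairs are not tested), `diffs` (per-bin list of score
#'   differences).
#' @export
stratify_by_copy_number <- function(pairs, profiles, motif = "shortHelper",
                                    bins = default_copy_bins()) {
  dd <- best_partner_pairs(pairs)
  cnt <- motif_counts(profiles, motif)
  missing <- setdiff(dd$peak_id_a, names(cnt))
  if (length(missing) > 0L) {
    stop("no profile for peak: ", missing[1L])
  }
  k <- cnt[dd$peak_id_a]
  diff <- dd$score_a - dd$score_b
  binned <- lapply(bins, function(rg) diff[k >= rg[1L] & k <= rg[2L]])
  summ <- data.frame(
    bin = names(bins),
    n = vapply(binned, length, 0L),
    median_diff = vapply(binned, function(d)
      if (length(d) > 0L) median(d) else NA_real_, 0),
    mean_diff = vapply(binned, function(d)
      if (length(d) > 0L) mean(d) else NA_real_, 0))
  rownames(summ) <- NULL
  combos <- utils::combn(names(bins), 2L)
  tests <- lapply(seq_len(ncol(combos)), function(i) {
    a <- binned[[combos[1L, i]]]; b <- binned[[combos[2L, i]]]
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    data.frame(bin_a = combos[1L, i], bin_b = combos[2L, i],
               p_value = mann_whitney_test(a, b)$p_value)
  })
  tests <- do.call(rbind, tests[!vapply(tests, is.null, TRUE)])
  if (is.null(tests)) {
    tests <- data.frame(bin_a = character(0), bin_b = character(0),
                        p_value = numeric(0))
  }
  list(summary = summ, tests = tests, diffs = binned)
}

#' Histogram of motif-center offsets from peak centers
#'
#' The offset of each hit is `motif center - peak center`, with peak center
#' `floor((start + end) / 2)` in genome coordinates and motif center `peak
#' start + hit start + floor(m / 2)`.  Counts are tabulated over
#' `[-window/2, window/2)`.
#'
#' @param hits Peak-relative hit table ([scan_peaks()]).
#' @param peaks Peak `data.frame` covering the hit peak ids.
#' @param motifs Named patterns (to obtain motif lengths).
#' @param window Total histogram width in bp.
#' @param bin_width Bin width in bp.
#' @return `data.frame` with `bin_start`, `bin_end` (offsets, half-open)
#'   and `count`.
#' @export
motif_center_profile <- function(hits, peaks, motifs, window = 2000L,
                                 bin_width = 50L) {
  breaks <- seq(-window / 2, window / 2, by = bin_width)
  if (nrow(hits) == 0L) {
    return(data.frame(bin_start = breaks[-length(breaks)],
                      bin_end = breaks[-1L],
                      count = 0L))
  }
  idx <- match(hits$peak_id, peaks$peak_id)
  if (anyNA(idx)) stop("hit references unknown peak: ",
                       hits$peak_id[is.na(idx)][1L])
  m <- nchar(motifs[hits$motif])
  peak_center <- floor((peaks$start[idx] + peaks$end[idx]) / 2)
  motif_center <- peaks$start[idx] + hits$start + floor(m / 2)
  offset <- motif_center - peak_center
  offset <- offset[offset >= -window / 2 & offset < window / 2]
  bin <- findInterval(offset, breaks, rightmost.closed = FALSE)
  cnt <- tabulate(bin, nbins = length(breaks) - 1L)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1L],
             count = cnt)
}

#' WRE-Helper spacing and orientation records
#'
#' One record per (WRE hit, Helper hit) pair within the same peak.  The
#' gap is measured edge to edge and signed relative to the WRE hit's
#' strand: positive when the Helper lies 3' of the WRE in the WRE's
#' orientation.  Orientation is `same` when the two hits are on the same
#' strand.
#'
#' @param hits Peak-relative hit table ([scan_peaks()]) containing both
#'   motifs.
#' @param motifs Named patterns (for motif lengths).
#' @param wre,helper Motif names.
#' @return `data.frame`: `peak_id`, `wre_start`, `wre_strand`,
#'   `helper_start`, `helper_strand`, `signed_gap`,
#'   `relative_orientation`.
#' @export
spacing_orientation <- function(hits, motifs, wre = "WRE",
                                helper = "Helper") {
  m_wre <- nchar(motifs[[wre]])
  m_helper <- nchar(motifs[[helper]])
  wre_hits <- hits[hits$motif == wre, ]
  helper_hits <- hits[hits$motif == helper, ]
  common <- intersect(unique(wre_hits$peak_id), unique(helper_hits$peak_id))
  recs <- lapply(common, function(pid) {
    wh <- wre_hits[wre_hits$peak_id == pid, ]
    hh <- helper_hits[helper_hits$peak_id == pid, ]
    grid <- expand.grid(iw = seq_len(nrow(wh)), ih = seq_len(nrow(hh)))
    ws <- wh$start[grid$iw]; we <- ws + m_wre
    hs <- hh$start[grid$ih]; he <- hs + m_helper
    # forward-coordinate edge gap: positive when Helper is right of the WRE
    gap_fwd <- ifelse(hs + he >= ws + we, hs - we, he - ws)
    flip <- wh$strand[grid$iw] == "-"
    data.frame(peak_id = pid,
               wre_start = ws, wre_strand = wh$strand[grid$iw],
               helper_start = hs, helper_strand = hh$strand[grid$ih],
               signed_gap = as.integer(ifelse(flip, -gap_fwd, gap_fwd)),
               relative_orientation = ifelse(
                 wh$strand[grid$iw] == hh$strand[grid$ih],
                 "same", "opposite"))
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(peak_id = character(0), wre_start = integer(0),
                      wre_strand = character(0), helper_start = integer(0),
                      helper_strand = character(0), signed_gap = integer(0),
                      relative_orientation = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Summarize spacing records as a gap x orientation count table
#'
#' @param records Output of [spacing_orientation()].
#' @param gap_breaks Breaks for binning signed gaps.
#' @return `data.frame` with `gap_bin`, `orientation`, `count`.
#' @export
spacing_summary <- function(records,
                            gap_breaks = c(-Inf, -50, -25, -11, 0, 11, 25,
                                           50, Inf)) {
  if (nrow(records) == 0L) {
    return(data.frame(gap_bin = character(0), orientation = character(0),
                      count = integer(0)))
  }
  gb <- cut(records$signed_gap, gap_breaks, right = FALSE)
  tab <- as.data.frame(table(gap_bin = gb,
                             orientation = records$relative_orientation))
  names(tab)[3L] <- "count"
  tab
}

#' Compare per-peak motif incidence between two peak sets
#'
#' @param profiles_a,profiles_b Profile tables ([profile_peaks()]).
#' @param motif Motif name.
#' @return List: `mean_incidence_a`, `mean_incidence_b`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_incidence <- function(profiles_a, profiles_b, motif) {
  ia <- profiles_a$incidence[profiles_a$motif == motif]
  ib <- profiles_b$incidence[profiles_b$motif == motif]
  stopifnot(length(ia) > 0L, length(ib) > 0L)
  res <- mann_whitney_test(ia, ib)
  list(mean_incidence_a = mean(ia), mean_incidence_b = mean(ib),
       p_value = res$p_value, n_a = length(ia), n_b = length(ib))
}

#' Fraction of peaks containing a motif
#'
#' @param profiles Profile table ([profile_peaks()]).
#' @param motif Motif name.
#' @param min_count Minimum occurrences to count a peak (default 1).
#' @return Proportion in [0, 1].
#' @export
fraction_with_motif <- function(profiles, motif, min_count = 1L) {
  cnt <- motif_counts(profiles, motif)
  mean(cnt >= min_count)
}
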