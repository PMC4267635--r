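# IUPAC degenerate-motif scanning.
#
# The scanner is deliberately simple and exhaustive: every window on both
# strands is tested, overlapping occurrences are kept, and an N in the
# scanned sequence matches no motif symbol (assembly gaps never create
# hits).  Minus-strand occurrences are found by matching the reverse
# complement of the pattern and are reported with the leftmost coordinate
# on the forward sequence, so one coordinate system serves all downstream
# spacing and positional analyses.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

SCAN_BASES <- c("A", "C", "G", "T", "N")

# symbol x base membership matrix; the base N row is all FALSE
.iupac_allow <- local({
  m <- sapply(names(IUPAC_SETS), function(s) SCAN_BASES %in% IUPAC_SETS[[s]])
  rownames(m) <- SCAN_BASES
  m["N", ] <- FALSE
  m
})

#' Built-in motif set
#'
#' The motifs of the WRE/Helper system: the canonical Wnt Response Element
#' bound by the HMG box (`WRE`, CTTTGWWS), a relaxed 6-mer version
#' (`relaxedWRE`, CTTTGW), the extended GC-rich Helper site bound by the
#' C-clamp (`Helper`, RCCGCC) and its short form (`shortHelper`, RCCG).
#'
#' @return Named character vector of IUPAC patterns.
#' @export
builtin_motifs <- function() {
  c(WRE = "CTTTGWWS", relaxedWRE = "CTTTGW",
    Helper = "RCCGCC", shortHelper = "RCCG")
}

#' Does an IUPAC symbol match a base?
#'
#' Standard IUPAC semantics, except that the base N (unknown/assembly gap)
#' matches nothing.
#'
#' @param symbol A single IUPAC code.
#' @param base A single base in A, C, G, T, N.
#' @return Logical.
#' @export
iupac_match <- function(symbol, base) {
  if (!symbol %in% colnames(.iupac_allow)) {
    stop("invalid IUPAC symbol: ", symbol)
  }
  if (!base %in% SCAN_BASES) stop("invalid base: ", base)
  unname(.iupac_allow[base, symbol])
}

#' Reverse complement of an IUPAC pattern or sequence
#'
#' @param x Character vector of sequences over the IUPAC alphabet.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

.validate_pattern <- function(pattern) {
  sym <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (length(sym) < 2L) stop("motif pattern must have length >= 2")
  bad <- !sym %in% names(IUPAC_SETS)
  if (any(bad)) stop("invalid IUPAC symbol in pattern: ", sym[bad][1L])
  sym
}

.encode_sequence <- function(sequence) {
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1L]], SCAN_BASES)
  if (anyNA(codes)) stop("sequence contains characters outside A,C,G,T,N")
  codes
}

# vectorized single-strand match: 0-based start offsets of all windows
# matching `sym` (a character vector of IUPAC symbols) in encoded sequence
.match_starts <- function(codes, sym) {
  m <- length(sym)
  L <- length(codes)
  if (L < m) return(integer(0))
  n <- L - m + 1L
  ok <- .iupac_allow[codes[seq_len(n)], sym[1L]]
  for (j in seq_len(m)[-1L]) {
    idx <- which(ok)
    if (length(idx) == 0L) return(integer(0))
    ok[idx] <- .iupac_allow[codes[idx + j - 1L], sym[j]]
  }
  which(ok) - 1L
}

#' Scan one sequence for a degenerate motif on both strands
#'
#' All overlapping occurrences are reported.  Minus-strand occurrences are
#' found by matching the reverse complement of the pattern and reported
#' with `start` = 0-based offset of the leftmost matched base on the
#' forward sequence.  A window whose forward and reverse-complement
#' patterns both match yields two hits (one per strand).
#'
#' @param sequence Sequence over A, C, G, T, N.
#' @param pattern IUPAC pattern string.
#' @param motif_name Name recorded in the output (defaults to the pattern).
#' @param strands Strands to scan (subset of `c("+", "-")`).
#' @return `data.frame` with columns `motif`, `start`, `strand`, sorted by
#'   `start` then strand.
#' @export
scan_sequence <- function(sequence, pattern, motif_name = pattern,
                          strands = c("+", "-")) {
  sym <- .validate_pattern(pattern)
  stopifnot(all(strands %in% c("+", "-")))
  codes <- .encode_sequence(sequence)
  starts <- integer(0)
  strand <- character(0)
  if ("+" %in% strands) {
    s <- .match_starts(codes, sym)
    starts <- c(starts, s)
    strand <- c(strand, rep("+", length(s)))
  }
  if ("-" %in% strands) {
    rc <- .validate_pattern(reverse_complement(pattern))
    s <- .match_starts(codes, rc)
    starts <- c(starts, s)
    strand <- c(strand, rep("-", length(s)))
  }
  ord <- order(starts, strand)
  data.frame(motif = rep(motif_name, length(starts)),
             start = as.integer(starts[ord]), strand = strand[ord])
}

#' Scan a set of peak sequences for a motif set
#'
#' @param peak_sequences Named character vector (names are peak ids).
#' @param motifs Named character vector of IUPAC patterns.
#' @param strands Strands to scan.
#' @return `data.frame` with columns `peak_id`, `motif`, `start`, `strand`,
#'   one row per hit.
#' @export
scan_peaks <- function(peak_sequences, motifs, strands = c("+", "-")) {
  stopifnot(length(motifs) > 0L, !is.null(names(motifs)))
  res <- vector("list", length(peak_sequences) * length(motifs))
  k <- 0L
  ids <- names(peak_sequences)
  for (i in seq_along(peak_sequences)) {
    codes <- .encode_sequence(peak_sequences[[i]])
    for (mn in names(motifs)) {
      sym <- .validate_pattern(motifs[[mn]])
      rc <- .validate_pattern(reverse_complement(motifs[[mn]]))
      sp <- .match_starts(codes, sym)
      sm <- if ("-" %in% strands) .match_starts(codes, rc) else integer(0)
      if (!"+" %in% strands) sp <- integer(0)
      n <- length(sp) + length(sm)
      if (n > 0L) {
        k <- k + 1L
        st <- c(sp, sm)
        sd <- c(rep("+", length(sp)), rep("-", length(sm)))
        ord <- order(st, sd)
        res[[k]] <- data.frame(peak_id = rep(ids[i], n), motif = rep(mn, n),
                               start = as.integer(st[ord]), strand = sd[ord])
      }
    }
  }
  if (k == 0L) {
    return(data.frame(peak_id = character(0), motif = character(0),
                      start = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, res[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Per-peak motif count and incidence profiles
#'
#' Incidence is the count of motif occurrences (both strands, overlapping
#' occurrences included) divided by the peak length.
#'
#' @param peak_sequences Named character vector of peak sequences.
#' @param motifs Named character vector of IUPAC patterns.
#' @param strands Strands to scan.
#' @return Long-format `data.frame`: `peak_id`, `motif`, `length`, `count`,
#'   `incidence`, with one row per peak x motif.
#' @export
profile_peaks <- function(peak_sequences, motifs, strands = c("+", "-")) {
  stopifnot(length(motifs) > 0L, !is.null(names(motifs)))
  lens <- nchar(peak_sequences)
  if (any(lens == 0L)) stop("zero-length peak sequence: ",
                            names(peak_sequences)[lens == 0L][1L])
  hits <- scan_peaks(peak_sequences, motifs, strands)
  ids <- names(peak_sequences)
  out <- expand.grid(peak_id = ids, motif = names(motifs),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$peak_id, ids), match(out$motif, names(motifs))), ]
  rownames(out) <- NULL
  key <- paste(hits$peak_id, hits$motif, sep = "\r")
  cnt <- table(key)
  out$length <- as.integer(lens[out$peak_id])
  okey <- paste(out$peak_id, out$motif, sep = "\r")
  out$count <- as.integer(ifelse(okey %in% names(cnt), cnt[okey], 0L))
  out$incidence <- out$count / out$length
  out
}

#' Extract one motif's per-peak counts from a profile table
#'
#' @param profiles Output of [profile_peaks()].
#' @param motif Motif name.
#' @return Named integer vector of counts keyed by peak id.
#' @export
motif_counts <- function(profiles, motif) {
  sub <- profiles[profiles$motif == motif, ]
  if (nrow(sub) == 0L) stop("motif not present in profiles: ", motif)
  setNames(sub$count, sub$peak_id)
}

#' Build a positional weight matrix from aligned hit sequences
#'
#' Column probabilities are `(base count + pseudocount) / (n + 4 *
#' pseudocount)`.
#'
#' @param aligned_hit_sequences Character vector of equal-length sequences
#'   over A, C, G, T.
#' @param pseudocount Positive pseudocount added per base.
#' @param name Matrix name.
#' @param threshold_fraction Default scanning threshold as a fraction of the
#'   maximum attainable log-odds score.
#' @return A `cclamp_pwm` list: `name`, `columns` (4 x m probability
#'   matrix, rows A,C,G,T), `pseudocount`, `threshold_fraction`.
#' @export
pwm_from_hits <- function(aligned_hit_sequences, pseudocount = 0.25,
                          name = "pwm", threshold_fraction = 0.8) {
  stopifnot(length(aligned_hit_sequences) > 0L, pseudocount > 0,
            threshold_fraction > 0, threshold_fraction <= 1)
  lens <- nchar(aligned_hit_sequences)
  if (length(unique(lens)) != 1L) stop("hit sequences must have equal length")
  m <- lens[1L]
  n <- length(aligned_hit_sequences)
  chars <- do.call(rbind, strsplit(aligned_hit_sequences, "", fixed = TRUE))
  cols <- sapply(seq_len(m), function(j) {
    cnt <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    (as.numeric(cnt) + pseudocount) / (n + 4 * pseudocount)
  })
  cols <- matrix(cols, nrow = 4L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(name = name, columns = cols, pseudocount = pseudocount,
                 threshold_fraction = threshold_fraction),
            class = "cclamp_pwm")
}

#' Build a weight matrix from a degenerate consensus pattern
#'
#' Admitted bases share the column probability mass equally (up to the
#' pseudocount), so scanning with `threshold_fraction = 1` reproduces the
#' degenerate-pattern hit set.
#'
#' @param pattern IUPAC pattern.
#' @param pseudocount Small positive pseudocount.
#' @param name Matrix name.
#' @param threshold_fraction Default scanning threshold.
#' @return A `cclamp_pwm` object.
#' @export
pwm_from_consensus <- function(pattern, pseudocount = 1e-6, name = pattern,
                               threshold_fraction = 0.8) {
  sym <- .validate_pattern(pattern)
  cols <- sapply(sym, function(s) {
    p <- setNames(rep(pseudocount, 4L), c("A", "C", "G", "T"))
    p[IUPAC_SETS[[s]]] <- p[IUPAC_SETS[[s]]] + 1 / length(IUPAC_SETS[[s]])
    p / sum(p)
  })
  cols <- matrix(cols, nrow = 4L,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(list(name = name, columns = cols, pseudocount = pseudocount,
                 threshold_fraction = threshold_fraction),
            class = "cclamp_pwm")
}

# log-odds score matrix against a background frequency vector
.pwm_logodds <- function(wm, background) {
  bg <- background[c("A", "C", "G", "T")]
  log2(wm$columns / bg)
}

#' Scan a sequence with a positional weight matrix
#'
#' Each window on each strand is scored by the log-odds of the matrix
#' against the background nucleotide model; windows scoring at least
#' `threshold_fraction` times the maximum attainable score are hits.
#' Windows containing N are skipped.
#'
#' @param sequence Sequence over A, C, G, T, N.
#' @param wm A `cclamp_pwm` object.
#' @param background Named base-frequency vector (A, C, G, T); defaults to
#'   uniform.
#' @param threshold_fraction Override of the matrix default.
#' @param strands Strands to scan.
#' @return `data.frame` with columns `motif`, `start`, `strand`, `score`.
#' @export
pwm_scan <- function(sequence, wm, background = NULL,
                     threshold_fraction = NULL, strands = c("+", "-")) {
  stopifnot(inherits(wm, "cclamp_pwm"))
  if (is.null(background)) {
    background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  }
  if (is.null(threshold_fraction)) threshold_fraction <- wm$threshold_fraction
  lo <- .pwm_logodds(wm, background)
  m <- ncol(lo)
  max_score <- sum(apply(lo, 2L, max))
  cutoff <- threshold_fraction * max_score
  score_strand <- function(codes, lo) {
    L <- length(codes)
    if (L < m) return(list(starts = integer(0), scores = numeric(0)))
    n <- L - m + 1L
    sc <- rep(0, n)
    valid <- rep(TRUE, n)
    for (j in seq_len(m)) {
      cj <- codes[j:(j + n - 1L)]
      isn <- cj == 5L
      valid <- valid & !isn
      cj[isn] <- 1L
      sc <- sc + lo[cj, j]
    }
    keep <- which(valid & sc >= cutoff - 1e-12)
    list(starts = keep - 1L, scores = sc[keep])
  }
  codes <- .encode_sequence(sequence)
  # minus strand: score reverse-complemented windows = reverse columns and
  # complement rows of the log-odds matrix
  lo_rc <- lo[c("T", "G", "C", "A"), rev(seq_len(m)), drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  starts <- integer(0); strand <- character(0); score <- numeric(0)
  if ("+" %in% strands) {
    r <- score_strand(codes, lo)
    starts <- c(starts, r$starts)
    strand <- c(strand, rep("+", length(r$starts)))
    score <- c(score, r$scores)
  }
  if ("-" %in% strands) {
    r <- score_strand(codes, lo_rc)
    starts <- c(starts, r$starts)
    strand <- c(strand, rep("-", length(r$starts)))
    score <- c(score, r$scores)
  }
  ord <- order(starts, strand)
  data.frame(motif = rep(wm$name, length(starts)),
             start = as.integer(starts[ord]),
             strand = strand[ord], score = score[ord])
}

# all k-mer windows of a character vector of sequences (forward strand)
.kmer_windows <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  })
  w <- unlist(out, use.names = FALSE)
  w[!grepl("N", w, fixed = TRUE)]
}

#' Differential k-mer enrichment between two sequence sets
#'
#' A simplified differential motif analysis: k-mer windows are counted on
#' the forward strand with each k-mer unified with its reverse complement
#' (one count per window, so a palindromic window still counts once), and
#' each unified k-mer class is tested by a two-sided Fisher exact test of
#' its window count against the total window count in each set.
#'
#' @param seqs_a,seqs_b Character vectors of sequences (foreground,
#'   background).
#' @param k Word size (>= 4).
#' @param max_kmers Keep only the `max_kmers` most frequent classes
#'   (pooled) before testing; `Inf` tests all.
#' @return `data.frame` with columns `kmer` (canonical form), `count_a`,
#'   `count_b`, `odds_ratio`, `p`, `q`, sorted by `q` then descending odds
#'   ratio.
#' @export
differential_kmer_enrichment <- function(seqs_a, seqs_b, k = 6L,
                                         max_kmers = Inf) {
  stopifnot(k >= 4L, length(seqs_a) > 0L, length(seqs_b) > 0L)
  if (all(nchar(seqs_a) < k) || all(nchar(seqs_b) < k)) {
    stop("k is larger than every sequence in one of the sets")
  }
  canonical <- function(words) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)))
    ifelse(words <= rc, words, rc)
  }
  wa <- .kmer_windows(seqs_a, k)
  wb <- .kmer_windows(seqs_b, k)
  ca <- table(canonical(wa))
  cb <- table(canonical(wb))
  kmers <- union(names(ca), names(cb))
  count_a <- as.integer(ifelse(kmers %in% names(ca), ca[kmers], 0L))
  count_b <- as.integer(ifelse(kmers %in% names(cb), cb[kmers], 0L))
  if (is.finite(max_kmers) && length(kmers) > max_kmers) {
    keep <- order(-(count_a + count_b))[seq_len(max_kmers)]
    kmers <- kmers[keep]; count_a <- count_a[keep]; count_b <- count_b[keep]
  }
  tot_a <- length(wa); tot_b <- length(wb)
  res <- vapply(seq_along(kmers), function(i) {
    tab <- matrix(c(count_a[i], tot_a - count_a[i],
                    count_b[i], tot_b - count_b[i]), nrow = 2L)
    ft <- stats::fisher.test(tab)
    c(unname(ft$estimate), ft$p.value)
  }, numeric(2L))
  out <- data.frame(kmer = kmers, count_a = count_a, count_b = count_b,
                    odds_ratio = res[1L, ], p = res[2L, ])
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$q, -out$odds_ratio), ]
  rownames(out) <- NULL
  out
}
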