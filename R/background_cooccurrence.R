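# Background model for WRE/Helper co-occurrence.
#
# The observed number of peaks carrying at least one WRE and at least N
# Helper sites is compared with the number expected under an i.i.d.
# nucleotide background: each peak of length L offers 2*(L-m+1) windows
# per motif (both strands), each matching independently with the product
# of the per-position background probabilities admitted by the IUPAC
# symbols.  Window overlap dependence is ignored; the Monte Carlo checks
# in the test suite bound the resulting error.  The tail p-value for the
# observed count is exact for this model: a Poisson-binomial over the
# per-peak containment probabilities, computed by convolution.

#' Nucleotide background frequencies from a sequence set
#'
#' @param seqs Character vector of sequences; N bases are ignored.
#' @return Named frequency vector over A, C, G, T summing to 1.
#' @export
background_from_sequences <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  cnt <- table(factor(chars, levels = c("A", "C", "G", "T")))
  tot <- sum(cnt)
  if (tot == 0L) stop("no A/C/G/T bases in sequence set")
  as.numeric(cnt) / tot -> f
  setNames(f, c("A", "C", "G", "T"))
}

#' Uniform nucleotide background
#'
#' @return Named frequency vector with each base at 1/4.
#' @export
uniform_background <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}

.check_background <- function(background) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(background)))
  b <- background[c("A", "C", "G", "T")]
  if (abs(sum(b) - 1) > 1e-9 || any(b < 0)) {
    stop("background frequencies must be nonnegative and sum to 1")
  }
  b
}

#' Per-window match probability of a degenerate motif
#'
#' The product over pattern positions of the summed background frequencies
#' of the bases each IUPAC symbol admits.
#'
#' @param pattern IUPAC pattern string.
#' @param background Named base-frequency vector (A, C, G, T).
#' @return Probability that one window matches the pattern.
#' @export
position_match_probability <- function(pattern, background) {
  sym <- .validate_pattern(pattern)
  b <- .check_background(background)
  prod(vapply(sym, function(s) sum(b[IUPAC_SETS[[s]]]), 0))
}

#' Probability that a peak contains at least N motif occurrences
#'
#' Models the both-strand occurrence count in a length-`L` peak as
#' `Binomial(n = 2*(L - m + 1), p)` with `p` the per-window match
#' probability of the pattern on its own strand and of its reverse
#' complement on the other (equal by complement symmetry of the
#' background product), windows treated as independent.
#'
#' @param L Peak length in bp.
#' @param pattern IUPAC pattern string.
#' @param n_min Minimum number of occurrences (>= 1).
#' @param background Named base-frequency vector.
#' @return `P(X >= n_min)`; 0 (with a warning) when `L < m`.
#' @export
containment_probability <- function(L, pattern, n_min = 1L, background) {
  sym <- .validate_pattern(pattern)
  stopifnot(n_min >= 1L)
  m <- length(sym)
  if (L < m) {
    warning("peak shorter than motif (L = ", L, ", m = ", m, ")")
    return(0)
  }
  # the reverse-complement pattern has the same match probability only for
  # complement-symmetric backgrounds; compute both explicitly
  p_fwd <- position_match_probability(pattern, background)
  p_rev <- position_match_probability(reverse_complement(pattern), background)
  n_windows <- L - m + 1
  # total count = Binom(n, p_fwd) + Binom(n, p_rev); for equal p this is
  # Binom(2n, p); otherwise convolve the two binomial tails exactly
  if (abs(p_fwd - p_rev) < 1e-15) {
    return(pbinom(n_min - 1, size = 2 * n_windows, prob = p_fwd,
                  lower.tail = FALSE))
  }
  # exact convolution truncated where the mass becomes negligible
  kmax <- min(n_windows, n_min + ceiling(20 * (1 + n_windows * (p_fwd + p_rev))))
  pf <- stats::dbinom(0:kmax, n_windows, p_fwd)
  pr <- stats::dbinom(0:kmax, n_windows, p_rev)
  total <- rep(0, 2L * kmax + 1L)
  for (i in 0:kmax) {
    total[i + seq_len(kmax + 1L)] <- total[i + seq_len(kmax + 1L)] +
      pf[i + 1L] * pr
  }
  sum(total[(n_min + 1L):length(total)])
}

#' Exact Poisson-binomial survival function
#'
#' `P(X >= t)` for a sum of independent Bernoulli variables with success
#' probabilities `q`, computed by O(K^2) convolution.  Probabilities are
#' clipped to [0, 1] after each step for numerical stability.
#'
#' @param q Numeric vector of probabilities in [0, 1].
#' @param t Threshold count; `t <= 0` returns 1.
#' @return `P(X >= t)`.
#' @export
poisson_binomial_sf <- function(q, t) {
  stopifnot(all(q >= 0 & q <= 1))
  if (t <= 0) return(1)
  K <- length(q)
  if (t > K) return(0)
  pmf <- c(1, rep(0, K))  # pmf[j+1] = P(X = j) over processed terms
  for (i in seq_len(K)) {
    pmf <- c(pmf[1L] * (1 - q[i]),
             pmf[-1L] * (1 - q[i]) + pmf[-(K + 1L)] * q[i])
    pmf <- pmin(pmax(pmf, 0), 1)
  }
  min(1, max(0, sum(pmf[(t + 1L):(K + 1L)])))
}

#' Observed vs expected WRE/Helper co-occurrence table
#'
#' For each Helper copy threshold `N`, counts the peaks whose scanned
#' profiles show at least one WRE and at least `N` Helper sites, computes
#' the number expected under the background model, and an exact
#' Poisson-binomial upper-tail p-value for the observed count.
#'
#' @param profiles Long profile table from [profile_peaks()] containing the
#'   WRE and Helper motifs for every peak.
#' @param background Named base-frequency vector, e.g. from
#'   [background_from_sequences()].
#' @param n_values Helper thresholds to tabulate (default 1..5).
#' @param wre,helper Motif names in `profiles`.
#' @param wre_pattern,helper_pattern IUPAC patterns used for the
#'   background probabilities (default the built-in WRE/Helper).
#' @param condition_label Label copied into every row.
#' @param fixed_length If `TRUE`, use the mean peak length for every peak's
#'   containment probability (single-binomial variant) instead of per-peak
#'   lengths.
#' @return `data.frame` with one row per `N`: `condition`,
#'   `n_peaks_with_wre`, `helper_threshold`, `n_peaks_with_n_helpers`,
#'   `expected_both`, `observed_both`, `p_value`.
#' @export
cooccurrence_table <- function(profiles, background, n_values = 1:5,
                               wre = "WRE", helper = "Helper",
                               wre_pattern = builtin_motifs()[["WRE"]],
                               helper_pattern = builtin_motifs()[["Helper"]],
                               condition_label = "peaks",
                               fixed_length = FALSE) {
  wre_cnt <- motif_counts(profiles, wre)
  helper_cnt <- motif_counts(profiles, helper)
  ids <- names(wre_cnt)
  stopifnot(length(ids) > 0L, setequal(ids, names(helper_cnt)))
  helper_cnt <- helper_cnt[ids]
  lens <- profiles$length[profiles$motif == wre]
  if (fixed_length) lens <- rep(round(mean(lens)), length(lens))
  n_wre <- sum(wre_cnt >= 1L)
  p_wre <- vapply(lens, containment_probability, 0,
                  pattern = wre_pattern, n_min = 1L,
                  background = background)
  rows <- lapply(n_values, function(N) {
    observed <- sum(wre_cnt >= 1L & helper_cnt >= N)
    p_helper <- vapply(lens, containment_probability, 0,
                       pattern = helper_pattern, n_min = N,
                       background = background)
    q <- p_wre * p_helper
    data.frame(condition = condition_label,
               n_peaks_with_wre = n_wre,
               helper_threshold = N,
               n_peaks_with_n_helpers = sum(helper_cnt >= N),
               expected_both = sum(q),
               observed_both = observed,
               p_value = poisson_binomial_sf(q, observed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
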