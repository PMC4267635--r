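# Independent oracles and small data builders shared across tests.
# Every oracle here is written against the definition, not against the
# package implementation: the scanner oracle checks windows one by one,
# the statistics oracles enumerate the null distribution directly.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1L]]]), collapse = "")
}

# per-window, per-strand matcher; returns data.frame(start, strand)
naive_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  one_strand <- function(pat) {
    psym <- strsplit(pat, "", fixed = TRUE)[[1L]]
    m <- length(psym)
    L <- length(chars)
    if (L < m) return(integer(0))
    hits <- integer(0)
    for (s in 0:(L - m)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        b <- chars[s + j]
        if (b == "N" || !(b %in% iupac_sets[[psym[j]]])) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits <- c(hits, s)
    }
    hits
  }
  plus <- one_strand(pattern)
  minus <- one_strand(naive_revcomp(pattern))
  data.frame(start = c(plus, minus),
             strand = c(rep("+", length(plus)), rep("-", length(minus))))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# exact Mann-Whitney two-sided p by enumerating group assignments and
# counting x-beats-y pairs (U statistic), independently of rank sums
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(nx))
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, u_stat)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact signed-rank two-sided p by enumerating sign flips of the raw
# differences (ranks recomputed per outcome)
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  ws <- apply(signs, 1L, function(s) sum(rank(abs(d))[s > 0]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# exact hypergeometric upper-tail by enumerating all positions of set_b
oracle_hyper_p <- function(n_a, n_b, universe, observed) {
  combos <- utils::combn(universe, n_b)
  overlaps <- colSums(combos <= n_a)  # set_a occupies slots 1..n_a
  mean(overlaps >= observed)
}

# unweighted running-sum ES, written from the definition
oracle_gsea_es <- function(in_subset) {
  nh <- sum(in_subset); nm <- sum(!in_subset)
  run <- cumsum(ifelse(in_subset, 1 / nh, -1 / nm))
  run[which.max(abs(run))]
}

make_peaks <- function(chrom, start, end = start + 100L, score = NULL,
                       ids = NULL) {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = start, end = end,
             peak_id = if (is.null(ids)) sprintf("pk_%03d", seq_len(n))
                       else ids,
             score = if (is.null(score)) rep(1, n) else score)
}

make_genes <- function(gene_id, chrom, strand, tss, tes,
                       exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, chrom = rep_len(chrom, n),
             strand = strand, tss = tss, tes = tes,
             exon_starts = I(if (is.null(exon_starts))
               rep(list(integer(0)), n) else exon_starts),
             exon_ends = I(if (is.null(exon_ends))
               rep(list(integer(0)), n) else exon_ends))
}
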