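# Peak-to-feature annotation and promoter-background motif enrichment.
#
# Two promoter definitions coexist, both used in the analyses this
# package supports: a 4 kb window centered on the TSS for feature
# annotation, and a -1000/+100 bp window for promoter motif-density
# comparisons.  Both are explicit parameters.

#' Assign peaks to genomic feature categories
#'
#' The decision is made on the peak center with precedence promoter >
#' exon > intron > other > intergenic.  `promoter` is TSS +/-
#' `promoter_halfwidth`; `other` is within `tes_halfwidth` of the
#' transcript end; `intron` is inside the transcript but not in an exon.
#' The signed TSS distance is peak center minus TSS, flipped for minus
#' strand genes, so positive always means downstream of the TSS.
#'
#' @param peaks Peak `data.frame`.
#' @param genes Gene-model `data.frame` ([read_gene_models()]).
#' @param promoter_halfwidth Half-width of the promoter window (default
#'   2000, i.e. a 4 kb window).
#' @param tes_halfwidth Half-width of the transcript-end window (default
#'   1000).
#' @return `data.frame`: `peak_id`, `category`, `gene_id` (nearest TSS),
#'   `tss_distance`.
#' @export
assign_features <- function(peaks, genes, promoter_halfwidth = 2000L,
                            tes_halfwidth = 1000L) {
  categories <- c("promoter", "exon", "intron", "other", "intergenic")
  if (is.null(genes) || nrow(genes) == 0L) {
    warning("no gene models; all peaks assigned intergenic")
    return(data.frame(peak_id = peaks$peak_id,
                      category = factor(rep("intergenic", nrow(peaks)),
                                        levels = categories),
                      gene_id = NA_character_,
                      tss_distance = NA_integer_))
  }
  center <- floor((peaks$start + peaks$end) / 2)
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) {
      return(data.frame(peak_id = peaks$peak_id[i], category = "intergenic",
                        gene_id = NA_character_,
                        tss_distance = NA_integer_))
    }
    cen <- center[i]
    # nearest gene by |center - TSS|
    dist_raw <- cen - g$tss
    j <- which.min(abs(dist_raw))
    sgn <- ifelse(g$strand == "+", 1L, -1L)
    tssd <- as.integer(sgn[j] * dist_raw[j])
    # half-open promoter window [tss - hw, tss + hw)
    in_promoter <- dist_raw >= -promoter_halfwidth &
      dist_raw < promoter_halfwidth
    tx_lo <- pmin(g$tss, g$tes); tx_hi <- pmax(g$tss, g$tes)
    in_exon <- vapply(seq_len(nrow(g)), function(k) {
      es <- g$exon_starts[[k]]; ee <- g$exon_ends[[k]]
      length(es) > 0L && any(cen >= es & cen < ee)
    }, TRUE)
    in_tx <- cen >= tx_lo & cen < tx_hi
    near_tes <- abs(cen - g$tes) <= tes_halfwidth
    category <- if (any(in_promoter)) "promoter"
      else if (any(in_exon)) "exon"
      else if (any(in_tx)) "intron"
      else if (any(near_tes)) "other"
      else "intergenic"
    data.frame(peak_id = peaks$peak_id[i], category = category,
               gene_id = g$gene_id[j], tss_distance = tssd)
  })
  out <- do.call(rbind, out)
  out$category <- factor(out$category, levels = categories)
  rownames(out) <- NULL
  out
}

#' Feature category counts
#'
#' @param assignments Output of [assign_features()].
#' @return Named integer vector over all five categories; sums to the
#'   number of peaks.
#' @export
feature_distribution <- function(assignments) {
  table(assignments$category)
}

#' Promoter windows around TSSs
#'
#' Strand-aware windows from `upstream` bp before to `downstream` bp after
#' the TSS (default -1000/+100), truncated at chromosome edges when
#' lengths are supplied.
#'
#' @param genes Gene-model `data.frame`.
#' @param upstream,downstream Window extents in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   edge truncation.
#' @return `data.frame`: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
promoter_windows <- function(genes, upstream = 1000L, downstream = 100L,
                             chrom_lengths = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1L)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    end <- pmin(end, chrom_lengths[genes$chrom])
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end))
}

#' Motif density comparison between bound and background promoters
#'
#' Per-promoter incidence is occurrences per kb (count / length * 1000);
#' bound and background sets are compared by a two-sided Mann-Whitney
#' test.
#'
#' @param bound_promoter_seqs Character vector of promoter sequences with
#'   an associated peak.
#' @param all_promoter_seqs Background promoter sequences.
#' @param pattern IUPAC pattern (default the extended Helper site).
#' @return List: `incidence_per_kb_bound`, `incidence_per_kb_background`
#'   (means), `per_promoter_bound`, `per_promoter_background`, `p_value`.
#' @export
promoter_incidence_enrichment <- function(bound_promoter_seqs,
                                          all_promoter_seqs,
                                          pattern =
                                            builtin_motifs()[["Helper"]]) {
  per_kb <- function(seqs) {
    vapply(seqs, function(s) {
      nrow(scan_sequence(s, pattern)) / nchar(s) * 1000
    }, 0, USE.NAMES = FALSE)
  }
  ib <- per_kb(bound_promoter_seqs)
  ig <- per_kb(all_promoter_seqs)
  res <- mann_whitney_test(ib, ig)
  list(incidence_per_kb_bound = mean(ib),
       incidence_per_kb_background = mean(ig),
       per_promoter_bound = ib, per_promoter_background = ig,
       p_value = res$p_value)
}
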