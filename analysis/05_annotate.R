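#!/usr/bin/env Rscript
# Stage 5: genomic feature annotation and promoter Helper density.
#
# Assigns every top peak to promoter (4 kb window centered on the TSS) /
# exon / intron / other / intergenic, and compares Helper-site density
# (occurrences per kb) in promoters overlapped by WT peaks against all
# promoters (-1000/+100 bp windows).

suppressPackageStartupMessages(library(cclampscan))
source("analysis/common.R")

inp <- load_fixture()
dir.create("results/annotation", showWarnings = FALSE, recursive = TRUE)

for (set in c("wt", "mut")) {
  peaks <- if (set == "wt") inp$peaks_wt else inp$peaks_mut
  a <- assign_features(peaks, inp$genes)
  write.table(a, sprintf("results/annotation/features_%s.tsv", set),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(set, "feature distribution:\n")
  print(feature_distribution(a))
}

prom <- promoter_windows(inp$genes,
                         chrom_lengths = nchar(inp$genome))
prom_peaks <- data.frame(chrom = prom$chrom, start = prom$start,
                         end = prom$end, peak_id = prom$gene_id,
                         score = 0)
prom_seqs <- extract_peak_sequences(prom_peaks, inp$genome)
bound <- unique(overlap_regions(prom_peaks, inp$peaks_wt)$peak_id_a)
if (length(bound) >= 2 && length(bound) < length(prom_seqs)) {
  enr <- promoter_incidence_enrichment(prom_seqs[bound], prom_seqs)
  cat(sprintf(
    "Helper density: %.2f per kb in WT-bound promoters (n=%d) vs %.2f in all promoters (n=%d); Mann-Whitney p = %.3g\n",
    enr$incidence_per_kb_bound, length(bound),
    enr$incidence_per_kb_background, length(prom_seqs), enr$p_value))
} else {
  cat("Too few WT-bound promoters for the density comparison\n")
}
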