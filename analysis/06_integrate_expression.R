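#!/usr/bin/env Rscript
# Stage 6: linking occupancy to nascent-transcription changes.
#
# Selects regulated genes (p < 0.02), links peaks with score > 67 to
# genes with a TSS within 30 kb of the peak center, tests the overlap of
# downregulated and peak-linked genes (hypergeometric, detected-gene
# universe), runs the unweighted peak-score GSEA, and stratifies
# downregulation by the motif class of each gene's linked peaks.

suppressPackageStartupMessages(library(cclampscan))
source("analysis/common.R")

inp <- load_fixture()
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

motifs <- builtin_motifs()
prof_wt <- profile_peaks(inp$seqs_wt, motifs)

reg <- select_regulated(inp$expression, p_cutoff = 0.02)
cat(sprintf("Regulated genes at p<0.02: %d down, %d up (%.0f%% down)\n",
            length(reg$down), length(reg$up),
            100 * length(reg$down) /
              max(1, length(reg$down) + length(reg$up))))

links <- link_peaks_to_genes(inp$peaks_wt, inp$genes,
                             max_distance = 30000L, min_score = 67)
classes <- classify_gene_links(links, prof_wt)
write.table(classes, "results/integration/gene_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ov <- hypergeometric_overlap(reg$down, unique(links$gene_id),
                             nrow(inp$expression))
cat(sprintf(
  "Downregulated genes with a linked peak (score > 67, 30 kb): %d (hypergeometric p = %.3g)\n",
  ov$overlap, ov$p_value))

linked_down <- intersect(reg$down, classes$gene_id)
ranked <- classes$gene_id[order(-classes$max_peak_score,
                                classes$gene_id)]
if (length(linked_down) >= 1 && length(linked_down) < length(ranked)) {
  gsea <- peak_score_gsea(ranked, linked_down, n_permutations = 2000,
                          seed = 42)
  cat(sprintf("Peak-score GSEA: ES = %.3f, permutation p = %.3g\n",
              gsea$enrichment_score, gsea$p_value))
}

assoc <- motif_class_association(classes, inp$expression)
write.table(assoc$summary, "results/integration/class_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(assoc$tests, "results/integration/class_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Median log2 fold change by motif class of linked peaks:\n")
print(assoc$summary, digits = 3)

report <- target_gene_report(links, classes, inp$expression, reg$down)
write.table(report, "results/integration/target_genes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Target-gene report: %d downregulated genes with linked peaks\n",
            nrow(report)))
print(head(report[, c("gene_id", "log2_fold_change", "tss_distances",
                      "motif_class")], 5))
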