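#!/usr/bin/env Rscript
# Stage 2: degenerate-motif scanning of the top peaks.
#
# Scans the top 1000 peaks of each set for the built-in motifs (WRE,
# relaxed WRE, Helper, short Helper), compares per-peak Helper/WRE
# incidence between WT and mut, and runs the simplified differential
# k-mer analysis with the mut peaks as background.  The expectation from
# the study design: similar WRE content in both sets, excess Helper
# content in WT, and GC-rich Helper-like 6-mers at the top of the
# differential table.

suppressPackageStartupMessages(library(cclampscan))
source("analysis/common.R")

inp <- load_fixture()
dir.create("results/motifs", showWarnings = FALSE, recursive = TRUE)

motifs <- builtin_motifs()
prof_wt <- profile_peaks(inp$seqs_wt, motifs)
prof_mut <- profile_peaks(inp$seqs_mut, motifs)
write.table(prof_wt, "results/motifs/profiles_wt.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof_mut, "results/motifs/profiles_mut.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (mn in c("WRE", "Helper")) {
  cmp <- compare_incidence(prof_wt, prof_mut, mn)
  cat(sprintf(
    "%s incidence: WT %.4g vs mut %.4g per bp (Mann-Whitney p = %.3g)\n",
    mn, cmp$mean_incidence_a, cmp$mean_incidence_b, cmp$p_value))
  cat(sprintf("%s present in %.1f%% of WT and %.1f%% of mut peaks\n", mn,
              100 * fraction_with_motif(prof_wt, mn),
              100 * fraction_with_motif(prof_mut, mn)))
}

kmer <- differential_kmer_enrichment(unname(inp$seqs_wt),
                                     unname(inp$seqs_mut), k = 6,
                                     max_kmers = 500)
write.table(kmer, "results/motifs/differential_kmers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Top differential 6-mers (WT vs mut background):\n")
print(head(kmer, 5))
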