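#!/usr/bin/env Rscript
# Stage 4: comparative occupancy between the WT and mutant peak sets.
#
# Matched-region strength (which set binds co-occupied regions more
# strongly), stratification of the score difference by Helper copy
# number, the positional profile of short Helper sites around WT peak
# centers, WRE-Helper spacing/orientation, and replicate-style reciprocal
# overlap of the top 20% of peaks.

suppressPackageStartupMessages(library(cclampscan))
source("analysis/common.R")

inp <- load_fixture()
dir.create("results/comparison", showWarnings = FALSE, recursive = TRUE)

motifs <- builtin_motifs()
prof_wt <- profile_peaks(inp$seqs_wt, motifs)
hits_wt <- scan_peaks(inp$seqs_wt, motifs)

pairs <- overlap_regions(inp$peaks_wt, inp$peaks_mut)
strength <- classify_strength(pairs)
write.table(strength$pairs, "results/comparison/matched_pairs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Co-occupied regions: %d pairs (%d distinct WT peaks)\n",
            nrow(pairs), strength$n_tested))
print(strength$class_counts)
cat(sprintf("Paired signed-rank p = %.3g\n", strength$p_value))

strata <- stratify_by_copy_number(pairs, prof_wt, motif = "Helper")
write.table(strata$summary, "results/comparison/copy_strata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(strata$tests, "results/comparison/copy_strata_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Score difference by WT Helper copy number:\n")
print(strata$summary, digits = 3)

center <- motif_center_profile(hits_wt[hits_wt$motif == "shortHelper", ],
                               inp$peaks_wt, motifs)
write.table(center, "results/comparison/center_profile_wt.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

spacing <- spacing_orientation(hits_wt, motifs)
write.table(spacing, "results/comparison/spacing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(spacing_summary(spacing),
            "results/comparison/spacing_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("WRE-Helper spacing records: %d (%.0f%% same orientation)\n",
            nrow(spacing),
            100 * mean(spacing$relative_orientation == "same")))

recip <- reciprocal_overlap_fraction(inp$peaks_wt, inp$peaks_mut, 0.2)
cat(sprintf("Reciprocal overlap of top 20%%: %.0f%% / %.0f%%\n",
            100 * recip[["frac_a_in_b"]], 100 * recip[["frac_b_in_a"]]))
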