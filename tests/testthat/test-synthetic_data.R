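test_that("generated genomes hit the configured GC content and determinism", {
  cfg <- synthetic_config(seed = 3, n_chromosomes = 1L,
                          chrom_length = 1000000L, n_genes = 10L)
  g <- generate_genome(cfg)
  chars <- strsplit(g$genome[[1]], "", fixed = TRUE)[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - cfg$gc_content), 0.003)
  g2 <- generate_genome(cfg)
  expect_identical(g$genome, g2$genome)
  expect_identical(g$genes, g2$genes)
  # AT-only genome at gc_content 0
  cfg0 <- synthetic_config(seed = 3, n_chromosomes = 1L,
                           chrom_length = 50000L, n_genes = 5L,
                           gc_content = 0)
  g0 <- generate_genome(cfg0)
  expect_false(grepl("[GC]", g0$genome[[1]]))
})

test_that("gene models satisfy their structural invariants", {
  cfg <- synthetic_config(seed = 13, n_chromosomes = 2L,
                          chrom_length = 200000L, n_genes = 30L)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$genes), 30L)
  for (i in seq_len(nrow(g$genes))) {
    es <- g$genes$exon_starts[[i]]; ee <- g$genes$exon_ends[[i]]
    expect_true(all(ee > es))
    if (length(es) > 1) expect_true(all(es[-1] >= ee[-length(ee)]))
    if (g$genes$strand[i] == "+") {
      expect_lt(g$genes$tss[i], g$genes$tes[i])
    } else {
      expect_gt(g$genes$tss[i], g$genes$tes[i])
    }
  }
  # genes never overlap within a chromosome
  for (ch in unique(g$genes$chrom)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    lo <- pmin(gg$tss, gg$tes); hi <- pmax(gg$tss, gg$tes)
    ord <- order(lo)
    expect_true(all(lo[ord][-1] >= hi[ord][-length(ord)]))
  }
})

test_that("every planted motif is recovered by the scanner at its position", {
  cfg <- synthetic_config(seed = 21, n_chromosomes = 1L,
                          chrom_length = 300000L, n_genes = 10L,
                          n_peaks_wt = 150L, n_peaks_mut = 100L,
                          p_plant_helper_wt = 0.5, p_plant_wre_wt = 0.5)
  g <- generate_genome(cfg)
  p <- generate_peaks(cfg, g)
  motifs <- builtin_motifs()
  for (set in c("wt", "mut")) {
    man <- p$manifest[[set]]$planted
    if (is.null(man)) next
    peaks <- if (set == "wt") p$peaks_wt else p$peaks_mut
    seqs <- extract_peak_sequences(peaks, p$genome)
    for (r in seq_len(nrow(man))) {
      hits <- scan_sequence(seqs[[man$peak_id[r]]],
                            motifs[[man$motif[r]]])
      expect_true(man$peak_offset[r] %in% hits$start)
    }
  }
})

test_that("planted counts respect the configured composition", {
  # forced double-Helper planting: every peak scans >= 2 Helpers
  sim <- simulate_peak_sequences(60, 400, p_both = 1, copies = 2,
                                 seed = 41)
  prof <- profile_peaks(sim$sequences, builtin_motifs()[c("WRE", "Helper")])
  helper <- motif_counts(prof, "Helper")
  wre <- motif_counts(prof, "WRE")
  expect_true(all(helper >= 2L))
  expect_true(all(wre >= 1L))
  expect_true(all(sim$planted_copies == 2L))
})

test_that("null planting leaves counts at the background closed form", {
  sim <- simulate_peak_sequences(400, 500, seed = 17, gc_content = 0.5)
  prof <- profile_peaks(sim$sequences, c(Helper = "RCCGCC"))
  bg <- uniform_background()
  p1 <- containment_probability(500, "RCCGCC", 1, bg)
  frac <- fraction_with_motif(prof, "Helper")
  se <- sqrt(p1 * (1 - p1) / 400)
  expect_lt(abs(frac - p1), 4 * se + 0.01)
})

test_that("scores track Helper copy number only through the copy term", {
  cfg0 <- synthetic_config(seed = 7, n_chromosomes = 1L,
                           chrom_length = 300000L, n_genes = 10L,
                           n_peaks_wt = 200L, n_peaks_mut = 10L,
                           p_plant_helper_wt = 0.9,
                           score_per_helper_copy = 0)
  g <- generate_genome(cfg0)
  p <- generate_peaks(cfg0, g)
  copies <- p$manifest$wt$planted_copies
  expect_lt(abs(cor(p$peaks_wt$score, copies, method = "spearman")), 0.2)
  cfg5 <- synthetic_config(seed = 7, n_chromosomes = 1L,
                           chrom_length = 300000L, n_genes = 10L,
                           n_peaks_wt = 200L, n_peaks_mut = 10L,
                           p_plant_helper_wt = 0.9,
                           score_per_helper_copy = 5)
  p5 <- generate_peaks(cfg5, generate_genome(cfg5))
  expect_gt(cor(p5$peaks_wt$score, p5$manifest$wt$planted_copies,
                method = "spearman"), 0.5)
})

test_that("null expression has uniform p-values, effects drive selection", {
  cfg <- synthetic_config(seed = 5)
  nulls <- unlist(lapply(1:10, function(s) {
    c2 <- synthetic_config(seed = s)
    classes <- data.frame(gene_id = paste0("g", 1:200),
                          motif_class = "none")
    generate_expression(c2, classes)$p_value
  }))
  frac <- mean(nulls < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  classes <- data.frame(gene_id = paste0("g", 1:200),
                        motif_class = "both_multi_helper")
  ex <- generate_expression(cfg, classes)
  # Gaussian power at effect/sd = 1.0/0.3 and two-sided alpha 0.02:
  # P(|Z - 10/3| > 2.326) ~ 0.843
  power <- pnorm(-stats::qnorm(1 - 0.01) + 1 / 0.3) +
    pnorm(-stats::qnorm(1 - 0.01) - 1 / 0.3)
  frac_sel <- mean(ex$p_value < 0.02 & ex$log2_fold_change < 0)
  expect_lt(abs(frac_sel - power), 4 * sqrt(power * (1 - power) / 200))
  ex2 <- generate_expression(cfg, classes)
  expect_identical(ex, ex2)
})

test_that("fixtures round-trip through the readers and differ across seeds", {
  dir1 <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 77, n_chromosomes = 1L,
                          chrom_length = 200000L, n_genes = 10L,
                          n_peaks_wt = 60L, n_peaks_mut = 60L)
  fx <- make_fixture(cfg, dir1)
  expect_true(all(file.exists(fx$paths)))
  genome <- read_fasta(fx$paths[["genome"]])
  pk <- read_bed(fx$paths[["peaks_wt"]])
  expect_identical(pk$start, fx$data$peaks_wt$start)
  genes <- read_gene_models(fx$paths[["genes"]])
  expect_identical(genes$gene_id, fx$data$genes$gene_id)
  ex <- read_expression_table(fx$paths[["expression"]])
  expect_equal(nrow(ex), 10L)
  seqs <- extract_peak_sequences(pk, genome)
  expect_identical(unname(nchar(seqs)), pk$end - pk$start)
  dir2 <- withr::local_tempdir()
  fx2 <- make_fixture(synthetic_config(seed = 78, n_chromosomes = 1L,
                                       chrom_length = 200000L,
                                       n_genes = 10L, n_peaks_wt = 60L,
                                       n_peaks_mut = 60L), dir2)
  expect_false(identical(readLines(fx$paths[["genome"]]),
                         readLines(fx2$paths[["genome"]])))
})
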