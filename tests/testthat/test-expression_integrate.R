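test_that("regulated-gene selection uses strict inequalities", {
  ex <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2_fold_change = c(-0.77, -0.77, 0, 1.1),
                   p_value = c(0.001, 0.05, 0.001, 0.01))
  sel <- select_regulated(ex, p_cutoff = 0.02)
  expect_equal(sel$down, "a")
  expect_equal(sel$up, "d")
  expect_length(intersect(sel$down, sel$up), 0)
})

test_that("peak-gene linking respects distance and strict score cutoffs", {
  genes <- make_genes("g1", "chr1", "+", tss = 50000L, tes = 60000L)
  # peak center exactly 29999 bp away with the 30 kb cutoff -> linked
  pk <- make_peaks("chr1", 19901L, 20101L, score = 100, ids = "p")
  expect_equal(link_peaks_to_genes(pk, genes, 30000L)$gene_id, "g1")
  # center 30001 away -> not linked
  pk2 <- make_peaks("chr1", 19899L, 20099L, score = 100, ids = "p")
  expect_equal(nrow(link_peaks_to_genes(pk2, genes, 30000L)), 0L)
  # strict score rule: 66.9 and exactly 67 are excluded at cutoff 67
  pk3 <- make_peaks("chr1", 49900L, 50100L, score = 66.9, ids = "p")
  expect_equal(nrow(link_peaks_to_genes(pk3, genes, 30000L,
                                        min_score = 67)), 0L)
  pk3$score <- 67
  expect_equal(nrow(link_peaks_to_genes(pk3, genes, 30000L,
                                        min_score = 67)), 0L)
  pk3$score <- 67.1
  expect_equal(nrow(link_peaks_to_genes(pk3, genes, 30000L,
                                        min_score = 67)), 1L)
})

test_that("peak-gene links equal a brute-force all-pairs check", {
  withr::with_seed(121, {
    for (rep in 1:10) {
      ng <- sample(3:10, 1); np <- sample(5:30, 1)
      genes <- make_genes(sprintf("g%02d", 1:ng),
                          sample(c("chr1", "chr2"), ng, replace = TRUE),
                          sample(c("+", "-"), ng, replace = TRUE),
                          tss = sample(0:100000, ng),
                          tes = sample(0:100000, ng))
      pk <- make_peaks(sample(c("chr1", "chr2"), np, replace = TRUE),
                       sample(0:100000, np),
                       score = runif(np, 0, 100))
      pk$end <- pk$start + sample(100:1000, np, replace = TRUE)
      links <- link_peaks_to_genes(pk, genes, max_distance = 20000L,
                                   min_score = 30)
      brute <- 0L
      for (i in seq_len(np)) for (j in seq_len(ng)) {
        cen <- floor((pk$start[i] + pk$end[i]) / 2)
        if (pk$chrom[i] == genes$chrom[j] &&
            abs(cen - genes$tss[j]) <= 20000 && pk$score[i] > 30) {
          brute <- brute + 1L
          d <- (cen - genes$tss[j]) *
            (if (genes$strand[j] == "+") 1L else -1L)
          hit <- links[links$gene_id == genes$gene_id[j] &
                         links$peak_id == pk$peak_id[i], ]
          expect_equal(nrow(hit), 1L)
          expect_equal(hit$tss_distance, d)
        }
      }
      expect_equal(nrow(links), brute)
    }
  })
})

test_that("hypergeometric overlap matches closed form and enumeration", {
  res <- hypergeometric_overlap(paste0("g", 1:10), paste0("g", 1:10), 20)
  expect_equal(res$overlap, 10L)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(hypergeometric_overlap(character(0), paste0("g", 1:3),
                                      10)$p_value, 1)
  expect_error(hypergeometric_overlap(paste0("g", 1:5), "g1", 3),
               "universe")
  withr::with_seed(19, {
    for (rep in 1:10) {
      U <- sample(6:12, 1)
      na <- sample(1:(U - 1), 1); nb <- sample(1:(U - 1), 1)
      universe <- paste0("u", seq_len(U))
      a <- universe[seq_len(na)]
      b <- sample(universe, nb)
      got <- hypergeometric_overlap(a, b, U)
      want <- oracle_hyper_p(na, nb, U, got$overlap)
      expect_equal(got$p_value, want, tolerance = 1e-12)
    }
  })
})

test_that("GSEA running sum matches the worked example and symmetry", {
  genes <- paste0("g", 1:4)  # ranked best-first
  res <- peak_score_gsea(genes, c("g1", "g2"), exhaustive = TRUE)
  expect_equal(res$enrichment_score, 1.0)
  expect_equal(res$p_value, 1 / 6)
  res_bottom <- peak_score_gsea(genes, c("g3", "g4"), exhaustive = TRUE)
  expect_equal(res_bottom$enrichment_score, -1.0)
  expect_equal(res_bottom$p_value, 1 / 6)
})

test_that("exhaustive GSEA equals subset enumeration for short lists", {
  withr::with_seed(23, {
    for (rep in 1:6) {
      n <- sample(5:8, 1)
      genes <- paste0("g", seq_len(n))
      k <- sample(2:(n - 2), 1)
      subset <- sample(genes, k)
      got <- peak_score_gsea(genes, subset, exhaustive = TRUE)
      in_sub <- genes %in% subset
      es_want <- oracle_gsea_es(in_sub)
      combos <- utils::combn(n, k)
      all_es <- apply(combos, 2, function(idx)
        oracle_gsea_es(seq_len(n) %in% idx))
      p_want <- if (es_want >= 0) {
        mean(all_es >= es_want - 1e-12)
      } else {
        mean(all_es <= es_want + 1e-12)
      }
      expect_equal(got$enrichment_score, es_want, tolerance = 1e-12)
      expect_equal(got$p_value, p_want, tolerance = 1e-12)
    }
  })
})

test_that("permutation GSEA approaches the exhaustive p with smoothing", {
  genes <- paste0("g", 1:8)
  subset <- c("g1", "g2", "g3")
  exact <- peak_score_gsea(genes, subset, exhaustive = TRUE)$p_value
  perm <- peak_score_gsea(genes, subset, n_permutations = 4000,
                          seed = 5)$p_value
  expect_lt(abs(perm - exact), 0.03)
  expect_error(peak_score_gsea(genes, character(0)), "subset")
  expect_error(peak_score_gsea(genes, genes), "subset")
})

test_that("gene motif classes take the strongest linked-peak class", {
  links <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                      peak_id = c("p1", "p2", "p3", "p4"),
                      tss_distance = c(100L, 5000L, -200L, 0L),
                      score = c(80, 90, 70, 99))
  prof <- rbind(
    data.frame(peak_id = c("p1", "p2", "p3", "p4"), motif = "WRE",
               length = 100L, count = c(1L, 0L, 1L, 0L), incidence = 0),
    data.frame(peak_id = c("p1", "p2", "p3", "p4"), motif = "Helper",
               length = 100L, count = c(2L, 0L, 1L, 1L), incidence = 0))
  cls <- classify_gene_links(links, prof)
  expect_equal(as.character(cls$motif_class[cls$gene_id == "g1"]),
               "both_multi_helper")
  expect_equal(as.character(cls$motif_class[cls$gene_id == "g2"]), "both")
  expect_equal(as.character(cls$motif_class[cls$gene_id == "g3"]),
               "helper_only")
  expect_equal(cls$max_peak_score[cls$gene_id == "g1"], 90)
})

test_that("motif-class association recovers a planted downregulation shift", {
  withr::with_seed(29, {
    classes <- data.frame(
      gene_id = paste0("g", 1:200),
      motif_class = rep(c("wre_only", "both_multi_helper"), each = 100))
    lfc <- c(rnorm(100, -0.3, 0.3), rnorm(100, -1.0, 0.3))
  })
  ex <- data.frame(gene_id = classes$gene_id, log2_fold_change = lfc,
                   p_value = 0.001)
  res <- motif_class_association(classes, ex)
  med <- setNames(res$summary$median_log2fc, res$summary$motif_class)
  expect_lt(med[["both_multi_helper"]], med[["wre_only"]])
  expect_lt(res$tests$p_value[1], 0.01)
})

test_that("tiny motif classes are reported but never tested", {
  classes <- data.frame(gene_id = paste0("g", 1:5),
                        motif_class = c("wre_only", "wre_only", "wre_only",
                                        "both", "both"))
  ex <- data.frame(gene_id = classes$gene_id,
                   log2_fold_change = rnorm(5), p_value = 0.5)
  res <- motif_class_association(classes, ex)
  expect_equal(nrow(res$tests), 0L)
  expect_equal(sort(res$summary$n), c(2L, 3L))
  one <- motif_class_association(classes[1:3, ], ex[1:3, ])
  expect_equal(nrow(one$tests), 0L)
})

test_that("the target-gene report formats distances and filters genes", {
  links <- data.frame(gene_id = c("AXIN2", "AXIN2", "SP5", "UNREG"),
                      peak_id = c("p1", "p2", "p3", "p4"),
                      tss_distance = c(483L, 4234L, -176L, 10L),
                      score = c(80, 70, 95, 99))
  classes <- data.frame(gene_id = c("AXIN2", "SP5", "UNREG"),
                        motif_class = c("both", "both_multi_helper",
                                        "none"),
                        max_peak_score = c(80, 95, 99),
                        n_peaks = c(2L, 1L, 1L))
  ex <- data.frame(gene_id = c("AXIN2", "SP5", "UNREG", "NOLINK"),
                   log2_fold_change = c(-0.77, -1.2, -0.9, -2),
                   p_value = c(0.001, 0.001, 0.5, 0.001))
  reg <- select_regulated(ex, 0.02)$down
  rep_tab <- target_gene_report(links, classes, ex, reg)
  expect_equal(rep_tab$tss_distances[rep_tab$gene_id == "AXIN2"],
               "483, 4234")
  expect_false("UNREG" %in% rep_tab$gene_id)   # not regulated
  expect_false("NOLINK" %in% rep_tab$gene_id)  # no linked peak
})

test_that("peak counting near TSSs matches the link table", {
  genes <- make_genes(c("g1", "g2"), "chr1", "+", tss = c(10000L, 90000L),
                      tes = c(20000L, 95000L))
  pk <- make_peaks("chr1", c(5000L, 15000L, 88000L), score = 10)
  cnt <- count_peaks_near_tss(pk, genes, max_distance = 50000L)
  expect_equal(unname(cnt["g1"]), 2L)
  expect_equal(unname(cnt["g2"]), 1L)
})
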