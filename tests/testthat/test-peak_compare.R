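test_that("overlap_regions respects half-open boundaries", {
  a <- make_peaks("chr1", 100L, 200L, ids = "a1")
  b1 <- make_peaks("chr1", 199L, 300L, ids = "b1")
  b2 <- make_peaks("chr1", 200L, 300L, ids = "b2")
  expect_equal(overlap_regions(a, b1)$overlap_bp, 1L)
  expect_equal(nrow(overlap_regions(a, b2)), 0L)
})

test_that("overlap_regions equals a brute-force quadratic scan", {
  withr::with_seed(44, {
    for (rep in 1:25) {
      na <- sample(5:30, 1); nb <- sample(5:30, 1)
      a <- make_peaks(sample(c("chr1", "chr2"), na, replace = TRUE),
                      sample(0:2000, na))
      a$end <- a$start + sample(20:300, na, replace = TRUE)
      b <- make_peaks(sample(c("chr1", "chr2"), nb, replace = TRUE),
                      sample(0:2000, nb), ids = sprintf("qk_%03d", 1:nb))
      b$end <- b$start + sample(20:300, nb, replace = TRUE)
      got <- overlap_regions(a, b)
      brute <- list()
      for (i in seq_len(na)) for (j in seq_len(nb)) {
        if (a$chrom[i] != b$chrom[j]) next
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
        if (ov >= 1) {
          brute[[length(brute) + 1]] <- data.frame(
            peak_id_a = a$peak_id[i], peak_id_b = b$peak_id[j],
            overlap_bp = ov)
        }
      }
      brute <- do.call(rbind, brute)
      if (is.null(brute)) {
        expect_equal(nrow(got), 0L)
      } else {
        key_got <- sort(paste(got$peak_id_a, got$peak_id_b,
                              got$overlap_bp))
        key_brute <- sort(paste(brute$peak_id_a, brute$peak_id_b,
                                brute$overlap_bp))
        expect_identical(key_got, key_brute)
      }
    }
  })
})

test_that("reciprocal overlap hits the trivial extremes and planted rate", {
  withr::with_seed(2, {
    a <- make_peaks("chr1", seq(0L, 9900L, by = 100L))
    a$end <- a$start + 50L
    a$score <- runif(nrow(a), 1, 100)
  })
  expect_equal(unname(reciprocal_overlap_fraction(a, a)), c(1, 1))
  b <- a
  b$start <- b$start + 50L
  b$end <- b$end + 50L
  expect_equal(unname(reciprocal_overlap_fraction(a, b)), c(0, 0))
})

test_that("reciprocal overlap recovers the generator's shared fraction", {
  cfg <- synthetic_config(seed = 31, n_chromosomes = 1L,
                          chrom_length = 500000L, n_genes = 10L,
                          n_peaks_wt = 300L, n_peaks_mut = 300L,
                          frac_shared = 0.6)
  g <- generate_genome(cfg)
  p <- generate_peaks(cfg, g)
  rof <- reciprocal_overlap_fraction(p$peaks_wt, p$peaks_mut,
                                     top_fraction = 1)
  # all peaks considered: at least the shared 60% must overlap
  expect_gt(rof[["frac_a_in_b"]], 0.55)
  expect_gt(rof[["frac_b_in_a"]], 0.55)
  expect_lt(rof[["frac_a_in_b"]], 0.85)
})

test_that("strength classification applies the symmetric ratio rule", {
  pairs <- data.frame(peak_id_a = c("a1", "a2", "a3"),
                      peak_id_b = c("b1", "b2", "b3"),
                      overlap_bp = c(10L, 10L, 10L),
                      score_a = c(30, 10, 10),
                      score_b = c(10, 10, 30))
  res <- classify_strength(pairs)
  expect_equal(unname(res$pairs$class),
               c("a_stronger", "similar", "b_stronger"))
  # swapping the sets exchanges the class labels
  swapped <- pairs
  swapped[, c("score_a", "score_b")] <- pairs[, c("score_b", "score_a")]
  res2 <- classify_strength(swapped)
  expect_equal(unname(res$class_counts["a_stronger"]),
               unname(res2$class_counts["b_stronger"]))
  expect_equal(res$p_value, res2$p_value)
  bad <- pairs
  bad$score_b[1] <- 0
  expect_error(classify_strength(bad), "positive")
})

test_that("best_partner_pairs keeps the maximum-overlap partner", {
  pairs <- data.frame(peak_id_a = c("a1", "a1", "a2"),
                      peak_id_b = c("b1", "b2", "b1"),
                      overlap_bp = c(5L, 50L, 7L),
                      score_a = c(10, 10, 20), score_b = c(1, 2, 3))
  dd <- best_partner_pairs(pairs)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$peak_id_b[dd$peak_id_a == "a1"], "b2")
})

test_that("copy-number stratification recovers an additive score effect", {
  withr::with_seed(55, {
    n <- 240
    copies <- sample(0:5, n, replace = TRUE)
    score_a <- 50 + 5 * copies + rnorm(n, 0, 3)
    score_b <- 35 + rnorm(n, 0, 3)
  })
  pairs <- data.frame(peak_id_a = sprintf("a%03d", 1:n),
                      peak_id_b = sprintf("b%03d", 1:n),
                      overlap_bp = 100L, score_a = score_a,
                      score_b = score_b)
  prof <- data.frame(peak_id = pairs$peak_id_a, motif = "Helper",
                     length = 500L, count = copies,
                     incidence = copies / 500)
  res <- stratify_by_copy_number(pairs, prof, motif = "Helper")
  expect_true(all(diff(res$summary$median_diff) > 0))
  p01 <- res$tests$p_value[res$tests$bin_a == "0" & res$tests$bin_b == "4+"]
  expect_lt(p01, 1e-6)
})

test_that("empty copy-number bins are reported but not tested", {
  pairs <- data.frame(peak_id_a = c("a1", "a2"), peak_id_b = c("b1", "b2"),
                      overlap_bp = 10L, score_a = c(5, 6),
                      score_b = c(5, 6))
  prof <- data.frame(peak_id = c("a1", "a2"), motif = "Helper",
                     length = 100L, count = c(0L, 0L), incidence = 0)
  res <- stratify_by_copy_number(pairs, prof, motif = "Helper")
  expect_equal(res$summary$n, c(2L, 0L, 0L, 0L))
  expect_equal(nrow(res$tests), 0L)
})

test_that("motif center offsets follow the stated convention", {
  peaks <- make_peaks("chr1", 0L, 200L, ids = "p1")
  hits <- data.frame(peak_id = "p1", motif = "WRE", start = 96L,
                     strand = "+")
  prof <- motif_center_profile(hits, peaks, c(WRE = "CTTTGWWS"),
                               window = 200, bin_width = 10)
  # motif center 96 + 4 = 100 = peak center -> offset 0
  expect_equal(sum(prof$count), 1L)
  expect_equal(prof$count[prof$bin_start == 0], 1L)
})

test_that("uniformly planted hits give a flat center profile", {
  withr::with_seed(66, {
    n <- 4000
    offsets <- sample(-500:499, n, replace = TRUE)
  })
  peaks <- make_peaks("chr1", 0L, 1000L, ids = "p1")
  hits <- data.frame(peak_id = "p1", motif = "M",
                     start = 500L + offsets, strand = "+")
  prof <- motif_center_profile(hits, peaks, c(M = "AA"),
                               window = 1000, bin_width = 50)
  gof <- chisq.test(prof$count)
  expect_gt(gof$p.value, 0.001)
})

test_that("spacing records follow the sign and orientation conventions", {
  hits <- data.frame(peak_id = rep("p1", 2), motif = c("WRE", "Helper"),
                     start = c(10L, 30L), strand = c("+", "+"))
  motifs <- builtin_motifs()
  rec <- spacing_orientation(hits, motifs)
  expect_equal(rec$signed_gap, 12L)  # helper starts at 30, WRE ends at 18
  expect_equal(rec$relative_orientation, "same")
  hits$start <- c(30L, 10L)
  rec <- spacing_orientation(hits, motifs)
  expect_equal(rec$signed_gap, -14L)
  hits$strand <- c("-", "+")
  rec <- spacing_orientation(hits, motifs)
  expect_equal(rec$signed_gap, 14L)  # flipped to the WRE's strand
  expect_equal(rec$relative_orientation, "opposite")
})

test_that("spacing emits one record per WRE x Helper hit pair", {
  withr::with_seed(77, {
    sim <- simulate_peak_sequences(40, 300, p_wre = 0.8, p_helper = 0.8,
                                   seed = 77)
  })
  hits <- scan_peaks(sim$sequences, builtin_motifs()[c("WRE", "Helper")])
  rec <- spacing_orientation(hits, builtin_motifs())
  nw <- table(hits$peak_id[hits$motif == "WRE"])
  nh <- table(hits$peak_id[hits$motif == "Helper"])
  both <- intersect(names(nw), names(nh))
  expect_equal(nrow(rec), sum(as.integer(nw[both]) * as.integer(nh[both])))
})

test_that("incidence comparison and motif fractions behave at the extremes", {
  prof <- data.frame(peak_id = c("a", "b"), motif = "WRE", length = 100L,
                     count = c(1L, 2L), incidence = c(0.01, 0.02))
  same <- compare_incidence(prof, prof, "WRE")
  expect_equal(same$p_value, 1)
  pa <- data.frame(peak_id = c("a", "b"), motif = "M", length = 10L,
                   count = 0L, incidence = c(0.1, 0.2))
  pb <- data.frame(peak_id = c("c", "d"), motif = "M", length = 10L,
                   count = 0L, incidence = c(0.3, 0.4))
  expect_equal(compare_incidence(pa, pb, "M")$p_value, 2 / 6)
  prof2 <- data.frame(peak_id = letters[1:4], motif = "M", length = 10L,
                      count = c(0L, 1L, 2L, 0L), incidence = 0)
  expect_equal(fraction_with_motif(prof2, "M"), 0.5)
  expect_equal(fraction_with_motif(prof2, "M", min_count = 0), 1)
})
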