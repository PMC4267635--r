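# Seeded synthetic-data generator.
#
# Produces a toy genome, gene models, two peak sets ("WT" with a
# functional secondary DNA-binding domain, "mut" without) with planted
# WRE/Helper motifs, score structure tied to Helper copy number, and an
# expression table whose downregulation depends on the motif class of
# nearby peaks.  Planting overwrites genome bases, so the ground-truth
# manifest is exact: every planted motif is recoverable by the scanner at
# its recorded position.  All randomness derives from `config$seed`
# (stage-offset seeds keep the stages individually reproducible).

#' Synthetic study configuration
#'
#' Defaults emulate the statistical structure of a two-condition ChIP-seq
#' comparison: similar WRE planting in both sets, much higher Helper
#' planting in WT (0.2 vs 0.05), Helper copy numbers skewed to single
#' copies, WRE-Helper gaps within ~11 bp either side, WT scores increasing
#' with Helper copy number, and class-dependent downregulation strongest
#' for genes near peaks with a WRE plus two or more Helpers.
#'
#' @param seed Integer seed.
#' @param ... Overrides of any default field.
#' @return A `cclamp_config` list.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 2L,
    chrom_length = 1000000L,
    gc_content = 0.41,
    n_genes = 200L,
    n_peaks_wt = 1000L,
    n_peaks_mut = 1000L,
    peak_length_range = c(300L, 700L),
    frac_shared = 0.6,
    p_plant_wre_wt = 0.35,
    p_plant_wre_mut = 0.35,
    p_plant_helper_wt = 0.2,
    p_plant_helper_mut = 0.05,
    p_plant_wre_shared = 0.35,
    p_plant_helper_shared = 0.05,
    helper_copy_distribution = c(`1` = 0.5, `2` = 0.3, `3` = 0.12,
                                 `4` = 0.05, `5` = 0.03),
    gap_distribution = list(values = c(-11:-1, 1:11),
                            probs = rep(1 / 22, 22)),
    score_base_wt = 50,
    score_base_mut = 35,
    score_per_helper_copy = 5,
    score_per_helper_copy_mut = 0,
    score_noise_sd = 3,
    score_floor = 1,
    link_distance = 30000L,
    effect_log2fc_by_class = c(none = 0, helper_only = -0.05,
                               wre_only = -0.3, both = -0.6,
                               both_multi_helper = -1.0),
    expression_noise_sd = 0.3
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L) stop("unknown config field: ", unknown[1L])
  cfg[names(override)] <- override
  stopifnot(cfg$gc_content >= 0, cfg$gc_content <= 1,
            abs(sum(cfg$helper_copy_distribution) - 1) < 1e-9,
            abs(sum(cfg$gap_distribution$probs) - 1) < 1e-9,
            all(diff(cfg$peak_length_range) >= 0))
  class(cfg) <- "cclamp_config"
  cfg
}

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = .base_probs(gc))
}

#' Generate the toy genome and gene models
#'
#' Chromosomes are i.i.d. bases at the configured GC content.  Genes are
#' placed non-overlapping in evenly spaced slots with alternating strands;
#' each gene gets 2-4 exons.
#'
#' @param config A `cclamp_config`.
#' @return List: `genome` (named character vector) and `genes`
#'   (gene-model `data.frame`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "cclamp_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- setNames(vapply(chroms, function(ch) {
    paste(.random_bases(config$chrom_length, config$gc_content),
          collapse = "")
  }, ""), chroms)
  per_chrom <- ceiling(config$n_genes / config$n_chromosomes)
  slot <- floor(config$chrom_length / per_chrom)
  min_len <- 2000L
  if (slot < 3L * min_len) stop("genes do not fit on the configured genome")
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    for (si in seq_len(per_chrom)) {
      if (gi >= config$n_genes) break
      gi <- gi + 1L
      lo <- (si - 1L) * slot
      glen <- sample(min_len:min(10000L, slot - min_len), 1L)
      gstart <- lo + sample.int(slot - glen - 100L, 1L)
      gend <- gstart + glen
      strand <- if (gi %% 2L == 1L) "+" else "-"
      n_ex <- sample(2:4, 1L)
      # exon boundaries from sorted internal cut points
      cuts <- sort(sample(seq(gstart + 50L, gend - 50L, by = 10L),
                          2L * (n_ex - 1L)))
      es <- c(gstart, cuts[seq(2L, length(cuts), by = 2L)])
      ee <- c(cuts[seq(1L, length(cuts), by = 2L)], gend)
      rows[[gi]] <- data.frame(
        gene_id = sprintf("gene_%04d", gi), chrom = chroms[ci],
        strand = strand,
        tss = if (strand == "+") gstart else gend - 1L,
        tes = if (strand == "+") gend else gstart,
        exon_starts = I(list(as.integer(es))),
        exon_ends = I(list(as.integer(ee))))
    }
  }
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  list(genome = genome, genes = genes)
}

# realize a degenerate pattern into concrete bases
.realize_pattern <- function(pattern) {
  sym <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(sym, function(s) {
    opts <- IUPAC_SETS[[s]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, ""), collapse = "")
}

.draw_gap <- function(gap_dist) {
  sample(gap_dist$values, 1L, prob = gap_dist$probs)
}

# Plan motif placements inside one peak (peak-relative 0-based offsets).
# Returns a data.frame of motif/start/strand/seq rows, or rows that fit.
.plan_planting <- function(L, plant_wre, helper_copies, gap_dist,
                           wre_pattern, helper_pattern) {
  m_wre <- nchar(wre_pattern)
  m_helper <- nchar(helper_pattern)
  placed <- list()
  occupied <- integer(0)  # bases already used by planted motifs
  fits <- function(s, m) {
    s >= 0L && s + m <= L && !any((s:(s + m - 1L)) %in% occupied)
  }
  center_pos <- function(m) {
    # anchor near the peak center with spread L/8
    for (i in 1:100) {
      s <- round(L / 2 - m / 2 + rnorm(1L, 0, L / 8))
      if (fits(s, m)) return(as.integer(s))
    }
    NA_integer_
  }
  anchor <- NA_integer_
  anchor_m <- m_wre
  if (plant_wre) {
    s <- center_pos(m_wre)
    if (!is.na(s)) {
      strand <- sample(c("+", "-"), 1L)
      seq <- .realize_pattern(wre_pattern)
      if (strand == "-") seq <- reverse_complement(seq)
      placed[[length(placed) + 1L]] <- data.frame(
        motif = "WRE", start = s, strand = strand, seq = seq)
      occupied <- c(occupied, s:(s + m_wre - 1L))
      anchor <- s
    }
  }
  if (helper_copies > 0L) {
    prev_start <- anchor
    prev_m <- anchor_m
    for (k in seq_len(helper_copies)) {
      s <- NA_integer_
      for (i in 1:100) {
        cand <- if (is.na(prev_start)) {
          # no anchor: start a cluster near the center
          round(L / 2 - m_helper / 2 + rnorm(1L, 0, L / 8))
        } else {
          g <- .draw_gap(gap_dist)
          # g > 0: helper 3' of previous element; g < 0: 5' with |g| gap
          if (g >= 0) prev_start + prev_m + g else
            prev_start + g - m_helper
        }
        if (!is.na(cand) && fits(cand, m_helper)) {
          s <- as.integer(cand)
          break
        }
      }
      if (is.na(s)) {
        # fallback: any free slot
        free <- setdiff(0:(L - m_helper), unique(unlist(
          lapply(occupied, function(o) (o - m_helper + 1L):o))))
        free <- free[free >= 0L]
        if (length(free) == 0L) next
        s <- sample(free, 1L)
      }
      strand <- sample(c("+", "-"), 1L)
      seq <- .realize_pattern(helper_pattern)
      if (strand == "-") seq <- reverse_complement(seq)
      placed[[length(placed) + 1L]] <- data.frame(
        motif = "Helper", start = s, strand = strand, seq = seq)
      occupied <- c(occupied, s:(s + m_helper - 1L))
      prev_start <- s
      prev_m <- m_helper
    }
  }
  if (length(placed) == 0L) return(NULL)
  do.call(rbind, placed)
}

#' Generate the two peak sets with planted motifs
#'
#' Peaks are placed uniformly; a configured fraction of regions is shared
#' between the sets (the mutant interval jittered by up to 100 bp).  Per
#' region, a WRE is planted with the applicable WRE probability and a
#' Helper cluster (copy count from `helper_copy_distribution`, gaps from
#' `gap_distribution`, anchored at the WRE when present, else near the
#' peak center) with the applicable Helper probability.  Shared regions
#' are planted once, with the `*_shared` probabilities (they model
#' co-bound, WRE-driven sites, so their Helper probability defaults to
#' the mutant level), and the mutant peak inherits whatever planted
#' motifs fall inside its jittered interval.  Planted bases overwrite the
#' genome.  Scores are `score_base + score_per_helper_copy * copies +
#' N(0, sd)` floored at `score_floor`; the copy term uses each set's own
#' coefficient (0 for the mutant by default, since its secondary domain
#' cannot read Helpers).
#'
#' @param config A `cclamp_config`.
#' @param genome_obj Output of [generate_genome()].
#' @return List: `peaks_wt`, `peaks_mut` (peak `data.frame`s), `genome`
#'   (with planted bases), `manifest` (list with per-peak planting truth).
#' @export
generate_peaks <- function(config, genome_obj) {
  stopifnot(inherits(config, "cclamp_config"))
  set.seed(config$seed + 1L)
  genome_chars <- lapply(genome_obj$genome,
                         function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  chroms <- names(genome_chars)
  chrom_len <- vapply(genome_chars, length, 0L)
  wre_pattern <- builtin_motifs()[["WRE"]]
  helper_pattern <- builtin_motifs()[["Helper"]]
  n_shared <- round(config$frac_shared *
                      min(config$n_peaks_wt, config$n_peaks_mut))
  draw_len <- function(n) {
    if (config$peak_length_range[1L] == config$peak_length_range[2L]) {
      rep(config$peak_length_range[1L], n)
    } else {
      sample(config$peak_length_range[1L]:config$peak_length_range[2L], n,
             replace = TRUE)
    }
  }
  place <- function(n, lens) {
    ch <- sample(chroms, n, replace = TRUE)
    st <- vapply(seq_len(n), function(i) {
      sample.int(chrom_len[ch[i]] - lens[i], 1L) - 1L
    }, 0L)
    data.frame(chrom = ch, start = as.integer(st),
               end = as.integer(st + lens))
  }
  len_wt <- draw_len(config$n_peaks_wt)
  pk_wt <- place(config$n_peaks_wt, len_wt)
  pk_wt$peak_id <- sprintf("wt_%05d", seq_len(config$n_peaks_wt))
  len_mut <- draw_len(config$n_peaks_mut)
  pk_mut <- place(config$n_peaks_mut, len_mut)
  # shared regions: first n_shared mutant peaks jittered over WT regions
  if (n_shared > 0L) {
    jit <- sample(-100:100, n_shared, replace = TRUE)
    pk_mut$chrom[seq_len(n_shared)] <- pk_wt$chrom[seq_len(n_shared)]
    st <- pmax(0L, pk_wt$start[seq_len(n_shared)] + jit)
    en <- pmin(chrom_len[pk_mut$chrom[seq_len(n_shared)]],
               st + len_mut[seq_len(n_shared)])
    pk_mut$start[seq_len(n_shared)] <- as.integer(st)
    pk_mut$end[seq_len(n_shared)] <- as.integer(en)
  }
  pk_mut$peak_id <- sprintf("mut_%05d", seq_len(config$n_peaks_mut))

  plant_set <- function(pk, p_wre, p_helper, copy_coef, score_base) {
    # p_wre / p_helper may be per-peak vectors
    n <- nrow(pk)
    plant_wre <- runif(n) < p_wre
    plant_helper <- runif(n) < p_helper
    copies <- ifelse(plant_helper,
                     as.integer(sample(
                       as.integer(names(config$helper_copy_distribution)),
                       n, replace = TRUE,
                       prob = config$helper_copy_distribution)), 0L)
    manifest <- vector("list", n)
    planted_copies <- integer(n)
    planted_wre <- logical(n)
    for (i in seq_len(n)) {
      if (!plant_wre[i] && copies[i] == 0L) next
      L <- pk$end[i] - pk$start[i]
      plan <- .plan_planting(L, plant_wre[i], copies[i],
                             config$gap_distribution, wre_pattern,
                             helper_pattern)
      if (is.null(plan)) next
      ch <- pk$chrom[i]
      for (r in seq_len(nrow(plan))) {
        gpos <- pk$start[i] + plan$start[r]  # 0-based genome offset
        bases <- strsplit(plan$seq[r], "", fixed = TRUE)[[1L]]
        genome_chars[[ch]][(gpos + 1L):(gpos + length(bases))] <<- bases
      }
      planted_wre[i] <- any(plan$motif == "WRE")
      planted_copies[i] <- sum(plan$motif == "Helper")
      manifest[[i]] <- data.frame(
        peak_id = pk$peak_id[i], chrom = ch, motif = plan$motif,
        genome_start = pk$start[i] + plan$start,
        peak_offset = plan$start, strand = plan$strand, seq = plan$seq)
    }
    score <- score_base + copy_coef * planted_copies +
      rnorm(n, 0, config$score_noise_sd)
    pk$score <- pmax(config$score_floor, score)
    list(peaks = pk,
         manifest = do.call(rbind, manifest[!vapply(manifest, is.null,
                                                    TRUE)]),
         planted_wre = planted_wre, planted_copies = planted_copies)
  }
  shared_wt <- seq_len(nrow(pk_wt)) <= n_shared
  wt <- plant_set(pk_wt,
                  ifelse(shared_wt, config$p_plant_wre_shared,
                         config$p_plant_wre_wt),
                  ifelse(shared_wt, config$p_plant_helper_shared,
                         config$p_plant_helper_wt),
                  config$score_per_helper_copy, config$score_base_wt)
  # shared mutant peaks inherit the region planting; only the
  # mutant-unique peaks receive their own planting draws
  shared_mut <- seq_len(nrow(pk_mut)) <= n_shared
  mut <- plant_set(pk_mut,
                   ifelse(shared_mut, 0, config$p_plant_wre_mut),
                   ifelse(shared_mut, 0, config$p_plant_helper_mut),
                   config$score_per_helper_copy_mut, config$score_base_mut)
  if (n_shared > 0L && !is.null(wt$manifest)) {
    inherit <- lapply(seq_len(n_shared), function(i) {
      wm <- wt$manifest[wt$manifest$peak_id == pk_wt$peak_id[i], ,
                        drop = FALSE]
      if (nrow(wm) == 0L) return(NULL)
      mlen <- nchar(wm$seq)
      inside <- wm$genome_start >= pk_mut$start[i] &
        wm$genome_start + mlen <= pk_mut$end[i]
      if (!any(inside)) return(NULL)
      wm <- wm[inside, , drop = FALSE]
      data.frame(peak_id = pk_mut$peak_id[i], chrom = wm$chrom,
                 motif = wm$motif, genome_start = wm$genome_start,
                 peak_offset = wm$genome_start - pk_mut$start[i],
                 strand = wm$strand, seq = wm$seq)
    })
    inherit <- do.call(rbind, inherit[!vapply(inherit, is.null, TRUE)])
    if (!is.null(inherit)) {
      mut$manifest <- rbind(mut$manifest, inherit)
      agg_w <- tapply(inherit$motif == "WRE", inherit$peak_id, any)
      agg_h <- tapply(inherit$motif == "Helper", inherit$peak_id, sum)
      idx <- match(names(agg_w), pk_mut$peak_id)
      mut$planted_wre[idx] <- mut$planted_wre[idx] | agg_w
      mut$planted_copies[idx] <- mut$planted_copies[idx] +
        as.integer(agg_h)
    }
  }
  genome <- setNames(vapply(genome_chars, paste, "", collapse = ""),
                     chroms)
  manifest <- list(
    config = config,
    wt = list(planted = wt$manifest, planted_wre = wt$planted_wre,
              planted_copies = wt$planted_copies,
              peak_ids = pk_wt$peak_id),
    mut = list(planted = mut$manifest, planted_wre = mut$planted_wre,
               planted_copies = mut$planted_copies,
               peak_ids = pk_mut$peak_id),
    n_shared = n_shared)
  list(peaks_wt = wt$peaks, peaks_mut = mut$peaks, genome = genome,
       manifest = manifest)
}

#' Ground-truth motif class per gene
#'
#' Links WT peaks to genes by TSS distance and derives each gene's class
#' from the *planted* motif content of its linked peaks (strongest class
#' wins, as in [classify_gene_links()]).  Genes without links are `none`.
#'
#' @param config A `cclamp_config`.
#' @param peaks Peak `data.frame` (WT set).
#' @param genes Gene-model `data.frame`.
#' @param planted_wre,planted_copies Per-peak planting truth (aligned with
#'   `peaks`).
#' @return `data.frame`: `gene_id`, `motif_class`.
#' @export
ground_truth_gene_classes <- function(config, peaks, genes, planted_wre,
                                      planted_copies) {
  lv <- c("none", "helper_only", "wre_only", "both", "both_multi_helper")
  peak_class <- ifelse(planted_wre & planted_copies >= 2L,
                       "both_multi_helper",
                ifelse(planted_wre & planted_copies >= 1L, "both",
                ifelse(planted_wre, "wre_only",
                ifelse(planted_copies >= 1L, "helper_only", "none"))))
  names(peak_class) <- peaks$peak_id
  links <- link_peaks_to_genes(peaks, genes,
                               max_distance = config$link_distance)
  cls <- setNames(rep("none", nrow(genes)), genes$gene_id)
  if (nrow(links) > 0L) {
    rk <- match(peak_class[links$peak_id], lv)
    best <- tapply(rk, links$gene_id, max)
    cls[names(best)] <- lv[best]
  }
  data.frame(gene_id = genes$gene_id,
             motif_class = factor(cls, levels = lv))
}

#' Generate the expression table from gene classes
#'
#' `log2_fold_change = effect(class) + N(0, expression_noise_sd)`;
#' p-values are two-sided Gaussian tests of the fold change against the
#' noise standard deviation, so genes carrying an effect get small
#' p-values.
#'
#' @param config A `cclamp_config`.
#' @param gene_classes `data.frame` with `gene_id` and `motif_class`.
#' @return Expression `data.frame`: `gene_id`, `log2_fold_change`,
#'   `p_value`.
#' @export
generate_expression <- function(config, gene_classes) {
  stopifnot(inherits(config, "cclamp_config"))
  set.seed(config$seed + 2L)
  eff <- config$effect_log2fc_by_class[as.character(gene_classes$motif_class)]
  lfc <- eff + rnorm(nrow(gene_classes), 0, config$expression_noise_sd)
  p <- 2 * pnorm(-abs(lfc) / config$expression_noise_sd)
  data.frame(gene_id = gene_classes$gene_id, log2_fold_change = lfc,
             p_value = p)
}

#' Write a complete synthetic fixture to a directory
#'
#' Generates genome, genes, peaks (with planting) and expression, writes
#' them in the standard formats plus a JSON ground-truth manifest, and
#' returns the paths and in-memory objects.
#'
#' @param config A `cclamp_config`.
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths) and `data` (in-memory
#'   objects including the manifest).
#' @export
make_fixture <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_genome(config)
  p <- generate_peaks(config, g)
  classes <- ground_truth_gene_classes(config, p$peaks_wt, g$genes,
                                       p$manifest$wt$planted_wre,
                                       p$manifest$wt$planted_copies)
  expr <- generate_expression(config, classes)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             genes = file.path(dir, "genes.tsv"),
             peaks_wt = file.path(dir, "peaks_wt.bed"),
             peaks_mut = file.path(dir, "peaks_mut.bed"),
             expression = file.path(dir, "expression.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta(p$genome, paths[["genome"]])
  write_gene_models(g$genes, paths[["genes"]])
  write_bed(p$peaks_wt, paths[["peaks_wt"]])
  write_bed(p$peaks_mut, paths[["peaks_mut"]])
  write.table(expr, paths[["expression"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest_json <- list(
    config = unclass(config),
    n_shared = p$manifest$n_shared,
    wt_planted = p$manifest$wt$planted,
    mut_planted = p$manifest$mut$planted,
    gene_classes = data.frame(gene_id = classes$gene_id,
                              motif_class =
                                as.character(classes$motif_class)))
  jsonlite::write_json(manifest_json, paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  list(paths = paths,
       data = list(genome = p$genome, genes = g$genes,
                   peaks_wt = p$peaks_wt, peaks_mut = p$peaks_mut,
                   expression = expr, gene_classes = classes,
                   manifest = p$manifest))
}

#' Fast per-peak sequence simulator with planting
#'
#' A lightweight generator used for replicated statistical checks: draws
#' i.i.d. peak sequences at a given GC content and plants motifs directly,
#' skipping the genome/gene machinery.  Planting is either independent
#' (`p_wre`, `p_helper` per peak) or joint (`p_both`: a composite WRE +
#' Helper-cluster element planted together).
#'
#' @param n_peaks Number of peaks.
#' @param peak_length Length of every peak (bp).
#' @param gc_content Background GC fraction.
#' @param p_wre,p_helper Independent planting probabilities.
#' @param p_both Probability of planting a joint WRE + Helper composite
#'   (overrides the independent draws for peaks where it fires).
#' @param copies Helper copy count used when a cluster is planted; either
#'   a fixed integer or a named probability vector as in
#'   [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `sequences` (named character vector), `planted_wre`
#'   (logical), `planted_copies` (integer).
#' @export
simulate_peak_sequences <- function(n_peaks, peak_length, gc_content = 0.41,
                                    p_wre = 0, p_helper = 0, p_both = 0,
                                    copies = c(`1` = 0.5, `2` = 0.3,
                                               `3` = 0.12, `4` = 0.05,
                                               `5` = 0.03),
                                    seed = 1L) {
  set.seed(seed)
  gap_dist <- list(values = c(-11:-1, 1:11), probs = rep(1 / 22, 22))
  wre_pattern <- builtin_motifs()[["WRE"]]
  helper_pattern <- builtin_motifs()[["Helper"]]
  bases <- .random_bases(n_peaks * peak_length, gc_content)
  big <- paste(bases, collapse = "")
  starts <- (seq_len(n_peaks) - 1L) * peak_length + 1L
  seqs <- substring(big, starts, starts + peak_length - 1L)
  draw_copies <- function() {
    if (length(copies) == 1L && is.null(names(copies))) {
      as.integer(copies)
    } else {
      as.integer(sample(as.integer(names(copies)), 1L, prob = copies))
    }
  }
  planted_wre <- logical(n_peaks)
  planted_copies <- integer(n_peaks)
  for (i in seq_len(n_peaks)) {
    both <- p_both > 0 && runif(1L) < p_both
    wre <- both || runif(1L) < p_wre
    helper_copies <- if (both || runif(1L) < p_helper) draw_copies() else 0L
    if (!wre && helper_copies == 0L) next
    plan <- .plan_planting(peak_length, wre, helper_copies, gap_dist,
                           wre_pattern, helper_pattern)
    if (is.null(plan)) next
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (r in seq_len(nrow(plan))) {
      b <- strsplit(plan$seq[r], "", fixed = TRUE)[[1L]]
      chars[(plan$start[r] + 1L):(plan$start[r] + length(b))] <- b
    }
    seqs[i] <- paste(chars, collapse = "")
    planted_wre[i] <- any(plan$motif == "WRE")
    planted_copies[i] <- sum(plan$motif == "Helper")
  }
  names(seqs) <- sprintf("peak_%05d", seq_len(n_peaks))
  list(sequences = seqs, planted_wre = planted_wre,
       planted_copies = planted_copies)
}
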