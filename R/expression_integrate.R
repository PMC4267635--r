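# Integration of peak occupancy with nascent-transcription changes:
# regulated-gene selection, peak-to-gene linking by TSS distance,
# overlap and rank-enrichment statistics, and motif-class association.

#' Select regulated gene sets from an expression table
#'
#' `down` genes have `p_value < p_cutoff` and `log2_fold_change < 0`;
#' `up` analogously (strict inequalities, so a zero fold change is in
#' neither set).
#'
#' @param expression `data.frame` from [read_expression_table()].
#' @param p_cutoff Significance cutoff in (0, 1).
#' @return List of character vectors `down` and `up` (disjoint).
#' @export
select_regulated <- function(expression, p_cutoff = 0.02) {
  stopifnot(p_cutoff > 0, p_cutoff < 1)
  sig <- expression$p_value < p_cutoff
  list(down = expression$gene_id[sig & expression$log2_fold_change < 0],
       up = expression$gene_id[sig & expression$log2_fold_change > 0])
}

#' Link peaks to genes by TSS distance
#'
#' A peak links to every gene whose TSS lies within `max_distance` bp of
#' the peak center (inclusive) provided its score exceeds `min_score`
#' (strict, matching a "score > cutoff" selection rule).  Genes with no
#' links are omitted.
#'
#' @param peaks Peak `data.frame`.
#' @param genes Gene-model `data.frame`.
#' @param max_distance Distance cutoff in bp (e.g. 30000 or 50000).
#' @param min_score Minimum peak score (strict); default `-Inf` keeps all.
#' @return `data.frame` with one row per link: `gene_id`, `peak_id`,
#'   `tss_distance` (signed, positive downstream of the TSS), `score`.
#' @export
link_peaks_to_genes <- function(peaks, genes, max_distance = 30000L,
                                min_score = -Inf) {
  stopifnot(max_distance > 0)
  pk <- peaks[peaks$score > min_score, , drop = FALSE]
  if (nrow(pk) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene_id = character(0), peak_id = character(0),
                      tss_distance = integer(0), score = numeric(0)))
  }
  center <- floor((pk$start + pk$end) / 2)
  links <- lapply(seq_len(nrow(genes)), function(j) {
    same <- pk$chrom == genes$chrom[j]
    d <- center - genes$tss[j]
    keep <- same & abs(d) <= max_distance
    if (!any(keep)) return(NULL)
    sgn <- if (genes$strand[j] == "+") 1L else -1L
    data.frame(gene_id = genes$gene_id[j], peak_id = pk$peak_id[keep],
               tss_distance = as.integer(sgn * d[keep]),
               score = pk$score[keep])
  })
  out <- do.call(rbind, links[!vapply(links, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), peak_id = character(0),
                      tss_distance = integer(0), score = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of an overlap at least as large as observed when
#' both sets are drawn from a common universe.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Size of the gene universe (must be at least each
#'   set's size).
#' @return List: `overlap`, `p_value`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe_size < length(set_a) || universe_size < length(set_b)) {
    stop("universe smaller than one of the sets")
  }
  ov <- length(intersect(set_a, set_b))
  if (length(set_a) == 0L || length(set_b) == 0L) {
    return(list(overlap = 0L, p_value = 1))
  }
  p <- phyper(ov - 1, length(set_a), universe_size - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = ov, p_value = min(1, p))
}

# unweighted GSEA running-sum maximum deviation from zero
.gsea_es <- function(in_subset, n_hit, n_miss) {
  step <- ifelse(in_subset, 1 / n_hit, -1 / n_miss)
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Peak-score gene-set enrichment (unweighted running sum)
#'
#' Genes ranked by descending maximum peak score are walked with an
#' unweighted Kolmogorov-Smirnov-style running sum (+1/|subset| on a hit,
#' -1/(n - |subset|) on a miss); the enrichment score is the maximum
#' deviation from zero.  The p-value is the fraction of random same-size
#' gene subsets with |ES| at least as large (with +1 smoothing), or the
#' exact fraction over all subsets when `exhaustive = TRUE`.
#'
#' @param ranked_genes Character vector of gene ids, ranked best first.
#' @param gene_subset Subset of `ranked_genes` to test.
#' @param n_permutations Number of random subsets (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param exhaustive If `TRUE`, enumerate all same-size subsets (exact p,
#'   no smoothing); feasible only for short lists.
#' @return List: `enrichment_score`, `p_value`, `n_genes`, `n_subset`,
#'   `method`.
#' @export
peak_score_gsea <- function(ranked_genes, gene_subset,
                            n_permutations = 1000L, seed = 1L,
                            exhaustive = FALSE) {
  n <- length(ranked_genes)
  stopifnot(n >= 2L, !anyDuplicated(ranked_genes))
  if (length(gene_subset) == 0L || length(setdiff(ranked_genes,
                                                  gene_subset)) == 0L) {
    stop("gene subset must be a nonempty proper subset of the ranked list")
  }
  if (!all(gene_subset %in% ranked_genes)) {
    stop("gene subset contains genes absent from the ranked list")
  }
  in_subset <- ranked_genes %in% gene_subset
  n_hit <- sum(in_subset)
  n_miss <- n - n_hit
  es <- .gsea_es(in_subset, n_hit, n_miss)
  # one-sided null comparison in the direction of the observed ES
  as_extreme <- function(e) {
    if (es >= 0) e >= es - 1e-12 else e <= es + 1e-12
  }
  if (exhaustive) {
    combos <- utils::combn(n, n_hit)
    all_es <- apply(combos, 2L, function(idx) {
      .gsea_es(seq_len(n) %in% idx, n_hit, n_miss)
    })
    p <- mean(as_extreme(all_es))
    method <- "exhaustive"
  } else {
    stopifnot(n_permutations >= 100L)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hits <- vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, n_hit)
      as_extreme(.gsea_es(seq_len(n) %in% idx, n_hit, n_miss))
    }, TRUE)
    p <- (sum(hits) + 1) / (n_permutations + 1)
    method <- "permutation"
  }
  list(enrichment_score = es, p_value = p, n_genes = n, n_subset = n_hit,
       method = method)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Motif classes for linked genes
#'
#' Each linked peak is classified from its WRE/Helper counts (`none`,
#' `wre_only`, `helper_only`, `both`, `both_multi_helper` = one or more
#' WREs with two or more Helpers); a gene takes the strongest class among
#' its linked peaks in the order none < helper_only < wre_only < both <
#' both_multi_helper.
#'
#' @param links Link table from [link_peaks_to_genes()].
#' @param profiles Profile table ([profile_peaks()]) covering the linked
#'   peaks.
#' @param wre,helper Motif names.
#' @return `data.frame`: `gene_id`, `motif_class`, `max_peak_score`,
#'   `n_peaks`.
#' @export
classify_gene_links <- function(links, profiles, wre = "WRE",
                                helper = "Helper") {
  lv <- c("none", "helper_only", "wre_only", "both", "both_multi_helper")
  if (nrow(links) == 0L) {
    return(data.frame(gene_id = character(0),
                      motif_class = factor(character(0), levels = lv),
                      max_peak_score = numeric(0), n_peaks = integer(0)))
  }
  wre_cnt <- motif_counts(profiles, wre)
  helper_cnt <- motif_counts(profiles, helper)
  w <- wre_cnt[links$peak_id]
  h <- helper_cnt[links$peak_id]
  if (anyNA(w) || anyNA(h)) stop("linked peak missing from profiles")
  peak_class <- ifelse(w >= 1L & h >= 2L, "both_multi_helper",
                ifelse(w >= 1L & h >= 1L, "both",
                ifelse(w >= 1L, "wre_only",
                ifelse(h >= 1L, "helper_only", "none"))))
  rank <- match(peak_class, lv)
  out <- do.call(rbind, lapply(split(seq_len(nrow(links)), links$gene_id),
                               function(idx) {
    data.frame(gene_id = links$gene_id[idx[1L]],
               motif_class = lv[max(rank[idx])],
               max_peak_score = max(links$score[idx]),
               n_peaks = length(idx))
  }))
  out$motif_class <- factor(out$motif_class, levels = lv)
  rownames(out) <- NULL
  out
}

#' Association of motif class with transcription change
#'
#' Per-class summaries of log2 fold change and pairwise Mann-Whitney tests
#' between classes; classes with fewer than `min_class_size` genes are
#' reported but not tested.
#'
#' @param gene_classes `data.frame` with `gene_id` and `motif_class`
#'   (e.g. from [classify_gene_links()]).
#' @param expression Expression `data.frame`.
#' @param min_class_size Smallest class entering tests (default 3).
#' @return List: `summary` (class / n / median_log2fc / mean_log2fc),
#'   `tests` (class_a / class_b / p_value).
#' @export
motif_class_association <- function(gene_classes, expression,
                                    min_class_size = 3L) {
  merged <- merge(gene_classes, expression, by = "gene_id")
  cls <- as.character(merged$motif_class)
  groups <- split(merged$log2_fold_change, cls)
  summ <- data.frame(
    motif_class = names(groups),
    n = vapply(groups, length, 0L),
    median_log2fc = vapply(groups, median, 0),
    mean_log2fc = vapply(groups, mean, 0))
  rownames(summ) <- NULL
  tests <- NULL
  if (length(groups) >= 2L) {
    combos <- utils::combn(names(groups), 2L)
    tests <- lapply(seq_len(ncol(combos)), function(i) {
      a <- groups[[combos[1L, i]]]; b <- groups[[combos[2L, i]]]
      if (length(a) < min_class_size || length(b) < min_class_size) {
        return(NULL)
      }
      data.frame(class_a = combos[1L, i], class_b = combos[2L, i],
                 p_value = mann_whitney_test(a, b)$p_value)
    })
    tests <- do.call(rbind, tests[!vapply(tests, is.null, TRUE)])
  }
  if (is.null(tests)) {
    tests <- data.frame(class_a = character(0), class_b = character(0),
                        p_value = numeric(0))
  }
  list(summary = summ, tests = tests)
}

#' Report of regulated genes with linked peaks
#'
#' One row per regulated gene carrying at least one linked peak: fold
#' change, significance, comma-joined signed TSS distances of its peaks,
#' maximum peak score and motif class.
#'
#' @param links Link table ([link_peaks_to_genes()]).
#' @param gene_classes Class table ([classify_gene_links()]).
#' @param expression Expression `data.frame`.
#' @param regulated Character vector of regulated gene ids (e.g.
#'   `select_regulated(...)$down`).
#' @param known_targets Optional character vector flagged in a `known`
#'   column.
#' @return `data.frame`, one row per reported gene, sorted by fold change.
#' @export
target_gene_report <- function(links, gene_classes, expression, regulated,
                               known_targets = NULL) {
  keep <- intersect(regulated, unique(links$gene_id))
  if (length(keep) == 0L) {
    return(data.frame(gene_id = character(0), log2_fold_change = numeric(0),
                      p_value = numeric(0), tss_distances = character(0),
                      max_peak_score = numeric(0),
                      motif_class = character(0), known = logical(0)))
  }
  rows <- lapply(keep, function(g) {
    lk <- links[links$gene_id == g, ]
    lk <- lk[order(abs(lk$tss_distance)), ]
    ex <- expression[expression$gene_id == g, ]
    gc <- gene_classes[gene_classes$gene_id == g, ]
    data.frame(gene_id = g,
               log2_fold_change = ex$log2_fold_change[1L],
               p_value = ex$p_value[1L],
               tss_distances = paste(lk$tss_distance, collapse = ", "),
               max_peak_score = max(lk$score),
               motif_class = as.character(gc$motif_class[1L]),
               known = if (is.null(known_targets)) NA else
                 g %in% known_targets)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$log2_fold_change), ]
  rownames(out) <- NULL
  out
}

#' Count peaks within a distance of each gene's TSS
#'
#' @param peaks Peak `data.frame`.
#' @param genes Gene-model `data.frame`.
#' @param max_distance Distance cutoff in bp (default 50000).
#' @param gene_ids Optional restriction to a gene subset.
#' @return Named integer vector of peak counts per gene.
#' @export
count_peaks_near_tss <- function(peaks, genes, max_distance = 50000L,
                                 gene_ids = NULL) {
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, ]
  links <- link_peaks_to_genes(peaks, genes, max_distance = max_distance)
  cnt <- table(links$gene_id)
  out <- setNames(integer(nrow(genes)), genes$gene_id)
  out[names(cnt)] <- as.integer(cnt)
  out
}
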