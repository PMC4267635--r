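# End-to-end orchestration: scan -> profiles -> co-occurrence ->
# comparisons -> annotation -> expression integration, with every stage's
# table written as TSV and a parameter-echo summary.  All outputs are
# deterministic given the input files and seed.

.write_stage_tsv <- function(x, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cclampscan schema=", schema, " v1"), con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full occupancy/transcription analysis pipeline
#'
#' Consumes a fixture directory (as produced by [make_fixture()], or any
#' directory holding the same standard formats), runs every analysis
#' stage on the top `top_k` peaks of each set and writes the stage tables
#' to `out_dir`.
#'
#' @param fixture_paths Named paths: `genome`, `genes`, `peaks_wt`,
#'   `peaks_mut`, `expression` (as in `make_fixture()$paths`).
#' @param out_dir Output directory.
#' @param top_k Number of top-scoring peaks analyzed per set.
#' @param motifs Named IUPAC patterns (default [builtin_motifs()]).
#' @param background One of `"peaks"` (frequencies of the analyzed WT peak
#'   sequences), `"uniform"`, or a named frequency vector.
#' @param link_distance TSS-link cutoff in bp.
#' @param min_link_score Strict score cutoff for peak-gene links.
#' @param p_cutoff Regulated-gene significance cutoff.
#' @param seed Seed for the permutation test.
#' @param n_permutations GSEA permutations.
#' @return Invisibly, a list with every stage's result and the output
#'   paths.
#' @export
run_pipeline <- function(fixture_paths, out_dir, top_k = 1000L,
                         motifs = builtin_motifs(),
                         background = "peaks",
                         link_distance = 30000L, min_link_score = 67,
                         p_cutoff = 0.02, seed = 1L,
                         n_permutations = 1000L) {
  need <- c("genome", "genes", "peaks_wt", "peaks_mut", "expression")
  missing <- setdiff(need, names(fixture_paths))
  if (length(missing) > 0L) stop("missing input path: ", missing[1L])
  for (f in fixture_paths[need]) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_fasta(fixture_paths[["genome"]])
  genes <- read_gene_models(fixture_paths[["genes"]])
  peaks_wt <- top_peaks(read_bed(fixture_paths[["peaks_wt"]]), top_k)
  peaks_mut <- top_peaks(read_bed(fixture_paths[["peaks_mut"]]), top_k)
  expression <- read_expression_table(fixture_paths[["expression"]])

  seqs_wt <- extract_peak_sequences(peaks_wt, genome)
  seqs_mut <- extract_peak_sequences(peaks_mut, genome)
  prof_wt <- profile_peaks(seqs_wt, motifs)
  prof_mut <- profile_peaks(seqs_mut, motifs)
  hits_wt <- scan_peaks(seqs_wt, motifs)
  hits_mut <- scan_peaks(seqs_mut, motifs)
  .write_stage_tsv(prof_wt, file.path(out_dir, "profiles_wt.tsv"),
                   "profiles")
  .write_stage_tsv(prof_mut, file.path(out_dir, "profiles_mut.tsv"),
                   "profiles")

  bg <- if (identical(background, "peaks")) {
    background_from_sequences(seqs_wt)
  } else if (identical(background, "uniform")) {
    uniform_background()
  } else {
    .check_background(background)
  }

  cooc <- rbind(
    cooccurrence_table(prof_wt, bg, condition_label = "WT"),
    cooccurrence_table(prof_mut,
                       if (identical(background, "peaks"))
                         background_from_sequences(seqs_mut) else bg,
                       condition_label = "mut"))
  .write_stage_tsv(cooc, file.path(out_dir, "cooccurrence.tsv"),
                   "cooccurrence")

  pairs <- overlap_regions(peaks_wt, peaks_mut)
  strength <- classify_strength(pairs)
  .write_stage_tsv(strength$pairs, file.path(out_dir, "matched_pairs.tsv"),
                   "matched_pairs")
  strata <- stratify_by_copy_number(pairs, prof_wt, motif = "Helper")
  .write_stage_tsv(strata$summary, file.path(out_dir, "copy_strata.tsv"),
                   "copy_strata")
  recip <- reciprocal_overlap_fraction(peaks_wt, peaks_mut)
  incid <- compare_incidence(prof_wt, prof_mut, "Helper")
  incid_wre <- compare_incidence(prof_wt, prof_mut, "WRE")
  center_prof <- motif_center_profile(
    hits_wt[hits_wt$motif == "shortHelper", ], peaks_wt, motifs)
  .write_stage_tsv(center_prof, file.path(out_dir, "center_profile.tsv"),
                   "center_profile")
  spacing <- spacing_orientation(hits_wt, motifs)
  .write_stage_tsv(spacing, file.path(out_dir, "spacing.tsv"), "spacing")

  assign_wt <- assign_features(peaks_wt, genes)
  assign_mut <- assign_features(peaks_mut, genes)
  .write_stage_tsv(assign_wt, file.path(out_dir, "features_wt.tsv"),
                   "features")
  .write_stage_tsv(assign_mut, file.path(out_dir, "features_mut.tsv"),
                   "features")

  links <- link_peaks_to_genes(peaks_wt, genes,
                               max_distance = link_distance,
                               min_score = min_link_score)
  classes <- classify_gene_links(links, prof_wt)
  regulated <- select_regulated(expression, p_cutoff = p_cutoff)
  assoc <- motif_class_association(classes, expression)
  .write_stage_tsv(assoc$summary, file.path(out_dir, "class_summary.tsv"),
                   "class_summary")
  .write_stage_tsv(assoc$tests, file.path(out_dir, "class_tests.tsv"),
                   "class_tests")
  report <- target_gene_report(links, classes, expression, regulated$down)
  .write_stage_tsv(report, file.path(out_dir, "target_genes.tsv"),
                   "target_genes")

  overlap_down <- hypergeometric_overlap(
    regulated$down, unique(links$gene_id), nrow(expression))
  gsea <- NULL
  linked_down <- intersect(regulated$down, classes$gene_id)
  ranked <- classes$gene_id[order(-classes$max_peak_score,
                                  classes$gene_id)]
  if (length(linked_down) >= 1L &&
      length(linked_down) < length(ranked)) {
    gsea <- peak_score_gsea(ranked, linked_down,
                            n_permutations = n_permutations, seed = seed)
  }

  summary_lines <- c(
    "cclampscan pipeline summary",
    paste0("seed=", seed, " top_k=", top_k,
           " link_distance=", link_distance,
           " min_link_score=", min_link_score, " p_cutoff=", p_cutoff),
    paste0("background=", paste(names(bg), round(bg, 4), sep = ":",
                                collapse = " ")),
    paste0("n_peaks_wt=", nrow(peaks_wt), " n_peaks_mut=",
           nrow(peaks_mut), " n_genes=", nrow(genes),
           " n_expression=", nrow(expression)),
    paste0("helper_incidence_p=", format(incid$p_value, digits = 6),
           " wre_incidence_p=", format(incid_wre$p_value, digits = 6)),
    paste0("strength_test=", strength$test, " n=", strength$n_tested,
           " p=", format(strength$p_value, digits = 6)),
    paste0("reciprocal_overlap=", paste(round(recip, 4), collapse = ",")),
    paste0("n_down=", length(regulated$down), " n_up=",
           length(regulated$up), " n_linked_genes=",
           length(unique(links$gene_id)),
           " n_linked_down=", length(linked_down)),
    paste0("overlap_down_p=", format(overlap_down$p_value, digits = 6)),
    if (!is.null(gsea)) {
      paste0("gsea_es=", format(gsea$enrichment_score, digits = 6),
             " gsea_p=", format(gsea$p_value, digits = 6))
    } else "gsea=not_run")
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(
    peaks_wt = peaks_wt, peaks_mut = peaks_mut,
    profiles_wt = prof_wt, profiles_mut = prof_mut,
    hits_wt = hits_wt, hits_mut = hits_mut,
    background = bg, cooccurrence = cooc,
    strength = strength, strata = strata,
    reciprocal_overlap = recip,
    incidence_helper = incid, incidence_wre = incid_wre,
    center_profile = center_prof, spacing = spacing,
    features_wt = assign_wt, features_mut = assign_mut,
    links = links, gene_classes = classes, regulated = regulated,
    class_association = assoc, target_report = report,
    overlap_down = overlap_down, gsea = gsea,
    out_dir = out_dir))
}
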