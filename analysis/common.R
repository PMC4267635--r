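# Shared loader for the analysis stages: reads the stage-1 fixture and
# prepares the top-1000 peak sets and their sequences.

load_fixture <- function(fixture_dir = "results/fixture", top_k = 1000L) {
  paths <- c(genome = file.path(fixture_dir, "genome.fasta"),
             genes = file.path(fixture_dir, "genes.tsv"),
             peaks_wt = file.path(fixture_dir, "peaks_wt.bed"),
             peaks_mut = file.path(fixture_dir, "peaks_mut.bed"),
             expression = file.path(fixture_dir, "expression.tsv"))
  if (!all(file.exists(paths))) {
    stop("fixture not found under ", fixture_dir,
         "; run analysis/01_simulate.R first")
  }
  genome <- read_fasta(paths[["genome"]])
  peaks_wt <- top_peaks(read_bed(paths[["peaks_wt"]]), top_k)
  peaks_mut <- top_peaks(read_bed(paths[["peaks_mut"]]), top_k)
  list(paths = paths,
       genome = genome,
       genes = read_gene_models(paths[["genes"]]),
       peaks_wt = peaks_wt,
       peaks_mut = peaks_mut,
       expression = read_expression_table(paths[["expression"]]),
       seqs_wt = extract_peak_sequences(peaks_wt, genome),
       seqs_mut = extract_peak_sequences(peaks_mut, genome))
}
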