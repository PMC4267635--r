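#' @importFrom stats median p.adjust pbinom phyper pnorm rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

# All genomic coordinates in this package are 0-based half-open (BED
# convention).  1-based values only appear in labelled report columns.

#' Read a BED3/BED5 peak file
#'
#' Peaks are scored genomic intervals, the unit of every occupancy statistic
#' in the package.  Columns beyond the fifth are ignored.
#'
#' @param path Path to a tab-delimited BED file (>= 3 columns; optional
#'   4th = name, 5th = score).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, in file order.  Missing names are auto-filled
#'   (`peak_00001`, ...); missing scores default to 0.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": start >= end")
  }
  peak_id <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 4L && nzchar(fields[[i]][4L]) && fields[[i]][4L] != ".") {
      fields[[i]][4L]
    } else {
      sprintf("peak_%05d", i)
    }
  }, "")
  score <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 5L) {
      s <- suppressWarnings(as.numeric(fields[[i]][5L]))
      if (is.na(s)) stop("malformed BED line ", i, ": non-numeric score")
      s
    } else 0
  }, 0)
  if (any(score < 0)) stop("negative peak score at line ", which(score < 0)[1L])
  if (anyDuplicated(peak_id)) {
    stop("duplicate peak id: ", peak_id[duplicated(peak_id)][1L])
  }
  data.frame(chrom = chrom, start = start, end = end,
             peak_id = peak_id, score = score)
}

#' Write peaks as BED5
#'
#' Round-trips with [read_bed()]: coordinates and scores are preserved
#' exactly.
#'
#' @param peaks Peak `data.frame` as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end", "peak_id", "score") %in%
                  names(peaks)))
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    format(peaks$score, trim = TRUE, scientific = FALSE,
                           drop0trailing = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is normalized to T; the alphabet is
#' restricted to A, C, G, T, N.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L])
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence '", nm[bad][1L], "' contains non-ACGTN characters")
  }
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Extract plus-strand peak sequences from a genome
#'
#' Peaks are strandless, so the plus-strand genome sequence is returned for
#' every peak.
#'
#' @param peaks Peak `data.frame`.
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector keyed by `peak_id`; each string has length
#'   `end - start`.
#' @export
extract_peak_sequences <- function(peaks, genome) {
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom) > 0L) {
    stop("chromosome not in genome: ", missing_chrom[1L])
  }
  lens <- nchar(genome)[peaks$chrom]
  bad <- which(peaks$start < 0L | peaks$end > lens)
  if (length(bad) > 0L) {
    stop("peak '", peaks$peak_id[bad[1L]], "' out of chromosome bounds")
  }
  out <- substr(genome[peaks$chrom], peaks$start + 1L, peaks$end)
  names(out) <- peaks$peak_id
  out
}

#' Read a gene-model table
#'
#' Expects a tab-delimited file with a header and columns `gene_id`,
#' `chrom`, `strand`, `tss`, `tes`, `exon_starts`, `exon_ends` (the exon
#' columns comma-joined, 0-based half-open).  The TSS is the leftmost
#' coordinate for + strand genes and the rightmost for - strand genes.
#'
#' @param path Path to the table.
#' @return A `data.frame` with list-columns `exon_starts` / `exon_ends`
#'   holding integer vectors.
#' @export
read_gene_models <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(tab))) {
    stop("gene-model table must contain columns: ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene_id: ", tab$gene_id[duplicated(tab$gene_id)][1L])
  }
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  parse_ints <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) integer(0) else
        as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
    })
  }
  tab$exon_starts <- if ("exon_starts" %in% names(tab))
    parse_ints(as.character(tab$exon_starts)) else
      lapply(seq_len(nrow(tab)), function(i) integer(0))
  tab$exon_ends <- if ("exon_ends" %in% names(tab))
    parse_ints(as.character(tab$exon_ends)) else
      lapply(seq_len(nrow(tab)), function(i) integer(0))
  for (i in seq_len(nrow(tab))) {
    es <- tab$exon_starts[[i]]; ee <- tab$exon_ends[[i]]
    if (length(es) != length(ee)) {
      stop("gene ", tab$gene_id[i], ": exon start/end count mismatch")
    }
    if (length(es) > 1L && any(es[-1L] < ee[-length(ee)])) {
      stop("gene ", tab$gene_id[i], ": exons overlap or are unsorted")
    }
  }
  tab
}

#' Write a gene-model table
#'
#' @param genes Gene-model `data.frame` as from [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  join <- function(col) vapply(col, paste, "", collapse = ",")
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss, tes = genes$tes,
                    exon_starts = join(genes$exon_starts),
                    exon_ends = join(genes$exon_ends))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Consumes per-gene transcription-change records (e.g. nascent-RNA
#' sequencing output processed elsewhere): one row per gene with a log2
#' fold change and a p-value.
#'
#' @param path Path to a delimited file with a header.
#' @param gene_col,lfc_col,p_col Column names for gene id, log2 fold change
#'   and p-value.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @return `data.frame` with columns `gene_id`, `log2_fold_change`,
#'   `p_value`.
#' @export
read_expression_table <- function(path, gene_col = "gene_id",
                                  lfc_col = "log2_fold_change",
                                  p_col = "p_value", sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c(gene_col, lfc_col, p_col)
  if (!all(need %in% names(tab))) {
    stop("expression table must contain columns: ",
         paste(need, collapse = ", "))
  }
  gene <- as.character(tab[[gene_col]])
  lfc <- suppressWarnings(as.numeric(tab[[lfc_col]]))
  p <- suppressWarnings(as.numeric(tab[[p_col]]))
  if (anyNA(lfc)) stop("unparseable log2 fold change at row ",
                       which(is.na(lfc))[1L])
  if (anyNA(p)) stop("unparseable p-value at row ", which(is.na(p))[1L])
  if (any(p < 0 | p > 1)) stop("p-value outside [0, 1] at row ",
                               which(p < 0 | p > 1)[1L])
  if (anyDuplicated(gene)) {
    stop("duplicate gene_id: ", gene[duplicated(gene)][1L])
  }
  data.frame(gene_id = gene, log2_fold_change = lfc, p_value = p)
}

#' Rank peaks and keep the top K
#'
#' Ranking is by descending score with ties broken by (chrom, start) so the
#' selection is deterministic.
#'
#' @param peaks Peak `data.frame`.
#' @param top_k Number of peaks to keep; if `NULL` or larger than the set,
#'   all peaks are returned (still sorted).
#' @return The top-ranked peaks.
#' @export
top_peaks <- function(peaks, top_k = NULL) {
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord, , drop = FALSE]
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}
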