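#' Read and write the pipeline's standard file formats
#'
#' Thin wrappers over `Biostrings` (FASTA/FASTQ) and `rtracklayer`
#' (BED/GFF3/wiggle). Genomic tables inside the package are 0-based
#' half-open; conversion to the 1-based conventions of GFF3/GRanges
#' happens only here, at the boundary.
#'
#' @param seqs named character vector of sequences (DNA).
#' @param path file path.
#' @name smallmir-io
NULL

#' @rdname smallmir-io
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname smallmir-io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname smallmir-io
#' @param reads character vector of reads.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read_", seq_len(n))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname smallmir-io
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' @rdname smallmir-io
#' @param df interval data.frame with `chrom`, `start`, `end`, `strand`
#'   and optionally `name`, `score` (0-based half-open).
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1L, df$end),
    strand = df$strand)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname smallmir-io
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             score = if (!is.null(gr$score)) gr$score else NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname smallmir-io
#' @param track named list of per-chromosome score vectors (`NA` missing).
#' @export
write_wig <- function(track, path) {
  grl <- lapply(names(track), function(chrom) {
    v <- track[[chrom]]
    pos <- which(!is.na(v))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                           score = v[pos])
  })
  gr <- do.call(c, grl)
  rtracklayer::export(gr, path, format = "WIG")
  invisible(path)
}

#' @rdname smallmir-io
#' @param chrom_lengths named integer vector giving each chromosome's
#'   length (positions without a score become `NA`).
#' @export
read_wig <- function(path, chrom_lengths) {
  gr <- rtracklayer::import(path, format = "WIG")
  out <- lapply(names(chrom_lengths), function(chrom) {
    v <- rep(NA_real_, chrom_lengths[[chrom]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (length(g) > 0L) {
      pos <- BiocGenerics::start(g)
      v[pos] <- g$score
    }
    v
  })
  setNames(out, names(chrom_lengths))
}

#' @rdname smallmir-io
#' @param candidates candidate data.frame (see [candidate_from_reads()]).
#' @export
write_candidates_gff3 <- function(candidates, path) {
  if (nrow(candidates) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  prec <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$start + 1L, candidates$end),
    strand = candidates$strand)
  prec$type <- "miRNA_primary_transcript"
  prec$ID <- candidates$name
  mat <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(candidates$mature_start + 1L, candidates$mature_end),
    strand = candidates$strand)
  mat$type <- "miRNA"
  mat$ID <- paste0(candidates$name, "_mature")
  mat$Parent <- candidates$name
  gr <- c(prec, mat)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname smallmir-io
#' @export
read_candidates_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "miRNA_primary_transcript"]
  data.frame(name = gr$ID,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full result bundle of a pipeline run
#'
#' Emits candidate precursors as GFF3 and FASTA, alignments as BED6 (score
#' = read count) plus a TSV with `n_hits`, the per-category summary, star
#' calls, conservation verdicts, family target-test tables, and the run
#' report as JSON with the configuration hash embedded. Empty results
#' produce valid, well-formed files with headers.
#'
#' @param results list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_outputs <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  cand <- results$candidates
  if (is.null(cand)) {
    cand <- data.frame(name = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), mature_start = integer(0),
                       mature_end = integer(0), sequence = character(0))
  }
  write_candidates_gff3(cand, file.path(dir, "candidates.gff3"))
  if (nrow(cand) > 0L) {
    write_fasta(setNames(cand$sequence, cand$name),
                file.path(dir, "candidates.fa"))
  } else {
    writeLines(character(0), file.path(dir, "candidates.fa"))
  }
  .write_tsv(cand, file.path(dir, "candidates.tsv"))
  aln <- results$alignments
  if (!is.null(aln) && nrow(aln) > 0L) {
    write_bed(data.frame(chrom = aln$chrom, start = aln$start,
                         end = aln$end, strand = aln$strand,
                         name = aln$sequence, score = aln$count),
              file.path(dir, "alignments.bed"))
  } else {
    writeLines(character(0), file.path(dir, "alignments.bed"))
  }
  .write_tsv(if (is.null(aln)) data.frame() else aln,
             file.path(dir, "alignments.tsv"))
  .write_tsv(results$category_summary, file.path(dir, "categories.tsv"))
  .write_tsv(results$star_calls, file.path(dir, "star_calls.tsv"))
  if (!is.null(results$novel)) {
    .write_tsv(results$novel, file.path(dir, "novel_candidates.tsv"))
  }
  for (side in c("main", "ncrna")) {
    tt <- results$target_tests[[side]]
    if (!is.null(tt)) {
      .write_tsv(tt$results, file.path(dir, paste0("target_tests_",
                                                   side, ".tsv")))
    }
  }
  jsonlite::write_json(results$report,
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  summary_lines <- c(
    paste0("smallmir run ", results$report$config_hash),
    paste0("raw reads: ", results$report$reads$raw),
    paste0("unique mapped-stage reads: ", results$report$n_unique_reads),
    paste0("candidates: ", results$report$n_candidates),
    paste0("novel (either approach): ",
           if (is.null(results$report$n_novel)) 0 else
             results$report$n_novel),
    paste0("conserved novel: ",
           if (is.null(results$report$n_conserved_novel)) 0 else
             results$report$n_conserved_novel))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
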