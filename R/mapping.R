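#' Build an exact-match genome index
#'
#' Wraps the genome in `Biostrings` objects for exact (no-mismatch)
#' matching on both strands. A read maps to the minus strand at a locus
#' exactly when its reverse complement occurs on the plus strand there, so
#' both strands are searched against the forward genome.
#'
#' @param genome named character vector of chromosome sequences (DNA).
#' @return an index object for [map_exact()] and [map_reads()].
#' @export
build_index <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  list(genome = Biostrings::DNAStringSet(genome),
       chrom_lengths = setNames(nchar(genome), names(genome)))
}

#' Map one unique read exactly to the genome
#'
#' @param ur a unique-read sequence (RNA or DNA) or a one-row data.frame
#'   with a `sequence` column.
#' @param index from [build_index()].
#' @return data.frame of `GenomicAlignment`s: `sequence`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `n_hits` (total exact placements
#'   of this sequence genome-wide, both strands).
#' @export
map_exact <- function(ur, index) {
  seq <- if (is.data.frame(ur)) ur$sequence else ur
  res <- map_reads(data.frame(sequence = seq, count = 1L), index)
  res[, c("sequence", "chrom", "start", "end", "strand", "n_hits")]
}

#' Map collapsed unique reads exactly to the genome
#'
#' Exact placements on both strands via `Biostrings::matchPDict` (reads
#' grouped by width). Multi-mapping reads are retained with all their
#' placements; `n_hits` records the genome-wide placement count of each
#' sequence so downstream stages can flip that policy.
#'
#' @param reads data.frame with `sequence` (RNA or DNA) and `count`.
#' @param index from [build_index()].
#' @return data.frame with `sequence` (as supplied), `count`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `n_hits`.
#' @export
map_reads <- function(reads, index) {
  empty <- data.frame(sequence = character(0), count = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_hits = integer(0))
  if (nrow(reads) == 0L) return(empty)
  dna <- toupper(rna_to_dna(reads$sequence))
  hits <- list()
  for (w in unique(nchar(dna))) {
    sel <- which(nchar(dna) == w)
    for (str in c("+", "-")) {
      pats <- if (str == "+") dna[sel] else revcomp_dna(dna[sel])
      pd <- Biostrings::PDict(pats)
      for (chrom in names(index$genome)) {
        m <- Biostrings::matchPDict(pd, index$genome[[chrom]])
        starts <- Biostrings::startIndex(m)
        ns <- lengths(starts)
        if (sum(ns) == 0L) next
        hits[[length(hits) + 1L]] <- data.frame(
          i = rep(sel, ns), chrom = chrom,
          start = unlist(starts) - 1L, strand = str,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  h$sequence <- reads$sequence[h$i]
  h$count <- if (is.null(reads$count)) 1L else reads$count[h$i]
  h$end <- h$start + nchar(h$sequence)
  nh <- table(h$i)
  h$n_hits <- as.integer(nh[as.character(h$i)])
  h <- h[order(h$chrom, h$start, h$strand, h$sequence), ]
  rownames(h) <- NULL
  h[, c("sequence", "count", "chrom", "start", "end", "strand", "n_hits")]
}
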