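#' Discover candidate precursor hairpins around mapped reads
#'
#' Slides 110-nt windows (at `stride`-nt steps) over the regions 100 nt
#' up- and downstream of mapped reads (merged per chromosome and strand),
#' folds each window with the local engine, extracts unbranched stem-loops
#' with at least `min_pairs` base pairs, maps them back to genome
#' coordinates and deduplicates overlapping extractions (keeping the
#' highest pair count per overlapping cluster, ties to the leftmost).
#'
#' @param alignments data.frame from [map_reads()].
#' @param genome named character vector of chromosome sequences.
#' @param flank region extension around reads (default 100 nt).
#' @param window sliding window length (default 110 nt).
#' @param stride window step (default 10 nt; use 1 for small test genomes).
#' @param min_pairs minimum stem pairs (default 20).
#' @param min_loop folding engine minimum loop.
#' @param max_bulge largest bulge/internal-loop side tolerated while
#'   extending a stem outward (default 8; `Inf` disables the cap).
#' @return data.frame of hairpin loci: `chrom`, `start`, `end`, `strand`
#'   (0-based half-open, genome), `pairs`, `loop_start`, `loop_end`,
#'   `max_bulge`, `sequence` (DNA, 5'->3'), `structure`.
#' @export
discover_hairpins <- function(alignments, genome, flank = 100L,
                              window = 110L, stride = 10L,
                              min_pairs = 20L, min_loop = 3L,
                              max_bulge = 8L) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      pairs = integer(0), loop_start = integer(0),
                      loop_end = integer(0), max_bulge = integer(0),
                      sequence = character(0), structure = character(0))
  if (nrow(alignments) == 0L) return(empty)
  found <- list()
  for (chrom in unique(alignments$chrom)) {
    L <- nchar(genome[[chrom]])
    for (str in c("+", "-")) {
      al <- alignments[alignments$chrom == chrom &
                         alignments$strand == str, , drop = FALSE]
      if (nrow(al) == 0L) next
      ir <- IRanges::reduce(IRanges::IRanges(
        pmax(0L, al$start - flank) + 1L, pmin(L, al$end + flank)))
      starts <- integer(0)
      for (k in seq_along(ir)) {
        rs <- BiocGenerics::start(ir)[k] - 1L
        re <- BiocGenerics::end(ir)[k]
        if (re - rs < window) {
          ws <- rs
        } else {
          ws <- seq.int(rs, re - window, by = stride)
          if (ws[length(ws)] < re - window) ws <- c(ws, re - window)
        }
        starts <- c(starts, ws)
      }
      wlen <- pmin(window, L - starts)
      keep <- wlen >= 20L
      starts <- starts[keep]; wlen <- wlen[keep]
      if (length(starts) == 0L) next
      wseqs <- substring(genome[[chrom]], starts + 1L, starts + wlen)
      if (str == "-") wseqs <- revcomp_dna(wseqs)
      folded <- .fold_batch(wseqs, min_loop)
      for (i in seq_along(starts)) {
        hp <- extract_hairpins(folded$structure[i], min_pairs, max_bulge)
        if (nrow(hp) == 0L) next
        # window-local -> genome coordinates (strand-aware)
        if (str == "+") {
          gs <- starts[i] + hp$start
          ge <- starts[i] + hp$end
          gl0 <- starts[i] + hp$loop_start
          gl1 <- starts[i] + hp$loop_end
        } else {
          we <- starts[i] + wlen[i]
          gs <- we - hp$end
          ge <- we - hp$start
          gl0 <- we - hp$loop_end
          gl1 <- we - hp$loop_start
        }
        found[[length(found) + 1L]] <- data.frame(
          chrom = chrom, start = gs, end = ge, strand = str,
          pairs = hp$pairs, loop_start = gl0, loop_end = gl1,
          max_bulge = hp$max_bulge,
          sequence = substr(wseqs[i], hp$start + 1L, hp$end),
          structure = substr(folded$structure[i], hp$start + 1L, hp$end),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(found) == 0L) return(empty)
  h <- do.call(rbind, found)
  # deduplicate overlapping extractions per chrom/strand
  keep <- logical(nrow(h))
  for (grp in split(seq_len(nrow(h)),
                    paste(h$chrom, h$strand))) {
    g <- h[grp, , drop = FALSE]
    o <- grp[order(-g$pairs, g$start)]
    taken <- matrix(integer(0), ncol = 2)
    for (i in o) {
      if (nrow(taken) == 0L ||
          !any(h$start[i] < taken[, 2] & h$end[i] > taken[, 1])) {
        keep[i] <- TRUE
        taken <- rbind(taken, c(h$start[i], h$end[i]))
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  # refinement: re-extract each locus from a window centred on it; sliding
  # windows that clip a stem near their edge, or extend it through flank
  # pairings, otherwise win the dedup with inflated pair counts
  for (i in seq_len(nrow(h))) {
    L <- nchar(genome[[h$chrom[i]]])
    mid <- (h$start[i] + h$end[i]) %/% 2L
    ws <- max(0L, min(mid - window %/% 2L, L - window))
    we <- min(L, ws + window)
    if (we - ws < 20L) next
    wseq <- .feature_seq(genome[[h$chrom[i]]], ws, we, h$strand[i])
    fs <- fold_local(wseq, min_loop)[[1]]
    hp <- extract_hairpins(fs, min_pairs, max_bulge)
    if (nrow(hp) == 0L) next
    if (h$strand[i] == "+") {
      gs <- ws + hp$start; ge <- ws + hp$end
      gl0 <- ws + hp$loop_start; gl1 <- ws + hp$loop_end
    } else {
      gs <- we - hp$end; ge <- we - hp$start
      gl0 <- we - hp$loop_end; gl1 <- we - hp$loop_start
    }
    ov <- pmax(0L, pmin(ge, h$end[i]) - pmax(gs, h$start[i]))
    best <- which.max(ov)
    if (ov[best] < (h$end[i] - h$start[i]) %/% 2L) next
    h$start[i] <- gs[best]; h$end[i] <- ge[best]
    h$loop_start[i] <- gl0[best]; h$loop_end[i] <- gl1[best]
    h$pairs[i] <- hp$pairs[best]
    h$max_bulge[i] <- hp$max_bulge[best]
    h$sequence[i] <- substr(wseq, hp$start[best] + 1L, hp$end[best])
    h$structure[i] <- substr(fs$structure, hp$start[best] + 1L,
                             hp$end[best])
  }
  h <- h[!duplicated(h[, c("chrom", "start", "end", "strand")]), ,
         drop = FALSE]
  h <- h[order(h$chrom, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Build a candidate precursor from reads on a hairpin
#'
#' Reads mapped inside the stem-loop (same strand) are grouped by
#' identical 5' end; within each group the highest-expressed sequence is
#' the group representative (ties to the longer, then lexicographically
#' smaller sequence). Groups are tried in order of read support; the first
#' representative with at least `min_in_stem` nucleotides inside the stem
#' and not spanning the terminal loop becomes the candidate mature.
#'
#' @param hairpin one row of [discover_hairpins()] output (or an
#'   equivalent list).
#' @param alignments data.frame from [map_reads()].
#' @param min_in_stem minimum mature nucleotides inside the stem
#'   (default 16).
#' @return a one-row candidate data.frame, or `NULL` if no group passes.
#' @export
candidate_from_reads <- function(hairpin, alignments, min_in_stem = 16L) {
  h <- as.list(hairpin)
  inside <- alignments$chrom == h$chrom &
    alignments$strand == h$strand &
    alignments$start >= h$start & alignments$end <= h$end
  reads <- alignments[inside, , drop = FALSE]
  if (nrow(reads) == 0L) return(NULL)
  arms <- rbind(c(h$start, h$loop_start), c(h$loop_end, h$end))
  groups <- .group_by_5p(reads)
  for (g in groups) {
    m <- g$rep
    in_arm <- pmax(0L, pmin(m$end, arms[, 2]) - pmax(m$start, arms[, 1]))
    if (all(in_arm > 0L)) next            # spans the loop
    if (max(in_arm) < min_in_stem) next   # too little of it in the stem
    return(data.frame(
      name = paste0("cand_", h$chrom, "_", h$start, "_", h$strand),
      chrom = h$chrom, start = h$start, end = h$end, strand = h$strand,
      stem_pairs = h$pairs, loop_start = h$loop_start,
      loop_end = h$loop_end, sequence = h$sequence,
      structure = h$structure,
      mature_seq = m$sequence, mature_start = m$start,
      mature_end = m$end, mature_count = m$count,
      precursor_count = sum(reads$count),
      arm = if (in_arm[1] >= in_arm[2]) "5p" else "3p",
      stringsAsFactors = FALSE))
  }
  NULL
}

#' Remove exonic candidates; tag ncRNA-derived ones
#'
#' Candidates whose mature is assigned to the exon category by the
#' majority-overlap rule are excluded; candidates whose mature falls
#' within annotated ncRNA are retained but tagged `ncrna_derived` (they
#' are analyzed separately downstream, not discarded).
#'
#' @param candidates data.frame of candidates.
#' @param ann an [annotation_set()].
#' @return list `candidates` (with `ncrna_derived` flag and `category`
#'   column) and `n_excluded_exonic`.
#' @export
exclude_exonic <- function(candidates, ann) {
  if (nrow(candidates) == 0L) {
    candidates$ncrna_derived <- logical(0)
    candidates$category <- character(0)
    return(list(candidates = candidates, n_excluded_exonic = 0L))
  }
  mat <- data.frame(chrom = candidates$chrom,
                    start = candidates$mature_start,
                    end = candidates$mature_end,
                    strand = candidates$strand)
  cat <- assign_categories(mat, ann)
  keep <- cat != "exon"
  out <- candidates[keep, , drop = FALSE]
  out$category <- cat[keep]
  out$ncrna_derived <- cat[keep] == "ncRNA"
  rownames(out) <- NULL
  list(candidates = out, n_excluded_exonic = sum(!keep))
}
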