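#' Construct an annotation set
#'
#' An annotation set is a data.frame of stranded genome intervals (0-based
#' half-open) with a `category` in miRNA, ncRNA, repeat, exon, intron (the
#' complement of all intervals is intergenic). miRNA precursor rows may
#' additionally carry the annotated mature interval (`mature_start`,
#' `mature_end`) and the hairpin terminal-loop interval (`loop_start`,
#' `loop_end`), which star-product calling requires.
#'
#' @param df data.frame with at least `chrom`, `start`, `end`, `strand`,
#'   `category`, `name`.
#' @return the validated data.frame (with the optional columns filled with
#'   `NA` when absent).
#' @export
annotation_set <- function(df) {
  need <- c("chrom", "start", "end", "strand", "category", "name")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$category %in%
                  c("miRNA", "ncRNA", "repeat", "exon", "intron")))
  stopifnot(all(df$end > df$start))
  for (col in c("mature_start", "mature_end", "loop_start", "loop_end")) {
    if (is.null(df[[col]])) df[[col]] <- NA_integer_
  }
  df
}

#' Assign mapped reads to annotation categories
#'
#' A read is assigned to a category if at least `min_frac` (default half)
#' of its sequence falls inside an interval of that category; among
#' qualifying categories the highest-priority one wins. The priority order
#' follows the conventional listing (miRNA first); reads qualifying for no
#' category are intergenic. Strand must match for miRNA and ncRNA (their
#' processing is strand-specific); repeat/exon/intron overlap ignores
#' strand.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open), e.g. from [map_reads()].
#' @param ann an [annotation_set()].
#' @param priority category precedence, highest first.
#' @param min_frac minimum overlap fraction of the read length (default
#'   0.5; exactly half qualifies).
#' @param stranded_categories categories requiring read/annotation strand
#'   match.
#' @return character vector of categories, one per alignment (a total
#'   function: every alignment gets exactly one category).
#' @export
assign_categories <- function(alignments, ann,
                              priority = c("miRNA", "ncRNA", "repeat",
                                           "exon", "intron"),
                              min_frac = 0.5,
                              stranded_categories = c("miRNA", "ncRNA")) {
  n <- nrow(alignments)
  out <- rep("intergenic", n)
  if (n == 0L || nrow(ann) == 0L) return(out)
  qr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start + 1L, alignments$end))
  ar <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end))
  ov <- GenomicRanges::findOverlaps(qr, ar)
  if (length(ov) == 0L) return(out)
  qi <- S4Vectors::queryHits(ov)
  ai <- S4Vectors::subjectHits(ov)
  ostart <- pmax(alignments$start[qi], ann$start[ai])
  oend <- pmin(alignments$end[qi], ann$end[ai])
  frac <- (oend - ostart) / (alignments$end[qi] - alignments$start[qi])
  cat_i <- ann$category[ai]
  strand_ok <- !(cat_i %in% stranded_categories) |
    alignments$strand[qi] == ann$strand[ai]
  keep <- frac >= min_frac & strand_ok
  if (!any(keep)) return(out)
  qi <- qi[keep]
  prio <- match(cat_i[keep], priority)
  best <- tapply(prio, qi, min)
  out[as.integer(names(best))] <- priority[best]
  out
}

#' @rdname assign_categories
#' @param aln a one-row alignment data.frame.
#' @export
assign_category <- function(aln, ann, ...) {
  assign_categories(aln[1, , drop = FALSE], ann, ...)[1]
}

#' Summarize mapped read counts per annotation category
#'
#' @param alignments data.frame from [map_reads()] (`count` column used as
#'   the read weight; multi-mapping reads contribute their full count at
#'   each placement).
#' @param ann an [annotation_set()].
#' @param ... passed to [assign_categories()].
#' @return data.frame `category`, `reads`, `fraction` (fractions sum to 1),
#'   over all six categories including intergenic.
#' @export
summarize_categories <- function(alignments, ann, ...) {
  cats <- c("miRNA", "ncRNA", "repeat", "exon", "intron", "intergenic")
  cnt <- setNames(rep(0, length(cats)), cats)
  if (nrow(alignments) > 0L) {
    assigned <- assign_categories(alignments, ann, ...)
    agg <- tapply(alignments$count, assigned, sum)
    cnt[names(agg)] <- agg
  }
  tot <- sum(cnt)
  data.frame(category = cats, reads = as.numeric(cnt),
             fraction = if (tot > 0) as.numeric(cnt) / tot else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

# precursor-local 5' end of a stranded genome interval
.five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

# group reads by identical 5' end and pick each group's representative:
# highest count, ties to the longer then lexicographically smaller sequence
.group_by_5p <- function(reads) {
  fp <- .five_prime(reads$start, reads$end, reads$strand)
  split_idx <- split(seq_len(nrow(reads)), fp)
  groups <- lapply(split_idx, function(ix) {
    g <- reads[ix, , drop = FALSE]
    o <- order(-g$count, -nchar(g$sequence), g$sequence)
    list(rep = g[o[1], , drop = FALSE], total = sum(g$count))
  })
  groups[order(-vapply(groups, `[[`, numeric(1), "total"),
               as.integer(names(groups)))]
}

#' Call miRNA-star products from annotated precursors
#'
#' For each annotated miRNA precursor with exactly one annotated mature,
#' reads mapping within the precursor (same strand) that overlap the
#' annotated mature by less than half and lie mostly on the opposite arm
#' (the other side of the hairpin loop) are grouped by identical 5' end;
#' the group with the highest read support is the candidate star product.
#' Stars expressed above their annotated mature counterpart and stars above
#' an absolute copy-number threshold are flagged.
#'
#' @param alignments data.frame from [map_reads()].
#' @param ann an [annotation_set()] whose miRNA rows carry mature and loop
#'   coordinates (precursors lacking loop coordinates are skipped with a
#'   warning).
#' @param high_expr_threshold flag stars with count strictly greater than
#'   this copy number (default 3000).
#' @return data.frame of star calls: `precursor`, `star_sequence` (RNA),
#'   `star_count`, `mature_count`, `ratio`, `higher_than_mature`,
#'   `high_expression`.
#' @export
call_star_products <- function(alignments, ann, high_expr_threshold = 3000) {
  mir <- ann[ann$category == "miRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mir))) {
    p <- mir[i, ]
    if (is.na(p$mature_start) || is.na(p$mature_end)) next
    if (is.na(p$loop_start) || is.na(p$loop_end)) {
      warning("precursor ", p$name, " lacks loop coordinates; skipped")
      next
    }
    inside <- alignments$chrom == p$chrom &
      alignments$strand == p$strand &
      alignments$start >= p$start & alignments$end <= p$end
    reads <- alignments[inside, , drop = FALSE]
    if (nrow(reads) == 0L) next
    len <- reads$end - reads$start
    ov_mat <- pmax(0L, pmin(reads$end, p$mature_end) -
                     pmax(reads$start, p$mature_start))
    mature_count <- sum(reads$count[ov_mat / len >= 0.5])
    # the arm on the other side of the loop from the annotated mature
    if (p$mature_end <= p$loop_start) {
      opp <- c(p$loop_end, p$end)
    } else {
      opp <- c(p$start, p$loop_start)
    }
    ov_opp <- pmax(0L, pmin(reads$end, opp[2]) - pmax(reads$start, opp[1]))
    star_reads <- reads[ov_mat / len < 0.5 & ov_opp / len >= 0.5, ,
                        drop = FALSE]
    if (nrow(star_reads) == 0L) next
    g <- .group_by_5p(star_reads)[[1]]
    out[[length(out) + 1L]] <- data.frame(
      precursor = p$name, star_sequence = g$rep$sequence,
      star_count = g$total, mature_count = mature_count,
      ratio = if (mature_count > 0) g$total / mature_count else Inf,
      higher_than_mature = g$total > mature_count,
      high_expression = g$total > high_expr_threshold,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(precursor = character(0), star_sequence = character(0),
                      star_count = integer(0), mature_count = integer(0),
                      ratio = numeric(0), higher_than_mature = logical(0),
                      high_expression = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
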