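#' Trim the 3' adapter from fixed-length small-RNA reads
#'
#' Scans candidate adapter start positions left to right over the read; at
#' each position the adapter prefix is compared against the read suffix
#' (overlap of at least `min_overlap` nt), counting mismatches. The read
#' prefix before the leftmost position with at most `max_mismatch`
#' mismatches is the insert; reads where no position qualifies are
#' discarded (an untrimmed read has an indeterminate insert length, and a
#' full-length insert would fail the 18-28 nt size filter anyway).
#'
#' @param read a single read sequence (36 nt expected).
#' @param adapter the 3' adapter sequence (DNA).
#' @param max_mismatch maximum mismatches tolerated in the adapter overlap
#'   (default 3).
#' @param min_overlap minimum adapter/read overlap considered (default 6 nt;
#'   shorter overlaps are indistinguishable from noise).
#' @return the insert string, or `NA_character_` if the read contains
#'   non-ACGT characters or no adapter position qualifies.
#' @export
trim_adapter <- function(read, adapter, max_mismatch = 3L, min_overlap = 6L) {
  stopifnot(length(read) == 1L, nchar(adapter) >= 1L)
  trim_adapters(read, adapter, max_mismatch, min_overlap)
}

#' @rdname trim_adapter
#' @param reads character vector of reads (all the same length).
#' @export
trim_adapters <- function(reads, adapter, max_mismatch = 3L, min_overlap = 6L) {
  n <- length(reads)
  if (n == 0L) return(character(0))
  rl <- unique(nchar(reads))
  stopifnot(length(rl) == 1L)
  out <- rep(NA_character_, n)
  ok <- !grepl("[^ACGTacgt]", reads)
  if (!any(ok)) return(out)
  idx <- which(ok)
  mat <- matrix(unlist(strsplit(toupper(reads[idx]), "", fixed = TRUE)),
                nrow = length(idx), byrow = TRUE)
  ac <- strsplit(toupper(adapter), "", fixed = TRUE)[[1]]
  na <- length(ac)
  pos <- rep(NA_integer_, length(idx))
  for (p in 0:(rl - min_overlap)) {          # 0-based adapter start in read
    w <- min(na, rl - p)
    if (w < min_overlap) break
    mism <- rowSums(mat[, (p + 1L):(p + w), drop = FALSE] !=
                      matrix(ac[seq_len(w)], nrow = length(idx),
                             ncol = w, byrow = TRUE))
    hit <- is.na(pos) & mism <= max_mismatch
    pos[hit] <- p
  }
  have <- !is.na(pos)
  out[idx[have]] <- substr(reads[idx][have], 1L, pos[have])
  out
}

#' DUST low-complexity score
#'
#' Triplet-based complexity score: over each window of at most `window` nt,
#' score = sum over triplet types of n(n-1)/2 divided by (w - 3), where n is
#' the count of each overlapping triplet in the window and w the window
#' length. The sequence score is the maximum over windows (reads of at most
#' `window` nt have a single window). Homopolymers score maximally;
#' sequences whose triplets are all distinct score 0.
#'
#' @param seq character scalar, length >= 3.
#' @param window maximum window length (default 64).
#' @return numeric score.
#' @export
dust_score <- function(seq, window = 64L) {
  n <- nchar(seq)
  stopifnot(n >= 3L)
  b <- .base_codes(seq)
  b[is.na(b)] <- 0L  # non-ACGT treated as A; such reads are rejected earlier
  tri <- b[1:(n - 2L)] * 16L + b[2:(n - 1L)] * 4L + b[3:n]
  score_win <- function(t, w) {
    cnt <- tabulate(t + 1L, nbins = 64L)
    sum(cnt * (cnt - 1L) / 2) / (w - 3L)
  }
  if (n <= window) return(score_win(tri, n))
  best <- 0
  for (s in 1:(n - window + 1L)) {
    best <- max(best, score_win(tri[s:(s + window - 3L)], window))
  }
  best
}

#' @rdname dust_score
#' @param threshold sequences with maximum window score at or above this are
#'   dropped (default 2.0, common DUST practice).
#' @return `dust_filter`: TRUE to keep, FALSE to drop.
#' @export
dust_filter <- function(seq, threshold = 2.0, window = 64L) {
  dust_score(seq, window) < threshold
}

#' Collapse trimmed inserts into supported unique reads
#'
#' Groups identical insert sequences, sums their read support, and applies
#' the size and support filters: only sequences of 18-28 nt represented by
#' at least `min_count` raw reads are kept. Dropped raw-read counts are
#' reported by reason so that reads are conserved exactly across the stage.
#'
#' @param inserts character vector of trimmed insert sequences (DNA), one
#'   element per raw read (`NA` entries are not allowed here; remove
#'   untrimmable reads first).
#' @param min_len,max_len insert length bounds (defaults 18 and 28 nt).
#' @param min_count minimum raw-read support (default 2).
#' @return list with `reads` (data.frame `sequence` in RNA, `count`, sorted
#'   by decreasing count) and `dropped` (named integer vector of raw-read
#'   counts by reason: `too_short`, `too_long`, `low_support`).
#' @export
collapse_and_filter <- function(inserts, min_len = 18L, max_len = 28L,
                                min_count = 2L) {
  stopifnot(!anyNA(inserts))
  dropped <- c(too_short = 0L, too_long = 0L, low_support = 0L)
  if (length(inserts) == 0L) {
    return(list(reads = data.frame(sequence = character(0),
                                   count = integer(0)),
                dropped = dropped))
  }
  tab <- table(inserts)
  seqs <- names(tab)
  cnt <- as.integer(tab)
  len <- nchar(seqs)
  short <- len < min_len
  long <- len > max_len
  low <- !short & !long & cnt < min_count
  dropped["too_short"] <- sum(cnt[short])
  dropped["too_long"] <- sum(cnt[long])
  dropped["low_support"] <- sum(cnt[low])
  keep <- !short & !long & !low
  reads <- data.frame(sequence = dna_to_rna(seqs[keep]),
                      count = cnt[keep], stringsAsFactors = FALSE)
  reads <- reads[order(-reads$count, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads, dropped = dropped)
}

#' Preprocess raw small-RNA reads end to end
#'
#' Rejects reads with non-ACGT characters, trims the 3' adapter, removes
#' low-complexity inserts (DUST), collapses identical inserts and applies
#' the 18-28 nt / >= 2 reads filters. Every raw read is accounted for in
#' the returned statistics.
#'
#' @param raw_reads character vector of fixed-length reads (DNA).
#' @param adapter 3' adapter sequence.
#' @param max_mismatch,min_overlap see [trim_adapter()].
#' @param dust_threshold,dust_window see [dust_filter()].
#' @param min_len,max_len,min_count see [collapse_and_filter()].
#' @return list with `reads` (collapsed unique reads, RNA) and `stats`
#'   (named integer vector: raw, non_acgt, no_adapter, low_complexity,
#'   too_short, too_long, low_support, kept).
#' @export
preprocess_reads <- function(raw_reads, adapter, max_mismatch = 3L,
                             min_overlap = 6L, dust_threshold = 2.0,
                             dust_window = 64L, min_len = 18L,
                             max_len = 28L, min_count = 2L) {
  n_raw <- length(raw_reads)
  bad <- grepl("[^ACGTacgt]", raw_reads)
  inserts <- rep(NA_character_, n_raw)
  inserts[!bad] <- trim_adapters(raw_reads[!bad], adapter,
                                 max_mismatch, min_overlap)
  no_adapter <- sum(is.na(inserts) & !bad)
  inserts <- inserts[!is.na(inserts)]
  # complexity filter on unique inserts (score depends only on the sequence);
  # inserts shorter than 3 nt cannot be scored and fail the length filter later
  uq <- unique(inserts[nchar(inserts) >= 3L])
  low_seqs <- uq[!vapply(uq, dust_filter, logical(1),
                         threshold = dust_threshold, window = dust_window)]
  is_low <- inserts %in% low_seqs
  n_low <- sum(is_low)
  cf <- collapse_and_filter(inserts[!is_low], min_len, max_len, min_count)
  stats <- c(raw = n_raw, non_acgt = sum(bad), no_adapter = no_adapter,
             low_complexity = n_low, cf$dropped,
             kept = sum(cf$reads$count))
  stopifnot(sum(stats[-1L]) == n_raw)  # conservation of reads
  list(reads = cf$reads, stats = stats)
}
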