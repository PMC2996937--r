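#' Sequence alphabet utilities
#'
#' The genome and everything read from or written to FASTA/FASTQ is kept in
#' DNA (ACGT); mature miRNA, collapsed reads and seeds are reported in RNA
#' (ACGU), matching the convention of published miRNA tables. These two
#' helpers own the mapping; nothing else in the package converts alphabets.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' Reverse complement of DNA sequences
#'
#' Plain-character implementation used in tight loops; `U` is complemented
#' like `T` so RNA input is tolerated (output is DNA).
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp_dna <- function(x) {
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# integer base codes A=0 C=1 G=2 T/U=3, NA otherwise
.base_codes <- function(seq) {
  b <- utf8ToInt(seq)
  out <- rep(NA_integer_, length(b))
  out[b == 65L | b == 97L] <- 0L
  out[b == 67L | b == 99L] <- 1L
  out[b == 71L | b == 103L] <- 2L
  out[b == 84L | b == 116L | b == 85L | b == 117L] <- 3L
  out
}

.codes_to_dna <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

# integer codes of all k-mer windows of a sequence (NA where any base is
# non-ACGT); returns integer(0) for sequences shorter than k
.window_codes <- function(seq, k) {
  b <- .base_codes(seq)
  n <- length(b)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- integer(m)
  na <- logical(m)
  for (off in 0:(k - 1L)) {
    v <- b[(1L + off):(m + off)]
    na <- na | is.na(v)
    v[is.na(v)] <- 0L
    code <- code + v * 4L^(k - 1L - off)
  }
  storage.mode(code) <- "integer"
  code[na] <- NA_integer_
  code
}

# random DNA string(s) under the current RNG state
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# substring in 0-based half-open coordinates
.sub0 <- function(seq, start, end) substr(seq, start + 1L, end)

# sequence of a stranded genome feature, 5'->3' (DNA alphabet)
.feature_seq <- function(genome_seq, start, end, strand) {
  s <- .sub0(genome_seq, start, end)
  if (strand == "-") revcomp_dna(s) else s
}

.gc_fraction <- function(x) {
  b <- .base_codes(x)
  mean(b == 1L | b == 2L, na.rm = TRUE)
}
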