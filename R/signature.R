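#' Read-signature score of a candidate precursor
#'
#' Scores the biogenesis signature of the reads on a candidate precursor:
#' Drosha/Dicer processing concentrates read 5' ends at the mature 5' end,
#' produces a star product with 2-nt 3'-overhang duplex geometry, and
#' leaves the terminal loop read-poor. The score is
#' `w1 * f5 + w2 * star - w3 * floop + w4 * min(max(z, 0), 5)` where `f5`
#' is the count fraction of reads whose 5' end lies within 2 nt of the
#' mature 5' end, `star` indicates reads at the expected star 5' position
#' on the opposite arm, `floop` is the count fraction of reads overlapping
#' the loop, and `z` the folding shuffle z-score. Significance comes from
#' `n_perm` permutations repositioning every read uniformly within the
#' precursor; the add-one empirical p passes at `p <= p_threshold`.
#'
#' @param candidate one-row candidate data.frame from
#'   [candidate_from_reads()].
#' @param alignments data.frame from [map_reads()].
#' @param n_perm permutations of read positions (default 100).
#' @param weights the four score weights (defaults 2, 1, 2, 0.5).
#' @param z folding shuffle z-score of the precursor (computed at
#'   `n_shuffle_z` shuffles when `NULL`; it is constant across
#'   permutations, so it shifts observed and null scores equally).
#' @param n_shuffle_z shuffles used when `z` is `NULL`.
#' @param p_threshold pass cut-off on the empirical p (default 0.01, the
#'   high-confidence criterion).
#' @param min_loop folding engine minimum loop.
#' @return data.frame `candidate`, `approach`, `score`, `p`, `pass`.
#' @export
read_signature_score <- function(candidate, alignments, n_perm = 100L,
                                 weights = c(2, 1, 2, 0.5), z = NULL,
                                 n_shuffle_z = 1000L, p_threshold = 0.01,
                                 min_loop = 3L) {
  cd <- as.list(candidate)
  L <- cd$end - cd$start
  inside <- alignments$chrom == cd$chrom &
    alignments$strand == cd$strand &
    alignments$start >= cd$start & alignments$end <= cd$end
  reads <- alignments[inside, , drop = FALSE]
  if (nrow(reads) == 0L) stop("no reads on candidate ", cd$name)
  # genome -> precursor-local 5'->3' coordinates
  to_local <- function(s, e) {
    if (cd$strand == "+") cbind(s - cd$start, e - cd$start)
    else cbind(cd$end - e, cd$end - s)
  }
  rl <- to_local(reads$start, reads$end)
  ml <- to_local(cd$mature_start, cd$mature_end)[1, ]
  ll <- to_local(cd$loop_start, cd$loop_end)[1, ]
  if (is.null(z)) {
    z <- shuffle_significance(cd$sequence, n_shuffle_z, min_loop)$z
  }
  if (is.na(z)) z <- 0
  # pruned pair table: spurious short helices would corrupt the mature's
  # pairing partner and hence the expected star position
  pt <- .prune_short_helices(pair_table(cd$structure))
  # expected star 5' end under 2-nt 3'-overhang duplex geometry
  s0 <- NA_integer_
  for (off in 2:6) {
    q <- pt[ml[2] - off]            # partner of mature base (m1 - 1 - off)
    if (ml[2] - off >= 1L && !is.na(q)) { s0 <- q - (off - 2L); break }
  }
  opp <- if (ml[2] <= ll[1]) c(ll[2], L) else c(0L, ll[1])
  cnt <- reads$count
  tot <- sum(cnt)
  score_of <- function(st, en) {
    f5 <- sum(cnt[abs(st - ml[1]) <= 2L]) / tot
    ov_opp <- pmax(0L, pmin(en, opp[2]) - pmax(st, opp[1]))
    star <- as.numeric(!is.na(s0) &&
                         any(ov_opp / (en - st) >= 0.5 &
                               abs(st - s0) <= 2L))
    floop <- sum(cnt[pmin(en, ll[2]) > pmax(st, ll[1])]) / tot
    weights[1] * f5 + weights[2] * star - weights[3] * floop +
      weights[4] * min(max(z, 0), 5)
  }
  obs <- score_of(rl[, 1], rl[, 2])
  lens <- rl[, 2] - rl[, 1]
  ge <- 0L
  for (i in seq_len(n_perm)) {
    st <- vapply(lens, function(l) sample.int(max(1L, L - l + 1L), 1L) - 1L,
                 integer(1))
    if (score_of(st, st + lens) >= obs) ge <- ge + 1L
  }
  p <- (1 + ge) / (n_perm + 1)
  data.frame(candidate = cd$name, approach = "signature", score = obs,
             p = p, pass = p <= p_threshold, stringsAsFactors = FALSE)
}
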