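# a hand-built candidate with ideal biogenesis geometry; the structure is
# written down directly (a clean 28-pair stem), since this file exercises
# the read-signature score, not the folding engine
mk_candidate <- function() {
  p <- local({ set.seed(51); smallmir:::.build_precursor(28L, 10L, 22L, "5p") })
  db <- paste0(strrep("(", 28), strrep(".", 10), strrep(")", 28))
  data.frame(name = "cand", chrom = "c", start = 0L, end = p$length,
             strand = "+", sequence = p$seq, structure = db,
             mature_start = p$mature_offset[1],
             mature_end = p$mature_offset[2],
             loop_start = p$loop_offset[1], loop_end = p$loop_offset[2],
             stringsAsFactors = FALSE)
}

test_that("an ideal read signature reaches the minimal permutation p", {
  cd <- mk_candidate()
  # five distinct read groups, all in their ideal windows: a permutation
  # can only tie (never beat) this configuration, and a tie requires every
  # group to land back in its window simultaneously (~1e-6 per permutation)
  m0 <- cd$mature_start
  w <- cd$mature_end - m0
  aln <- data.frame(
    sequence = c("M", "Ma", "Mb", "Mc", "S"),
    count = c(60L, 20L, 10L, 5L, 8L), chrom = "c",
    start = c(m0, m0 - 1L, m0 - 2L, m0 + 1L, cd$end - cd$mature_end + 2L),
    strand = "+", n_hits = 1L)
  aln$end <- aln$start + w
  set.seed(54)
  r <- read_signature_score(cd, aln, n_perm = 100, z = 5)
  expect_equal(r$p, 1 / 101)
  expect_true(r$pass)
})

test_that("uniformly scattered reads are rarely significant", {
  cd <- mk_candidate()
  set.seed(53)
  L <- cd$end
  rejections <- 0L
  for (rep in 1:50) {
    st <- sample(0:(L - 20L), 12, replace = TRUE)
    aln <- data.frame(sequence = paste0("r", 1:12), count = 1L,
                      chrom = "c", start = st, end = pmin(st + 20L, L),
                      strand = "+", n_hits = 1L)
    r <- read_signature_score(cd, aln, n_perm = 100, z = 0)
    if (r$p > 0.05) rejections <- rejections + 1L
  }
  # ~90% of null configurations, allowing Monte-Carlo noise at n = 50
  expect_gte(rejections, 44L)
})

test_that("candidates without reads are an error", {
  cd <- mk_candidate()
  empty <- data.frame(sequence = character(0), count = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_hits = integer(0))
  expect_error(read_signature_score(cd, empty), "no reads")
})
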