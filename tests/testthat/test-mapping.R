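test_that("exact mapping places reads on both strands", {
  set.seed(31)
  g <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  idx <- build_index(c(chr1 = g))
  fwd <- substr(g, 101, 122)          # genome[100:122), 0-based
  hit <- map_exact(dna_to_rna(fwd), idx)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 100L)
  expect_equal(hit$end, 122L)
  expect_equal(hit$strand, "+")
  rev <- revcomp_dna(substr(g, 51, 72))  # genome[50:72) on the minus strand
  hit2 <- map_exact(dna_to_rna(rev), idx)
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$start, 50L)
  expect_equal(hit2$end, 72L)
  expect_equal(hit2$strand, "-")
})

test_that("multi-mapping reads carry all placements and n_hits", {
  g <- paste0("TTTT", strrep("ACGTGCAGTCAGGCATCACGTGCA", 2), "TTTT")
  idx <- build_index(c(chr1 = g))
  r <- dna_to_rna("ACGTGCAGTCAGGCATCACGTGCA")
  hits <- map_exact(r, idx)
  expect_equal(nrow(hits), 2L)
  expect_true(all(hits$n_hits == 2L))
})

test_that("mapping agrees with a naive full scan on random reads", {
  set.seed(33)
  g <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  idx <- build_index(c(chr1 = g))
  reads <- c(
    # half planted from the genome (either strand), half random
    vapply(1:50, function(i) {
      s <- sample(20000 - 25, 1)
      seq <- substr(g, s, s + sample(18:28, 1) - 1)
      if (runif(1) < 0.5) seq else revcomp_dna(seq)
    }, character(1)),
    vapply(1:50, function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(18:28, 1),
                   replace = TRUE), collapse = "")
    }, character(1)))
  mapped <- map_reads(data.frame(sequence = dna_to_rna(reads),
                                 count = 1L), idx)
  for (r in unique(reads)) {
    expected <- naive_scan(r, g)
    got <- mapped[rna_to_dna(mapped$sequence) == r, , drop = FALSE]
    got <- got[order(got$start, got$strand), ]
    expect_equal(nrow(got), nrow(expected), info = r)
    if (nrow(expected) > 0) {
      expect_equal(got$start, expected$start, info = r)
      expect_equal(got$strand, expected$strand, info = r)
      expect_true(all(got$n_hits == nrow(expected)))
    }
  }
})
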