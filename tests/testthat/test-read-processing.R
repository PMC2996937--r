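adapter <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter trimming honours the mismatch threshold and leftmost rule", {
  insert <- "ACGTACGTACGTACGTACGTAC"            # 22 nt
  read <- paste0(insert, substr(adapter, 1, 14)) # 36 nt, exact adapter
  expect_equal(trim_adapter(read, adapter), insert)
  # corrupt 3 of the 14 adapter bases: still trimmed; 4: rejected
  corrupt <- function(r, k) {
    pos <- 22 + c(2, 5, 9, 12)[seq_len(k)]
    for (p in pos) {
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, p, p))[1]
    }
    r
  }
  expect_equal(trim_adapter(corrupt(read, 3), adapter), insert)
  # with 4 corruptions the true position no longer qualifies; the result
  # must agree with an explicit scan of every remaining position (a
  # shorter spurious overlap further right may legitimately qualify)
  r4 <- corrupt(read, 4)
  rc <- strsplit(r4, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  best <- NA_integer_
  for (p in 0:(36 - 6)) {
    w <- min(length(ac), 36 - p)
    if (w < 6) break
    if (sum(rc[(p + 1):(p + w)] != ac[1:w]) <= 3) { best <- p; break }
  }
  expect_false(identical(best, 22L))  # the planted position is disqualified
  got4 <- trim_adapter(r4, adapter)
  if (is.na(best)) expect_true(is.na(got4)) else
    expect_equal(got4, substr(r4, 1, best))
  # reads with N are rejected before trimming
  readN <- read
  substr(readN, 5, 5) <- "N"
  expect_true(is.na(trim_adapter(readN, adapter)))
})

test_that("leftmost qualifying adapter position wins (brute-force audit)", {
  set.seed(11)
  ac <- strsplit(adapter, "")[[1]]
  for (rep in 1:40) {
    read <- paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE),
                  collapse = "")
    rc <- strsplit(read, "")[[1]]
    # brute force: every start position, overlap >= 6, mismatches <= 3
    best <- NA_integer_
    for (p in 0:(36 - 6)) {
      w <- min(length(ac), 36 - p)
      if (w < 6) break
      mism <- sum(rc[(p + 1):(p + w)] != ac[1:w])
      if (mism <= 3) { best <- p; break }
    }
    got <- trim_adapter(read, adapter)
    if (is.na(best)) expect_true(is.na(got)) else
      expect_equal(got, substr(read, 1, best))
  }
})

test_that("DUST scores match the triplet formula", {
  # hand evaluation: ACACACACACAC has 10 triplets, 5 ACA + 5 CAC
  expect_equal(dust_score("ACACACACACAC"), (5 * 4 / 2 + 5 * 4 / 2) / 9)
  # homopolymer: 18 identical triplets over 20 nt
  expect_equal(dust_score(strrep("A", 20)), 18 * 17 / 2 / 17)
  expect_false(dust_filter(strrep("A", 20)))
  # all triplets distinct -> score 0, kept
  s <- "ACGTAGCTTGCAATCCGGAT"
  tri <- substring(s, 1:18, 3:20)
  stopifnot(!anyDuplicated(tri))
  expect_equal(dust_score(s), 0)
  expect_true(dust_filter(s))
})

test_that("collapsing applies the length and support filters", {
  a22 <- paste(rep("ACGT", 6), collapse = "")  # 24 nt
  res <- collapse_and_filter(c(a22, a22, "ACGTACGTACGTACGTACGTA"))
  expect_equal(nrow(res$reads), 1L)
  expect_equal(res$reads$count, 2L)
  expect_equal(res$reads$sequence, dna_to_rna(a22))
  expect_equal(unname(res$dropped["low_support"]), 1L)
  # 17-mers are dropped however well supported
  r17 <- collapse_and_filter(rep(substr(strrep("ACGTA", 4), 1, 17), 100))
  expect_equal(nrow(r17$reads), 0L)
  expect_equal(unname(r17$dropped["too_short"]), 100L)
  # 29-mers likewise
  r29 <- collapse_and_filter(rep(substr(strrep("ACGTA", 6), 1, 29), 5))
  expect_equal(unname(r29$dropped["too_long"]), 5L)
})

test_that("collapse matches a brute-force dictionary on a random fixture", {
  set.seed(21)
  pool <- vapply(1:120, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(15:30, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  inserts <- sample(pool, 1000, replace = TRUE)
  res <- collapse_and_filter(inserts)
  dict <- table(inserts)
  keep <- nchar(names(dict)) >= 18 & nchar(names(dict)) <= 28 & dict >= 2
  expected <- sort(dna_to_rna(names(dict)[keep]))
  expect_equal(sort(res$reads$sequence), expected)
  for (s in names(dict)[keep]) {
    expect_equal(res$reads$count[res$reads$sequence == dna_to_rna(s)],
                 unname(as.integer(dict[s])))
  }
})

test_that("every raw read is accounted for across preprocessing", {
  st <- small_study()
  prep <- preprocess_reads(st$reads$reads, st$truth$config$adapter)
  expect_equal(unname(sum(prep$stats[-1])), unname(prep$stats["raw"]))
  expect_true(all(nchar(prep$reads$sequence) >= 18,
                  nchar(prep$reads$sequence) <= 28))
  expect_true(all(prep$reads$count >= 2))
  expect_true(all(grepl("^[ACGU]+$", prep$reads$sequence)))
})
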