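test_that("DP optimum matches exhaustive enumeration on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                 collapse = "")
    expect_identical(fold_local(seq)[[1]]$score,
                     brute_force_fold_score(seq),
                     info = seq)
  }
})

test_that("known small folds are reproduced", {
  fs <- fold_local("GCGAAAGC")[[1]]
  expect_equal(fs$structure, "((....))")
  expect_equal(nrow(fs$pairs), 2L)
  fs_a <- fold_local(strrep("A", 30))[[1]]
  expect_equal(fs_a$structure, strrep(".", 30))
  expect_equal(fs_a$score, 0L)
})

test_that("folding is deterministic", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "U"), 80, replace = TRUE),
               collapse = "")
  expect_identical(fold_local(seq)[[1]]$structure,
                   fold_local(seq)[[1]]$structure)
})

test_that("dot-bracket pair tables are balanced and non-crossing", {
  pt <- pair_table("((..((...))..))")
  expect_equal(pt[1], 14L)  # 0-based partner of position 0
  expect_error(pair_table("(()"), "unbalanced")
  expect_error(pair_table("())"), "unbalanced")
})

test_that("stem-loop extraction finds single and multiple hairpins", {
  one <- extract_hairpins("((((....))))")
  expect_equal(nrow(one), 1L)
  expect_equal(one$pairs, 4L)
  expect_equal(c(one$start, one$end), c(0L, 12L))
  # two hairpins joined in a multiloop: two stem-loops, the branching
  # region in neither
  two <- extract_hairpins("..((((...)))).((((...))))..")
  expect_equal(nrow(two), 2L)
  expect_equal(two$pairs, c(4L, 4L))
  expect_true(all(two$end - two$start == 11L))
})

test_that("bulges are recorded and capped during outward extension", {
  db <- "((((...((((....))))...))))"
  unlimited <- extract_hairpins(db)
  expect_equal(unlimited$pairs, 8L)
  expect_equal(unlimited$max_bulge, 3L)
  capped <- extract_hairpins(db, max_bulge = 2L)
  expect_equal(capped$pairs, 4L)
})

test_that("short helices are pruned before extraction", {
  # lone pair inside the loop would otherwise read as a branch
  db <- "((((((..(...)...))))))"
  hp <- extract_hairpins(db)
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$pairs, 6L)
})

test_that("windows shorter than 20 nt yield no hairpin loci", {
  aln <- data.frame(sequence = "ACGUACGUAC", count = 1L,
                    chrom = "c", start = 2L, end = 12L, strand = "+",
                    n_hits = 1L)
  genome <- c(c = "ACGTACGTACGTACG")  # 15 nt: every window is too short
  expect_equal(nrow(discover_hairpins(aln, genome, flank = 100L)), 0L)
})
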