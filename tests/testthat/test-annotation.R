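mk_ann <- function(...) {
  annotation_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

test_that("majority-overlap assignment treats exactly half as qualifying", {
  ann <- mk_ann(list(chrom = "c", start = 100L, end = 200L, strand = "+",
                     category = "miRNA", name = "m1"))
  # 22-nt read with exactly 11 nt inside -> miRNA
  aln <- data.frame(chrom = "c", start = 89L, end = 111L, strand = "+")
  expect_equal(assign_category(aln, ann), "miRNA")
  # 10 of 22 inside -> intergenic
  aln2 <- data.frame(chrom = "c", start = 88L, end = 110L, strand = "+")
  expect_equal(assign_category(aln2, ann), "intergenic")
})

test_that("priority resolves multi-category overlap (brute-force audit)", {
  ann <- mk_ann(
    list(chrom = "c", start = 100L, end = 200L, strand = "+",
         category = "repeat", name = "r1"),
    list(chrom = "c", start = 100L, end = 200L, strand = "+",
         category = "intron", name = "i1"))
  aln <- data.frame(chrom = "c", start = 150L, end = 172L, strand = "+")
  expect_equal(assign_category(aln, ann), "repeat")
  # order of annotation rows must not matter
  ann_rev <- ann[rev(seq_len(nrow(ann))), ]
  expect_equal(assign_category(aln, ann_rev), "repeat")
})

test_that("strand is enforced for miRNA/ncRNA but not repeats", {
  ann <- mk_ann(
    list(chrom = "c", start = 100L, end = 200L, strand = "+",
         category = "ncRNA", name = "n1"))
  aln <- data.frame(chrom = "c", start = 150L, end = 172L, strand = "-")
  expect_equal(assign_category(aln, ann), "intergenic")
  ann$category <- "repeat"
  expect_equal(assign_category(aln, ann), "repeat")
})

test_that("category summaries are complete and normalized", {
  empty <- summarize_categories(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), count = integer(0)),
    mk_ann(list(chrom = "c", start = 1L, end = 10L, strand = "+",
                category = "exon", name = "e")))
  expect_equal(sum(empty$reads), 0)
  st <- small_study()
  prep <- preprocess_reads(st$reads$reads, st$truth$config$adapter)
  aln <- map_reads(prep$reads, build_index(st$genome))
  tab <- summarize_categories(aln, st$truth$annotations)
  expect_equal(sum(tab$fraction), 1)
  expect_setequal(tab$category, c("miRNA", "ncRNA", "repeat", "exon",
                                  "intron", "intergenic"))
})

test_that("star products are recovered from annotated precursors", {
  st <- small_study()
  prep <- preprocess_reads(st$reads$reads, st$truth$config$adapter)
  aln <- map_reads(prep$reads, build_index(st$genome))
  stars <- call_star_products(aln, st$truth$annotations)
  known <- st$truth$precursors[st$truth$precursors$kind == "annotated", ]
  counts <- st$reads$feature_counts
  expressed <- counts$name[counts$star_reads >= 2 & counts$mature_reads >= 2]
  recovered <- intersect(known$name, expressed)
  expect_true(all(stars$precursor %in% known$name))
  expect_gte(sum(recovered %in% stars$precursor), 1L)
  for (p in intersect(recovered, stars$precursor)) {
    sc <- stars[stars$precursor == p, ]
    planted_ratio <- counts$star_reads[counts$name == p] /
      counts$mature_reads[counts$name == p]
    expect_lt(abs(sc$ratio - planted_ratio), 0.25)
  }
})

test_that("precursors with reads on one arm only yield no star call", {
  ann <- mk_ann(list(chrom = "c", start = 0L, end = 80L, strand = "+",
                     category = "miRNA", name = "p"))
  ann$mature_start <- 5L; ann$mature_end <- 27L
  ann$loop_start <- 35L; ann$loop_end <- 45L
  aln <- data.frame(sequence = "X", count = 50L, chrom = "c",
                    start = 5L, end = 27L, strand = "+", n_hits = 1L)
  expect_equal(nrow(call_star_products(aln, ann)), 0L)
})

test_that("high-expression stars are flagged above the copy threshold", {
  ann <- mk_ann(list(chrom = "c", start = 0L, end = 80L, strand = "+",
                     category = "miRNA", name = "p"))
  ann$mature_start <- 5L; ann$mature_end <- 27L
  ann$loop_start <- 35L; ann$loop_end <- 45L
  aln <- data.frame(sequence = c("M", "S"), count = c(10L, 3001L),
                    chrom = "c", start = c(5L, 50L), end = c(27L, 72L),
                    strand = "+", n_hits = 1L)
  sc <- call_star_products(aln, ann, high_expr_threshold = 3000)
  expect_true(sc$high_expression)
  expect_true(sc$higher_than_mature)
  # exactly at the threshold: not flagged (strictly greater than)
  aln$count[2] <- 3000L
  expect_false(call_star_products(aln, ann, 3000)$high_expression)
})
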