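test_that("configs are validated", {
  expect_error(generator_config(planted_target_enrichment = 1),
               "planted_target_enrichment")
  expect_error(generator_config(planted_avoidance_depletion = 1.2))
  expect_error(generator_config(n_planted_mirna = 2, n_enriched_seeds = 5))
})

test_that("an empty configuration yields an empty truth set", {
  cfg <- generator_config(genome_length = 20000L, n_planted_mirna = 0L,
                          n_annotated_mirna = 0L,
                          n_planted_ncrna_hairpins = 0L,
                          n_decoy_hairpins = 0L, n_enriched_seeds = 0L,
                          read_depth = 0L, n_utrs = 0L, seed = 5L)
  set.seed(5)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$truth$precursors), 0L)
  expect_equal(nchar(g$genome[[1]]), 20000L)
  reads <- generate_reads(g$genome, g$truth, cfg)
  expect_equal(length(reads$reads), 0L)
  utr <- generate_utr_set(g$truth, cfg)
  expect_equal(length(utr$utrs), 0L)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(genome_length = 40000L, n_planted_mirna = 3L,
                          n_annotated_mirna = 2L,
                          n_planted_ncrna_hairpins = 1L,
                          n_decoy_hairpins = 2L, read_depth = 2000L,
                          n_utrs = 10L, utr_length_range = c(300L, 500L),
                          n_enriched_seeds = 2L, n_background_loci = 50L,
                          seed = 99L)
  s1 <- generate_synthetic_study(cfg)
  s2 <- generate_synthetic_study(cfg)
  expect_identical(s1, s2)
})

test_that("planted precursors refold with at least 20 stem pairs", {
  st <- small_study()
  pr <- st$truth$precursors
  for (i in which(pr$kind != "decoy_stem")) {
    s <- smallmir:::.feature_seq(st$genome[[1]], pr$start[i], pr$end[i],
                                 pr$strand[i])
    hp <- extract_hairpins(fold_local(s)[[1]], 20L)
    expect_gte(nrow(hp), 1L)
  }
  # decoys record which candidate filter they violate
  dec <- pr[pr$kind %in% c("decoy_stem", "decoy_exon", "decoy_noreads"), ]
  expect_true(all(!is.na(dec$violated_filter)))
})

test_that("planted matures occur in the genome exactly at their locus", {
  st <- small_study()
  pr <- st$truth$precursors
  g <- Biostrings::DNAString(st$genome[[1]])
  for (i in seq_len(nrow(pr))) {
    mat <- rna_to_dna(pr$mature_seq[i])
    hits <- Biostrings::countPattern(mat, g) +
      Biostrings::countPattern(revcomp_dna(mat), g)
    expect_equal(hits, 1L, info = pr$name[i])
    at <- smallmir:::.feature_seq(st$genome[[1]], pr$mature_start[i],
                                  pr$mature_end[i], pr$strand[i])
    expect_equal(at, mat, info = pr$name[i])
  }
  # seeds are unique across planted matures
  expect_false(anyDuplicated(substr(pr$mature_seq, 2, 8)) > 0)
})

test_that("the conservation track separates planted and background", {
  st <- small_study()
  cfg <- st$truth$config
  tr <- st$track[[1]]
  expect_true(all(tr >= 0 & tr <= 1, na.rm = TRUE))
  expect_lt(abs(mean(is.na(tr)) - cfg$track_missing_fraction), 0.02)
  pr <- st$truth$precursors
  for (i in which(pr$conserved)) {
    m <- mean(tr[(pr$mature_start[i] + 1):pr$mature_end[i]], na.rm = TRUE)
    expect_gte(m, 0.8)
  }
  # background mean within 3 standard errors of its target
  bg <- tr
  for (i in which(pr$conserved)) {
    bg[(pr$mature_start[i] + 1):pr$mature_end[i]] <- NA
  }
  se <- sd(bg, na.rm = TRUE) / sqrt(sum(!is.na(bg)))
  expect_lt(abs(mean(bg, na.rm = TRUE) - cfg$track_background_mean),
            3 * se + 0.01)
  # a fully missing track is representable
  set.seed(6)
  t2 <- generate_conservation_track(st$genome, st$truth, cfg,
                                    missing_fraction = 1)
  expect_true(all(is.na(t2[[1]][1:100])))
})

test_that("reads reproduce planted sequences exactly when jitter is off", {
  cfg <- generator_config(genome_length = 40000L, n_planted_mirna = 3L,
                          n_annotated_mirna = 2L,
                          n_planted_ncrna_hairpins = 1L,
                          n_decoy_hairpins = 0L, read_depth = 3000L,
                          n_utrs = 0L, n_enriched_seeds = 0L,
                          jitter_5p = 0, jitter_3p = 0,
                          background_read_fraction = 0, seed = 77L)
  set.seed(77)
  g <- generate_genome(cfg)
  reads <- generate_reads(g$genome, g$truth, cfg)
  inserts <- unique(trim_adapters(reads$reads, cfg$adapter))
  planted <- rna_to_dna(c(g$truth$precursors$mature_seq,
                          g$truth$precursors$star_seq))
  expect_true(all(inserts %in% planted))
})

test_that("planted expression spans orders of magnitude", {
  st <- small_study()
  fc <- st$reads$feature_counts
  expressed <- fc$mature_reads + fc$star_reads
  expect_gte(max(expressed) / max(1, min(expressed)), 100)
  expect_true(all(fc$mature_reads + fc$star_reads >=
                    st$truth$config$min_planted_reads))
})

test_that("planted UTR sites show the configured conservation contrast", {
  set.seed(91)
  seeds <- data.frame(
    seed = c("ACGUGAU", "UGGACUA", "CAUGGCA"),
    target_motif = revcomp_dna(rna_to_dna(c("ACGUGAU", "UGGACUA",
                                            "CAUGGCA"))),
    class = c("enriched", "enriched", "avoided"),
    source = "synthetic", stringsAsFactors = FALSE)
  cfg <- generator_config(n_utrs = 250L,
                          utr_length_range = c(800L, 1200L),
                          n_planted_mirna = 3L, n_enriched_seeds = 2L)
  utr <- generate_utr_set(list(seeds = seeds), cfg)
  tab <- scan_utrs(utr$utrs, utr$track)
  background_rate <- sum(tab$table$c) / sum(tab$table$t)
  rate_of <- function(m) {
    i <- match(m, tab$table$motif)
    tab$table$c[i] / tab$table$t[i]
  }
  for (k in 1:2) expect_gt(rate_of(seeds$target_motif[k]), background_rate)
  expect_lt(rate_of(seeds$target_motif[3]), background_rate)
})
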