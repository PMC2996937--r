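
mk_table <- function(motif, t, c) {
  M <- length(motif)
  tab <- data.frame(motif = motif, t = t, c = c,
                    stringsAsFactors = FALSE)
  ot <- order(-tab$t, tab$motif); tab$R_t[ot] <- seq_len(M)
  oc <- order(-tab$c, tab$motif); tab$R_c[oc] <- seq_len(M)
  structure(list(table = tab, M = M, total_windows = sum(t), k = 7L),
            class = "motif_table")
}

test_that("the scan counts windows exactly as the stated rule", {
  # 30-nt UTR: window starts 15..23 (0-based), 9 windows
  set.seed(81)
  utr <- c(u1 = paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                      collapse = ""))
  tr <- list(u1 = rep(NA_real_, 30))
  tab <- scan_utrs(utr, tr)
  expect_equal(tab$total_windows, 9L)
  expect_equal(sum(tab$table$t), 9L)
  expect_equal(sum(tab$table$c), 0L)
  # a window with only 2 scored positions counts toward t only
  tr2 <- list(u1 = c(rep(NA_real_, 15), 1.0, 1.0, rep(NA_real_, 13)))
  tab2 <- scan_utrs(utr, tr2)
  expect_equal(sum(tab2$table$c), 0L)
  # with >= 3 scored high positions the first window becomes conserved
  tr3 <- list(u1 = c(rep(NA_real_, 15), 1, 1, 1, rep(NA_real_, 12)))
  tab3 <- scan_utrs(utr, tr3)
  expect_equal(sum(tab3$table$c), 1L)
})

test_that("the (t, c) table equals a naive recount on a random fixture", {
  set.seed(82)
  utrs <- setNames(vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(40:120, 1),
                 replace = TRUE), collapse = "")
  }, character(1)), paste0("u", 1:10))
  track <- lapply(utrs, function(s) {
    v <- rbeta(nchar(s), 1, 1.2)
    v[sample(nchar(s), nchar(s) %/% 5)] <- NA
    v
  })
  got <- scan_utrs(utrs, track)
  ref <- naive_scan_utrs(utrs, track)
  expect_equal(got$total_windows, ref$total)
  for (m in got$table$motif) {
    expect_equal(got$table$t[got$table$motif == m],
                 ref$t[[m]], info = m)
    cc <- got$table$c[got$table$motif == m]
    expect_equal(cc, if (is.null(ref$c[[m]])) 0L else ref$c[[m]], info = m)
  }
  expect_equal(length(setdiff(ls(ref$t), got$table$motif)), 0L)
})

test_that("rank scores follow the stated rank-difference definition", {
  tab <- mk_table(c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT"),
                  t = c(40L, 30L, 20L, 10L), c = c(0L, 10L, 20L, 5L))
  rs <- rank_score(tab)
  # motif ranked 1st by t and 4th by c -> (1-4)/4
  expect_equal(rs$rank_score[rs$motif == "AAAAAAA"], (1 - 4) / 4)
  expect_equal(rs$rank_score[rs$motif == "GGGGGGG"], (3 - 1) / 4)
  # c proportional to t: identical orderings, all scores zero
  tab0 <- mk_table(c("AAAAAAA", "CCCCCCC", "GGGGGGG"),
                   t = c(30L, 20L, 10L), c = c(30L, 20L, 10L))
  expect_true(all(rank_score(tab0)$rank_score == 0))
  # agreement with an independent re-rank on a random table
  set.seed(83)
  motifs <- unique(vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = "")
  }, character(1)))
  t <- sample(1:500, length(motifs)); c <- pmin(t, rpois(length(motifs), 5))
  tabr <- mk_table(motifs, t, c)
  rs2 <- rank_score(tabr)
  ord_t <- motifs[order(-t, motifs)]
  ord_c <- motifs[order(-c, motifs)]
  for (m in motifs) {
    expect_equal(rs2$rank_score[rs2$motif == m],
                 (match(m, ord_t) - match(m, ord_c)) / length(motifs))
  }
})

test_that("scrambled-seed controls obey composition and frequency rules", {
  set.seed(84)
  st <- small_study()
  tab <- scan_utrs(st$utrs$utrs, st$utrs$track)
  # degenerate composition: the only permutation is the motif itself
  expect_true(scramble_controls("AAAAAAA", tab)$untestable)
  target <- tab$table$motif[which.max(tab$table$t)]
  ctrl <- scramble_controls(target, tab, n = 100, tol = 0.5)
  if (!ctrl$untestable) {
    srt <- function(x) paste(sort(strsplit(x, "")[[1]]), collapse = "")
    expect_true(all(vapply(ctrl$controls$motif, srt, "") == srt(target)))
    expect_false(target %in% ctrl$controls$motif)
    t0 <- tab$table$t[tab$table$motif == target]
    expect_true(all(abs(ctrl$controls$t - t0) <= 0.5 * t0))
    expect_equal(ctrl$p0,
                 sum(ctrl$controls$c) / sum(ctrl$controls$t))
  }
})

test_that("binomial target tests reproduce closed forms", {
  tab <- mk_table(c("GAATGAT", "AGATGAT", "TAATGAG", "ATATGAG"),
                  t = c(10L, 10L, 10L, 10L), c = c(10L, 5L, 5L, 5L))
  ctrl <- list(controls = data.frame(motif = "x", t = 10L, c = 5L),
               p0 = 0.5, n_accepted = 1L, untestable = FALSE)
  # seed AUCAUUC targets GAATGAT; c = t = 10, p0 = 0.5
  r <- binomial_target_test("AUCAUUC", tab, controls = ctrl)
  expect_equal(r$p_excess, 0.5^10)
  expect_equal(r$p_deficit, 1)
  expect_equal(r$verdict, "excess")
  # c = 0: deficit tail is (1-p0)^t, excess tail is 1
  tab2 <- mk_table(c("GAATGAT", "AGATGAT"), t = c(10L, 10L),
                   c = c(0L, 5L))
  r2 <- binomial_target_test("AUCAUUC", tab2, controls = ctrl)
  expect_equal(r2$p_deficit, 0.5^10)
  expect_equal(r2$p_excess, 1)
})

test_that("seed families follow the position 2-8 rule", {
  fam <- build_families(c("AAUCAUUCACGGACAACACUUU",
                          "GAUCAUUCAAAAAAAAAAAAAA",
                          "UGGAAUGUAAAGAAGUAUGUAU"))
  expect_equal(nrow(fam), 2L)
  f1 <- fam[fam$seed == "AUCAUUC", ]
  expect_equal(f1$n_members, 2L)
  expect_equal(f1$target_motif, "GAATGAT")
  expect_warning(build_families(c("ACGUACGUACGUACGAUGUAC", "AUCG")),
                 "shorter than 8")
})

test_that("family proportions recover planted excess on synthetic UTRs", {
  set.seed(85)
  seeds <- data.frame(
    seed = c("ACGUGAU", "UGGACUA", "CCAGUAC"),
    target_motif = revcomp_dna(rna_to_dna(c("ACGUGAU", "UGGACUA",
                                            "CCAGUAC"))),
    class = "enriched", source = "synthetic", stringsAsFactors = FALSE)
  cfg <- generator_config(n_utrs = 300L,
                          utr_length_range = c(800L, 1200L),
                          n_planted_mirna = 3L, n_enriched_seeds = 3L)
  utr <- generate_utr_set(list(seeds = seeds), cfg)
  tab <- scan_utrs(utr$utrs, utr$track)
  res <- family_proportion_test(seeds$seed, tab, n_sim = 100)
  expect_true(all(res$results$verdict %in%
                    c("excess", "deficit", "neither", "untestable")))
  expect_gte(res$n_testable, 2L)
  expect_gte(res$observed_excess, 2 / 3)
  expect_lt(res$p_excess, 0.05)
  expect_equal(length(res$ci_excess), 2L)
})
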