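# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: structures are enumerated recursively, mapping
# is a naive full scan, and counts are recomputed with plain dictionaries.

# all non-crossing pair sets over 1..n with a minimum hairpin loop,
# as lists of 2-column matrices (1-based positions)
enumerate_structures <- function(n, min_loop = 3L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (j - i < min_loop + 1L) {
      return(list(matrix(integer(0), ncol = 2)))
    }
    out <- rec(i, j - 1L)  # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      left <- if (k > i) rec(i, k - 1L) else
        list(matrix(integer(0), ncol = 2))
      right <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else
        list(matrix(integer(0), ncol = 2))
      for (l in left) for (r in right) {
        out[[length(out) + 1L]] <- rbind(l, r, c(k, j))
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

pair_weight_of <- function(a, b) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, "CG" = 3L, "AT" = 2L, "AU" = 2L, "GT" = 1L, "GU" = 1L, 0L)
}

# best achievable pairing score by exhaustive enumeration
brute_force_fold_score <- function(seq, min_loop = 3L) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  best <- 0L
  for (st in enumerate_structures(length(ch), min_loop)) {
    sc <- 0L
    if (nrow(st) > 0L) {
      for (r in seq_len(nrow(st))) {
        sc <- sc + pair_weight_of(ch[st[r, 1]], ch[st[r, 2]])
      }
    }
    if (sc > best) best <- sc
  }
  best
}

# naive exact-match scan of a read against a genome string, both strands;
# returns data.frame(start, end, strand), 0-based half-open
naive_scan <- function(read_dna, genome_seq) {
  hits <- list()
  for (str in c("+", "-")) {
    pat <- if (str == "+") read_dna else revcomp_dna(read_dna)
    p <- gregexpr(pat, genome_seq, fixed = TRUE)[[1]]
    if (p[1] != -1L) {
      # gregexpr misses overlapping occurrences; rescan manually
      starts <- integer(0)
      from <- 1L
      while (TRUE) {
        q <- regexpr(pat, substr(genome_seq, from, nchar(genome_seq)),
                     fixed = TRUE)
        if (q == -1L) break
        starts <- c(starts, from + q - 2L)  # 0-based
        from <- from + q
      }
      hits[[length(hits) + 1L]] <- data.frame(
        start = starts, end = starts + nchar(pat), strand = str)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# dinucleotide count vector of a sequence, named by the 2-mer
dinuc_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) < 2L) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

# a small, fully planted study shared by several test files (cached)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(
        genome_length = 60000L, n_planted_mirna = 6L,
        n_annotated_mirna = 3L, n_planted_ncrna_hairpins = 2L,
        n_decoy_hairpins = 3L, read_depth = 5000L, n_utrs = 40L,
        utr_length_range = c(400L, 900L), n_enriched_seeds = 3L,
        n_background_loci = 100L, seed = 424L)
      cache <<- generate_synthetic_study(cfg)
    }
    cache
  }
})

# naive per-window recount of the (t, c) table
naive_scan_utrs <- function(utrs, track, skip = 15, k = 7,
                            min_scored = 3, thr = 0.8) {
  t_tab <- new.env(parent = emptyenv())
  c_tab <- new.env(parent = emptyenv())
  total <- 0L
  for (u in names(utrs)) {
    seq <- utrs[[u]]; sc <- track[[u]]
    if (nchar(seq) < skip + k) next
    for (s in (skip + 1):(nchar(seq) - k + 1)) {
      w <- substr(seq, s, s + k - 1)
      if (grepl("[^ACGT]", w)) next
      total <- total + 1L
      t_tab[[w]] <- (if (is.null(t_tab[[w]])) 0L else t_tab[[w]]) + 1L
      v <- sc[s:(s + k - 1)]
      if (sum(!is.na(v)) >= min_scored &&
          mean(v, na.rm = TRUE) >= thr) {
        c_tab[[w]] <- (if (is.null(c_tab[[w]])) 0L else c_tab[[w]]) + 1L
      }
    }
  }
  list(t = t_tab, c = c_tab, total = total)
}
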