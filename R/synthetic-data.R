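#' Configuration for the synthetic study generator
#'
#' Defines the conditions of a fully self-contained synthetic study:
#' a genome with planted miRNA precursor hairpins (annotated, novel,
#' ncRNA-hosted, and decoy loci), annotation blocks for every category,
#' a per-base conservation track, adapter-bearing 36-nt reads whose
#' expression spans several orders of magnitude, and a 3'UTR set with
#' planted conserved and avoided seed-match sites. All downstream stages
#' have recoverable planted truth.
#'
#' @param genome_length genome size in nt.
#' @param n_planted_mirna number of novel (unannotated) planted precursors.
#' @param n_annotated_mirna number of annotated miRNA precursors (these
#'   carry an annotated mature and emit star-arm reads, so star calling has
#'   known truth).
#' @param n_planted_ncrna_hairpins precursors hosted inside annotated ncRNA
#'   intervals; their seeds are the planted "avoided" seeds.
#' @param n_decoy_hairpins hairpin-like loci each violating one candidate
#'   filter (short stem / exonic origin / no read support, cycled); the
#'   violated filter is recorded in the truth table.
#' @param read_depth total raw reads.
#' @param adapter 3' adapter appended to every insert (DNA).
#' @param expression_log_range orders of magnitude spanned by planted
#'   expression (log-uniform law).
#' @param n_utrs,utr_length_range 3'UTR count and length bounds (nt).
#' @param planted_target_enrichment multiplier (> 1) on the background
#'   window-conservation rate for target sites of enriched seeds.
#' @param planted_avoidance_depletion multiplier in (0,1) for avoided seeds.
#' @param n_enriched_seeds how many novel-mature seeds are planted as
#'   conserved-target (enriched) seeds.
#' @param jitter_5p,jitter_3p per-read probability of a 1-nt shift of the
#'   mature 5'/3' end (end heterogeneity).
#' @param background_read_fraction fraction of reads drawn from background
#'   degradation loci rather than planted features.
#' @param n_background_loci size of the background degradation locus pool.
#' @param star_fraction per-feature fraction of reads from the star arm.
#' @param min_planted_reads minimum mature read count per expressed planted
#'   feature (deep-coverage regime: every true feature present in the
#'   library is represented by at least two reads).
#' @param track_background_mean,track_conserved_mean means of the per-base
#'   conservation score distributions outside/inside planted conserved
#'   matures.
#' @param track_missing_fraction fraction of genome positions without a
#'   conservation score.
#' @param utr_background_conserved_rate background probability that a UTR
#'   7-mer window is conserved.
#' @param chrom chromosome name.
#' @param seed RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(genome_length = 500000L,
                             n_planted_mirna = 30L,
                             n_annotated_mirna = 10L,
                             n_planted_ncrna_hairpins = 5L,
                             n_decoy_hairpins = 10L,
                             read_depth = 50000L,
                             adapter = "TCGTATGCCGTCTTCTGCTTG",
                             expression_log_range = 6,
                             n_utrs = 1600L,
                             utr_length_range = c(1000L, 3000L),
                             planted_target_enrichment = 3,
                             planted_avoidance_depletion = 0.3,
                             n_enriched_seeds = 10L,
                             jitter_5p = 0.05,
                             jitter_3p = 0.2,
                             background_read_fraction = 0.2,
                             n_background_loci = 800L,
                             star_fraction = 0.12,
                             min_planted_reads = 8L,
                             track_background_mean = 0.3,
                             track_conserved_mean = 0.9,
                             track_missing_fraction = 0.1,
                             utr_background_conserved_rate = 0.15,
                             chrom = "chr1",
                             seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(genome_length, n_planted_mirna, n_annotated_mirna,
              n_planted_ncrna_hairpins, n_decoy_hairpins, read_depth,
              n_utrs, n_enriched_seeds)
  stopifnot(all(counts >= 0), expression_log_range >= 0,
            planted_target_enrichment > 1,
            planted_avoidance_depletion > 0,
            planted_avoidance_depletion < 1,
            n_enriched_seeds <= n_planted_mirna,
            nchar(adapter) >= 1L,
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 30L)
  class(cfg) <- "generator_config"
  cfg
}

# ---- placement ------------------------------------------------------------

# place n non-overlapping intervals of the given lengths, optionally inside
# one of the `within` intervals (matrix cols start,end); `occupied` is a
# 2-col matrix updated by reference semantics via return value
.place_intervals <- function(lens, genome_length, occupied,
                             within = NULL, max_tries = 100L,
                             what = "feature") {
  out <- matrix(NA_integer_, nrow = length(lens), ncol = 2)
  for (i in seq_along(lens)) {
    len <- lens[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (is.null(within)) {
        if (genome_length <= len) break
        s <- sample.int(genome_length - len, 1L) - 1L
      } else {
        ok <- within[, 2] - within[, 1] >= len
        if (!any(ok)) break
        host <- sample(rep(which(ok), 2L), 1L)  # rep() guards length-1 sample
        s <- within[host, 1] +
          sample.int(within[host, 2] - within[host, 1] - len + 1L, 1L) - 1L
      }
      e <- s + len
      if (nrow(occupied) == 0L ||
          !any(s < occupied[, 2] & e > occupied[, 1])) {
        out[i, ] <- c(s, e)
        occupied <- rbind(occupied, c(s, e))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", what, " ", i, " of ", length(lens),
           " after ", max_tries, " tries: config overfull for genome_length ",
           genome_length)
    }
  }
  list(intervals = out, occupied = occupied)
}

# ---- precursor construction ----------------------------------------------

# near-perfect-stem precursor: arm1 + loop + revcomp(arm1) with `n_mut`
# G-U wobbles planted inside the mature's pairing partner region. Real
# mature/star duplexes are imperfect, and a perfect palindrome would carry
# the mature's exact reverse complement on the opposite arm (breaking
# uniqueness of the planted mature in the genome); wobble conversion
# breaks sequence identity while keeping the helix fully paired, so the
# folding engine still recovers one clean stem. The loop uses only A/C
# (which cannot pair with each other) so it cannot fold in on itself.
# Mature inside one arm, star opposite with 2-nt 3' overhang geometry.
.build_precursor <- function(arm_len, loop_len, mature_len, arm,
                             n_mut = 3L) {
  arm1 <- .random_dna(1, arm_len)
  # loop over {A,C} only: no two of A/C can base-pair, so the terminal
  # loop cannot fold in on itself and split the stem-loop
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                collapse = "")
  seq <- paste0(arm1, loop, revcomp_dna(arm1))
  L <- 2L * arm_len + loop_len
  if (arm == "5p") {
    m0 <- sample(rep(2:(arm_len - mature_len), 2L), 1L)
  } else {
    m0 <- sample(rep((arm_len + loop_len):(L - mature_len - 2L), 2L), 1L)
  }
  m1 <- m0 + mature_len
  if (n_mut > 0L) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    mpos <- m0:(m1 - 1L)
    # wobble-convertible: mature G (partner C -> T) or T (partner A -> G)
    cand <- mpos[ch[mpos + 1L] %in% c("G", "T")]
    cand <- cand[L - 1L - cand >= 0L & L - 1L - cand < L]
    if (length(cand) > 1L) {
      sel <- sample(cand, min(n_mut, length(cand)))
    } else sel <- cand
    for (p in sel) {
      q <- L - 1L - p
      ch[q + 1L] <- if (ch[p + 1L] == "G") "T" else "G"
    }
    seq <- paste(ch, collapse = "")
  }
  s0 <- L - m1 + 2L
  s1 <- L - m0 + 2L
  list(seq = seq, length = L, arm = arm,
       mature_offset = c(m0, m1), star_offset = c(s0, s1),
       loop_offset = c(arm_len, arm_len + loop_len),
       mature_seq = .sub0(seq, m0, m1), star_seq = .sub0(seq, s0, s1),
       stem_pairs = arm_len)
}

# ---- genome ---------------------------------------------------------------

#' Generate the synthetic genome and its planted truth
#'
#' Builds a random background genome, places annotation blocks (ncRNA,
#' exon, intron, repeat; the complement is intergenic), and embeds planted
#' precursor hairpins: annotated miRNA (with annotated mature and loop),
#' novel intergenic precursors, ncRNA-hosted precursors, and decoys that
#' each violate a stated candidate filter. Precursor arms are exact reverse
#' complements separated by a loop, so the folding engine recovers an
#' unbranched stem-loop with at least 20 pairs for every non-decoy
#' precursor. Planted mature sequences and their seeds (positions 2-8) are
#' verified unique (re-drawn on collision, bounded retries).
#'
#' @param config a [generator_config()]. The caller is responsible for
#'   seeding (or use [generate_synthetic_study()] which seeds once).
#' @return list with `genome` (named character vector) and `truth` (list of
#'   `precursors`, `annotations`, `intergenic`, `seeds`, `config`).
#' @export
generate_genome <- function(config) {
  L <- config$genome_length
  chrom <- config$chrom
  genome <- .random_dna(1, L)
  occupied <- matrix(integer(0), ncol = 2)

  n_ncrna_blocks <- max(config$n_planted_ncrna_hairpins,
                        min(12L, L %/% 40000L))
  n_exon_blocks <- max(if (config$n_decoy_hairpins > 0L) 2L else 0L,
                       min(30L, L %/% 16000L))
  n_intron_blocks <- min(30L, max(1L, L %/% 16000L))
  n_repeat_blocks <- min(25L, max(1L, L %/% 25000L))

  blocks <- list()
  block_cats <- c(rep("ncRNA", n_ncrna_blocks), rep("exon", n_exon_blocks),
                  rep("intron", n_intron_blocks),
                  rep("repeat", n_repeat_blocks))
  block_lens <- c(sample(150:400, n_ncrna_blocks, replace = TRUE),
                  sample(800:2500, n_exon_blocks, replace = TRUE),
                  sample(800:3000, n_intron_blocks, replace = TRUE),
                  sample(200:800, n_repeat_blocks, replace = TRUE))
  pl <- .place_intervals(block_lens, L, occupied, what = "annotation block")
  block_occ <- pl$occupied
  feat_occ <- matrix(integer(0), ncol = 2)
  blocks <- data.frame(chrom = chrom, start = pl$intervals[, 1],
                       end = pl$intervals[, 2],
                       strand = sample(c("+", "-"), length(block_lens),
                                       replace = TRUE),
                       category = block_cats,
                       name = paste0(block_cats, "_",
                                     seq_along(block_cats)),
                       stringsAsFactors = FALSE)

  # planted precursors: annotated, novel, ncRNA-hosted, decoys
  kinds <- c(rep("annotated", config$n_annotated_mirna),
             rep("novel", config$n_planted_mirna),
             rep("ncrna", config$n_planted_ncrna_hairpins),
             rep(c("decoy_stem", "decoy_exon", "decoy_noreads"),
                 length.out = config$n_decoy_hairpins))
  prec <- list()
  seen_matures <- character(0)
  seen_seeds <- character(0)
  gseq <- genome
  for (k in seq_along(kinds)) {
    kind <- kinds[k]
    for (try in seq_len(100L)) {
      if (kind == "decoy_stem") {
        p <- .build_precursor(arm_len = 13L, loop_len = 10L,
                              mature_len = 10L, arm = "5p")
        # short stem: 13 bp < 20, and the 22-nt read spans into the loop
        p$mature_offset <- c(0L, 22L)
        p$mature_seq <- .sub0(p$seq, 0L, 22L)
      } else {
        p <- .build_precursor(arm_len = sample(25:30, 1L),
                              loop_len = sample(8:15, 1L),
                              mature_len = sample(20:23, 1L),
                              arm = sample(c("5p", "3p"), 1L))
      }
      mat_dna <- p$mature_seq
      seed7 <- substr(mat_dna, 2L, 8L)
      if (mat_dna %in% seen_matures || seed7 %in% seen_seeds) next
      # non-decoy precursors must refold into an unbranched stem-loop of
      # at least 20 pairs under the package's own engine
      if (kind != "decoy_stem" &&
          nrow(extract_hairpins(fold_local(p$seq)[[1]], 20L)) == 0L) next
      # place it
      within <- switch(kind,
        ncrna = as.matrix(blocks[blocks$category == "ncRNA",
                                 c("start", "end")]),
        decoy_exon = as.matrix(blocks[blocks$category == "exon",
                                      c("start", "end")]),
        NULL)
      # features placed inside host blocks only avoid other features;
      # free-space features avoid blocks and features alike
      avoid <- if (is.null(within)) rbind(block_occ, feat_occ) else feat_occ
      res <- tryCatch(
        .place_intervals(p$length, L, avoid, within = within,
                         max_tries = 100L, what = paste0(kind, " precursor")),
        error = function(e) NULL)
      if (is.null(res)) next
      iv <- res$intervals[1, ]
      strand <- if (kind == "ncrna") {
        host <- blocks$category == "ncRNA" & blocks$start <= iv[1] &
          blocks$end >= iv[2]
        blocks$strand[which(host)[1]]
      } else sample(c("+", "-"), 1L)
      ins <- if (strand == "-") revcomp_dna(p$seq) else p$seq
      cand_genome <- paste0(.sub0(gseq, 0L, iv[1]), ins,
                            .sub0(gseq, iv[2], L))
      # uniqueness of the planted mature in the whole genome (both strands)
      hits <- Biostrings::countPattern(mat_dna,
                                       Biostrings::DNAString(cand_genome)) +
        Biostrings::countPattern(revcomp_dna(mat_dna),
                                 Biostrings::DNAString(cand_genome))
      if (hits != 1L) next
      # recoverability in genomic context: a 110-nt window centred on the
      # planted locus (real flanks included) must still yield an
      # unbranched stem-loop of >= 20 pairs covering the mature
      if (kind != "decoy_stem") {
        centre <- (iv[1] + iv[2]) %/% 2L
        ws <- max(0L, min(centre - 55L, L - 110L))
        we <- min(L, ws + 110L)
        wseq <- .feature_seq(cand_genome, ws, we, strand)
        hp <- extract_hairpins(fold_local(wseq)[[1]], 20L, max_bulge = 8L)
        if (nrow(hp) == 0L) next
        # mature interval in window-local 5'->3' coordinates
        mg <- if (strand == "+") iv[1] + p$mature_offset else
          c(iv[1] + p$length - p$mature_offset[2],
            iv[1] + p$length - p$mature_offset[1])
        mloc <- if (strand == "+") mg - ws else c(we - mg[2], we - mg[1])
        cover <- hp[hp$start <= mloc[1] & hp$end >= mloc[2], , drop = FALSE]
        if (nrow(cover) == 0L) next
        # the mature must also satisfy the candidate filters against the
        # extracted stem-loop: >= 16 nt inside one arm, not spanning the
        # detected terminal loop (junk helices can displace the loop)
        ok_mature <- FALSE
        for (hrow in seq_len(nrow(cover))) {
          hh <- cover[hrow, ]
          in5 <- max(0L, min(mloc[2], hh$loop_start) - max(mloc[1], hh$start))
          in3 <- max(0L, min(mloc[2], hh$end) - max(mloc[1], hh$loop_end))
          if (!(in5 > 0L && in3 > 0L) && max(in5, in3) >= 16L) {
            ok_mature <- TRUE
            break
          }
        }
        if (!ok_mature) next
      }
      feat_occ <- rbind(feat_occ, matrix(iv, ncol = 2))
      gseq <- cand_genome
      seen_matures <- c(seen_matures, mat_dna)
      seen_seeds <- c(seen_seeds, seed7)
      # precursor-local offsets -> genome coordinates
      loc2gen <- function(off) {
        if (strand == "+") iv[1] + off else c(iv[1] + p$length - off[2],
                                              iv[1] + p$length - off[1])
      }
      gm <- loc2gen(p$mature_offset)
      gs <- loc2gen(p$star_offset)
      gl <- loc2gen(p$loop_offset)
      prec[[length(prec) + 1L]] <- data.frame(
        name = paste0(kind, "_", k), kind = kind, chrom = chrom,
        start = iv[1], end = iv[2], strand = strand,
        arm = p$arm, stem_pairs = p$stem_pairs,
        mature_start = gm[1], mature_end = gm[2],
        mature_seq = dna_to_rna(mat_dna),
        star_start = gs[1], star_end = gs[2],
        star_seq = dna_to_rna(p$star_seq),
        loop_start = gl[1], loop_end = gl[2],
        conserved = kind %in% c("annotated", "novel", "ncrna"),
        violated_filter = switch(kind,
                                 decoy_stem = "stem_pairs",
                                 decoy_exon = "exonic_origin",
                                 decoy_noreads = "no_read_support",
                                 NA_character_),
        stringsAsFactors = FALSE)
      break
    }
    if (length(prec) < k) {
      stop("could not plant ", kind, " precursor after 100 redraws; ",
           "config overfull for genome_length ", L)
    }
  }
  precursors <- if (length(prec) > 0L) do.call(rbind, prec) else
    data.frame(name = character(0), kind = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), arm = character(0),
               stem_pairs = integer(0), mature_start = integer(0),
               mature_end = integer(0), mature_seq = character(0),
               star_start = integer(0), star_end = integer(0),
               star_seq = character(0), loop_start = integer(0),
               loop_end = integer(0), conserved = logical(0),
               violated_filter = character(0))
  rownames(precursors) <- NULL

  # annotation set: blocks + annotated precursor intervals (category miRNA)
  ann <- blocks
  ann$mature_start <- NA_integer_; ann$mature_end <- NA_integer_
  ann$loop_start <- NA_integer_; ann$loop_end <- NA_integer_
  known <- precursors[precursors$kind == "annotated", , drop = FALSE]
  if (nrow(known) > 0L) {
    ann <- rbind(ann, data.frame(
      chrom = known$chrom, start = known$start, end = known$end,
      strand = known$strand, category = "miRNA", name = known$name,
      mature_start = known$mature_start, mature_end = known$mature_end,
      loop_start = known$loop_start, loop_end = known$loop_end,
      stringsAsFactors = FALSE))
  }
  ann <- annotation_set(ann[order(ann$start), , drop = FALSE])
  rownames(ann) <- NULL

  # seed classes: enriched from the first novel matures, avoided from
  # ncRNA-hosted matures, the rest background
  novel <- precursors[precursors$kind == "novel", , drop = FALSE]
  ncr <- precursors[precursors$kind == "ncrna", , drop = FALSE]
  seeds <- data.frame(seed = character(0), target_motif = character(0),
                      class = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  mk_seed <- function(rows, class) {
    if (nrow(rows) == 0L) return(NULL)
    s <- substr(rows$mature_seq, 2L, 8L)
    data.frame(seed = s, target_motif = revcomp_dna(s), class = class,
               source = rows$name, stringsAsFactors = FALSE)
  }
  ne <- min(config$n_enriched_seeds, nrow(novel))
  parts <- list(
    mk_seed(novel[seq_len(ne), , drop = FALSE], "enriched"),
    if (nrow(novel) > ne)
      mk_seed(novel[(ne + 1L):nrow(novel), , drop = FALSE], "background"),
    mk_seed(ncr, "avoided"),
    mk_seed(precursors[precursors$kind == "annotated", , drop = FALSE],
            "background"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) > 0L) seeds <- do.call(rbind, parts)
  rownames(seeds) <- NULL

  # intergenic complement of all annotated intervals
  occ <- rbind(as.matrix(ann[, c("start", "end")]),
               as.matrix(precursors[, c("start", "end")]))
  ig <- .complement_intervals(occ, L)
  intergenic <- data.frame(chrom = chrom, start = ig[, 1], end = ig[, 2],
                           strand = "*", category = "intergenic",
                           name = paste0("intergenic_", seq_len(nrow(ig))),
                           stringsAsFactors = FALSE)

  truth <- list(precursors = precursors, annotations = ann,
                intergenic = intergenic, seeds = seeds, config = config)
  list(genome = setNames(gseq, chrom), truth = truth)
}

# complement of a set of intervals within [0, L)
.complement_intervals <- function(iv, L) {
  if (nrow(iv) == 0L) return(matrix(c(0L, L), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- list()
  cur <- 0L
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] > cur) out[[length(out) + 1L]] <- c(cur, iv[i, 1])
    cur <- max(cur, iv[i, 2])
  }
  if (cur < L) out[[length(out) + 1L]] <- c(cur, L)
  do.call(rbind, out)
}
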