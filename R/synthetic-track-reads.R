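#' Generate the per-base conservation track
#'
#' Background positions draw scores from a Beta distribution with mean
#' `track_background_mean`; positions inside planted conserved mature
#' sequences draw from a high-mean Beta (redrawn, bounded, until the
#' interval mean is at least 0.8). A configurable fraction of background
#' positions carries no score (missing).
#'
#' @param genome named character vector from [generate_genome()].
#' @param truth the planted truth list.
#' @param config a [generator_config()].
#' @param missing_fraction overrides `config$track_missing_fraction` when
#'   not `NULL`.
#' @param background_mean overrides `config$track_background_mean`.
#' @return a conservation track: named list (one numeric vector per
#'   chromosome, `NA` = missing), scores in `[0, 1]`.
#' @export
generate_conservation_track <- function(genome, truth, config,
                                        missing_fraction = NULL,
                                        background_mean = NULL) {
  mf <- if (is.null(missing_fraction)) config$track_missing_fraction else
    missing_fraction
  bm <- if (is.null(background_mean)) config$track_background_mean else
    background_mean
  L <- nchar(genome[[1]])
  conc <- 8
  scores <- rbeta(L, bm * conc, (1 - bm) * conc)
  if (mf > 0) {
    n_miss <- round(mf * L)
    if (n_miss >= L) {
      scores[] <- NA_real_
    } else if (n_miss > 0L) {
      scores[sample.int(L, n_miss)] <- NA_real_
    }
  }
  cons <- truth$precursors[truth$precursors$conserved, , drop = FALSE]
  cm <- config$track_conserved_mean
  kc <- 60
  for (i in seq_len(nrow(cons))) {
    s <- cons$mature_start[i]; e <- cons$mature_end[i]
    stopifnot(s >= 0, e <= L)
    for (try in 1:100) {
      v <- rbeta(e - s, cm * kc, (1 - cm) * kc)
      if (mean(v) >= 0.8) break
    }
    scores[(s + 1L):e] <- v
  }
  setNames(list(scores), names(genome)[1])
}

#' Generate adapter-bearing raw reads from the planted truth
#'
#' Per-feature expression follows a log-uniform law over
#' `expression_log_range` orders of magnitude, with a minimum planted read
#' count (deep-coverage regime). Mature reads carry configurable 1-nt
#' 5'/3' end jitter; star-arm reads are emitted at `star_fraction` with the
#' 2-nt 3'-overhang duplex geometry baked into the planted star intervals.
#' Background/degradation reads come from a pool of random loci. Every read
#' is insert + 3' adapter, truncated (or `A`-padded) to 36 nt.
#'
#' @inheritParams generate_conservation_track
#' @return list with `reads` (character vector of 36-nt DNA reads),
#'   `feature_counts` (data.frame `name`, `mature_reads`, `star_reads`) and
#'   `background_loci` (data.frame of the degradation locus pool).
#' @export
generate_reads <- function(genome, truth, config) {
  gseq <- genome[[1]]
  L <- nchar(gseq)
  prec <- truth$precursors
  expressed <- prec[prec$kind != "decoy_noreads", , drop = FALSE]
  nf <- nrow(expressed)
  empty <- list(reads = character(0),
                feature_counts = data.frame(name = character(0),
                                            mature_reads = integer(0),
                                            star_reads = integer(0)),
                background_loci = data.frame())
  if (config$read_depth == 0L) return(empty)

  n_bg <- round(config$read_depth * config$background_read_fraction)
  n_feat <- config$read_depth - n_bg
  inserts <- character(0)

  feature_counts <- data.frame(name = character(0),
                               mature_reads = integer(0),
                               star_reads = integer(0))
  if (nf > 0L && n_feat > 0L) {
    w <- 10^runif(nf, 0, config$expression_log_range)
    cnt <- as.integer(rmultinom(1, n_feat, w / sum(w)))
    cnt <- pmax(cnt, config$min_planted_reads)
    star_cnt <- rbinom(nf, cnt, config$star_fraction)
    mat_cnt <- cnt - star_cnt
    for (i in seq_len(nf)) {
      f <- expressed[i, ]
      ins <- .jittered_inserts(gseq, f$mature_start, f$mature_end,
                               f$strand, mat_cnt[i],
                               config$jitter_5p, config$jitter_3p, L)
      sins <- .jittered_inserts(gseq, f$star_start, f$star_end,
                                f$strand, star_cnt[i],
                                config$jitter_5p, config$jitter_3p, L)
      inserts <- c(inserts, ins, sins)
    }
    feature_counts <- data.frame(name = expressed$name,
                                 mature_reads = mat_cnt,
                                 star_reads = star_cnt,
                                 stringsAsFactors = FALSE)
  }

  background_loci <- data.frame()
  if (n_bg > 0L && config$n_background_loci > 0L) {
    nl <- config$n_background_loci
    blen <- sample(18:28, nl, replace = TRUE)
    bstart <- vapply(blen, function(l) sample.int(L - l, 1L) - 1L,
                     integer(1))
    bstrand <- sample(c("+", "-"), nl, replace = TRUE)
    bw <- 10^runif(nl, 0, 2)
    bcnt <- as.integer(rmultinom(1, n_bg, bw / sum(bw)))
    keep <- bcnt > 0L
    bi <- rep(which(keep), bcnt[keep])
    inserts <- c(inserts, vapply(bi, function(j) {
      .feature_seq(gseq, bstart[j], bstart[j] + blen[j], bstrand[j])
    }, character(1)))
    background_loci <- data.frame(start = bstart, end = bstart + blen,
                                  strand = bstrand, count = bcnt)
  }

  reads <- paste0(inserts, config$adapter)
  short <- nchar(reads) < 36L
  if (any(short)) {
    reads[short] <- vapply(reads[short], function(r) {
      paste0(r, strrep("A", 36L - nchar(r)))
    }, character(1), USE.NAMES = FALSE)
  }
  reads <- substr(reads, 1L, 36L)
  list(reads = sample(reads), feature_counts = feature_counts,
       background_loci = background_loci)
}

# n jittered copies of a stranded feature interval, as insert sequences
.jittered_inserts <- function(gseq, start, end, strand, n, j5, j3, L) {
  if (n == 0L) return(character(0))
  d5 <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
               prob = c(j5 / 2, 1 - j5, j5 / 2))
  d3 <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
               prob = c(j3 / 2, 1 - j3, j3 / 2))
  if (strand == "+") {
    s <- start + d5; e <- end + d3
  } else {
    s <- start - d3; e <- end - d5
  }
  s <- pmax(0L, s); e <- pmin(L, e)
  vapply(seq_len(n), function(i) .feature_seq(gseq, s[i], e[i], strand),
         character(1))
}
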