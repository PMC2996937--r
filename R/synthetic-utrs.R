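#' Generate the synthetic 3'UTR set with planted target-site conservation
#'
#' UTR sequences are uniform random DNA; every 7-mer therefore occurs at a
#' comparable background frequency, which is what makes frequency-matched
#' scrambled-seed controls available. Conservation is laid down in three
#' layers: a low-mean per-base background, random high-score blocks sized
#' so that a background fraction `utr_background_conserved_rate` of 7-mer
#' windows is conserved, and per-occurrence adjustments at target sites of
#' planted seeds — occurrences of enriched-seed target motifs are raised to
#' `planted_target_enrichment` times the background conservation rate, and
#' occurrences of avoided-seed target motifs are suppressed to
#' `planted_avoidance_depletion` times it. All other motifs stay at the
#' background rate.
#'
#' @param truth planted truth from [generate_genome()] (its `seeds` table
#'   defines the planted conserved and avoided seeds).
#' @param config a [generator_config()].
#' @return list with `utrs` (named character vector, DNA), `track` (named
#'   list of per-UTR numeric score vectors, `NA` = missing) and
#'   `site_truth` (data.frame per planted motif: class, occurrence count,
#'   target conservation rate).
#' @export
generate_utr_set <- function(truth, config) {
  n <- config$n_utrs
  if (n == 0L) {
    return(list(utrs = setNames(character(0), character(0)),
                track = list(),
                site_truth = data.frame(motif = character(0),
                                        class = character(0),
                                        n_occurrences = integer(0),
                                        target_rate = numeric(0))))
  }
  lens <- sample(config$utr_length_range[1]:config$utr_length_range[2],
                 n, replace = TRUE)
  utrs <- setNames(vapply(lens, function(l) .random_dna(1, l), character(1)),
                   paste0("utr_", seq_len(n)))

  r0 <- config$utr_background_conserved_rate
  r_enr <- min(1, r0 * config$planted_target_enrichment)
  q_enr <- max(0, (r_enr - r0) / (1 - r0))
  q_avo <- 1 - config$planted_avoidance_depletion

  seeds <- truth$seeds
  special <- seeds[seeds$class %in% c("enriched", "avoided"), , drop = FALSE]
  sp_codes <- if (nrow(special) > 0L) {
    vapply(special$target_motif, function(m) .window_codes(m, 7L),
           integer(1), USE.NAMES = FALSE)
  } else integer(0)
  n_occ <- integer(nrow(special))

  block_len <- 34L
  track <- vector("list", n)
  bm <- 0.3; conc <- 8
  for (u in seq_len(n)) {
    l <- lens[u]
    sc <- rbeta(l, bm * conc, (1 - bm) * conc)
    # background conserved blocks
    nb <- rpois(1, r0 * max(0L, l - 21L) / (block_len - 6L))
    if (nb > 0L && l > block_len) {
      bs <- sample.int(l - block_len, nb, replace = TRUE)
      for (b in bs) {
        sc[b:(b + block_len - 1L)] <- rbeta(block_len, 0.92 * 60,
                                            0.08 * 60)
      }
    }
    # planted per-occurrence adjustments
    if (nrow(special) > 0L) {
      wc <- .window_codes(utrs[[u]], 7L)
      for (k in seq_len(nrow(special))) {
        occ <- which(!is.na(wc) & wc == sp_codes[k])
        n_occ[k] <- n_occ[k] + length(occ)
        if (length(occ) == 0L) next
        if (special$class[k] == "enriched") {
          hit <- occ[runif(length(occ)) < q_enr]
          for (o in hit) sc[o:(o + 6L)] <- rbeta(7L, 0.92 * 60, 0.08 * 60)
        } else {
          hit <- occ[runif(length(occ)) < q_avo]
          for (o in hit) sc[o:(o + 6L)] <- rbeta(7L, 0.2 * 30, 0.8 * 30)
        }
      }
    }
    mf <- config$track_missing_fraction
    if (mf > 0) {
      n_miss <- round(mf * l)
      if (n_miss >= l) sc[] <- NA_real_
      else if (n_miss > 0L) sc[sample.int(l, n_miss)] <- NA_real_
    }
    track[[u]] <- sc
  }
  names(track) <- names(utrs)
  site_truth <- data.frame(
    motif = special$target_motif, seed = special$seed,
    class = special$class, n_occurrences = n_occ,
    target_rate = ifelse(special$class == "enriched", r_enr,
                         r0 * config$planted_avoidance_depletion),
    stringsAsFactors = FALSE)
  list(utrs = utrs, track = track, site_truth = site_truth)
}

#' Generate a complete synthetic study in one call
#'
#' Seeds the RNG once from `config$seed` and produces the genome, truth,
#' conservation track, raw reads and UTR set. Identical configurations
#' yield byte-identical studies.
#'
#' @param config a [generator_config()].
#' @return list: `genome`, `truth`, `track`, `reads` (list from
#'   [generate_reads()]), `utrs` (list from [generate_utr_set()]).
#' @export
generate_synthetic_study <- function(config = generator_config()) {
  set.seed(config$seed)
  g <- generate_genome(config)
  track <- generate_conservation_track(g$genome, g$truth, config)
  reads <- generate_reads(g$genome, g$truth, config)
  utrs <- generate_utr_set(g$truth, config)
  list(genome = g$genome, truth = g$truth, track = track,
       reads = reads, utrs = utrs)
}
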