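#' Scan 3'UTRs for 7-mer motif conservation
#'
#' For each UTR, excluding the first 15 nt downstream of the stop codon,
#' a 7-nt window slides at 1-nt steps; every window increments the total
#' count `t` of its 7-mer and the conserved count `c` when at least 3
#' window positions carry a conservation score and the mean of the scored
#' positions is at least 0.8. Windows containing non-ACGT characters are
#' skipped. After the full scan, motifs with `t > 0` are ranked by `t` and
#' by `c` from high to low (ties broken by motif lexicographic order).
#'
#' @param utrs named character vector of UTR sequences (DNA).
#' @param track named list of per-UTR score vectors aligned to the
#'   sequences (`NA` = missing).
#' @param skip leading nucleotides excluded from the scan (default 15).
#' @param k motif length (default 7).
#' @param min_scored minimum scored positions for a window to be testable
#'   (default 3).
#' @param threshold conserved window mean cut-off (default 0.8, inclusive).
#' @return a `motif_table`: list with `table` (data.frame `motif`, `t`,
#'   `c`, `R_t`, `R_c`), `M` (number of motifs with `t > 0`) and
#'   `total_windows`.
#' @export
scan_utrs <- function(utrs, track, skip = 15L, k = 7L, min_scored = 3L,
                      threshold = 0.8) {
  nbins <- 4L^k
  t_cnt <- integer(nbins)
  c_cnt <- integer(nbins)
  total <- 0L
  for (u in seq_along(utrs)) {
    seq <- utrs[[u]]
    len <- nchar(seq)
    if (len < skip + k) next
    wc <- .window_codes(seq, k)
    sc <- track[[names(utrs)[u]]]
    stopifnot(length(sc) == len)
    scored <- !is.na(sc)
    v <- sc; v[!scored] <- 0
    csum <- c(0, cumsum(v))
    cn <- c(0L, cumsum(scored))
    m <- len - k + 1L
    win <- (skip + 1L):m                    # window starts, 1-based
    wc <- wc[win]
    ok <- !is.na(wc)
    nsc <- cn[win + k - 1L + 1L] - cn[win]
    smean <- (csum[win + k - 1L + 1L] - csum[win]) / pmax(nsc, 1L)
    conserved <- nsc >= min_scored & smean >= threshold
    total <- total + sum(ok)
    t_cnt <- t_cnt + tabulate(wc[ok] + 1L, nbins)
    c_cnt <- c_cnt + tabulate(wc[ok & conserved] + 1L, nbins)
  }
  present <- which(t_cnt > 0L)
  bases <- c("A", "C", "G", "T")
  motif <- vapply(present - 1L, function(code) {
    paste(bases[(code %/% 4L^((k - 1L):0L)) %% 4L + 1L], collapse = "")
  }, character(1))
  tab <- data.frame(motif = motif, t = t_cnt[present], c = c_cnt[present],
                    stringsAsFactors = FALSE)
  M <- nrow(tab)
  if (M > 0L) {
    ot <- order(-tab$t, tab$motif)
    tab$R_t[ot] <- seq_len(M)
    oc <- order(-tab$c, tab$motif)
    tab$R_c[oc] <- seq_len(M)
  } else {
    tab$R_t <- integer(0)
    tab$R_c <- integer(0)
  }
  structure(list(table = tab, M = M, total_windows = total,
                 k = k), class = "motif_table")
}

#' Motif rank score
#'
#' `score_i = (R_ti - R_ci) / M` over the `M` motifs with `t > 0`: a
#' positive score means the motif stands higher in the conserved-count
#' ranking than its overall abundance ranking predicts.
#'
#' @param table a `motif_table` from [scan_utrs()].
#' @return the table's data.frame with a `rank_score` column added.
#' @export
rank_score <- function(table) {
  tab <- table$table
  tab$rank_score <- (tab$R_t - tab$R_c) / table$M
  tab
}

# distinct permutations of the letters of a short string (memoized)
.distinct_permutations <- function(motif) {
  key <- paste(sort(strsplit(motif, "", fixed = TRUE)[[1]]), collapse = "")
  hit <- .smallmir_cache[[paste0("perm_", key)]]
  if (!is.null(hit)) return(hit)
  letters0 <- strsplit(key, "", fixed = TRUE)[[1]]
  res <- character(0)
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (ch in unique(remaining)) {
      rest <- remaining[-match(ch, remaining)]
      rec(paste0(prefix, ch), rest)
    }
  }
  rec("", letters0)
  res <- unlist(res)
  .smallmir_cache[[paste0("perm_", key)]] <- res
  res
}

#' Scrambled-seed control motifs
#'
#' Draws up to `n` distinct permutations of the target 7-mer's letters
#' (identical nucleotide composition, identity excluded) whose total UTR
#' frequency `t` lies within `tol` (default 10 percent) of the target
#' motif's `t`; the control conserved fraction `p0` pools conserved and
#' total counts over the accepted controls. Seeds whose composition
#' permits no qualifying control are flagged untestable.
#'
#' @param target_motif UTR-sense (DNA) 7-mer complementary to the seed.
#' @param table a `motif_table`.
#' @param n maximum accepted controls (default 100).
#' @param tol relative frequency tolerance (default 0.10).
#' @return list `controls` (data.frame `motif`, `t`, `c`), `p0`,
#'   `n_accepted`, `untestable`.
#' @export
scramble_controls <- function(target_motif, table, n = 100L, tol = 0.10) {
  tab <- table$table
  i <- match(target_motif, tab$motif)
  t_target <- if (is.na(i)) 0L else tab$t[i]
  perms <- setdiff(.distinct_permutations(target_motif), target_motif)
  if (length(perms) == 0L || t_target == 0L) {
    return(list(controls = NULL, p0 = NA_real_, n_accepted = 0L,
                untestable = TRUE))
  }
  j <- match(perms, tab$motif)
  t_ctrl <- ifelse(is.na(j), 0L, tab$t[j])
  c_ctrl <- ifelse(is.na(j), 0L, tab$c[j])
  ok <- abs(t_ctrl - t_target) <= tol * t_target & t_ctrl > 0L
  if (!any(ok)) {
    return(list(controls = NULL, p0 = NA_real_, n_accepted = 0L,
                untestable = TRUE))
  }
  idx <- which(ok)
  if (length(idx) > n) idx <- sample(idx, n)
  controls <- data.frame(motif = perms[idx], t = t_ctrl[idx],
                         c = c_ctrl[idx], stringsAsFactors = FALSE)
  list(controls = controls, p0 = sum(controls$c) / sum(controls$t),
       n_accepted = nrow(controls), untestable = FALSE)
}

#' Exact binomial test of target-site conservation
#'
#' Tests the conserved fraction of the seed's reverse-complement target
#' 7-mer against the pooled conserved fraction `p0` of scrambled-seed
#' controls: `p_excess = P[X >= c]` and `p_deficit = P[X <= c]` for
#' `X ~ Binomial(t, p0)`, each tail at `alpha` (the two directions are
#' reported separately, as excess and avoidance findings).
#'
#' @param seed RNA (or DNA) seed 7-mer (mature positions 2-8).
#' @param table a `motif_table`.
#' @param controls optional precomputed [scramble_controls()] result.
#' @param alpha per-tail significance level (default 0.05).
#' @param n_controls,tol passed to [scramble_controls()] when `controls`
#'   is `NULL`.
#' @return one-row data.frame: `seed`, `target_motif`, `t`, `c`, `p0`,
#'   `n_controls`, `p_excess`, `p_deficit`, `rank_score`, `verdict`
#'   (`excess`/`deficit`/`neither`/`untestable`).
#' @export
binomial_target_test <- function(seed, table, controls = NULL,
                                 alpha = 0.05, n_controls = 100L,
                                 tol = 0.10) {
  target <- revcomp_dna(rna_to_dna(seed))
  tab <- table$table
  i <- match(target, tab$motif)
  t <- if (is.na(i)) 0L else tab$t[i]
  cc <- if (is.na(i)) 0L else tab$c[i]
  rs <- if (is.na(i)) NA_real_ else (tab$R_t[i] - tab$R_c[i]) / table$M
  if (is.null(controls)) {
    controls <- scramble_controls(target, table, n_controls, tol)
  }
  if (t == 0L || controls$untestable) {
    return(data.frame(seed = seed, target_motif = target, t = t, c = cc,
                      p0 = NA_real_, n_controls = controls$n_accepted,
                      p_excess = NA_real_, p_deficit = NA_real_,
                      rank_score = rs, verdict = "untestable",
                      stringsAsFactors = FALSE))
  }
  pe <- binom_exact_tail(cc, t, controls$p0, "upper")
  pd <- binom_exact_tail(cc, t, controls$p0, "lower")
  verdict <- if (pe < alpha) "excess" else if (pd < alpha) "deficit" else
    "neither"
  data.frame(seed = seed, target_motif = target, t = t, c = cc,
             p0 = controls$p0, n_controls = controls$n_accepted,
             p_excess = pe, p_deficit = pd, rank_score = rs,
             verdict = verdict, stringsAsFactors = FALSE)
}

# verdict-only version of the target test (identical decision path,
# without the per-row data.frame overhead; used in simulations)
.target_verdict <- function(target_motif, table, alpha = 0.05,
                            n_controls = 100L, tol = 0.10) {
  tab <- table$table
  i <- match(target_motif, tab$motif)
  if (is.na(i)) return("untestable")
  ctrl <- scramble_controls(target_motif, table, n_controls, tol)
  if (ctrl$untestable) return("untestable")
  pe <- binom_exact_tail(tab$c[i], tab$t[i], ctrl$p0, "upper")
  pd <- binom_exact_tail(tab$c[i], tab$t[i], ctrl$p0, "lower")
  if (pe < alpha) "excess" else if (pd < alpha) "deficit" else "neither"
}

#' Group conserved matures into seed families
#'
#' The seed is mature positions 2-8 (1-based); matures sharing a seed form
#' one family, the unit of target-conservation testing. The family's
#' UTR-sense target motif is the seed's reverse complement in DNA.
#'
#' @param matures data.frame with `name` and `mature_seq` (RNA), or a
#'   character vector of mature sequences.
#' @return data.frame `seed`, `target_motif`, `n_members`, `members`.
#' @export
build_families <- function(matures) {
  if (is.character(matures)) {
    matures <- data.frame(name = paste0("mature_", seq_along(matures)),
                          mature_seq = matures, stringsAsFactors = FALSE)
  }
  short <- nchar(matures$mature_seq) < 8L
  if (any(short)) {
    warning(sum(short), " mature(s) shorter than 8 nt excluded from families")
    matures <- matures[!short, , drop = FALSE]
  }
  if (nrow(matures) == 0L) {
    return(data.frame(seed = character(0), target_motif = character(0),
                      n_members = integer(0), members = character(0)))
  }
  seed <- substr(matures$mature_seq, 2L, 8L)
  fam <- split(matures$name, seed)
  data.frame(seed = names(fam),
             target_motif = revcomp_dna(rna_to_dna(names(fam))),
             n_members = lengths(fam),
             members = vapply(fam, paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Family-proportion simulation test
#'
#' Compares the observed fraction of testable seed families with a
#' significant excess (and, symmetrically, deficit) of conserved target
#' sites against `n_sim` simulations in which the same number of seeds is
#' drawn at random (uniformly over motifs with `t > 0`) and put through
#' the identical test.
#'
#' @param families data.frame from [build_families()] (or a character
#'   vector of seeds).
#' @param table a `motif_table`.
#' @param n_sim simulations (default 1000).
#' @param alpha per-tail significance level.
#' @param n_controls,tol control parameters, as in
#'   [binomial_target_test()].
#' @return list with `results` (per-family test rows), `observed_excess`,
#'   `observed_deficit` (proportions over testable families),
#'   `background_excess`, `background_deficit` (simulation means),
#'   `ci_excess`, `ci_deficit` (2.5/97.5 percentiles), `p_excess`,
#'   `p_deficit` (add-one empirical), `n_testable`, `n_sim`.
#' @export
family_proportion_test <- function(families, table, n_sim = 1000L,
                                   alpha = 0.05, n_controls = 100L,
                                   tol = 0.10) {
  seeds <- if (is.data.frame(families)) families$seed else families
  stopifnot(length(seeds) >= 1L)
  results <- do.call(rbind, lapply(seeds, binomial_target_test,
                                   table = table, alpha = alpha,
                                   n_controls = n_controls, tol = tol))
  testable <- results$verdict != "untestable"
  n_testable <- sum(testable)
  obs_exc <- if (n_testable > 0L) mean(results$verdict[testable] == "excess")
    else NA_real_
  obs_def <- if (n_testable > 0L) mean(results$verdict[testable] == "deficit")
    else NA_real_
  tab <- table$table
  sim_exc <- numeric(n_sim)
  sim_def <- numeric(n_sim)
  nf <- length(seeds)
  for (s in seq_len(n_sim)) {
    # drawn motifs play the target role directly (same test, verdict only)
    pick <- sample.int(nrow(tab), nf, replace = nf > nrow(tab))
    v <- vapply(tab$motif[pick], .target_verdict, character(1),
                table = table, alpha = alpha, n_controls = n_controls,
                tol = tol, USE.NAMES = FALSE)
    tst <- v != "untestable"
    sim_exc[s] <- if (any(tst)) mean(v[tst] == "excess") else 0
    sim_def[s] <- if (any(tst)) mean(v[tst] == "deficit") else 0
  }
  list(results = results,
       observed_excess = obs_exc, observed_deficit = obs_def,
       background_excess = mean(sim_exc), background_deficit = mean(sim_def),
       ci_excess = quantile(sim_exc, c(0.025, 0.975), names = FALSE),
       ci_deficit = quantile(sim_def, c(0.025, 0.975), names = FALSE),
       p_excess = (1 + sum(sim_exc >= obs_exc)) / (n_sim + 1),
       p_deficit = (1 + sum(sim_def >= obs_def)) / (n_sim + 1),
       n_testable = n_testable, n_sim = n_sim)
}
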