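#' Dinucleotide-preserving sequence shuffle
#'
#' Uniform random shuffle preserving the exact dinucleotide count vector
#' and the first and last nucleotide (Altschul-Erickson Eulerian-path
#' shuffle on the dinucleotide multigraph): a random last-exit edge is
#' drawn for every vertex and accepted when the last-exit edges lead every
#' vertex to the terminal nucleotide; remaining edges are permuted
#' uniformly and the path is walked. Used as the folding-score null.
#'
#' @param seq character scalar.
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(seq) {
  stopifnot(nchar(seq) >= 2L)
  .dinuc_shuffles(seq, 1L)[1]
}

.dinuc_shuffles <- function(seq, n) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  if (L < 3L) return(rep(seq, n))
  first <- ch[1]
  last <- ch[L]
  edges <- split(ch[-1], ch[-L])
  verts <- names(edges)
  nonlast <- setdiff(verts, last)
  out <- character(n)
  for (r in seq_len(n)) {
    # last-exit edge per vertex, rejected until all chains reach `last`
    for (tries in 1:1000) {
      le <- vapply(edges, function(tg) tg[sample.int(length(tg), 1L)],
                   character(1))
      ok <- TRUE
      for (v in nonlast) {
        cur <- v
        steps <- 0L
        while (cur != last && steps <= length(verts)) {
          if (!(cur %in% verts)) break
          cur <- le[[cur]]
          steps <- steps + 1L
        }
        if (cur != last) { ok <- FALSE; break }
      }
      if (ok) break
    }
    # permute the remaining edges; append the reserved last-exit edge
    ordering <- lapply(verts, function(v) {
      tg <- edges[[v]]
      if (v == last) return(tg[sample.int(length(tg))])
      drop1 <- which(tg == le[[v]])[1]
      rest <- tg[-drop1]
      c(rest[sample.int(length(rest))], le[[v]])
    })
    names(ordering) <- verts
    idx <- setNames(rep(1L, length(verts)), verts)
    res <- character(L)
    res[1] <- first
    cur <- first
    for (i in 2:L) {
      nxt <- ordering[[cur]][idx[[cur]]]
      idx[[cur]] <- idx[[cur]] + 1L
      res[i] <- nxt
      cur <- nxt
    }
    out[r] <- paste(res, collapse = "")
  }
  out
}

#' Folding-score significance against dinucleotide-shuffled controls
#'
#' Folds the sequence and `n` dinucleotide-preserving shuffles of it;
#' reports the z-score of the observed pairing score against the shuffle
#' distribution and the add-one-corrected empirical p-value
#' `(1 + #\{shuffle >= observed\}) / (n + 1)`.
#'
#' @param seq character scalar (DNA or RNA).
#' @param n number of shuffled controls (default 1000).
#' @param min_loop minimum hairpin loop for the folding engine.
#' @return list `score` (observed), `z` (`NA` when the shuffle scores are
#'   constant), `p` (in `[1/(n+1), 1]`), `n`.
#' @export
shuffle_significance <- function(seq, n = 1000L, min_loop = 3L) {
  if (n <= 0L) stop("no controls: n must be positive")
  obs <- as.integer(.fold_scores_cpp(seq, as.integer(min_loop)))[1]
  sh <- .dinuc_shuffles(seq, n)
  sc <- as.integer(.fold_scores_cpp(sh, as.integer(min_loop)))
  s <- sd(sc)
  z <- if (is.na(s) || s == 0) NA_real_ else (obs - mean(sc)) / s
  p <- (1 + sum(sc >= obs)) / (n + 1)
  list(score = obs, z = z, p = p, n = n)
}
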