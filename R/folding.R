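#' Fold a local sequence window into its best base-pairing structure
#'
#' Local secondary-structure prediction by dynamic-programming maximum
#' weighted base pairing (Nussinov-style): pair weights G-C = 3, A-U = 2,
#' G-U = 1, with a minimum hairpin loop of `min_loop` unpaired nucleotides
#' between any pair. This deliberately trades nearest-neighbour
#' thermodynamic realism for a dependency-free, exactly testable engine;
#' the score is a proxy for -MFE, not kcal/mol. The traceback is
#' deterministic (ties resolved by leaving the 3' base unpaired, else by the
#' leftmost pairing partner), so identical input always yields an identical
#' structure.
#'
#' @param window_seq character scalar, DNA or RNA; windows are expected to
#'   be at most 110 nt (the caller slides a 110-nt window over the region
#'   100 nt up- and downstream of mapped reads).
#' @param min_loop minimum number of unpaired nucleotides inside a hairpin
#'   loop (default 3).
#' @return a list of `FoldedStructure` objects (always length 1; sequences
#'   of any length fold — the discovery stage is what refuses windows
#'   shorter than 20 nt); each has `sequence`, `structure` (dot-bracket),
#'   `score` and `pairs` (two-column 0-based matrix of paired positions).
#' @export
fold_local <- function(window_seq, min_loop = 3L) {
  stopifnot(length(window_seq) == 1L, nchar(window_seq) >= 1L)
  res <- .fold_one_cpp(window_seq, as.integer(min_loop))
  pt <- pair_table(res$structure)
  i <- which(!is.na(pt) & pt > seq_along(pt) - 1L)
  pairs <- cbind(i - 1L, pt[i])
  list(structure(
    list(sequence = window_seq, structure = res$structure,
         score = res$score, pairs = pairs),
    class = "folded_structure"))
}

# batch fold: returns data.frame(sequence, structure, score)
.fold_batch <- function(seqs, min_loop = 3L) {
  data.frame(sequence = seqs,
             structure = .fold_structures_cpp(seqs, as.integer(min_loop)),
             score = as.integer(.fold_scores_cpp(seqs, as.integer(min_loop))),
             stringsAsFactors = FALSE)
}

#' Pair table of a dot-bracket string
#'
#' @param db dot-bracket string (balanced, non-crossing).
#' @return integer vector: `pt[i]` is the 0-based partner of 0-based
#'   position `i - 1`, or `NA` if unpaired.
#' @export
pair_table <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j - 1L
      pt[j] <- i - 1L
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  pt
}

# remove helices shorter than min_stack stacked pairs from a pair table.
# The maximum-weighted-pairing engine has no loop or lone-pair penalty, so
# optimal structures are decorated with spurious 1-2-pair helices that a
# thermodynamic folder would never emit; extraction prunes them first so
# that stem-loop topology reflects the real helix architecture.
.prune_short_helices <- function(pt, min_stack = 4L) {
  repeat {
    n <- length(pt)
    changed <- FALSE
    i <- 1L
    while (i <= n) {
      j <- pt[i]
      if (is.na(j) || j <= i - 1L) { i <- i + 1L; next }
      # helix: consecutive stacked pairs starting at (i-1, j) 0-based
      len <- 1L
      while (i + len <= n && !is.na(pt[i + len]) &&
             pt[i + len] == j - len) len <- len + 1L
      if (len < min_stack) {
        for (k in 0:(len - 1L)) {
          pt[i + k] <- NA_integer_
          pt[j - k + 1L] <- NA_integer_
        }
        changed <- TRUE
      }
      i <- i + len
    }
    if (!changed) break
  }
  pt
}

# dot-bracket string after short-helix pruning
.pruned_db <- function(db, min_stack = 4L) {
  pt <- .prune_short_helices(pair_table(db), min_stack)
  out <- rep(".", length(pt))
  idx <- seq_along(pt) - 1L
  out[!is.na(pt) & pt > idx] <- "("
  out[!is.na(pt) & pt < idx] <- ")"
  paste(out, collapse = "")
}

#' Extract unbranched stem-loops from a folded structure
#'
#' A stem-loop is a run of nested base pairs closed by a terminal hairpin
#' loop, allowing internal loops and bulges of any size but no multiloop
#' branching: no position inside the stem-loop pairs outside it, and it
#' contains exactly one terminal loop. Extraction starts at each
#' hairpin-closing pair and walks outward through enclosing pairs until a
#' branch (a second enclosed helix) or the exterior is reached. The maximum
#' bulge/internal-loop side length seen along the walk is recorded.
#' Helices shorter than `min_stack` stacked pairs are pruned first (the
#' pairing engine has no lone-pair penalty, so unpruned optima carry
#' spurious one- and two-pair helices that would read as false branches).
#'
#' @param fs a `folded_structure` (from [fold_local()]) or a dot-bracket
#'   string.
#' @param min_pairs keep only stem-loops with at least this many base pairs
#'   (default 0, i.e. return all; the discovery pipeline filters at 20).
#' @param max_bulge stop extending the stem outward when a bulge/internal
#'   loop side longer than this is met (default `Inf`: bulges of any size
#'   are allowed and only recorded; the discovery pipeline caps them so
#'   stems do not grow through sparsely paired flanking sequence).
#' @param min_stack prune helices with fewer stacked pairs than this
#'   before extraction (default 4; 1 disables pruning).
#' @return data.frame with 0-based half-open `start`,`end` of the stem-loop,
#'   `pairs`, `loop_start`,`loop_end` (the terminal loop interval) and
#'   `max_bulge`.
#' @export
extract_hairpins <- function(fs, min_pairs = 0L, max_bulge = Inf,
                             min_stack = 4L) {
  db <- if (is.character(fs)) fs else fs$structure
  pt <- pair_table(db)
  if (min_stack > 1L) pt <- .prune_short_helices(pt, min_stack)
  n <- length(pt)
  out <- list()
  # hairpin-closing pairs: (i,j) paired with no paired position inside
  for (i in which(!is.na(pt) & pt > seq_len(n) - 1L)) {
    j <- pt[i] + 1L  # 1-based partner
    if (j - i > 1L && any(!is.na(pt[(i + 1L):(j - 1L)]))) next
    a <- i; b <- j; npairs <- 1L; bulge_seen <- 0L
    repeat {
      a2 <- a - 1L
      while (a2 >= 1L && is.na(pt[a2])) a2 <- a2 - 1L
      if (a2 < 1L) break
      b2 <- pt[a2] + 1L
      if (b2 <= b) break                     # partner not enclosing: branch
      if (b2 > b + 1L && any(!is.na(pt[(b + 1L):(b2 - 1L)]))) break  # multiloop
      if (max(a - a2 - 1L, b2 - b - 1L) > max_bulge) break
      bulge_seen <- max(bulge_seen, a - a2 - 1L, b2 - b - 1L)
      a <- a2; b <- b2; npairs <- npairs + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      start = a - 1L, end = b, pairs = npairs,
      loop_start = i, loop_end = j - 1L, max_bulge = bulge_seen)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      pairs = integer(0), loop_start = integer(0),
                      loop_end = integer(0), max_bulge = integer(0)))
  }
  res <- do.call(rbind, out)
  res[res$pairs >= min_pairs, , drop = FALSE]
}
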