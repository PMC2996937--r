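#' Local contiguous triplet structure composition
#'
#' For each interior position of a folded sequence, the paired/unpaired
#' status of the 3-position window around it (8 patterns, `(` = paired)
#' combined with the identity of the middle base gives one of 32 triplet
#' elements; their frequencies (normalized by the number of windows) are a
#' classic feature family for pre-miRNA classification.
#'
#' @param fs a `folded_structure` from [fold_local()], or a list with
#'   `sequence` and `structure`.
#' @return named numeric vector of 32 frequencies summing to 1.
#' @export
triplet_features <- function(fs) {
  seq <- toupper(dna_to_rna(fs$sequence))
  db <- fs$structure
  L <- nchar(seq)
  stopifnot(L >= 3L, nchar(db) == L)
  paired <- strsplit(db, "", fixed = TRUE)[[1]] != "."
  base <- strsplit(seq, "", fixed = TRUE)[[1]]
  # pairing patterns encoded u/p (unpaired/paired) over the 3-window
  pats <- c("uuu", "uup", "upu", "upp", "puu", "pup", "ppu", "ppp")
  bases <- c("A", "C", "G", "U")
  nm <- as.vector(outer(pats, bases, function(p, b) paste0(p, "_", b)))
  cnt <- setNames(rep(0L, 32L), nm)
  idx <- 2:(L - 1L)
  pat_code <- 4L * paired[idx - 1L] + 2L * paired[idx] + paired[idx + 1L]
  b <- match(base[idx], bases)
  ok <- !is.na(b)
  key <- pat_code[ok] + 8L * (b[ok] - 1L) + 1L
  tab <- tabulate(key, nbins = 32L)
  cnt[] <- tab
  cnt / length(idx)
}

#' Structure and thermodynamic-proxy features of a candidate hairpin
#'
#' Folds the sequence, compares its pairing score against `n_shuffle`
#' dinucleotide-preserving shuffles, and assembles the classifier feature
#' vector: length-normalized pairing score, shuffle z-score and empirical
#' p, the 32 triplet-composition frequencies, stem length (base pairs of
#' the best unbranched stem-loop), terminal loop size, and GC fraction.
#'
#' @param seq precursor sequence (DNA or RNA).
#' @param n_shuffle dinucleotide-shuffled controls (default 1000).
#' @param min_loop folding engine minimum loop.
#' @return named numeric vector of 37 features.
#' @export
hairpin_features <- function(seq, n_shuffle = 1000L, min_loop = 3L) {
  fs <- fold_local(seq, min_loop)[[1]]
  sig <- shuffle_significance(seq, n_shuffle, min_loop)
  # features describe the pruned structure, consistent with the extraction
  # semantics that define candidate stem-loops in the first place
  fs$structure <- .pruned_db(fs$structure)
  hp <- extract_hairpins(fs)
  if (nrow(hp) > 0L) {
    best <- hp[which.max(hp$pairs), ]
    stem_len <- best$pairs
    loop_size <- best$loop_end - best$loop_start
  } else {
    stem_len <- 0L
    loop_size <- 0L
  }
  z <- if (is.na(sig$z)) 0 else sig$z
  c(norm_score = fs$score / nchar(seq), shuffle_z = z,
    shuffle_log_p = log(sig$p), triplet_features(fs),
    stem_len = stem_len, loop_size = loop_size,
    gc = .gc_fraction(seq))
}

# feature matrix for a vector of sequences
.features_matrix <- function(seqs, n_shuffle = 1000L, min_loop = 3L) {
  as.data.frame(do.call(rbind, lapply(seqs, hairpin_features,
                                      n_shuffle = n_shuffle,
                                      min_loop = min_loop)),
                check.names = FALSE)
}

#' Synthesize training hairpins for the structure classifier
#'
#' Positive examples are synthetic precursor-like hairpins (exact
#' reverse-complement arms); negatives are hairpin-like sequences with
#' heavily degraded complementarity, emulating hairpins extracted from
#' exonic sequence that pass the structural pre-filter but are not miRNA
#' precursors.
#'
#' @param n_pos,n_neg examples per class (at least 30 each recommended).
#' @param n_shuffle shuffled controls per example for the features.
#' @param seed RNG seed (training fixtures are deterministic).
#' @return list `pos`, `neg` (feature data.frames), `pos_seqs`, `neg_seqs`.
#' @export
make_training_hairpins <- function(n_pos = 40L, n_neg = 40L,
                                   n_shuffle = 1000L, seed = 202L,
                                   min_pairs = 20L, max_bulge = 8L) {
  set.seed(seed)
  # every example goes through the same embed -> fold -> extract path as a
  # real candidate, so training and scoring distributions match
  embed_extract <- function(prec_seq, min_p) {
    for (try in 1:50) {
      win <- paste0(.random_dna(1, sample(15:35, 1L)), prec_seq,
                    .random_dna(1, sample(15:35, 1L)))
      win <- substr(win, 1L, 110L)
      fs <- fold_local(win)[[1]]
      hp <- extract_hairpins(fs, min_p, max_bulge)
      if (nrow(hp) > 0L) {
        best <- hp[which.max(hp$pairs), ]
        return(substr(win, best$start + 1L, best$end))
      }
    }
    NA_character_
  }
  draw_pos <- function() {
    embed_extract(.build_precursor(sample(25:30, 1L), sample(8:15, 1L),
                                   sample(20:23, 1L),
                                   sample(c("5p", "3p"), 1L))$seq,
                  min_pairs)
  }
  draw_set <- function(n, f) {
    out <- character(0)
    while (length(out) < n) {
      s <- f()
      if (!is.na(s)) out <- c(out, s)
    }
    out
  }
  pos_seqs <- draw_set(n_pos, draw_pos)
  # negatives are the hairpins background (exon-like) sequence actually
  # offers: the best extractable stem-loop of random windows. Stems of 20
  # pairs are vanishingly rare in random sequence, so the pair floor is
  # relaxed for the negative pool; windows are folded in batches
  neg_seqs <- character(0)
  min_pairs_neg <- min(min_pairs, 10L)
  while (length(neg_seqs) < n_neg) {
    wins <- .random_dna(400L, 110L)
    folded <- .fold_batch(wins)
    for (i in seq_along(wins)) {
      hp <- extract_hairpins(folded$structure[i], min_pairs_neg, max_bulge)
      if (nrow(hp) == 0L) next
      best <- hp[which.max(hp$pairs), ]
      neg_seqs <- c(neg_seqs, substr(wins[i], best$start + 1L, best$end))
      if (length(neg_seqs) >= n_neg) break
    }
  }
  list(pos = .features_matrix(pos_seqs, n_shuffle),
       neg = .features_matrix(neg_seqs, n_shuffle),
       pos_seqs = pos_seqs, neg_seqs = neg_seqs)
}

#' Train the precursor structure classifier
#'
#' Random-forest classifier over [hairpin_features()], trained on known
#' (or synthetic) precursors against exon-derived hairpins. Scoring
#' returns the class probability of being a true precursor; candidates
#' pass at a score of at least `threshold` (default 0.70; the boundary is
#' inclusive).
#'
#' @param pos,neg feature data.frames (rows = examples), e.g. from
#'   [make_training_hairpins()].
#' @param threshold pass cut-off on the class-probability score.
#' @param ntree random-forest size.
#' @param seed RNG seed; training is deterministic under a fixed seed.
#' @return a `structure_classifier` list (`forest`, `features`,
#'   `threshold`).
#' @export
train_structure_classifier <- function(pos, neg, threshold = 0.70,
                                       ntree = 500L, seed = 7L) {
  pos <- as.data.frame(pos)
  neg <- as.data.frame(neg)
  stopifnot(identical(names(pos), names(neg)))
  if (anyNA(pos) || anyNA(neg)) stop("missing feature values in training set")
  if (nrow(pos) < 30L || nrow(neg) < 30L) {
    warning("fewer than 30 training examples in a class")
  }
  if (max(nrow(pos), nrow(neg)) > 10L * min(nrow(pos), nrow(neg))) {
    warning("training class imbalance exceeds 10:1")
  }
  x <- rbind(pos, neg)
  y <- factor(rep(c("precursor", "background"),
                  c(nrow(pos), nrow(neg))),
              levels = c("background", "precursor"))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree)
  # random-forest vote fractions are poorly calibrated in the mid-range;
  # a logistic recalibration on the out-of-bag votes makes the reported
  # score an honest class probability, which is what a fixed 0.70 cut-off
  # presumes
  oob <- pmin(pmax(rf$votes[, "precursor"], 0.01), 0.99)
  cal <- suppressWarnings(
    glm((y == "precursor") ~ qlogis(oob), family = binomial()))
  structure(list(forest = rf, calibration = coef(cal),
                 features = names(pos), threshold = threshold),
            class = "structure_classifier")
}

#' @rdname train_structure_classifier
#' @param model a trained `structure_classifier`.
#' @param features feature data.frame of candidates to score (columns as in
#'   training).
#' @param ids optional candidate ids for the output.
#' @return `score_structure`: data.frame `candidate`, `approach`, `score`,
#'   `pass`.
#' @export
score_structure <- function(model, features, ids = NULL) {
  features <- as.data.frame(features)
  stopifnot(identical(names(features), model$features))
  if (is.null(ids)) ids <- rownames(features)
  if (nrow(features) == 0L) {
    return(data.frame(candidate = character(0), approach = character(0),
                      score = numeric(0), pass = logical(0)))
  }
  votes <- predict(model$forest, features, type = "prob")[, "precursor"]
  lin <- model$calibration[1] +
    model$calibration[2] * qlogis(pmin(pmax(votes, 0.01), 0.99))
  sc <- as.numeric(plogis(lin))
  data.frame(candidate = ids, approach = "structure",
             score = sc, pass = sc >= model$threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
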