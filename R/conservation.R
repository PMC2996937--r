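#' Mean per-base conservation of a genome interval
#'
#' Mean over scored positions only; an interval with no scored positions
#' has an undefined mean and is never called conserved.
#'
#' @param interval numeric length-2: 0-based half-open `c(start, end)`.
#' @param track numeric score vector for the chromosome (`NA` = missing).
#' @return list `mean` (`NA` if nothing scored) and `n_scored`.
#' @export
mean_conservation <- function(interval, track) {
  stopifnot(interval[1] >= 0, interval[2] <= length(track),
            interval[2] > interval[1])
  v <- track[(interval[1] + 1L):interval[2]]
  n <- sum(!is.na(v))
  list(mean = if (n > 0L) mean(v, na.rm = TRUE) else NA_real_,
       n_scored = n)
}

#' Conservation verdicts for candidate matures
#'
#' @param candidates candidate data.frame with `mature_start`,
#'   `mature_end` and `name`.
#' @param track per-chromosome score list (or a plain numeric vector for a
#'   single chromosome).
#' @param threshold conserved when mean `>= threshold` (default 0.8,
#'   boundary inclusive).
#' @return data.frame `candidate`, `mean_score`, `n_scored`, `conserved`.
#' @export
conservation_verdicts <- function(candidates, track, threshold = 0.8) {
  if (is.list(track) && !is.null(candidates$chrom)) {
    tr <- function(i) track[[candidates$chrom[i]]]
  } else {
    tr <- function(i) if (is.list(track)) track[[1]] else track
  }
  n <- nrow(candidates)
  ms <- numeric(n); ns <- integer(n)
  for (i in seq_len(n)) {
    r <- mean_conservation(c(candidates$mature_start[i],
                             candidates$mature_end[i]), tr(i))
    ms[i] <- if (is.na(r$mean)) NA_real_ else r$mean
    ns[i] <- r$n_scored
  }
  data.frame(candidate = candidates$name, mean_score = ms, n_scored = ns,
             conserved = !is.na(ms) & ns >= 1L & ms >= threshold,
             stringsAsFactors = FALSE)
}

#' Composition-matched background conservation distribution
#'
#' Each of `n_sim` simulations draws, for every candidate mature, an
#' interval of the same length from intron and intergenic space whose GC
#' fraction lies within `gc_tol` of the candidate set's aggregate GC
#' (greedy per-interval rejection sampling; the tolerance is relaxed
#' stepwise, with a warning, if matching is infeasible). Returns the null
#' distribution of counts per conservation bin (10 equal bins on the unit interval),
#' its 2.5/97.5 percentiles, the expected number of conserved intervals,
#' and the add-one empirical p that the observed conserved count is
#' reached by chance.
#'
#' @param matures data.frame with `chrom`, `mature_start`, `mature_end`.
#' @param ann an [annotation_set()]; sampling space is intron intervals
#'   plus the complement of all annotation (intergenic).
#' @param track per-chromosome score list.
#' @param genome named character vector (for GC matching).
#' @param n_sim simulations (default 1000).
#' @param gc_tol GC tolerance (default 0.05).
#' @param threshold conserved cut-off (default 0.8).
#' @param max_tries per-interval rejection budget before relaxing.
#' @return list: `bin_counts` (n_sim x 10 matrix), `bin_ci` (2 x 10),
#'   `expected_conserved`, `observed_conserved`, `observed_bins`, `p_emp`.
#' @export
background_conservation <- function(matures, ann, track, genome,
                                    n_sim = 1000L, gc_tol = 0.05,
                                    threshold = 0.8, max_tries = 50L) {
  stopifnot(nrow(matures) > 0L)
  chrom <- names(genome)[1]
  L <- nchar(genome[[1]])
  tr <- track[[chrom]]
  # intron + intergenic sampling space
  space <- rbind(
    as.matrix(ann[ann$category == "intron", c("start", "end")]),
    .complement_intervals(as.matrix(ann[, c("start", "end")]), L))
  space <- space[space[, 2] - space[, 1] >=
                   max(matures$mature_end - matures$mature_start), ,
                 drop = FALSE]
  lens <- matures$mature_end - matures$mature_start
  stopifnot(sum(space[, 2] - space[, 1]) >= sum(lens))
  # candidate aggregate GC
  b <- .base_codes(genome[[1]])
  gc_cum <- c(0, cumsum(b == 1L | b == 2L))
  gc_iv <- function(s, e) (gc_cum[e + 1L] - gc_cum[s + 1L]) / (e - s)
  target_gc <- sum(vapply(seq_len(nrow(matures)), function(i) {
    gc_cum[matures$mature_end[i] + 1L] - gc_cum[matures$mature_start[i] + 1L]
  }, numeric(1))) / sum(lens)

  w <- space[, 2] - space[, 1]
  draw_interval <- function(len, tol) {
    for (t in seq_len(max_tries)) {
      seg <- sample(rep(seq_len(nrow(space)), 2L), 1L, prob = rep(w, 2L))
      if (w[seg] < len) next
      s <- space[seg, 1] + sample.int(w[seg] - len + 1L, 1L) - 1L
      if (abs(gc_iv(s, s + len) - target_gc) <= tol) return(s)
    }
    NA_integer_
  }
  mean_iv <- function(s, e) {
    v <- tr[(s + 1L):e]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  bin_of <- function(m) pmin(floor(m * 10), 9) + 1L
  nb <- length(lens)
  bin_counts <- matrix(0L, n_sim, 10L)
  conserved_counts <- integer(n_sim)
  relaxed <- FALSE
  for (s in seq_len(n_sim)) {
    means <- numeric(nb)
    for (i in seq_len(nb)) {
      tol <- gc_tol
      repeat {
        st <- draw_interval(lens[i], tol)
        if (!is.na(st)) break
        tol <- tol + 0.05
        if (!relaxed) {
          warning("GC matching infeasible; tolerance relaxed to ", tol)
          relaxed <- TRUE
        }
      }
      repeat {
        m <- mean_iv(st, st + lens[i])
        if (!is.na(m)) break
        st <- draw_interval(lens[i], tol)
      }
      means[i] <- m
    }
    bin_counts[s, ] <- tabulate(bin_of(means), 10L)
    conserved_counts[s] <- sum(means >= threshold)
  }
  obs <- vapply(seq_len(nb), function(i) {
    mean_conservation(c(matures$mature_start[i], matures$mature_end[i]),
                      tr)$mean
  }, numeric(1))
  obs_cons <- sum(obs >= threshold, na.rm = TRUE)
  list(bin_counts = bin_counts,
       bin_ci = apply(bin_counts, 2, quantile, c(0.025, 0.975)),
       expected_conserved = mean(conserved_counts),
       observed_conserved = obs_cons,
       observed_bins = tabulate(bin_of(obs[!is.na(obs)]), 10L),
       p_emp = (1 + sum(conserved_counts >= obs_cons)) / (n_sim + 1))
}
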