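#' Exact binomial tail probability by direct summation
#'
#' Sums the binomial probability mass function term by term (log-space
#' terms, plain summation). Both tails include the point mass at `q`, so
#' `upper + lower >= 1` for any `q`.
#'
#' @param q count.
#' @param size number of trials.
#' @param prob success probability.
#' @param tail `"upper"` for `P[X >= q]`, `"lower"` for `P[X <= q]`.
#' @return probability in `[0, 1]`.
#' @export
binom_exact_tail <- function(q, size, prob, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(size >= 0, prob >= 0, prob <= 1)
  if (tail == "upper") {
    if (q <= 0) return(1)
    if (q > size) return(0)
    ks <- q:size
  } else {
    if (q < 0) return(0)
    if (q >= size) return(1)
    ks <- 0:q
  }
  if (prob == 0) return(if (0 %in% ks) 1 else 0)
  if (prob == 1) return(if (size %in% ks) 1 else 0)
  lt <- lchoose(size, ks) + ks * log(prob) + (size - ks) * log1p(-prob)
  min(1, sum(exp(lt)))
}

#' Exact hypergeometric upper-tail probability by direct summation
#'
#' `P[X >= k]` where `X` counts elements of a size-`K` subset hit when
#' drawing `n` of `N` elements without replacement. Used for the overlap of
#' the two prediction approaches over a shared candidate universe.
#'
#' @param N universe size.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param k observed overlap.
#' @return probability in `[0, 1]`.
#' @export
hyper_exact_upper <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  hi <- min(K, n)
  if (k > hi) stop("overlap ", k, " exceeds min(|A|,|B|) = ", hi)
  lo <- max(0L, K + n - N)
  if (k <= lo) return(1)
  xs <- k:hi
  lt <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  min(1, sum(exp(lt)))
}

#' Overlap of the two prediction approaches
#'
#' Counts candidates passing the structure approach, the read-signature
#' approach, and both, and computes the hypergeometric upper-tail
#' probability of an overlap at least as large arising by chance over the
#' shared candidate universe.
#'
#' @param structure_calls,signature_calls character vectors of candidate
#'   ids passing each approach.
#' @param universe character vector of all candidate ids considered by both.
#' @return list: `n_universe`, `n_structure`, `n_signature`, `n_overlap`,
#'   `p_hypergeometric`, `union` (ids passing either approach).
#' @export
combine_calls <- function(structure_calls, signature_calls, universe) {
  stopifnot(all(structure_calls %in% universe),
            all(signature_calls %in% universe))
  A <- unique(structure_calls)
  B <- unique(signature_calls)
  k <- length(intersect(A, B))
  list(n_universe = length(universe), n_structure = length(A),
       n_signature = length(B), n_overlap = k,
       p_hypergeometric = hyper_exact_upper(length(universe), length(A),
                                            length(B), k),
       union = union(A, B))
}
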