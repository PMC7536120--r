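#' Kimura two-parameter distance between aligned sequences
#'
#' Counts transition (P) and transversion (Q) proportions over comparable
#' sites (both bases in A/C/G/T; gapped or ambiguous columns are excluded
#' pairwise) and corrects for multiple hits:
#' `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`.
#' Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise an error.
#'
#' @param seq_a,seq_b Equal-length aligned sequences (strings).
#' @return List of class `k2p_result` with `P`, `Q`, `K`, `n_sites`
#'   (comparable sites) and `raw` (mismatch proportion).
#' @export
k2p <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  m <- length(a)
  if (m == 0) stop("no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / m
  Q <- sum(diff & !ts) / m
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop(sprintf("K2P saturation: P = %.3f, Q = %.3f", P, Q))
  K <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  if (K == 0) K <- 0  # clear IEEE negative zero for identical sequences
  structure(list(P = P, Q = Q, K = K, n_sites = m, raw = P + Q),
            class = "k2p_result")
}

#' Pairwise K2P distance matrix
#'
#' Symmetric matrix of K2P distances over a set of aligned sequences.
#' Saturated pairs are recorded as `NA` with a warning rather than aborting
#' the whole matrix.
#'
#' @param seqs Named character vector of aligned, equal-length sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  n_sat <- 0L
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      kij <- tryCatch(k2p(seqs[[i]], seqs[[j]])$K, error = function(e) {
        n_sat <<- n_sat + 1L
        NA_real_
      })
      d[i, j] <- d[j, i] <- kij
    }
  }
  if (n_sat > 0)
    warning(n_sat, " saturated pair(s) recorded as NA")
  d
}

#' Date a transposable-element proliferation burst
#'
#' Under a neutral clock each pairwise distance K between copies diverging
#' since a burst `t` years ago has expectation `2 * mu * t` (divergence
#' accrues on both lineages), so each pair dates the burst at `K / (2 mu)`.
#' The mean and min-max range over pairs are reported.
#'
#' @param distances Pairwise K2P matrix (from
#'   [pairwise_distance_matrix()]) or a vector of pairwise distances.
#' @param mu Substitution rate per bp per year (> 0).
#' @return List with `mean_age`, `range` (min, max) and `n_pairs`, in years.
#' @export
burst_age <- function(distances, mu) {
  if (mu <= 0) stop("mu must be > 0")
  if (is.matrix(distances)) distances <- distances[upper.tri(distances)]
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0) stop("no defined pairwise distances")
  ages <- distances / (2 * mu)
  list(mean_age = mean(ages), range = range(ages), n_pairs = length(ages))
}

#' Date an LTR retroelement insertion from its terminal repeats
#'
#' The two LTRs of a retroelement are identical at insertion and diverge
#' afterwards at twice the per-site rate, so the insertion age is
#' `K(ltr1, ltr2) / (2 mu)`; identical LTRs date the insertion to 0 years
#' (i.e. too recent for substitutions to accumulate).
#'
#' @param ltr1,ltr2 The element's two aligned LTR sequences.
#' @param mu Substitution rate per bp per year (> 0).
#' @return Insertion age in years.
#' @export
ltr_age <- function(ltr1, ltr2, mu) {
  if (mu <= 0) stop("mu must be > 0")
  k2p(ltr1, ltr2)$K / (2 * mu)
}

#' Detect an element insertion from junction-spanning read pairs
#'
#' In the coordinate frame of the insertion-bearing reference, a read pair
#' supports the left junction when one read lies entirely left of it and the
#' mate starts inside the element; symmetrically for the right junction. A
#' pair whose reads jump across the whole element interval spans the empty
#' (insertion-free) site. The verdict is `present` when both junctions have
#' at least `min_pairs` support, `absent` when neither junction has any
#' support and at least `min_pairs` pairs span the empty site, and
#' `ambiguous` otherwise. `min_pairs = 2` resists single chimeric pairs.
#'
#' @param read_pairs data.frame with `start1`, `end1`, `start2`, `end2`
#'   (read 1 left of read 2).
#' @param left_junction,right_junction Junction positions.
#' @param min_pairs Minimum supporting pairs per junction.
#' @return List of class `insertion_call` with `left_support`,
#'   `right_support`, `empty_support` and `verdict`.
#' @export
detect_insertion <- function(read_pairs, left_junction, right_junction,
                             min_pairs = 2L) {
  if (right_junction <= left_junction)
    stop("right_junction must exceed left_junction")
  if (nrow(read_pairs) == 0) {
    return(structure(list(left_support = 0L, right_support = 0L,
                          empty_support = 0L, verdict = "ambiguous"),
                     class = "insertion_call"))
  }
  inside <- function(s, e) s >= left_junction & e <= right_junction
  left_of <- read_pairs$end1 < left_junction
  right_of <- read_pairs$start2 > right_junction
  left_sup <- sum(left_of & inside(read_pairs$start2, read_pairs$end2))
  right_sup <- sum(inside(read_pairs$start1, read_pairs$end1) & right_of)
  empty_sup <- sum(left_of & right_of)
  verdict <- if (left_sup >= min_pairs && right_sup >= min_pairs) "present"
  else if (left_sup == 0L && right_sup == 0L && empty_sup >= min_pairs)
    "absent"
  else "ambiguous"
  structure(list(left_support = left_sup, right_support = right_sup,
                 empty_support = empty_sup, verdict = verdict),
            class = "insertion_call")
}
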