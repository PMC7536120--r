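#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity `2 * c1 * c0 / (n * (n - 1))` where `c1`
#' and `c0` are derived and ancestral allele counts among the `n = c1 + c0`
#' non-missing alleles. Sites with fewer than two non-missing alleles are
#' undefined (`NA`).
#'
#' @param c1 Derived-allele counts (vectorised).
#' @param n Total non-missing allele counts.
#' @return Per-site pi values.
#' @export
site_pi <- function(c1, n) {
  out <- 2 * c1 * (n - c1) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

#' Windowed nucleotide diversity (pi per bp)
#'
#' Sums per-site pi over the sites falling in a half-open window
#' `[start, end)` (0-based) and divides by the window length; monomorphic
#' positions contribute zero, so sites absent from the input do not need to
#' be enumerated. Sites with fewer than two non-missing alleles are skipped
#' with a message.
#'
#' @param positions 1-based site positions.
#' @param c1 Derived-allele count per site.
#' @param n Non-missing allele count per site (scalar or vector).
#' @param start,end Window bounds, 0-based half-open; a site at 1-based
#'   position p falls in the window when `start < p <= end`.
#' @return Window pi per bp.
#' @export
window_pi <- function(positions, c1, n, start, end) {
  if (end <= start) stop("end must exceed start")
  n <- rep_len(n, length(positions))
  in_win <- positions > start & positions <= end
  pi_site <- site_pi(c1[in_win], n[in_win])
  if (anyNA(pi_site)) {
    message("window_pi: skipped ", sum(is.na(pi_site)),
            " sites with < 2 non-missing alleles")
    pi_site <- pi_site[!is.na(pi_site)]
  }
  sum(pi_site) / (end - start)
}

#' Derived-allele counts of a haplotype set
#'
#' @param haps A [haplotype_set()].
#' @return List with `c1` (derived counts), `n` (non-missing totals) and
#'   `positions`.
#' @export
allele_counts <- function(haps) {
  a <- haps$alleles
  list(c1 = colSums(a == 1L, na.rm = TRUE),
       n = colSums(!is.na(a)),
       positions = haps$positions)
}

#' Tajima's D coefficients
#'
#' The standard constants for a sample of `n` haplotypes: `a1 = sum 1/i`,
#' `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Number of haplotypes (>= 2).
#' @return A list of class `tajima_constants`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                 c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2)),
            class = "tajima_constants")
}

#' Tajima's D
#'
#' Contrasts the window's average number of pairwise differences (`pi_sum`,
#' summed over sites, not per bp) with the scaled segregating-site count
#' `S / a1`: `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Negative
#' values indicate an excess of rare variants, as after a sweep or
#' expansion. With `S = 0` the statistic is undefined and `NA` is returned.
#'
#' @param S Number of segregating sites.
#' @param pi_sum Mean pairwise differences summed over the window.
#' @param n Number of haplotypes (>= 4, else the variance term is not
#'   positive).
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajima_d <- function(S, pi_sum, n) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S < 0) stop("S must be >= 0")
  if (S == 0) return(NA_real_)
  ct <- tajima_constants(n)
  (pi_sum - S / ct$a1) / sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
}

#' Extended haplotype homozygosity around a core allele
#'
#' Among the carriers of `core_allele` at the core site, haplotypes are
#' grouped by their allele string from the core out to each marker; EHH at a
#' marker is `sum_h C(e_h, 2) / C(n_c, 2)` over the group sizes `e_h`. EHH
#' equals 1 at the core and is non-increasing with distance.
#'
#' @param haps A [haplotype_set()].
#' @param core_site Site index of the core marker.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` or `"right"` of the core.
#' @param stop_below Stop extending the curve once EHH drops below this
#'   value (the first sub-threshold marker is still included). The default 0
#'   returns the full curve to the chromosome edge; integration for iHS only
#'   needs the curve down to its truncation cutoff.
#' @return data.frame with `site`, `pos`, `distance` (bp from the core) and
#'   `ehh`, starting at the core itself (distance 0, ehh 1).
#' @export
ehh <- function(haps, core_site, core_allele, direction = c("right", "left"),
                stop_below = 0) {
  direction <- match.arg(direction)
  a <- haps$alleles
  carriers <- which(a[, core_site] == core_allele)
  n_c <- length(carriers)
  if (n_c < 2) stop("EHH undefined: fewer than 2 carriers of the core allele")
  idx <- if (direction == "right") {
    if (core_site == ncol(a)) integer() else (core_site + 1L):ncol(a)
  } else {
    if (core_site == 1L) integer() else (core_site - 1L):1L
  }
  denom <- choose(n_c, 2)
  grp <- rep(1L, n_c)
  out_site <- c(core_site, idx)
  out_ehh <- numeric(length(out_site))
  out_ehh[1] <- 1
  k <- 1L
  for (s in idx) {
    k <- k + 1L
    al <- a[carriers, s]
    al[is.na(al)] <- 2L  # missing treated as its own allele state
    grp <- as.integer(factor(paste(grp, al)))
    sizes <- tabulate(grp)
    out_ehh[k] <- sum(choose(sizes, 2)) / denom
    if (out_ehh[k] < stop_below) break
  }
  out_site <- out_site[seq_len(k)]
  out_ehh <- out_ehh[seq_len(k)]
  data.frame(site = out_site, pos = haps$positions[out_site],
             distance = abs(haps$positions[out_site] -
                              haps$positions[core_site]),
             ehh = out_ehh)
}

# Trapezoidal integral of an EHH curve over physical distance, truncated at
# the first marker where EHH drops below `cutoff`. Returns NA when the curve
# reaches the chromosome edge still above the cutoff.
.ihh_one_side <- function(curve, cutoff) {
  below <- which(curve$ehh < cutoff)
  if (length(below) == 0) return(NA_real_)
  last <- below[1]
  d <- curve$distance[1:last]
  e <- curve$ehh[1:last]
  if (last == 1) return(0)
  sum(diff(d) * (utils::head(e, -1) + utils::tail(e, -1)) / 2)
}

#' Unstandardized iHS at a core site
#'
#' Integrates EHH over physical distance (trapezoid rule) separately for the
#' ancestral and the derived core allele, in both directions, truncating each
#' integral where EHH first falls below `cutoff`. The unstandardized score is
#' `ln(iHH_A / iHH_D)`; a long derived-allele haplotype (a sweep) gives
#' iHH_D > iHH_A and hence a negative score. Sites where EHH is still above
#' the cutoff at a chromosome edge are not scored (`NA`), as are monomorphic
#' cores (error) and cores where either allele has fewer than two carriers
#' (`NA`).
#'
#' @param haps A [haplotype_set()].
#' @param core_site Site index.
#' @param cutoff EHH truncation threshold in (0, 1).
#' @return A one-row data.frame with `site`, `pos`, `daf` (derived-allele
#'   frequency), `ihh_a`, `ihh_d` and `uihs`, possibly `NA`-valued.
#' @export
ihs_unstandardized <- function(haps, core_site, cutoff = 0.05) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  a <- haps$alleles[, core_site]
  n1 <- sum(a == 1L, na.rm = TRUE)
  n0 <- sum(a == 0L, na.rm = TRUE)
  if (n1 == 0 || n0 == 0) stop("monomorphic core site")
  daf <- n1 / (n1 + n0)
  rec <- data.frame(site = core_site, pos = haps$positions[core_site],
                    daf = daf, ihh_a = NA_real_, ihh_d = NA_real_,
                    uihs = NA_real_)
  if (n1 < 2 || n0 < 2) return(rec)
  ihh <- function(allele) {
    l <- .ihh_one_side(ehh(haps, core_site, allele, "left",
                           stop_below = cutoff), cutoff)
    r <- .ihh_one_side(ehh(haps, core_site, allele, "right",
                           stop_below = cutoff), cutoff)
    l + r
  }
  ihh_a <- ihh(0L)
  ihh_d <- ihh(1L)
  rec$ihh_a <- ihh_a
  rec$ihh_d <- ihh_d
  if (!is.na(ihh_a) && !is.na(ihh_d) && ihh_a > 0 && ihh_d > 0)
    rec$uihs <- log(ihh_a / ihh_d)
  rec
}

#' iHS scan over all scorable sites
#'
#' Applies [ihs_unstandardized()] to every site where both alleles have at
#' least two carriers, then standardizes with [standardize_ihs()].
#'
#' @param haps A [haplotype_set()].
#' @param cutoff EHH truncation threshold.
#' @param n_bins Frequency bins for standardization.
#' @param min_per_bin Minimum records per bin before merging.
#' @return data.frame of iHS records with a `ihs` (standardized) column.
#' @export
ihs_scan <- function(haps, cutoff = 0.05, n_bins = 50L, min_per_bin = 20L) {
  cnt <- allele_counts(haps)
  scorable <- which(cnt$c1 >= 2 & (cnt$n - cnt$c1) >= 2)
  recs <- do.call(rbind, lapply(scorable, function(s)
    ihs_unstandardized(haps, s, cutoff)))
  n_edge <- sum(is.na(recs$uihs))
  if (n_edge > 0)
    message("ihs_scan: ", n_edge,
            " sites unscored (chromosome edge before EHH cutoff)")
  standardize_ihs(recs, n_bins = n_bins, min_per_bin = min_per_bin)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Records are binned by derived-allele frequency into `n_bins` equal-width
#' bins on \[0, 1\]; bins with fewer than `min_per_bin` scored records are
#' merged with their neighbours. Within each bin the unstandardized scores
#' are centred and scaled to unit variance, making |iHS| comparable across
#' frequencies.
#'
#' @param records data.frame from [ihs_unstandardized()] (needs `daf` and
#'   `uihs`).
#' @param n_bins Number of equal-width frequency bins.
#' @param min_per_bin Minimum scored records per bin.
#' @return `records` with `bin` and standardized `ihs` columns appended.
#' @export
standardize_ihs <- function(records, n_bins = 50L, min_per_bin = 20L) {
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(records$daf, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  # merge under-filled bins with their left neighbour (leftmost merges right)
  repeat {
    present <- sort(unique(bin[!is.na(records$uihs)]))
    counts <- vapply(present, function(b)
      sum(bin == b & !is.na(records$uihs)), 0L)
    if (length(present) <= 1L || all(counts >= min_per_bin)) break
    small <- present[which.min(counts)]
    pos <- match(small, present)
    target <- if (pos > 1) present[pos - 1L] else present[pos + 1L]
    bin[bin == small] <- target
  }
  records$bin <- bin
  records$ihs <- NA_real_
  for (b in unique(bin)) {
    sel <- bin == b & !is.na(records$uihs)
    if (sum(sel) >= 2) {
      x <- records$uihs[sel]
      s <- stats::sd(x)
      if (s > 0) records$ihs[sel] <- (x - mean(x)) / s
    }
  }
  records
}

#' Sliding-window summary of per-site values
#'
#' Tiles `[0, max(positions))` with half-open windows `[w*step, w*step +
#' window_bp)` and summarises the sites in each window with the chosen
#' statistic. Windows with fewer than `min_snps` sites get `NA` so that
#' unstable estimates never enter outlier ranking.
#'
#' @param positions 1-based site positions.
#' @param values Per-site values (e.g. standardized iHS).
#' @param window_bp,step_bp Window length and slide in bp.
#' @param stat `"fraction_extreme"` (fraction with `|value| > threshold`),
#'   `"mean"` or `"sum"`.
#' @param threshold Extremeness threshold for `fraction_extreme`.
#' @param min_snps Minimum sites per window.
#' @return data.frame with `start`, `end` (0-based half-open), `n_snps`,
#'   `value`.
#' @export
scan_windows <- function(positions, values, window_bp = 100000,
                         step_bp = 10000,
                         stat = c("fraction_extreme", "mean", "sum"),
                         threshold = 2, min_snps = 10L) {
  stat <- match.arg(stat)
  ok <- !is.na(values)
  positions <- positions[ok]
  values <- values[ok]
  max_pos <- if (length(positions)) max(positions) else window_bp
  starts <- seq(0, max(0, max_pos - 1), by = step_bp)
  out <- data.frame(start = starts, end = starts + window_bp,
                    n_snps = NA_integer_, value = NA_real_)
  for (i in seq_along(starts)) {
    sel <- positions > starts[i] & positions <= starts[i] + window_bp
    n <- sum(sel)
    out$n_snps[i] <- n
    if (n >= min_snps) {
      v <- values[sel]
      out$value[i] <- switch(stat,
        fraction_extreme = mean(abs(v) > threshold),
        mean = mean(v),
        sum = sum(v))
    }
  }
  out
}

#' Flag outlier windows in one tail
#'
#' Ranks the non-missing window values and flags the extreme `fraction` in
#' the requested tail; ties at the cut value are all included (with a warning
#' when the tie expands the set).
#'
#' @param stats data.frame from [scan_windows()] (needs a `value` column).
#' @param tail `"lower"` (e.g. Tajima's D) or `"upper"` (e.g. extreme-iHS
#'   fraction).
#' @param fraction Fraction of non-missing windows to flag.
#' @return `stats` with a logical `outlier` column.
#' @export
outlier_windows <- function(stats, tail = c("lower", "upper"),
                            fraction = 0.01) {
  tail <- match.arg(tail)
  v <- stats$value
  ok <- !is.na(v)
  n <- sum(ok)
  if (n == 0) stop("no non-missing windows")
  n_flag <- max(1L, ceiling(fraction * n))
  sorted <- sort(v[ok], decreasing = (tail == "upper"))
  cut <- sorted[n_flag]
  flag <- ok & (if (tail == "upper") v >= cut else v <= cut)
  if (sum(flag) > n_flag)
    warning("ties at the cut expanded the outlier set from ", n_flag,
            " to ", sum(flag), " windows")
  stats$outlier <- flag
  stats
}
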