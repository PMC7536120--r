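#' Squared genotype correlation (r^2) between two sites
#'
#' Squared Pearson correlation of allele dosages over pairwise-complete
#' samples — the composite genotype LD measure plink reports. Undefined
#' (`NA`) when fewer than two complete pairs remain or either site is
#' monomorphic among them; it is symmetric in its arguments and invariant to
#' swapping allele labels (`d -> 2 - d`).
#'
#' @param dosage_a,dosage_b Equal-length dosage vectors (0/1/2, `NA`
#'   allowed).
#' @return r^2 in \[0, 1\], or `NA`.
#' @export
genotype_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b))
    stop("dosage vectors must have equal length")
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2) return(NA_real_)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Thin sites to a minimum physical spacing
#'
#' Greedy left-to-right: a site is kept iff its position is at least
#' `min_bp` beyond the last kept site (plink's `--bp-space` behaviour).
#'
#' @param positions Sorted site positions.
#' @param min_bp Minimum spacing in bp (0 keeps everything).
#' @return Integer indices of the kept sites.
#' @export
thin_by_bp <- function(positions, min_bp = 100) {
  if (is.unsorted(positions)) stop("positions must be sorted")
  n <- length(positions)
  if (n == 0) return(integer())
  keep <- integer(n)
  keep[1] <- 1L
  m <- 1L
  last <- positions[1]
  for (i in seq_len(n)[-1]) {
    if (positions[i] >= last + min_bp) {
      m <- m + 1L
      keep[m] <- i
      last <- positions[i]
    }
  }
  keep[seq_len(m)]
}

#' Distance-binned LD decay profile
#'
#' Computes r^2 for all site pairs within `max_pairs_window` sites and
#' `max_bp` of each other, optionally subsampling pairs, and averages r^2 in
#' left-closed distance bins `[k*bin_bp, (k+1)*bin_bp)`.
#'
#' @param positions Sorted site positions.
#' @param dosage Samples x sites dosage matrix.
#' @param max_pairs_window Maximum index separation between paired sites
#'   (plink `--ld-window`).
#' @param max_bp Maximum physical separation (plink `--ld-window-kb`).
#' @param bin_bp Bin width in bp.
#' @param max_pairs If finite, randomly subsample to this many pairs.
#' @param seed Seed for pair subsampling.
#' @return data.frame of class `ld_profile` with `bin_start`, `bin_mid`,
#'   `mean_r2`, `n_pairs`.
#' @export
ld_profile <- function(positions, dosage, max_pairs_window = 500L,
                       max_bp = 2e6, bin_bp = 100, max_pairs = Inf,
                       seed = 1L) {
  n <- length(positions)
  if (ncol(dosage) != n) stop("dosage must have one column per site")
  pairs_i <- pairs_j <- integer(0)
  for (i in seq_len(max(0L, n - 1L))) {
    j_max <- min(n, i + max_pairs_window)
    js <- (i + 1L):j_max
    js <- js[positions[js] - positions[i] <= max_bp]
    pairs_i <- c(pairs_i, rep.int(i, length(js)))
    pairs_j <- c(pairs_j, js)
  }
  if (length(pairs_i) == 0) stop("no computable site pairs")
  if (is.finite(max_pairs) && length(pairs_i) > max_pairs) {
    set.seed(seed)
    sel <- sample.int(length(pairs_i), max_pairs)
    message("ld_profile: subsampled ", max_pairs, " of ", length(pairs_i),
            " pairs")
    pairs_i <- pairs_i[sel]; pairs_j <- pairs_j[sel]
  }
  r2 <- vapply(seq_along(pairs_i), function(k)
    genotype_r2(dosage[, pairs_i[k]], dosage[, pairs_j[k]]), 0)
  dist <- positions[pairs_j] - positions[pairs_i]
  ok <- !is.na(r2)
  if (!all(ok))
    message("ld_profile: ", sum(!ok), " pairs undefined (monomorphic)")
  r2 <- r2[ok]; dist <- dist[ok]
  if (length(r2) == 0) stop("no computable site pairs")
  bin <- floor(dist / bin_bp) * bin_bp
  agg_mean <- tapply(r2, bin, mean)
  agg_n <- tapply(r2, bin, length)
  out <- data.frame(bin_start = as.numeric(names(agg_mean)),
                    bin_mid = as.numeric(names(agg_mean)) + bin_bp / 2,
                    mean_r2 = as.numeric(agg_mean),
                    n_pairs = as.integer(agg_n))
  out <- out[order(out$bin_start), ]
  rownames(out) <- NULL
  class(out) <- c("ld_profile", "data.frame")
  out
}

#' Expected r^2 under the Hill-Weir drift-recombination model
#'
#' The sample-size-adjusted expectation of r^2 at population recombination
#' parameter `C = c * d`:
#' `E[r^2] = (10 + C) / ((2 + C)(11 + C)) *
#'   (1 + ((3 + C)(12 + 12C + C^2)) / (n (2 + C)(11 + C)))`.
#'
#' @param d Distance in bp.
#' @param c Recombination-scale parameter per bp.
#' @param n Sample size (number of genotyped individuals).
#' @return Expected r^2.
#' @export
hill_weir_r2 <- function(d, c, n) {
  C <- c * d
  (10 + C) / ((2 + C) * (11 + C)) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit a nonlinear decay model to an LD profile
#'
#' Weighted (by pair count) least squares of either the Hill-Weir expected
#' r^2 curve (parameter `c`, fixed sample size `n`) or the simple hyperbolic
#' fallback `r^2 = a / (1 + b d)`.
#'
#' @param profile An [ld_profile()].
#' @param n Sample size (required for the Hill-Weir model).
#' @param model `"hill_weir"` or `"hyperbolic"`.
#' @return List of class `decay_fit` with `model`, `params`, `rss`,
#'   `predict` (a function of distance) and `d_max` (the profile's domain).
#' @export
fit_decay <- function(profile, n = NULL, model = c("hill_weir",
                                                   "hyperbolic")) {
  model <- match.arg(model)
  d <- profile$bin_mid
  y <- profile$mean_r2
  w <- profile$n_pairs
  if (stats::sd(y) == 0) {
    warning("flat LD profile: decay fit is degenerate")
    return(structure(list(model = model, params = NULL, rss = NA_real_,
                          predict = function(d) rep(y[1], length(d)),
                          d_max = max(d), degenerate = TRUE),
                     class = "decay_fit"))
  }
  if (model == "hill_weir") {
    if (is.null(n)) stop("Hill-Weir fit requires the sample size n")
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ hill_weir_r2(d, c, n),
                        start = list(c = 1e-4), weights = w,
                        lower = 1e-12, upper = 10,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("decay fit failed to converge: ", conditionMessage(e),
             " (profile range ", sprintf("%.3f-%.3f", min(y), max(y)), ")"))
    cc <- stats::coef(fit)[["c"]]
    params <- list(c = cc, n = n)
    pred <- function(dd) hill_weir_r2(dd, cc, n)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + b * d),
                        start = list(a = max(y), b = 1e-5), weights = w,
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("decay fit failed to converge: ", conditionMessage(e)))
    params <- as.list(stats::coef(fit))
    pred <- function(dd) params$a / (1 + params$b * dd)
  }
  structure(list(model = model, params = params,
                 rss = sum(w * (y - pred(d))^2), predict = pred,
                 d_max = max(d), degenerate = FALSE),
            class = "decay_fit")
}

#' Distance at which the fitted LD curve reaches a threshold
#'
#' Smallest distance d with fitted r^2(d) = `threshold`, found by root
#' bisection on the monotone decreasing fitted curve. An error is raised
#' when the curve never crosses the threshold within `d_max`.
#'
#' @param fit A [fit_decay()] result.
#' @param threshold r^2 threshold (default 0.2).
#' @param d_max Upper bound of the search (default 100x the profile domain).
#' @return Distance in bp.
#' @export
decay_extent <- function(fit, threshold = 0.2, d_max = NULL) {
  if (isTRUE(fit$degenerate)) stop("extent undefined for a degenerate fit")
  if (is.null(d_max)) d_max <- 100 * fit$d_max
  f0 <- fit$predict(0)
  if (f0 < threshold)
    stop(sprintf("threshold %.3f above the curve maximum %.3f", threshold,
                 f0))
  if (f0 == threshold) return(0)
  if (fit$predict(d_max) > threshold)
    stop("fitted curve never reaches the threshold within the search domain")
  stats::uniroot(function(d) fit$predict(d) - threshold,
                 lower = 0, upper = d_max, tol = 1e-6)$root
}

#' Window-based LD pruning of sites
#'
#' Within each `window_snps`-site window, repeatedly removes the later site
#' of any pair with r^2 above `r2_max` until no such pair remains, then
#' advances by `step_snps` (plink `--indep-pairwise` semantics with a
#' deterministic later-site tie-break).
#'
#' @param positions Sorted site positions.
#' @param dosage Samples x sites dosage matrix.
#' @param window_snps,step_snps Window size and step in site counts.
#' @param r2_max Maximum allowed pairwise r^2 among kept sites in a window.
#' @return Integer indices of the kept sites.
#' @export
ld_prune <- function(positions, dosage, window_snps = 50L, step_snps = 50L,
                     r2_max = 0.5) {
  n <- length(positions)
  keep <- rep(TRUE, n)
  start <- 1L
  while (start <= n) {
    win <- start:min(n, start + window_snps - 1L)
    repeat {
      active <- win[keep[win]]
      if (length(active) < 2) break
      removed <- FALSE
      for (ii in seq_len(length(active) - 1L)) {
        for (jj in (ii + 1L):length(active)) {
          r2 <- genotype_r2(dosage[, active[ii]], dosage[, active[jj]])
          if (!is.na(r2) && r2 > r2_max) {
            keep[active[jj]] <- FALSE
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) break
    }
    if (start + window_snps - 1L >= n) break
    start <- start + step_snps
  }
  which(keep)
}
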