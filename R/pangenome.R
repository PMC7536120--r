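#' Presence-calling thresholds for assembly alignment hits
#'
#' A gene is called present in a library if its alignment hit satisfies either
#' the single-contig rule (identity and coverage both strictly greater than
#' the `single_*` thresholds) or the split rule (exons broken over 2 to
#' `max_split_contigs` contigs, identity and coverage both at least the
#' `split_*` thresholds). The boundary semantics differ deliberately: the
#' single-contig clause is strict (">"), the split clause inclusive (">="),
#' and this changes counts at exact-threshold hits.
#'
#' @param single_min_identity,single_min_coverage Strict thresholds (%) for
#'   single-contig hits.
#' @param split_min_identity,split_min_coverage Inclusive thresholds (%) for
#'   split hits.
#' @param max_split_contigs Maximum number of contigs a split hit may span.
#' @return A list of class `presence_rule`.
#' @seealso [presence_rule_within_genus()], [presence_rule_cross_genus()]
#' @export
presence_rule <- function(single_min_identity, single_min_coverage,
                          split_min_identity, split_min_coverage,
                          max_split_contigs = 3L) {
  if (split_min_identity < single_min_identity ||
      split_min_coverage < single_min_coverage)
    stop("split thresholds must be >= single-contig thresholds")
  if (max_split_contigs < 1) stop("max_split_contigs must be >= 1")
  structure(list(single_min_identity = single_min_identity,
                 single_min_coverage = single_min_coverage,
                 split_min_identity = split_min_identity,
                 split_min_coverage = split_min_coverage,
                 max_split_contigs = as.integer(max_split_contigs)),
            class = "presence_rule")
}

#' @rdname presence_rule
#' @details `presence_rule_within_genus()` is the preset for genes from the
#'   same genus as the reference (more than 85% identity and coverage on one
#'   contig, or at least 90% on up to three contigs);
#'   `presence_rule_cross_genus()` is the relaxed preset for more divergent
#'   donor genomes (more than 70% identity and 75% coverage, or at least 80%
#'   on up to three contigs).
#' @export
presence_rule_within_genus <- function() presence_rule(85, 85, 90, 90, 3L)

#' @rdname presence_rule
#' @export
presence_rule_cross_genus <- function() presence_rule(70, 75, 80, 80, 3L)

#' Call gene presence from aggregated alignment hits
#'
#' @param hits data.frame with columns `identity`, `coverage` (percent, both
#'   in \[0, 100\]) and `n_contigs` (>= 1), one row per gene x library,
#'   already aggregated over contigs. Additional id columns pass through.
#' @param rule A [presence_rule()].
#' @return `hits` with a logical `present` column appended.
#' @export
call_presence <- function(hits, rule = presence_rule_within_genus()) {
  stopifnot(inherits(rule, "presence_rule"))
  need <- c("identity", "coverage", "n_contigs")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  if (any(hits$coverage > 100 | hits$coverage < 0))
    stop("coverage outside [0, 100]")
  if (any(hits$identity > 100 | hits$identity < 0))
    stop("identity outside [0, 100]")
  if (any(hits$n_contigs < 1)) stop("n_contigs must be >= 1")
  single <- hits$n_contigs == 1 &
    hits$identity > rule$single_min_identity &
    hits$coverage > rule$single_min_coverage
  split <- hits$n_contigs >= 2 & hits$n_contigs <= rule$max_split_contigs &
    hits$identity >= rule$split_min_identity &
    hits$coverage >= rule$split_min_coverage
  hits$present <- single | split
  hits
}

#' Exclude libraries with too few genes called present
#'
#' Libraries whose present-gene count falls below `min_present` are removed;
#' such libraries likely lost genes to low coverage or poor assembly rather
#' than true absence.
#'
#' @param pav A [pav_matrix()] (genes x libraries).
#' @param min_present Minimum number of present genes to retain a library
#'   (a library with exactly `min_present` is kept).
#' @return List with `pav` (the retained subset) and `excluded` (character
#'   vector of removed library names).
#' @export
filter_libraries <- function(pav, min_present = 39000) {
  counts <- colSums(unclass(pav))
  keep <- counts >= min_present
  if (any(!keep))
    message("filter_libraries: excluded ", sum(!keep), " libraries")
  list(pav = pav_matrix(unclass(pav)[, keep, drop = FALSE]),
       excluded = colnames(pav)[!keep])
}

# Gaussian-mixture log-likelihood of a 1-D k-means solution: weights are
# cluster proportions, means the cluster centres, sds the within-cluster sds
# (floored to keep degenerate clusters finite).
.kmeans_mixture_loglik <- function(x, cluster, k) {
  n <- length(x)
  ll_comp <- matrix(-Inf, n, k)
  for (j in seq_len(k)) {
    xj <- x[cluster == j]
    w <- length(xj) / n
    sdj <- if (length(xj) > 1) stats::sd(xj) else 0
    sdj <- max(sdj, 1e-6)
    ll_comp[, j] <- log(w) + stats::dnorm(x, mean(xj), sdj, log = TRUE)
  }
  m <- apply(ll_comp, 1, max)
  sum(m + log(rowSums(exp(ll_comp - m))))
}

#' Classify genes into occupancy classes by successive k-means with BIC
#'
#' Runs 1-D k-means on per-gene occupancy for k = 1..`k_max` with `restarts`
#' seeded restarts each, and selects k by minimum BIC. The BIC used for model
#' selection is `-2 * logLik + (3k - 1) * log(n)`, where the log-likelihood is
#' that of the Gaussian mixture implied by the k-means solution (cluster
#' proportions, means and within-cluster standard deviations). The
#' within-sum-of-squares form `n * log(WSS_k / n) + k * log(n)` is also
#' computed and reported (`bic_wss`), but it is not used for selection: for
#' clustered continuous data it decreases in k without bound (splitting a
#' genuine cluster cuts its WSS by roughly a third, which outweighs the
#' `log(n)` penalty at any realistic n), so its argmin is always `k_max`.
#' Clusters are relabelled in order of decreasing mean occupancy; with k = 3
#' the labels are the conventional core, shell and cloud.
#'
#' @param occ Numeric vector of per-gene occupancies in \[0, 1\].
#' @param k_max Largest number of clusters to consider (shrunk with a warning
#'   when there are fewer distinct occupancy values).
#' @param restarts Number of random restarts per k.
#' @param seed Integer seed for the k-means restarts.
#' @return A list of class `occupancy_classification` with `labels` (per-gene
#'   class), `cluster` (per-gene integer cluster, 1 = highest occupancy),
#'   `k`, `cluster_means` (descending), `bic` (selection BIC per k) and
#'   `bic_wss` (the WSS-form trace).
#' @export
classify_occupancy <- function(occ, k_max = 6L, restarts = 20L, seed = 1L) {
  if (any(occ < 0 | occ > 1)) stop("occupancies must be in [0, 1]")
  n <- length(occ)
  n_distinct <- length(unique(occ))
  if (n_distinct < k_max) {
    warning("fewer distinct occupancy values than k_max; shrinking k_max to ",
            n_distinct)
    k_max <- n_distinct
  }
  set.seed(seed)
  fits <- vector("list", k_max)
  bic <- bic_wss <- numeric(k_max)
  for (k in seq_len(k_max)) {
    km <- if (k == 1) {
      list(cluster = rep(1L, n), centers = matrix(mean(occ)),
           tot.withinss = sum((occ - mean(occ))^2))
    } else {
      stats::kmeans(occ, centers = k, nstart = restarts, iter.max = 100L)
    }
    fits[[k]] <- km
    ll <- .kmeans_mixture_loglik(occ, km$cluster, k)
    bic[k] <- -2 * ll + (3 * k - 1) * log(n)
    bic_wss[k] <- n * log(max(km$tot.withinss, 1e-12) / n) + k * log(n)
  }
  k_star <- which.min(bic)
  km <- fits[[k_star]]
  ord <- order(as.numeric(km$centers), decreasing = TRUE)
  relabel <- integer(k_star)
  relabel[ord] <- seq_len(k_star)
  cluster <- relabel[km$cluster]
  labels_for_k <- function(k) {
    if (k == 1) "core"
    else if (k == 2) c("core", "cloud")
    else if (k == 3) c("core", "shell", "cloud")
    else c("core", paste0("shell", seq_len(k - 2)), "cloud")
  }
  lab <- labels_for_k(k_star)
  structure(list(labels = lab[cluster], cluster = cluster, k = k_star,
                 cluster_means = sort(as.numeric(km$centers),
                                      decreasing = TRUE),
                 bic = bic, bic_wss = bic_wss, n = n),
            class = "occupancy_classification")
}

#' @export
print.occupancy_classification <- function(x, ...) {
  cat("occupancy_classification:", x$n, "genes, k* =", x$k, "\n")
  cat("cluster means:", paste(sprintf("%.3f", x$cluster_means),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square critical value
#'
#' Upper critical value of the chi-square distribution, e.g. 7.81 for
#' `df = 3`, `alpha = 0.05`.
#'
#' @param df Degrees of freedom.
#' @param alpha Significance level.
#' @return The critical value.
#' @export
chisq_critical <- function(df, alpha = 0.05) stats::qchisq(1 - alpha, df)

#' Chi-square test for subpopulation over-/under-representation of genes
#'
#' For each gene, observed presence counts per subpopulation are compared
#' against expected counts proportional to subpopulation sizes:
#' `e_i = O * n_i / N` where `O` is the gene's total presence count, `n_i`
#' the subpopulation size and `N` the total number of libraries. The
#' statistic `sum((o - e)^2 / e)` on `#subpops - 1` degrees of freedom gives
#' a p-value, and Benjamini-Hochberg correction is applied across all tested
#' genes. Genes never observed (O = 0) are excluded — their expected counts
#' would all be zero — and logged via the `excluded` attribute.
#'
#' @param pav A [pav_matrix()] restricted to non-admixed libraries.
#' @param labels Named character vector mapping library name to subpopulation
#'   (names must cover the PAV columns), or an unnamed vector aligned with
#'   the columns.
#' @param alpha Significance level for the candidate flag.
#' @return data.frame (one row per tested gene) with observed and expected
#'   counts per subpopulation, `chisq`, `df`, `p`, `q` and `candidate`
#'   (chisq above the critical value); attributes `excluded` (untested gene
#'   ids), `subpop_sizes` and `critical_value`.
#' @export
chisq_enrichment <- function(pav, labels, alpha = 0.05) {
  m <- unclass(pav)
  if (!is.null(names(labels))) {
    if (!all(colnames(m) %in% names(labels)))
      stop("labels missing for some libraries")
    labels <- labels[colnames(m)]
  } else if (length(labels) != ncol(m)) {
    stop("labels must match the number of libraries")
  }
  labels <- as.character(labels)
  subpops <- sort(unique(labels))
  if (length(subpops) < 2) stop("need >= 2 subpopulations")
  n_i <- vapply(subpops, function(s) sum(labels == s), 0L)
  if (any(n_i == 0)) stop("empty subpopulation")
  N <- sum(n_i)
  obs <- t(rowsum(t(m), group = labels))  # genes x subpops, sorted groups
  obs <- obs[, subpops, drop = FALSE]
  O <- rowSums(obs)
  tested <- O > 0
  excluded <- rownames(m)[!tested]
  if (length(excluded))
    message("chisq_enrichment: excluded ", length(excluded),
            " genes with zero observations")
  obs_t <- obs[tested, , drop = FALSE]
  O_t <- O[tested]
  exp_t <- outer(O_t, n_i / N)
  chisq <- rowSums((obs_t - exp_t)^2 / exp_t)
  df <- length(subpops) - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  crit <- chisq_critical(df, alpha)
  out <- data.frame(gene = rownames(m)[tested],
                    obs_t, exp_t,
                    chisq = chisq, df = df, p = p, q = q,
                    candidate = chisq > crit,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:(1 + df + 1)] <- paste0("obs_", subpops)
  names(out)[(2 + df + 1):(2 + 2 * df + 1)] <- paste0("exp_", subpops)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "subpop_sizes") <- n_i
  attr(out, "critical_value") <- crit
  out
}

#' Genes private to a single subpopulation
#'
#' A gene is private to subpopulation s when its within-s presence frequency
#' strictly exceeds `min_freq` while its frequency in every other
#' subpopulation is at most `tol` (strict absence under the default
#' `tol = 0`).
#'
#' @param pav A [pav_matrix()].
#' @param labels Subpopulation labels as in [chisq_enrichment()].
#' @param min_freq Strict lower bound on within-subpopulation frequency.
#' @param tol Maximum allowed frequency outside the focal subpopulation.
#' @return data.frame with `gene`, `subpop` and `freq`.
#' @export
private_genes <- function(pav, labels, min_freq = 0.1, tol = 0) {
  m <- unclass(pav)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- as.character(labels)
  subpops <- sort(unique(labels))
  n_i <- vapply(subpops, function(s) sum(labels == s), 0L)
  freq <- t(rowsum(t(m), group = labels))[, subpops, drop = FALSE]
  freq <- sweep(freq, 2, n_i, "/")
  out <- do.call(rbind, lapply(seq_along(subpops), function(j) {
    others <- freq[, -j, drop = FALSE]
    hit <- freq[, j] > min_freq & apply(others <= tol, 1, all)
    if (!any(hit)) return(NULL)
    data.frame(gene = rownames(m)[hit], subpop = subpops[j],
               freq = freq[hit, j], stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(gene = character(), subpop = character(),
                      freq = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Jaccard distance between binary presence profiles
#'
#' `d(a, b) = 1 - |intersection| / |union|` over presence profiles. A pair of
#' all-absent profiles has an undefined union; by convention its distance is
#' 0, with a warning.
#'
#' @param m Binary matrix; profiles are columns (e.g. libraries of a PAV or
#'   SV presence matrix).
#' @return Symmetric matrix of Jaccard distances with zero diagonal.
#' @export
jaccard_distance <- function(m) {
  m <- unclass(as.matrix(m))
  if (any(!(m %in% c(0, 1)))) stop("profiles must be binary")
  storage.mode(m) <- "numeric"
  inter <- crossprod(m)
  sizes <- colSums(m)
  union <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / union
  if (any(union == 0)) {
    warning("profile pair(s) with empty union: distance set to 0")
    d[union == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}
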