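#' Specification of one occupancy class for PAV simulation
#'
#' Per-gene occupancy within a class is drawn from a Beta distribution with
#' the given mean and concentration (alpha + beta); presence is then Bernoulli
#' per library. A concentration around 200 gives tight unimodal classes like
#' empirically observed core/shell/cloud occupancy clusters.
#'
#' @param n_genes Number of genes in the class.
#' @param mean_occupancy Class mean occupancy, in (0, 1]. A mean of exactly 1
#'   is the degenerate core limit: every gene present in every library.
#' @param concentration Beta concentration parameter (alpha + beta), > 0.
#' @param label Class label recorded in the truth table.
#' @return A list of class `pav_class_spec`.
#' @export
pav_class_spec <- function(n_genes, mean_occupancy, concentration = 200,
                           label = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (mean_occupancy <= 0 || mean_occupancy > 1)
    stop("mean_occupancy must be in (0, 1]")
  if (concentration <= 0) stop("concentration must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 mean_occupancy = mean_occupancy,
                 concentration = concentration,
                 label = label %||% sprintf("class_%.2f", mean_occupancy)),
            class = "pav_class_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic PAV matrix with known occupancy classes
#'
#' Draws a genes x libraries presence/absence matrix from a Beta-Bernoulli
#' model: each gene gets a latent occupancy from its class's Beta
#' distribution, then presence is sampled independently per library. Library
#' columns carry subpopulation labels, enabling enrichment analyses; by
#' default genes are exchangeable across subpopulations (the enrichment null).
#'
#' @param specs List of [pav_class_spec()] objects, one per occupancy class.
#' @param n_libraries Number of libraries (columns).
#' @param subpop_sizes Named integer vector of subpopulation sizes; must sum
#'   to `n_libraries`.
#' @param seed Integer seed; the output is a pure function of
#'   (parameters, seed).
#' @return List with `pav` (a [pav_matrix()]), `truth` (data.frame of gene,
#'   class label and latent occupancy) and `labels` (per-library subpopulation
#'   assignment).
#' @export
gen_pav_matrix <- function(specs, n_libraries, subpop_sizes = NULL,
                           seed = 1L) {
  if (inherits(specs, "pav_class_spec")) specs <- list(specs)
  if (is.null(subpop_sizes)) subpop_sizes <- c(all = n_libraries)
  if (is.null(names(subpop_sizes)))
    names(subpop_sizes) <- paste0("pop", seq_along(subpop_sizes))
  if (sum(subpop_sizes) != n_libraries)
    stop("subpop_sizes must sum to n_libraries")
  set.seed(seed)
  rows <- lapply(specs, function(sp) {
    p <- if (sp$mean_occupancy == 1) rep(1, sp$n_genes) else
      stats::rbeta(sp$n_genes, sp$mean_occupancy * sp$concentration,
                   (1 - sp$mean_occupancy) * sp$concentration)
    m <- matrix(stats::rbinom(sp$n_genes * n_libraries, 1L,
                              rep(p, times = n_libraries)),
                nrow = sp$n_genes, ncol = n_libraries)
    list(m = m, p = p, label = sp$label)
  })
  pav <- do.call(rbind, lapply(rows, `[[`, "m"))
  rownames(pav) <- sprintf("gene%05d", seq_len(nrow(pav)))
  labels <- rep(names(subpop_sizes), times = subpop_sizes)
  colnames(pav) <- sprintf("lib%03d_%s", seq_len(n_libraries), labels)
  names(labels) <- colnames(pav)
  truth <- data.frame(
    gene = rownames(pav),
    class = rep(vapply(rows, `[[`, "", "label"),
                times = vapply(rows, function(r) nrow(r$m), 0L)),
    occupancy = unlist(lapply(rows, `[[`, "p")),
    stringsAsFactors = FALSE)
  list(pav = pav_matrix(pav), truth = truth, labels = labels)
}

.transitions <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

# Apply n_sub substitution events to a sequence (character vector of bases),
# transition:transversion opportunity ratio kappa:1. Sites are drawn with
# replacement so multiple hits are possible, as in a real clock.
.mutate_seq <- function(x, n_sub, kappa) {
  if (n_sub == 0L) return(x)
  sites <- sample.int(length(x), n_sub, replace = TRUE)
  p_ts <- if (is.infinite(kappa)) 1 else kappa / (kappa + 2)
  for (s in sites) {
    base <- x[s]
    if (stats::runif(1) < p_ts) x[s] <- .transitions[[base]]
    else x[s] <- sample(.transversions[[base]], 1L)
  }
  x
}

#' Simulate a retrotransposon family diverging from a single burst
#'
#' One ancestral element (with two identical LTRs at its ends) proliferates at
#' a burst `burst_age` years ago; each copy then accumulates substitutions
#' independently under a Kimura two-parameter-compatible clock: the number of
#' events is Poisson(`burst_age * mu * element_length`) and each event is a
#' transition with probability `kappa / (kappa + 2)`. Expected pairwise
#' divergence between copies is therefore `2 * burst_age * mu` per site, the
#' quantity the K2P estimator targets.
#'
#' @param n_copies Number of element copies.
#' @param element_length Element length in bp; must be >= `2 * ltr_length`.
#' @param burst_age Burst age in years (>= 0).
#' @param mu Substitution rate per bp per year (> 0).
#' @param kappa Transition:transversion ratio (> 0; `Inf` = transitions only).
#' @param ltr_length Length of each terminal repeat in bp.
#' @param seed Integer seed.
#' @return List with `elements` (named character vector of copy sequences),
#'   `ltrs` (named character vector, two LTRs per copy, suffixes `_LTR5` and
#'   `_LTR3`), `ancestor` and the generating parameters.
#' @export
gen_te_family <- function(n_copies, element_length, burst_age, mu,
                          kappa = 2, ltr_length = 451, seed = 1L) {
  if (mu <= 0) stop("mu must be > 0")
  if (burst_age < 0) stop("burst_age must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (element_length < 2 * ltr_length)
    stop("element_length must be >= 2 * ltr_length")
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), element_length, replace = TRUE)
  anc[(element_length - ltr_length + 1):element_length] <- anc[1:ltr_length]
  copies <- vector("list", n_copies)
  for (i in seq_len(n_copies)) {
    n_sub <- stats::rpois(1L, burst_age * mu * element_length)
    copies[[i]] <- .mutate_seq(anc, n_sub, kappa)
  }
  ids <- sprintf("copy%02d", seq_len(n_copies))
  elements <- vapply(copies, paste0, "", collapse = "")
  names(elements) <- ids
  ltrs <- unlist(lapply(seq_len(n_copies), function(i) {
    x <- copies[[i]]
    out <- c(paste0(x[1:ltr_length], collapse = ""),
             paste0(x[(element_length - ltr_length + 1):element_length],
                    collapse = ""))
    names(out) <- paste0(ids[i], c("_LTR5", "_LTR3"))
    out
  }))
  list(elements = elements, ltrs = ltrs,
       ancestor = paste0(anc, collapse = ""),
       burst_age = burst_age, mu = mu, kappa = kappa,
       ltr_length = ltr_length)
}

#' Generate haplotypes containing a planted partial hard sweep
#'
#' Background haplotypes carry independent sites with per-site derived-allele
#' frequencies uniform on (0.05, 0.95). A fraction `core_freq` of haplotypes
#' (the carriers) share the derived allele at the core site, and across
#' `sweep_width_bp` around the core all carriers share one identical
#' haplotype — a hard sweep in its extreme form, which gives the carriers
#' EHH = 1 over the swept interval by construction.
#'
#' @param n_hap Number of haplotypes.
#' @param n_snps Number of segregating sites.
#' @param region_bp Length of the simulated region in bp; the core site is
#'   the site closest to the midpoint.
#' @param core_freq Derived-allele frequency at the core, in (0, 1).
#' @param sweep_width_bp Width of the swept interval centred on the core
#'   (0 = no shared flanking haplotype).
#' @param seed Integer seed.
#' @return List with `haps` (a [haplotype_set()]), `core_site` (site index),
#'   `core_pos`, and `carriers` (haplotype indices carrying the sweep).
#' @export
gen_sweep_haplotypes <- function(n_hap, n_snps, region_bp = 1e6,
                                 core_freq = 0.3, sweep_width_bp = 2e5,
                                 seed = 1L) {
  if (core_freq <= 0 || core_freq >= 1) stop("core_freq must be in (0, 1)")
  set.seed(seed)
  positions <- sort(sample.int(region_bp, n_snps))
  freqs <- stats::runif(n_snps, 0.05, 0.95)
  alleles <- matrix(stats::rbinom(n_hap * n_snps, 1L,
                                  rep(freqs, each = n_hap)),
                    nrow = n_hap, ncol = n_snps)
  core_site <- which.min(abs(positions - region_bp / 2))
  n_car <- max(2L, round(core_freq * n_hap))
  carriers <- sample.int(n_hap, n_car)
  alleles[, core_site] <- 0L
  alleles[carriers, core_site] <- 1L
  if (sweep_width_bp > 0) {
    lo <- positions[core_site] - sweep_width_bp / 2
    hi <- positions[core_site] + sweep_width_bp / 2
    swept <- which(positions >= lo & positions <= hi &
                     seq_len(n_snps) != core_site)
    if (length(swept)) {
      shared <- stats::rbinom(length(swept), 1L, freqs[swept])
      alleles[carriers, swept] <- matrix(shared, nrow = n_car,
                                         ncol = length(swept), byrow = TRUE)
    }
  }
  list(haps = haplotype_set(positions, alleles),
       core_site = core_site, core_pos = positions[core_site],
       carriers = sort(carriers))
}

#' Generate haplotypes with distance-decaying linkage disequilibrium
#'
#' Haplotype-copying process: ten founder haplotypes are drawn from
#' independent per-site frequencies; each subsequent haplotype copies a
#' uniformly chosen existing haplotype, switching to a new uniformly chosen
#' template between adjacent sites with probability
#' `1 - exp(-switch_prob_per_bp * d)` where `d` is the inter-site distance.
#' Mean r^2 between sites therefore decreases with physical distance; with
#' `switch_prob_per_bp = 0` every haplotype is an exact founder copy and LD
#' is flat.
#'
#' @param n_hap Number of haplotypes.
#' @param n_snps Number of sites, evenly spaced `spacing_bp` apart.
#' @param spacing_bp Distance between adjacent sites in bp.
#' @param switch_prob_per_bp Template-switch rate per bp.
#' @param seed Integer seed.
#' @return A [haplotype_set()].
#' @export
gen_ld_haplotypes <- function(n_hap, n_snps, spacing_bp = 1000,
                              switch_prob_per_bp = 1e-4, seed = 1L) {
  set.seed(seed)
  positions <- seq_len(n_snps) * spacing_bp
  freqs <- stats::runif(n_snps, 0.1, 0.9)
  n_founders <- min(10L, n_hap)
  alleles <- matrix(NA_integer_, n_hap, n_snps)
  for (i in seq_len(n_founders))
    alleles[i, ] <- stats::rbinom(n_snps, 1L, freqs)
  p_switch <- 1 - exp(-switch_prob_per_bp * spacing_bp)
  if (n_hap > n_founders) {
    for (i in (n_founders + 1L):n_hap) {
      tmpl <- sample.int(i - 1L, 1L)
      row <- integer(n_snps)
      row[1] <- alleles[tmpl, 1]
      switches <- stats::runif(n_snps - 1L) < p_switch
      for (j in 2:n_snps) {
        if (switches[j - 1L]) tmpl <- sample.int(i - 1L, 1L)
        row[j] <- alleles[tmpl, j]
      }
      alleles[i, ] <- row
    }
  }
  haplotype_set(positions, alleles)
}

#' Generate paired-end read coordinates around an element insertion site
#'
#' Produces a read-pair coordinate table in the coordinate frame of the
#' insertion-bearing reference. With `insertion_present = TRUE`, half the
#' pairs span the left junction (one read left of the junction, mate inside
#' the element) and half span the right junction; with
#' `insertion_present = FALSE` the pairs jump across the element interval,
#' i.e. they span the empty site.
#'
#' @param insertion_present Logical; is the element present in the sampled
#'   genome?
#' @param n_pairs Number of read pairs.
#' @param read_len Read length in bp.
#' @param insert_size Outer distance between the reads of a pair.
#' @param left_junction,right_junction 1-based positions of the element's two
#'   junction points on the insertion-bearing reference
#'   (`right_junction > left_junction`).
#' @param seed Integer seed.
#' @return data.frame with columns `pair`, `start1`, `end1`, `start2`, `end2`.
#' @export
gen_read_pairs_over_junction <- function(insertion_present, n_pairs,
                                         read_len = 100, insert_size = 400,
                                         left_junction = 5000,
                                         right_junction = 11500, seed = 1L) {
  if (right_junction <= left_junction)
    stop("right_junction must exceed left_junction")
  set.seed(seed)
  if (n_pairs == 0L)
    return(data.frame(pair = character(), start1 = numeric(),
                      end1 = numeric(), start2 = numeric(),
                      end2 = numeric(), stringsAsFactors = FALSE))
  gap <- insert_size - 2 * read_len
  if (gap < 2) stop("insert_size too small for read_len")
  start1 <- end1 <- start2 <- end2 <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (insertion_present) {
      j <- if (i %% 2 == 1) left_junction else right_junction
      off <- sample.int(gap - 1L, 1L)
      if (i %% 2 == 1) {
        # read 1 fully left of the left junction, mate inside the element
        end1[i] <- j - off
        start1[i] <- end1[i] - read_len + 1
        start2[i] <- end1[i] + gap + 1
        end2[i] <- start2[i] + read_len - 1
      } else {
        # read 1 inside the element, mate fully right of the right junction
        end1[i] <- j - off
        start1[i] <- end1[i] - read_len + 1
        start2[i] <- end1[i] + gap + 1
        end2[i] <- start2[i] + read_len - 1
      }
    } else {
      # element absent: the pair maps across the whole element interval
      off <- sample.int(gap - 1L, 1L)
      end1[i] <- left_junction - off
      start1[i] <- end1[i] - read_len + 1
      start2[i] <- right_junction + (gap - off) + 1
      end2[i] <- start2[i] + read_len - 1
    }
  }
  data.frame(pair = sprintf("pair%04d", seq_len(n_pairs)),
             start1 = start1, end1 = end1, start2 = start2, end2 = end2,
             stringsAsFactors = FALSE)
}
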