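#' Bonferroni-corrected per-test significance threshold
#'
#' `alpha / n_tests`; e.g. a 0.05 family-wise level over 8.58 million SNP
#' tests gives a per-marker threshold of about 5.8e-9.
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests.
#' @return Per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

# Deterministic provenance block written beside every pipeline output.
.write_provenance <- function(dir, config, seed) {
  lines <- c(
    paste0("seed\t", seed),
    paste0("pavpop_version\t",
           as.character(utils::packageVersion("pavpop"))),
    paste0("config_hash\t",
           sum(utf8ToInt(paste(deparse(config), collapse = "")))),
    vapply(names(config), function(nm)
      paste0(nm, "\t", paste(deparse(config[[nm]]), collapse = " ")), ""))
  writeLines(lines, file.path(dir, "provenance.tsv"))
}

#' Run the pan-genome classification and enrichment analysis
#'
#' Generates (or accepts) a PAV matrix, applies the library presence filter,
#' classifies gene occupancy into core/shell/cloud by successive k-means with
#' BIC, tests subpopulation over-/under-representation per gene, and collects
#' private genes. All tables are written as TSV under `out_dir` together
#' with a provenance block.
#'
#' @param config List with elements `out_dir`, `seed`, and either `pav` +
#'   `labels` (a [pav_matrix()] and subpopulation labels) or synthetic
#'   generation settings `specs` (list of [pav_class_spec()]), `n_libraries`,
#'   `subpop_sizes`. Optional: `min_present` (library filter, default 0 for
#'   synthetic data), `k_max`, `alpha`, `min_freq`.
#' @return List with `classification`, `enrichment`, `private`, `truth`
#'   (when synthetic), invisibly.
#' @export
run_pangenome <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$pav)) {
    gen <- gen_pav_matrix(config$specs, config$n_libraries,
                          config$subpop_sizes, seed = config$seed)
    pav <- gen$pav
    labels <- gen$labels
    truth <- gen$truth
  } else {
    pav <- config$pav
    labels <- config$labels
    truth <- NULL
  }
  if (nrow(pav) == 0 || ncol(pav) == 0)
    stop("pangenome stage 'classification' failed: empty PAV matrix")
  flt <- filter_libraries(pav, min_present = config$min_present %||% 0)
  pav <- flt$pav
  cls <- classify_occupancy(occupancy(pav), k_max = config$k_max %||% 6L,
                            seed = config$seed)
  enr <- chisq_enrichment(pav, labels[colnames(pav)],
                          alpha = config$alpha %||% 0.05)
  priv <- private_genes(pav, labels[colnames(pav)],
                        min_freq = config$min_freq %||% 0.1)
  cls_df <- data.frame(gene = rownames(pav), occupancy = occupancy(pav),
                       cluster = cls$cluster, label = cls$labels,
                       stringsAsFactors = FALSE)
  write_table(cls_df, file.path(config$out_dir, "classification.tsv"))
  write_table(enr, file.path(config$out_dir, "enrichment.tsv"))
  write_table(priv, file.path(config$out_dir, "private_genes.tsv"))
  .write_provenance(config$out_dir,
                    config[setdiff(names(config), c("pav", "labels"))],
                    config$seed)
  invisible(list(classification = cls, class_table = cls_df,
                 enrichment = enr, private = priv, truth = truth,
                 excluded_libraries = flt$excluded))
}

#' Run the windowed selection scan on planted-sweep haplotypes
#'
#' Generates haplotypes with a planted partial sweep, computes per-window pi
#' and Tajima's D (non-overlapping windows) and the sliding-window fraction
#' of extreme |iHS|, and flags outlier windows in the appropriate tails.
#'
#' @param config List with `out_dir`, `seed`, and optional overrides:
#'   `n_hap`, `n_snps`, `region_bp`, `core_freq`, `sweep_width_bp`,
#'   `ihs_window_bp` (default 100000), `ihs_step_bp` (default 10000),
#'   `tajima_window_bp` (default 10000), `cutoff`, `fraction`, `min_snps`.
#' @return List with `windows_tajima`, `windows_ihs`, `ihs_records`,
#'   `sweep_truth`, invisibly.
#' @export
run_selection <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- gen_sweep_haplotypes(config$n_hap %||% 200L,
                             config$n_snps %||% 400L,
                             config$region_bp %||% 1e6,
                             config$core_freq %||% 0.3,
                             config$sweep_width_bp %||% 2e5,
                             seed = config$seed)
  haps <- gs$haps
  cnt <- allele_counts(haps)
  n_hap <- nrow(haps$alleles)

  twin <- config$tajima_window_bp %||% 10000
  tstarts <- seq(0, max(cnt$positions) - 1, by = twin)
  taj <- data.frame(start = tstarts, end = tstarts + twin,
                    n_snps = NA_integer_, pi = NA_real_, D = NA_real_)
  for (i in seq_along(tstarts)) {
    sel <- cnt$positions > taj$start[i] & cnt$positions <= taj$end[i]
    seg <- cnt$c1[sel] > 0 & cnt$c1[sel] < cnt$n[sel]
    taj$n_snps[i] <- sum(seg)
    taj$pi[i] <- window_pi(cnt$positions, cnt$c1, cnt$n,
                           taj$start[i], taj$end[i])
    taj$D[i] <- tajima_d(sum(seg), sum(site_pi(cnt$c1[sel], cnt$n[sel])),
                         n_hap)
  }
  taj$value <- taj$D
  taj <- outlier_windows(taj, tail = "lower",
                         fraction = config$fraction %||% 0.01)

  ihs <- ihs_scan(haps, cutoff = config$cutoff %||% 0.05)
  wins <- scan_windows(ihs$pos, ihs$ihs,
                       window_bp = config$ihs_window_bp %||% 100000,
                       step_bp = config$ihs_step_bp %||% 10000,
                       stat = "fraction_extreme", threshold = 2,
                       min_snps = config$min_snps %||% 10L)
  wins <- outlier_windows(wins, tail = "upper",
                          fraction = config$fraction %||% 0.01)

  write_table(taj[, c("start", "end", "n_snps", "pi", "D", "outlier")],
              file.path(config$out_dir, "tajima_windows.tsv"))
  write_table(wins, file.path(config$out_dir, "ihs_windows.tsv"))
  write_table(ihs[, c("site", "pos", "daf", "uihs", "ihs")],
              file.path(config$out_dir, "ihs_records.tsv"))
  .write_provenance(config$out_dir, config, config$seed)
  invisible(list(windows_tajima = taj, windows_ihs = wins,
                 ihs_records = ihs,
                 sweep_truth = gs[c("core_site", "core_pos", "carriers")]))
}

#' Run the domestication-sweep calibration and pi-ratio test
#'
#' Calibrates the bottleneck severity to the genome-wide diversity ratio,
#' re-simulates fresh windows to verify the calibration, and computes the
#' empirical p-value for an observed window ratio.
#'
#' @param config List with `out_dir`, `seed`, `target_ratio` (default 0.22),
#'   `observed_ratio` (default 0.06), and optional `bottleneck_start`,
#'   `bottleneck_duration`, `n`, `theta`, `calib_reps`, `test_reps`,
#'   `fresh_reps`.
#' @return List with `calibration`, `fresh_ratio`, `test`, invisibly.
#' @export
run_sweep <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- calibrate_bottleneck(
    config$target_ratio %||% 0.22,
    bottleneck_start = config$bottleneck_start %||% 0.08,
    bottleneck_duration = config$bottleneck_duration %||% 0.04,
    n = config$n %||% 20L, theta = config$theta %||% 20,
    reps = config$calib_reps %||% 2000L, seed = config$seed)
  fresh <- config$fresh_reps %||% 1000L
  bot <- simulate_coalescent(cal$n, cal$demography, cal$theta, fresh,
                             seed = config$seed + 1L)
  con <- simulate_coalescent(cal$n, demography(0, 1), cal$theta, fresh,
                             seed = config$seed + 2L)
  fresh_ratio <- mean(bot$pi) / mean(con$pi)
  test <- pi_ratio_test(config$observed_ratio %||% 0.06, cal$demography,
                        n = cal$n, theta = cal$theta,
                        reps = config$test_reps %||% 10000L,
                        seed = config$seed + 3L)
  out <- data.frame(
    quantity = c("calibrated_severity", "achieved_ratio", "fresh_ratio",
                 "observed_ratio", "empirical_p"),
    value = c(cal$severity, cal$achieved_ratio, fresh_ratio,
              config$observed_ratio %||% 0.06, test$p))
  write_table(out, file.path(config$out_dir, "sweep_test.tsv"))
  .write_provenance(config$out_dir, config, config$seed)
  invisible(list(calibration = cal, fresh_ratio = fresh_ratio, test = test))
}
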