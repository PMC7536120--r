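test_that("window pi equals the brute-force pairwise oracle", {
  # one site, two haplotypes differing, 10-bp window
  expect_equal(window_pi(5L, c1 = 1, n = 2, start = 0, end = 10), 0.1)
  # empty window
  expect_equal(window_pi(integer(), numeric(), numeric(), 0, 10), 0)

  set.seed(21)
  for (rep in 1:20) {
    n_hap <- sample(4:20, 1)
    n_site <- sample(5:50, 1)
    L <- 1000
    a <- matrix(rbinom(n_hap * n_site, 1, runif(1, 0.1, 0.9)), n_hap)
    pos <- sort(sample(L, n_site))
    # brute force: mean pairwise differences over all haplotype pairs / L
    pairs <- utils::combn(n_hap, 2)
    bf <- mean(apply(pairs, 2, function(p) sum(a[p[1], ] != a[p[2], ]))) / L
    expect_equal(window_pi(pos, colSums(a), n_hap, 0, L), bf,
                 tolerance = 1e-12)
  }
})

test_that("Tajima constants and D match closed forms and the worked value", {
  c2_ <- tajima_constants(2)
  expect_equal(c2_$a1, 1)
  expect_equal(c2_$a2, 1)
  expect_equal(c2_$c1, 0)
  expect_equal(c2_$e1, 0)

  # independent oracle: raw definitional sums for n = 10
  n <- 10
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  ct <- tajima_constants(10)
  expect_equal(ct$a1, a1, tolerance = 1e-12)
  expect_equal(ct$a1, 2.828968, tolerance = 1e-6)
  expect_equal(ct$e1, c1 / a1, tolerance = 1e-12)
  expect_equal(ct$e1, 0.019061, tolerance = 1e-4)
  expect_equal(ct$e2, c2 / (a1^2 + a2), tolerance = 1e-12)
  expect_equal(ct$e2, 0.004949, tolerance = 1e-4)

  expect_equal(tajima_d(16, 16 / a1, 10), 0, tolerance = 1e-12)
  expect_true(is.na(tajima_d(0, 0, 10)))
  D <- (3 - 16 / a1) / sqrt(ct$e1 * 16 + ct$e2 * 16 * 15)
  expect_equal(tajima_d(16, 3.0, 10), D, tolerance = 1e-12)
  expect_equal(tajima_d(16, 3.0, 10), -2.1737, tolerance = 1e-4)
  expect_error(tajima_d(5, 1, 3), "n >= 4")
})

test_that("neutral coalescent windows have near-zero mean Tajima's D", {
  sim <- simulate_coalescent(20, theta = 10, reps = 1000, seed = 31)
  D <- vapply(seq_len(nrow(sim)), function(i)
    tajima_d(sim$S[i], sim$pi[i], 20), 0)
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.3)
})

test_that("EHH is 1 at the core, combinatorially correct, and monotone", {
  # 4 carriers splitting 2 + 2 at the next marker: EHH = 2 C(2,2) / C(4,2)
  a <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1), c(1, 1, 0),
             c(0, 0, 0), c(0, 1, 1))
  hs <- haplotype_set(c(10, 20, 30), a)
  e <- ehh(hs, 1L, 1L, "right")
  expect_equal(e$ehh[1], 1)
  expect_equal(e$ehh[2], 2 / 6, tolerance = 1e-12)
  expect_error(ehh(hs, 2L, 1L), NA)
  expect_error(ehh(haplotype_set(c(1, 2), rbind(c(1, 0), c(0, 0))), 1L, 1L),
               "carriers")

  # identical carriers keep EHH at exactly 1
  b <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(0, 0, 1, 0), c(0, 1, 1, 0))
  eb <- ehh(haplotype_set(c(1, 5, 9, 15), b), 1L, 1L, "right")
  expect_true(all(eb$ehh == 1))

  # monotone non-increasing on random haplotypes, both directions
  set.seed(41)
  for (rep in 1:10) {
    m <- matrix(rbinom(30 * 20, 1, 0.5), 30)
    hs2 <- haplotype_set(sort(sample(10000, 20)), m)
    core <- sample(20, 1)
    for (dir in c("left", "right")) {
      allele <- if (sum(m[, core]) >= 2) 1L else 0L
      cv <- ehh(hs2, core, allele, dir)
      expect_true(all(diff(cv$ehh) <= 1e-12))
    }
  }
})

test_that("iHS sign convention, symmetry, and degenerate cutoffs behave", {
  # mirror-image haplotype structure for the two alleles: iHS = 0.
  # Rows 1-4 carry the derived core allele, rows 5-8 the ancestral one;
  # both groups have identical flanking partitions.
  block <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 1), c(0, 1, 1))
  a <- cbind(rbind(block, block),
             c(1, 1, 1, 1, 0, 0, 0, 0),
             rbind(block, block))
  hs <- haplotype_set(seq_len(7) * 100, a)
  rec <- ihs_unstandardized(hs, 4L, cutoff = 0.3)
  expect_false(is.na(rec$uihs))
  expect_equal(rec$uihs, 0, tolerance = 1e-12)

  gs <- gen_sweep_haplotypes(120, 300, 1e6, 0.35, 2e5, seed = 13)
  rec2 <- ihs_unstandardized(gs$haps, gs$core_site)
  expect_lt(rec2$uihs, 0)  # sweep on the derived allele: iHH_D > iHH_A
  expect_gt(rec2$ihh_d, rec2$ihh_a)

  expect_error(ihs_unstandardized(gs$haps, gs$core_site, cutoff = 1.0),
               "cutoff")
  mono <- haplotype_set(c(1, 2), rbind(c(1, 1), c(1, 0), c(1, 0), c(1, 1)))
  expect_error(ihs_unstandardized(mono, 1L), "monomorphic")
})

test_that("iHS standardization centres and scales within frequency bins", {
  set.seed(51)
  recs <- data.frame(daf = runif(500, 0.05, 0.95),
                     uihs = rnorm(500, mean = 3, sd = 2))
  recs$uihs <- recs$uihs + recs$daf * 5  # frequency-dependent raw mean
  std <- standardize_ihs(recs, n_bins = 10, min_per_bin = 20)
  for (b in unique(std$bin)) {
    x <- std$ihs[std$bin == b]
    expect_lt(abs(mean(x)), 1e-12)
    expect_equal(stats::sd(x), 1, tolerance = 1e-12)
  }
  # single bin: overall mean 0, sd 1
  std1 <- standardize_ihs(recs, n_bins = 1)
  expect_lt(abs(mean(std1$ihs)), 1e-12)
  expect_equal(stats::sd(std1$ihs), 1, tolerance = 1e-12)
  # under-filled bins are merged
  few <- data.frame(daf = c(rep(0.1, 30), rep(0.9, 5)),
                    uihs = rnorm(35))
  stdf <- standardize_ihs(few, n_bins = 10, min_per_bin = 20)
  expect_lte(length(unique(stdf$bin)), 2L)
})

test_that("neutral standardized iHS has a normal-sized extreme tail", {
  haps <- gen_ld_haplotypes(200, 600, spacing_bp = 2000,
                            switch_prob_per_bp = 1e-4, seed = 8)
  ihs <- suppressMessages(ihs_scan(haps))
  frac <- mean(abs(ihs$ihs) > 2, na.rm = TRUE)
  expect_lt(abs(frac - 0.046), 0.02)
})

test_that("window scans tile correctly and flag planted outliers", {
  # 4 of 10 SNPs extreme in one window
  w <- scan_windows(positions = seq(1000, 10000, by = 1000),
                    values = c(2.5, -2.5, 2.1, 3, rep(0, 6)),
                    window_bp = 10000, step_bp = 10000, min_snps = 5)
  expect_equal(w$value[1], 0.4)
  # sparse window reported as NA
  w2 <- scan_windows(seq(1000, 10000, by = 1000), rep(1, 10),
                     window_bp = 5000, step_bp = 5000, min_snps = 10)
  expect_true(all(is.na(w2$value)))
  # tiling: away from edges every SNP falls in window_bp/step_bp windows
  pos <- seq(150000, 250000, by = 1000)
  w3 <- scan_windows(pos, rep(0, length(pos)), window_bp = 100000,
                     step_bp = 10000, min_snps = 1)
  covers <- vapply(pos, function(p)
    sum(w3$start < p & p <= w3$end), 0)
  expect_true(all(covers == 10))

  # outliers: unique minimum flagged in the lower tail
  st <- data.frame(value = c(5, 1, 3, 4, 2, 6, 7, 8, 9, 10))
  expect_equal(which(outlier_windows(st, "lower", 0.1)$outlier), 2L)
  expect_warning(out_t <- outlier_windows(data.frame(value = rep(1, 10)),
                                          "lower", 0.1), "ties")
  expect_true(all(out_t$outlier))

  # planted sweep: core-containing window flagged in the upper tail
  gs <- gen_sweep_haplotypes(200, 400, 1e6, 0.3, 2e5, seed = 4)
  scan <- suppressMessages(ihs_scan(gs$haps))
  wins <- scan_windows(scan$pos, scan$ihs, stat = "fraction_extreme")
  out <- outlier_windows(wins, tail = "upper", fraction = 0.05)
  fl <- out[out$outlier, ]
  expect_true(any(fl$start < gs$core_pos & gs$core_pos <= fl$end))
})
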