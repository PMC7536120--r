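test_that("genotype r2: worked values, symmetry, label invariance, missing data", {
  expect_equal(genotype_r2(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1)
  expect_equal(genotype_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_equal(genotype_r2(c(0, 1, 2, 2, NA), c(0, 1, 2, 2, 0)), 1)
  expect_true(is.na(genotype_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(61)
  for (i in 1:20) {
    a <- sample(0:2, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    r <- genotype_r2(a, b)
    expect_equal(r, genotype_r2(b, a))
    expect_equal(r, genotype_r2(2 - a, b))
  }
})

test_that("bp thinning is greedy and respects the spacing postcondition", {
  expect_equal(thin_by_bp(c(100, 150, 250), 100), c(1L, 3L))
  expect_equal(thin_by_bp(c(100, 150, 250), 0), 1:3)
  set.seed(62)
  for (i in 1:10) {
    pos <- sort(sample(1e5, 200))
    kept <- thin_by_bp(pos, 100)
    expect_true(all(diff(pos[kept]) >= 100))
    # greedy maximality: every dropped site is within 100 bp of a kept one
    dropped <- setdiff(seq_along(pos), kept)
    if (length(dropped))
      expect_true(all(vapply(dropped, function(d)
        min(abs(pos[d] - pos[kept])) < 100, TRUE)))
  }
})

test_that("LD profile bins pairs and respects the window rules", {
  dos <- matrix(sample(0:2, 40, replace = TRUE), 20, 2)
  prof <- ld_profile(c(100, 250), dos, bin_bp = 100)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$bin_start, 100)  # left-closed bin [100, 200)
  expect_equal(prof$n_pairs, 1L)

  # pairs beyond max_bp are excluded
  dos3 <- matrix(sample(0:2, 60, replace = TRUE), 20, 3)
  prof2 <- ld_profile(c(1, 1000, 2001002), dos3, max_bp = 2e6, bin_bp = 100)
  expect_false(any(prof2$bin_start >= 2e6))
  expect_error(ld_profile(c(1), dos[, 1, drop = FALSE]), "pairs")

  # decay profile from the LD generator is non-increasing after smoothing
  haps <- gen_ld_haplotypes(200, 600, 1000, 1e-4, seed = 2)
  dos_h <- haps$alleles[seq(1, 199, 2), ] + haps$alleles[seq(2, 200, 2), ]
  prof3 <- suppressMessages(
    ld_profile(haps$positions, dos_h, max_pairs_window = 150,
               max_bp = 1.5e5, bin_bp = 1000))
  block <- floor((seq_len(nrow(prof3)) - 1) / 30)
  sm <- tapply(prof3$mean_r2, block, mean)
  expect_true(all(diff(sm) <= 0.01))  # decays up to bin noise
  expect_gt(sm[1], sm[length(sm)])
})

test_that("decay fits recover known curves and invert extents", {
  d <- seq(50, 2e5, by = 100)
  exact <- data.frame(bin_start = d - 50, bin_mid = d,
                      mean_r2 = hill_weir_r2(d, 3e-5, 100), n_pairs = 100)
  class(exact) <- c("ld_profile", "data.frame")
  fit <- fit_decay(exact, n = 100)
  expect_lt(abs(fit$params$c - 3e-5) / 3e-5, 0.01)
  # extent matches the analytic crossing of the same curve
  ext <- decay_extent(fit, 0.2)
  analytic <- stats::uniroot(function(x) hill_weir_r2(x, 3e-5, 100) - 0.2,
                             c(1, 1e6))$root
  expect_lt(abs(ext - analytic) / analytic, 0.01)

  # hyperbolic fallback: a = 0.4, b = 1e-5 crosses 0.2 at exactly 1e5
  hyp <- data.frame(bin_start = d - 50, bin_mid = d,
                    mean_r2 = 0.4 / (1 + 1e-5 * d), n_pairs = 1)
  class(hyp) <- c("ld_profile", "data.frame")
  f3 <- fit_decay(hyp, model = "hyperbolic")
  expect_equal(decay_extent(f3, 0.2), 1e5, tolerance = 1e-4)
  # threshold above the curve maximum errors; threshold at d = 0 gives 0
  expect_error(decay_extent(f3, 0.5), "maximum")
  expect_equal(decay_extent(f3, 0.4), 0)

  flat <- data.frame(bin_start = d - 50, bin_mid = d, mean_r2 = 1,
                     n_pairs = 1)
  class(flat) <- c("ld_profile", "data.frame")
  expect_warning(ff <- fit_decay(flat, n = 100), "degenerate")
  expect_error(decay_extent(ff), "degenerate")

  # noisy profile: fitted curve stays inside the empirical envelope
  set.seed(63)
  noisy <- exact
  noisy$mean_r2 <- pmin(1, pmax(0, noisy$mean_r2 + rnorm(nrow(noisy), 0,
                                                         0.01)))
  fn <- fit_decay(noisy, n = 100)
  pred <- fn$predict(noisy$bin_mid)
  expect_true(all(pred <= max(noisy$mean_r2) + 0.02 &
                    pred >= min(noisy$mean_r2) - 0.02))
})

test_that("LD pruning removes correlated sites deterministically", {
  dos <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2),
               c(0, 2, 0, 2, 0, 2))
  kept <- ld_prune(c(100, 200, 300), dos, window_snps = 3, r2_max = 0.5)
  expect_equal(kept, c(1L, 3L))  # the later of the perfect pair is removed

  set.seed(64)
  low <- matrix(sample(0:2, 120, replace = TRUE), 10, 12)
  pos <- seq(100, 1200, by = 100)
  kept_all <- ld_prune(pos, low, window_snps = 12, r2_max = 0.999)
  expect_equal(kept_all, 1:12)

  # postcondition: no kept pair within a window exceeds r2_max
  for (i in 1:5) {
    m <- matrix(sample(0:2, 40 * 30, replace = TRUE), 40, 30)
    m[, 2] <- m[, 1]; m[, 15] <- pmin(2, m[, 14] + rbinom(40, 1, 0.1))
    kept <- ld_prune(seq_len(30) * 50, m, window_snps = 10, step_snps = 5,
                     r2_max = 0.5)
    for (w0 in seq(1, 30, by = 5)) {
      inwin <- kept[kept >= w0 & kept <= w0 + 9]
      if (length(inwin) >= 2) {
        cmb <- utils::combn(inwin, 2)
        for (cc in seq_len(ncol(cmb))) {
          r2 <- genotype_r2(m[, cmb[1, cc]], m[, cmb[2, cc]])
          if (!is.na(r2)) expect_lte(r2, 0.5)
        }
      }
    }
    expect_identical(kept, ld_prune(seq_len(30) * 50, m, window_snps = 10,
                                    step_snps = 5, r2_max = 0.5))
  }
})
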