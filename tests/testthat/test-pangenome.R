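test_that("presence calling honours the strict/inclusive boundary semantics", {
  rule <- presence_rule_within_genus()
  hits <- data.frame(
    identity = c(86, 85, 89, 90, 89, 95),
    coverage = c(86, 85, 89, 90, 89, 95),
    n_contigs = c(1, 1, 3, 3, 1, 4))
  out <- call_presence(hits, rule)
  # single-contig clause strict: 86/86 present, 85/85 absent
  # split clause inclusive: 90/90 on 3 contigs present, 89/89 absent
  # 4 contigs never present
  expect_equal(out$present, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))

  cross <- presence_rule_cross_genus()
  out2 <- call_presence(data.frame(identity = 70, coverage = 75,
                                   n_contigs = 1), cross)
  expect_false(out2$present)  # strict ">" at the exact threshold
  expect_true(call_presence(data.frame(identity = 70.5, coverage = 75.5,
                                       n_contigs = 1), cross)$present)
  expect_error(call_presence(data.frame(identity = 50, coverage = 101,
                                        n_contigs = 1), rule), "coverage")

  # monotonicity: raising identity or coverage never flips present -> absent
  set.seed(1)
  base <- data.frame(identity = runif(300, 60, 100),
                     coverage = runif(300, 60, 100),
                     n_contigs = sample(1:4, 300, replace = TRUE))
  p0 <- call_presence(base, rule)$present
  bumped <- base
  bumped$identity <- pmin(100, bumped$identity + runif(300, 0, 10))
  bumped$coverage <- pmin(100, bumped$coverage + runif(300, 0, 10))
  p1 <- call_presence(bumped, rule)$present
  expect_true(all(p1[p0]))
})

test_that("library filter applies the fewer-than threshold exactly", {
  m <- matrix(0L, 40000, 3,
              dimnames = list(sprintf("g%05d", 1:40000), c("A", "B", "C")))
  m[1:38999, 1] <- 1L
  m[1:39000, 2] <- 1L
  m[1:39500, 3] <- 1L
  flt <- suppressMessages(filter_libraries(pav_matrix(m)))
  expect_equal(flt$excluded, "A")
  expect_equal(colnames(flt$pav), c("B", "C"))  # exactly 39,000 is retained
  expect_equal(ncol(filter_libraries(pav_matrix(m), min_present = 0)$pav), 3L)
})

test_that("occupancy classification recovers planted classes and orders labels", {
  cls1 <- suppressWarnings(classify_occupancy(rep(1, 100)))
  expect_equal(cls1$k, 1L)
  expect_equal(unique(cls1$labels), "core")

  specs <- list(pav_class_spec(1000, 0.98, label = "core"),
                pav_class_spec(1000, 0.56, label = "shell"),
                pav_class_spec(1000, 0.12, label = "cloud"))
  g <- gen_pav_matrix(specs, 302, seed = 5)
  cls <- classify_occupancy(occupancy(g$pav), seed = 5)
  expect_equal(cls$k, 3L)
  expect_lt(max(abs(cls$cluster_means - c(0.98, 0.56, 0.12))), 0.03)
  # cluster means always reported in descending order
  expect_true(all(diff(cls$cluster_means) < 0))
  expect_equal(cls$labels[cls$cluster == 1][1], "core")

  # k recovery for one and two well-separated classes
  g2 <- gen_pav_matrix(list(pav_class_spec(1000, 0.9, label = "hi"),
                            pav_class_spec(1000, 0.2, label = "lo")),
                       302, seed = 6)
  expect_equal(classify_occupancy(occupancy(g2$pav), seed = 6)$k, 2L)
  g1 <- gen_pav_matrix(list(pav_class_spec(1500, 0.5, label = "only")),
                       302, seed = 7)
  expect_equal(classify_occupancy(occupancy(g1$pav), seed = 7)$k, 1L)

  expect_warning(classify_occupancy(c(0.1, 0.1, 0.5, 0.5, 0.9, 0.9),
                                    k_max = 6), "k_max")
})

test_that("chi-square enrichment matches the hand-computed worked example", {
  sizes <- c(Central = 130, CentralEast = 78, CentralNorth = 59,
             WestCoast = 35)
  labels <- rep(names(sizes), times = sizes)
  n_lib <- sum(sizes)
  expect_equal(n_lib, 302L)
  m <- matrix(0L, 3, n_lib,
              dimnames = list(c("gProp", "gOne", "gZero"), NULL))
  colnames(m) <- sprintf("L%03d", seq_len(n_lib))
  names(labels) <- colnames(m)
  # gProp present proportionally everywhere; gOne only in Central
  m["gProp", ] <- 1L
  m["gOne", labels == "Central"] <- 1L
  enr <- suppressMessages(chisq_enrichment(pav_matrix(m), labels))
  expect_equal(sort(unname(attr(enr, "subpop_sizes"))), sort(unname(sizes)))
  expect_equal(attr(enr, "excluded"), "gZero")

  prop <- enr[enr$gene == "gProp", ]
  expect_equal(prop$chisq, 0)
  expect_false(prop$candidate)

  one <- enr[enr$gene == "gOne", ]
  # independent oracle: direct formula evaluation
  o <- c(130, 78, 59, 35) * c(1, 0, 0, 0)
  e <- 130 * c(130, 78, 59, 35) / 302
  expect_equal(one$chisq, sum((o - e)^2 / e), tolerance = 1e-12)
  expect_equal(round(one$chisq), 172)
  expect_true(one$candidate)
  expect_equal(one$df, 3L)
  expect_equal(attr(enr, "critical_value"), 7.81, tolerance = 1e-3)
  # expected counts of the worked example: O * n_i / N
  expect_equal(unname(unlist(
    one[paste0("exp_", c("WestCoast", "CentralNorth", "CentralEast",
                         "Central"))])),
    130 * c(35, 59, 78, 130) / 302, tolerance = 1e-12)
  expect_equal(round(unname(unlist(
    one[paste0("exp_", c("WestCoast", "CentralNorth"))])), 1),
    c(15.1, 25.4))
})

test_that("enrichment conserves counts, controls type I error and BH is monotone", {
  sizes <- c(a = 130, b = 78, c = 59, d = 35)
  labels <- rep(names(sizes), times = sizes)
  set.seed(12)
  # null: genes present with equal probability in every subpopulation
  m <- matrix(rbinom(2000 * 302, 1L, 0.5), 2000, 302,
              dimnames = list(sprintf("g%04d", 1:2000),
                              sprintf("L%03d", 1:302)))
  names(labels) <- colnames(m)
  enr <- suppressMessages(chisq_enrichment(pav_matrix(m), labels))
  obs <- as.matrix(enr[, paste0("obs_", names(sizes))])
  exp_ <- as.matrix(enr[, paste0("exp_", names(sizes))])
  expect_equal(rowSums(obs), rowSums(exp_), tolerance = 1e-9,
               ignore_attr = TRUE)
  # BH q-values are monotone in p and never smaller than p
  ord <- order(enr$p)
  expect_true(all(diff(enr$q[ord]) >= -1e-12))
  expect_true(all(enr$q >= enr$p - 1e-12))
  expect_error(chisq_enrichment(pav_matrix(m), rep("a", 302)), "subpop")

  # type-I error: near-nominal for rare genes, where the test's multinomial
  # placement model holds (common genes are tested conservatively because
  # presences are spread without replacement over libraries)
  set.seed(13)
  m2 <- matrix(rbinom(4000 * 302, 1L, 0.05), 4000, 302,
               dimnames = list(sprintf("g%04d", 1:4000),
                               sprintf("L%03d", 1:302)))
  enr2 <- suppressMessages(chisq_enrichment(pav_matrix(m2), labels))
  rate <- mean(enr2$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(enr2)) + 0.005)
})

test_that("private genes require strict presence and strict absence", {
  labels <- c(A = "p1", B = "p1", C = "p2", D = "p2", E = "p2")
  m <- rbind(
    gHalf  = c(1, 0, 0, 0, 0),   # freq 0.5 in p1, absent in p2
    gLeak  = c(1, 0, 1, 0, 0),   # present in both
    gExact = c(0, 0, 0, 0, 0))
  colnames(m) <- names(labels)
  pg <- private_genes(pav_matrix(m), labels, min_freq = 0.1)
  expect_equal(pg$gene, "gHalf")
  expect_equal(pg$subpop, "p1")
  # boundary: frequency exactly min_freq is not private (strict >)
  labels10 <- setNames(rep(c("p1", "p2"), each = 10),
                       sprintf("L%02d", 1:20))
  m10 <- matrix(0L, 1, 20, dimnames = list("g", names(labels10)))
  m10[1, 1] <- 1L  # freq 0.1 in p1
  expect_equal(nrow(private_genes(pav_matrix(m10), labels10,
                                  min_freq = 0.1)), 0L)
  # tolerance parameter exposes the relaxed definition (a leaky gene can
  # then satisfy the rule from both sides)
  relaxed <- private_genes(pav_matrix(m), labels, min_freq = 0.1, tol = 0.5)
  expect_setequal(relaxed$gene, c("gHalf", "gLeak"))
  expect_equal(sort(unique(relaxed$gene[relaxed$subpop == "p1"])),
               c("gHalf", "gLeak"))
})

test_that("jaccard distance: worked values, conventions, triangle inequality", {
  prof <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 0, 0),
                d = c(0, 0, 1, 1))
  d <- jaccard_distance(prof)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)           # disjoint non-empty
  expect_equal(d["a", "b"], 1 - 1 / 3, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_warning(jaccard_distance(cbind(e = c(0, 0), f = c(0, 0))), "empty")

  # triangle inequality over all binary profiles of length 6
  all_prof <- t(as.matrix(expand.grid(rep(list(0:1), 6))))
  colnames(all_prof) <- sprintf("p%02d", seq_len(ncol(all_prof)))
  D <- suppressWarnings(jaccard_distance(all_prof))
  n <- ncol(D)
  viol <- 0L
  for (b in seq_len(n)) {
    slack <- outer(D[, b], D[b, ], "+") - D
    viol <- viol + sum(slack < -1e-12)
  }
  expect_equal(viol, 0L)
})
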