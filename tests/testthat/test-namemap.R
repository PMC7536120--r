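test_that("normalized identity divides matches by the longer sequence", {
  prot <- paste(rep("MKLVNTEWSA", 10), collapse = "")
  expect_equal(normalized_identity(prot, prot), 1.0)
  # exact 50-aa prefix of a 100-aa protein: 50 / 100
  expect_equal(normalized_identity(substr(prot, 1, 50), prot), 0.5)
  # dissimilar short peptides score near zero
  expect_lt(normalized_identity("WWWWWWWW", "GGGGGGGG"), 0.2)
  expect_error(normalized_identity("", prot), "non-empty")
  dna <- paste(rep("ATGGCC", 20), collapse = "")
  expect_equal(normalized_identity(dna, dna, type = "dna"), 1.0)
})

test_that("mutual best hits are reciprocal, symmetric, and tie-broken", {
  p1 <- paste(rep("MKLVNTEWSA", 10), collapse = "")
  p2 <- paste(rep("GHIRDFPQCY", 10), collapse = "")
  a <- c(a1 = p1, a2 = p2)
  b <- c(b1 = p1, b2 = p2)
  mbh <- mutual_best_hits(a, b)
  expect_equal(nrow(mbh), 2L)
  expect_equal(mbh$b[mbh$a == "a1"], "b1")
  expect_equal(mbh$b[mbh$a == "a2"], "b2")
  # symmetry under swapping the sets
  rev <- mutual_best_hits(b, a)
  expect_equal(sort(paste(rev$b, rev$a)), sort(paste(mbh$a, mbh$b)))
  # exact tie: two identical candidates; lexicographically smaller id wins
  tie <- suppressMessages(
    mutual_best_hits(c(a1 = p1), c(b2 = p1, b1 = p1)))
  expect_equal(tie$b, "b1")
  expect_true(tie$tie_broken)
  # single pair maps when identity is positive
  expect_equal(nrow(mutual_best_hits(c(x = p1), c(y = p1))), 1L)
})

test_that("locus names carry forward under unique overlap + MBH identity", {
  ann <- toy_annotation_pair()
  map <- map_locus_names(ann$old, ann$new)
  expect_true(all(map$mapped))
  expect_equal(map$name[map$new_locus == "G1"], "g1")

  # 69-aa exact prefix of the 100-aa protein: identity 0.69 < 0.70, unmapped
  low <- toy_annotation_pair(substr(ann$prot1, 1, 69))
  map_low <- map_locus_names(low$old, low$new)
  expect_false(map_low$mapped[map_low$new_locus == "G1"])
  expect_match(map_low$name[map_low$new_locus == "G1"], "^novel")
  # 71-aa prefix -> 0.71, mapped (inclusive >= 0.70)
  hi <- toy_annotation_pair(substr(ann$prot1, 1, 71))
  expect_true(map_locus_names(hi$old, hi$new)$mapped[1])

  # non-unique overlap: one old locus overlapping two new loci maps nothing
  old2 <- ann$old
  new2 <- ann$new
  new2$loci$start <- c(100, 600)
  new2$loci$end <- c(500, 1000)  # both new loci inside old g1
  map2 <- map_locus_names(old2, new2)
  expect_false(any(map2$mapped))
})

test_that("transcript rules distinguish protein MBH from UTR-only changes", {
  ann <- toy_annotation_pair()
  locus_map <- map_locus_names(ann$old, ann$new)
  tx <- map_transcript_names(ann$old, ann$new, locus_map)
  expect_equal(tx$rule[tx$new_tx == "G1.t1"], 1L)

  # protein at 89% (89-aa prefix): below the 90% rule-1 threshold
  low <- toy_annotation_pair(substr(ann$prot1, 1, 89))
  lm_low <- map_locus_names(low$old, low$new)   # still a locus-level MBH
  tx_low <- map_transcript_names(low$old, low$new, lm_low)
  expect_true(is.na(tx_low$old_tx[tx_low$new_tx == "G1.t1"]))

  # protein at 92%: rule 1 applies through the MBH
  mid <- toy_annotation_pair(substr(ann$prot1, 1, 92))
  tx_mid <- map_transcript_names(mid$old, mid$new,
                                 map_locus_names(mid$old, mid$new))
  expect_equal(tx_mid$rule[tx_mid$new_tx == "G1.t1"], 1L)

  # rule 2: identical proteins (so the protein MBH is consumed by a tie)
  # but transcripts pair up through their own MBH relation
  prot <- ann$prot1
  tx_base <- .toy_seq(300, c("A", "C", "G", "T"), 105)
  tx_b <- scramble_range(tx_base, 241, 300, type = "dna")  # UTR variant
  tx_B <- scramble_range(tx_b, 1, 10, type = "dna")        # ~97% of tx_b
  loci <- data.frame(locus = "gX", chrom = "chr1", start = 1, end = 400,
                     strand = "+", stringsAsFactors = FALSE)
  old_r2 <- annotation_set(
    loci, proteins = list(gX = c(gX.t1 = prot, gX.t2 = prot)),
    transcripts = list(gX = c(gX.t1 = tx_base, gX.t2 = tx_b)))
  loci_new <- loci
  loci_new$locus <- "GX"
  new_r2 <- annotation_set(
    loci_new, proteins = list(GX = c(GX.t1 = prot, GX.t2 = prot)),
    transcripts = list(GX = c(GX.t1 = tx_base, GX.t2 = tx_B)))
  lm_r2 <- map_locus_names(old_r2, new_r2)
  tx_r2 <- suppressMessages(map_transcript_names(old_r2, new_r2, lm_r2))
  expect_equal(tx_r2$rule[tx_r2$new_tx == "GX.t2"], 2L)
  expect_equal(tx_r2$old_tx[tx_r2$new_tx == "GX.t2"], "gX.t2")
})

test_that("self-mapping is total and injective", {
  ann <- toy_annotation_pair()
  self <- map_locus_names(ann$old, ann$old)
  expect_true(all(self$mapped))
  expect_equal(self$name, self$new_locus)
  tx_self <- map_transcript_names(ann$old, ann$old, self)
  expect_true(all(!is.na(tx_self$old_tx)))
  expect_false(any(duplicated(tx_self$old_tx)))
  expect_false(any(duplicated(self$name)))
})
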