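# Small in-code fixtures shared across test files.

write_test_vcf <- function(records, samples = c("s1", "s2"),
                           path = tempfile(fileext = ".vcf")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Tiny two-version annotation pair: two loci on one chromosome, one shared
# transcript each. `new_g1_protein` rewrites the new version's protein for
# locus g1. Sequences are fixed pseudorandom strings (non-periodic, so
# alignments cannot gain matches by register shifts).
.toy_seq <- function(n, alphabet, seed) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

toy_annotation_pair <- function(new_g1_protein = NULL) {
  prot1 <- .toy_seq(100, .aa20, 101)
  prot2 <- .toy_seq(100, .aa20, 102)
  tx1 <- .toy_seq(300, c("A", "C", "G", "T"), 103)
  tx2 <- .toy_seq(300, c("A", "C", "G", "T"), 104)
  loci_old <- data.frame(locus = c("g1", "g2"), chrom = "chr1",
                         start = c(100, 5000), end = c(1000, 6000),
                         strand = "+", stringsAsFactors = FALSE)
  loci_new <- loci_old
  loci_new$locus <- c("G1", "G2")
  old <- annotation_set(loci_old,
                        proteins = list(g1 = c(g1.t1 = prot1),
                                        g2 = c(g2.t1 = prot2)),
                        transcripts = list(g1 = c(g1.t1 = tx1),
                                           g2 = c(g2.t1 = tx2)))
  new_p1 <- new_g1_protein %||% prot1
  new <- annotation_set(loci_new,
                        proteins = list(G1 = c(G1.t1 = new_p1),
                                        G2 = c(G2.t1 = prot2)),
                        transcripts = list(G1 = c(G1.t1 = tx1),
                                           G2 = c(G2.t1 = tx2)))
  list(old = old, new = new, prot1 = prot1, prot2 = prot2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.transitions_for_test <- c(A = "G", G = "A", C = "T", T = "C")

# Substitute positions [from, to] (or the last n when from is NULL) with a
# cyclic letter rotation, guaranteeing a mismatch at every touched position.
.rot_protein <- local({
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  stats::setNames(ab[c(2:length(ab), 1)], ab)
})
.rot_dna <- c(A = "C", C = "G", G = "T", T = "A")

scramble_range <- function(seq, from, to, type = "protein") {
  v <- strsplit(seq, "")[[1]]
  rot <- if (type == "dna") .rot_dna else .rot_protein
  v[from:to] <- rot[v[from:to]]
  paste(v, collapse = "")
}

mutate_tail <- function(seq, n, type = "protein") {
  scramble_range(seq, nchar(seq) - n + 1, nchar(seq), type)
}
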