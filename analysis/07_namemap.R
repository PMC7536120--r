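#!/usr/bin/env Rscript
# Annotation name carry-forward between two versions of a toy annotation:
# mutual-best-hit locus mapping at 70% normalized identity and transcript
# mapping at 90%.

suppressPackageStartupMessages(library(pavpop))
out <- "results/namemap"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

set.seed(1)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
mkprot <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
mkdna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
prots <- replicate(4, mkprot(120))
txs <- replicate(4, mkdna(360))
old <- annotation_set(
  data.frame(locus = paste0("v1_g", 1:4), chrom = "chr1",
             start = c(100, 3000, 6000, 9000),
             end = c(1100, 4000, 7000, 10000), strand = "+",
             stringsAsFactors = FALSE),
  proteins = setNames(lapply(1:4, function(i)
    setNames(prots[i], paste0("v1_g", i, ".1"))), paste0("v1_g", 1:4)),
  transcripts = setNames(lapply(1:4, function(i)
    setNames(txs[i], paste0("v1_g", i, ".1"))), paste0("v1_g", 1:4)))

# version 2: g1 unchanged, g2 protein truncated to 75% (still mappable),
# g3 truncated to 60% (name not carried), g4 moved away (no overlap)
new_prots <- c(prots[1], substr(prots[2], 1, 90), substr(prots[3], 1, 72),
               prots[4])
new <- annotation_set(
  data.frame(locus = paste0("v2_g", 1:4), chrom = "chr1",
             start = c(120, 2950, 6100, 20000),
             end = c(1080, 3950, 7100, 21000), strand = "+",
             stringsAsFactors = FALSE),
  proteins = setNames(lapply(1:4, function(i)
    setNames(new_prots[i], paste0("v2_g", i, ".1"))), paste0("v2_g", 1:4)),
  transcripts = setNames(lapply(1:4, function(i)
    setNames(txs[i], paste0("v2_g", i, ".1"))), paste0("v2_g", 1:4)))

lm <- map_locus_names(old, new)
write_table(lm, file.path(out, "locus_map.tsv"))
message(sprintf("locus mapping: %d/%d names carried forward",
                sum(lm$mapped), nrow(lm)))
for (i in seq_len(nrow(lm)))
  message(sprintf("  %s -> %s%s", lm$new_locus[i], lm$name[i],
                  if (lm$mapped[i])
                    sprintf(" (identity %.2f)", lm$identity[i]) else ""))

tx <- map_transcript_names(old, new, lm)
write_table(tx, file.path(out, "transcript_map.tsv"))
message(sprintf("transcript mapping: %d/%d carried (rule 1: %d, rule 2: %d)",
                sum(!is.na(tx$old_tx)), nrow(tx),
                sum(tx$rule == 1, na.rm = TRUE),
                sum(tx$rule == 2, na.rm = TRUE)))
message("tables written under ", out)
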