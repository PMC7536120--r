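#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume, with
# ground truth written beside each one. All outputs are plain text under
# results/synthetic/.

suppressPackageStartupMessages(library(pavpop))
seed <- 1L
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("PAV matrix: 302 libraries, three occupancy classes (98/56/12%)")
specs <- list(pav_class_spec(5000, 0.98, label = "core"),
              pav_class_spec(5000, 0.56, label = "shell"),
              pav_class_spec(5000, 0.12, label = "cloud"))
gen <- gen_pav_matrix(specs, 302,
                      c(Central = 130, CentralEast = 78, CentralNorth = 59,
                        WestCoast = 35), seed = seed)
write_pav_matrix(gen$pav, file.path(out, "pav_matrix.tsv"))
write_table(gen$truth, file.path(out, "pav_truth.tsv"))
write_table(data.frame(library = names(gen$labels), subpop = gen$labels),
            file.path(out, "pav_labels.tsv"))

message("Phased haplotypes with a planted partial sweep (200 haplotypes)")
gs <- gen_sweep_haplotypes(200, 400, region_bp = 1e6, core_freq = 0.3,
                           sweep_width_bp = 2e5, seed = seed)
vt <- list(variants = data.frame(chrom = "chr1", pos = gs$haps$positions,
                                 ref = "A", alt = "G",
                                 stringsAsFactors = FALSE),
           dosage = t(gs$haps$alleles[c(TRUE, FALSE), ] +
                        gs$haps$alleles[c(FALSE, TRUE), ]),
           haplotypes = gs$haps)
colnames(vt$dosage) <- sprintf("ind%03d", 1:100)
class(vt) <- "variant_table"
write_vcf(vt, file.path(out, "sweep_haplotypes.vcf"))
write_table(data.frame(core_site = gs$core_site, core_pos = gs$core_pos,
                       n_carriers = length(gs$carriers)),
            file.path(out, "sweep_truth.tsv"))

message("Haplotypes with distance-decaying LD (200 haplotypes, 1,000 sites)")
hl <- gen_ld_haplotypes(200, 1000, spacing_bp = 1000,
                        switch_prob_per_bp = 1e-4, seed = seed)
vt2 <- list(variants = data.frame(chrom = "chr1", pos = hl$positions,
                                  ref = "A", alt = "G",
                                  stringsAsFactors = FALSE),
            dosage = t(hl$alleles[c(TRUE, FALSE), ] +
                         hl$alleles[c(FALSE, TRUE), ]),
            haplotypes = hl)
colnames(vt2$dosage) <- sprintf("ind%03d", 1:100)
class(vt2) <- "variant_table"
write_vcf(vt2, file.path(out, "ld_haplotypes.vcf"))

message("TE family: 12 copies, 6.5 kb, burst 45,000 years ago")
fam <- gen_te_family(12, 6500, 45000, mu = 6.5e-9, kappa = 2,
                     ltr_length = 451, seed = seed)
write_fasta(fam$elements, file.path(out, "te_family.fasta"))
write_fasta(fam$ltrs, file.path(out, "te_ltrs.fasta"))

message("Read pairs over the element junctions (present and absent cases)")
write_table(gen_read_pairs_over_junction(TRUE, 50, left_junction = 5000,
                                         right_junction = 11500,
                                         seed = seed),
            file.path(out, "read_pairs_present.tsv"))
write_table(gen_read_pairs_over_junction(FALSE, 50, left_junction = 5000,
                                         right_junction = 11500,
                                         seed = seed),
            file.path(out, "read_pairs_absent.tsv"))
message("done: ", out)
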