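#!/usr/bin/env Rscript
# Simulate the full synthetic study: a 12-chromosome true map with a
# scaffold-scale locus geometry, a fragmented assembly with planted
# mis-joins, three megagametophyte families from unrelated mothers (with
# genotyping error, missing data and diploid contamination), and the pooled
# diploid-coded call matrix a sequencing provider would deliver.
#
# Writes: results/true_map.tsv, results/scaffolds.agp, results/genes.gff3,
#         results/calls.vcf, results/true_labels.tsv

library(haplomap)
dir.create("results", showWarnings = FALSE)
seed <- 20260930L %% 100000L

tm <- simulate_true_map(n_chr = 12, chr_length_cM = 100, loci_per_chr = 120,
                        clusters_per_chr = 40,
                        families = c(fam1 = 260, fam2 = 220, fam3 = 420),
                        seed = seed)
sset <- simulate_assembly(
  tm, n_scaffolds = 450,
  markers_per_scaffold_dist = c(0.35, 0.25, 0.15, 0.1, 0.06, 0.04, 0.02,
                                0.015, 0.01, 0.0035, 0.0015),
  inter_chimera_rate = 0.08, intra_chimera_rate = 0.02, seed = seed + 1L)
tm <- assign_scaffolds(tm, sset)
message(sprintf("true map: %d loci on %d chromosomes; %d scaffolds (%d chimeric)",
                nrow(tm$loci), nrow(tm$chromosomes), nrow(sset$scaffolds),
                sum(sset$scaffolds$chimera_label != "none")))

mothers <- simulate_maternal_genotypes(tm, 3, seed = seed + 2L)
fams <- lapply(1:3, function(i)
  simulate_haploid_family(tm, tm$families$family_id[i],
                          tm$families$n_samples[i],
                          error_rate = 0.003, missing_rate = 0.05,
                          seed = seed + 2L + i, maternal = mothers[[i]]))
mix <- simulate_mixture(fams, contamination_rate = 0.02, seed = seed + 9L)
message(sprintf("pooled call matrix: %d markers x %d samples",
                nrow(mix$calls), ncol(mix$calls)))

write_true_map(tm, "results/true_map.tsv")
write_scaffold_agp(sset, "results/scaffolds.agp")
write_scaffold_gff3(sset, "results/genes.gff3")
# VCF of the pooled diploid-coded calls (het = contamination signal)
dip <- mix$calls
gt <- matrix(".", nrow(dip), ncol(dip), dimnames = dimnames(dip))
gt[which(dip == 0L)] <- "0/0"
gt[which(dip == 1L)] <- "1/1"
gt[which(dip == 2L)] <- "0/1"
con <- file("results/calls.vcf", "w")
writeLines(c("##fileformat=VCFv4.2", "##source=haplomap-analysis",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(dip)), collapse = "\t")), con)
meta <- tm$loci[match(rownames(dip), tm$loci$marker_id), ]
writeLines(paste(meta$scaffold_id, meta$scaffold_bp, meta$marker_id, "A", "T",
                 ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t"), con)
close(con)
utils::write.table(
  data.frame(sample_id = names(mix$true_labels), family = mix$true_labels),
  "results/true_labels.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
# chimera truth for later scoring
utils::write.table(sset$scaffolds, "results/scaffold_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/{true_map.tsv,scaffolds.agp,genes.gff3,calls.vcf,",
        "true_labels.tsv,scaffold_truth.tsv}")
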