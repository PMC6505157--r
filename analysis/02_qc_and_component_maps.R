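#!/usr/bin/env Rscript
# From the pooled diploid-coded calls: collapse heterozygotes, exclude
# contaminated samples, cluster samples into maternal families, recode to
# testcross markers, test segregation distortion, and build one component
# linkage map per family.
#
# Writes: results/sample_qc.tsv, results/family_assignment.tsv,
#         results/distortion.tsv, results/component_positions.tsv,
#         results/component_summary.tsv

source("analysis/00_config.R")

study <- build_study(cfg)
maps <- build_maps(study, cfg)

message(sprintf("QC: %d samples excluded of %d",
                nrow(maps$flt$exclusions), ncol(study$mix$calls)))
utils::write.table(cbind(maps$flt$sample_qc, retained = TRUE),
                   "results/sample_qc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cl <- maps$clusters
truth <- study$mix$true_labels[names(cl$assignment)]
agree <- mean(apply(table(cl$assignment, truth) > 0, 1, sum) == 1)
message(sprintf("clustering: k = %d families, sizes %s; pure clusters: %.0f%%",
                cl$k, paste(cl$sizes, collapse = "/"), 100 * agree))
utils::write.table(
  data.frame(sample_id = names(cl$assignment), family = cl$assignment,
             true_family = truth),
  "results/family_assignment.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# segregation distortion per family over informative markers; flagged
# markers (mostly error-faked second alleles at maternal-homozygous loci)
# are excluded from mapping
dist_all <- do.call(rbind, lapply(names(maps$distortion), function(f)
  cbind(family = f, maps$distortion[[f]])))
message(sprintf(
  "segregation distortion: %d of %d family-marker tests flagged and excluded",
  sum(dist_all$distorted), nrow(dist_all)))
utils::write.table(dist_all, "results/distortion.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pos <- do.call(rbind, lapply(names(maps$components), function(f)
  cbind(component = f, map_positions(maps$components[[f]]))))
utils::write.table(pos, "results/component_positions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

summ <- do.call(rbind, lapply(names(maps$components), function(f)
  cbind(component = f, map_summary(maps$components[[f]]))))
utils::write.table(summ, "results/component_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("component maps:")
for (f in names(maps$components))
  message(sprintf("  %s: %d LGs, %d bins, total %.1f cM", f,
                  length(maps$components[[f]]$maps),
                  nrow(maps$components[[f]]$binning$bins),
                  sum(vapply(maps$components[[f]]$maps,
                             function(m) max(m$cM), 0))))
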