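# Shared configuration for the analysis scripts.  Every script regenerates
# the simulation state it needs from these parameters (all generators are
# seed-deterministic), so each script can be run on its own, in order.

library(haplomap)

cfg <- list(
  seed = 20260930L %% 100000L,
  n_chr = 12, chr_length_cM = 100, loci_per_chr = 120, clusters_per_chr = 40,
  families = c(fam1 = 260, fam2 = 220, fam3 = 420),
  n_scaffolds = 450,
  scaffold_dist = c(0.35, 0.25, 0.15, 0.1, 0.06, 0.04, 0.02, 0.015, 0.01,
                    0.0035, 0.0015),
  inter_chimera_rate = 0.08, intra_chimera_rate = 0.02,
  error_rate = 0.003, missing_rate = 0.05, contamination_rate = 0.02)

build_study <- function(cfg) {
  tm <- simulate_true_map(n_chr = cfg$n_chr, chr_length_cM = cfg$chr_length_cM,
                          loci_per_chr = cfg$loci_per_chr,
                          clusters_per_chr = cfg$clusters_per_chr,
                          families = cfg$families, seed = cfg$seed)
  sset <- simulate_assembly(tm, cfg$n_scaffolds,
                            markers_per_scaffold_dist = cfg$scaffold_dist,
                            inter_chimera_rate = cfg$inter_chimera_rate,
                            intra_chimera_rate = cfg$intra_chimera_rate,
                            seed = cfg$seed + 1L)
  tm <- assign_scaffolds(tm, sset)
  mothers <- simulate_maternal_genotypes(tm, length(cfg$families),
                                         seed = cfg$seed + 2L)
  fams <- lapply(seq_along(cfg$families), function(i)
    simulate_haploid_family(tm, names(cfg$families)[i], cfg$families[[i]],
                            error_rate = cfg$error_rate,
                            missing_rate = cfg$missing_rate,
                            seed = cfg$seed + 2L + i,
                            maternal = mothers[[i]]))
  mix <- simulate_mixture(fams, cfg$contamination_rate, seed = cfg$seed + 9L)
  list(tm = tm, sset = sset, fams = fams, mix = mix)
}

# component maps rebuilt from the pooled calls via the full QC chain;
# used by scripts 02-06.  Markers flagged for segregation distortion
# (Bonferroni) are excluded before mapping: in this design they are almost
# exclusively maternal-homozygous loci where genotyping errors fake a second
# allele, and they would otherwise attach to linkage groups with spurious
# near-zero recombination fractions.
build_maps <- function(study, cfg) {
  hap <- collapse_heterozygous_calls(study$mix$calls)
  flt <- filter_samples(hap)
  cl <- cluster_families(flt$alleles, max_k = 6)
  rec <- recode_testcross(flt$alleles, cl$assignment)
  distortion <- lapply(rec, function(r)
    test_segregation_distortion(r$alleles))
  comps <- lapply(seq_along(rec), function(i) {
    keep <- !distortion[[i]]$distorted
    build_component_map(rec[[i]]$alleles[keep, , drop = FALSE],
                        seed = cfg$seed + 20L + i)
  })
  names(comps) <- names(rec)
  list(hap = hap, flt = flt, clusters = cl, recoded = rec,
       distortion = distortion, components = comps)
}

dir.create("results", showWarnings = FALSE)
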