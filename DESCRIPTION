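Package: haplomap
Title: Haploid Linkage Maps, Consensus Merging and Genome Assembly Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of ultra-dense haploid genetic linkage
    maps from conifer megagametophyte genotypes. Provides simulation of haploid
    testcross families, artificial genome assemblies with planted mis-joins and
    neutral coalescent haplotype panels; genotype quality control (heterozygote
    collapse, contamination filtering, maternal-family clustering, testcross
    recoding, segregation-distortion tests); marker binning, two-point
    recombination/LOD estimation, linkage grouping, RECORD marker ordering with
    ripple refinement and Kosambi map distances; consensus-map merging by
    constrained L1 optimization with RMSE-based candidate selection; map-length
    inflation estimation by marker-bin subsampling; classification of chimeric
    (split) assembly scaffolds against the map; inter-map synteny comparison;
    and cM-anchored population-genetic scans (segregating sites, nucleotide
    diversity, Tajima's D, Kelly's ZnS) in sliding windows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    quantreg,
    cluster,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
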