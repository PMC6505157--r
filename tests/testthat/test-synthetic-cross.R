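test_that("gamete simulation reproduces the Haldane recombinant fraction", {
  # two markers 10 cM apart: expected r = (1 - exp(-2d/100)) / 2
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 50, loci_per_chr = 2,
                          seed = 5)
  tm$loci$true_cM <- c(20, 30)
  fam <- simulate_haploid_family(tm, "f1", n_samples = 2000, seed = 7)
  ph <- fam$truth_phase
  g <- fam$alleles
  recomb <- (g[1, ] == ph[1]) != (g[2, ] == ph[2])
  expected <- (1 - exp(-0.2)) / 2
  tol <- 3 * sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(mean(recomb) - expected), tol)
})

test_that("family simulation handles edge cases and is deterministic", {
  tm <- simulate_true_map(n_chr = 2, chr_length_cM = 80, loci_per_chr = 5,
                          seed = 1)
  one <- simulate_haploid_family(tm, "f1", n_samples = 1, seed = 3)
  expect_equal(ncol(one$alleles), 1L)
  expect_false(anyNA(one$alleles))

  a <- simulate_haploid_family(tm, "f1", 40, error_rate = 0.05,
                               missing_rate = 0.1, seed = 9)
  b <- simulate_haploid_family(tm, "f1", 40, error_rate = 0.05,
                               missing_rate = 0.1, seed = 9)
  expect_identical(a$alleles, b$alleles)

  expect_error(simulate_haploid_family(tm, "f1", 0), "n_samples")
  expect_error(simulate_haploid_family(tm, "f1", 5, error_rate = 1), "rates")
  empty <- tm; empty$loci <- tm$loci[0, ]
  expect_error(simulate_haploid_family(empty, "f1", 5), "no loci")
})

test_that("error-free gametes are crossover realizations of the true map", {
  # with no errors, each sample switches phase along the chromosome in
  # contiguous blocks: adjacent tightly linked loci almost always agree
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 100, loci_per_chr = 40,
                          seed = 2)
  fam <- simulate_haploid_family(tm, "f1", 200, seed = 4)
  ph <- fam$truth_phase
  state <- (fam$alleles == ph) * 1L   # phase indicator per locus x sample
  switches <- colSums(abs(diff(state)))
  # switch count per gamete is bounded by crossovers; mean ~ 1 per Morgan
  expect_lt(mean(switches), 2.5)
  expect_true(all(fam$alleles %in% c(0L, 1L)))
})

test_that("mixture pooling preserves calls and plants contamination", {
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 60, loci_per_chr = 50,
                          seed = 11)
  f1 <- simulate_haploid_family(tm, "famA", 100, seed = 12)
  f2 <- simulate_haploid_family(tm, "famB", 100, seed = 13)

  mix0 <- simulate_mixture(list(f1, f2), contamination_rate = 0, seed = 14)
  expect_equal(dim(mix0$calls), c(50L, 200L))
  expect_equal(sort(colnames(mix0$calls)),
               sort(c(colnames(f1$alleles), colnames(f2$alleles))))
  expect_false(any(mix0$calls == 2L, na.rm = TRUE))
  # single family, zero contamination: matrix equals input up to shuffle
  solo <- simulate_mixture(list(f1), 0, seed = 15)
  expect_identical(solo$calls[, colnames(f1$alleles)], f1$alleles)
  expect_true(all(solo$true_labels == "famA"))

  mix <- simulate_mixture(list(f1, f2), contamination_rate = 0.05, seed = 16)
  het_frac <- mean(mix$calls == 2L, na.rm = TRUE)
  expect_lt(abs(het_frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  expect_equal(dim(mix$calls), dim(mix0$calls))

  again <- simulate_mixture(list(f1, f2), contamination_rate = 0.05,
                            seed = 16)
  expect_identical(mix$calls, again$calls)

  f3 <- simulate_haploid_family(tm, "famC", 10, seed = 17)
  f3$alleles <- f3$alleles[-1, , drop = FALSE]
  expect_error(simulate_mixture(list(f1, f3)), "conflicting marker lists")
})

test_that("assembly simulation respects chimera labels and span tiling", {
  tm <- simulate_true_map(n_chr = 3, chr_length_cM = 100, loci_per_chr = 60,
                          clusters_per_chr = 20, seed = 21)
  clean <- simulate_assembly(tm, 40, inter_chimera_rate = 0,
                             intra_chimera_rate = 0, seed = 22)
  expect_true(all(clean$scaffolds$chimera_label == "none"))

  # forced inter-chimeras on a 2-chromosome map
  tm2 <- simulate_true_map(n_chr = 2, chr_length_cM = 100, loci_per_chr = 60,
                           clusters_per_chr = 20, seed = 23)
  chim <- simulate_assembly(tm2, 30, inter_chimera_rate = 0.999, seed = 24,
                            markers_per_scaffold_dist =
                              c(0, 0.3, 0.3, 0.2, 0.1, 0.1, 0, 0, 0, 0, 0))
  multi_run <- chim$scaffolds$scaffold_id[
    chim$scaffolds$scaffold_id %in% chim$gaps$scaffold_id]
  expect_true(all(chim$scaffolds$chimera_label[
    chim$scaffolds$scaffold_id %in% multi_run] == "inter"))
  lgs_per_sc <- tapply(chim$marker_loci$chr_id, chim$marker_loci$scaffold_id,
                       function(x) length(unique(x)))
  expect_true(all(lgs_per_sc[chim$scaffolds$scaffold_id[
    chim$scaffolds$chimera_label == "inter"]] >= 2))

  # contig + gap spans tile [0, length_bp) without overlap
  for (sc in clean$scaffolds$scaffold_id[1:10]) {
    spans <- rbind(clean$contigs[clean$contigs$scaffold_id == sc,
                                 c("start", "end")],
                   clean$gaps[clean$gaps$scaffold_id == sc,
                              c("start", "end")])
    spans <- spans[order(spans$start), ]
    expect_equal(spans$start[1], 0)
    expect_equal(spans$end[nrow(spans)],
                 clean$scaffolds$length_bp[clean$scaffolds$scaffold_id == sc])
    if (nrow(spans) > 1)
      expect_equal(spans$start[-1], spans$end[-nrow(spans)])
  }

  # requesting more markers than loci is rejected
  tiny <- simulate_true_map(n_chr = 1, chr_length_cM = 10, loci_per_chr = 5,
                            seed = 25)
  expect_error(
    simulate_assembly(tiny, 50,
                      markers_per_scaffold_dist = c(0, 0, 0, 1, rep(0, 7)),
                      seed = 26),
    "exceed available loci")

  expect_identical(simulate_assembly(tm, 40, seed = 30)$marker_loci,
                   simulate_assembly(tm, 40, seed = 30)$marker_loci)
})

test_that("coalescent panels match neutral expectations", {
  # n = 2: mean pairwise difference = theta
  theta <- 2
  diffs <- vapply(1:5000, function(i) {
    p <- simulate_coalescent_probe(2, theta, seed = i)
    sum(p$haplotypes[1, ] != p$haplotypes[2, ])
  }, 0)
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - theta), 3 * se)

  # n = 10: mean S = theta * a1(10)
  S <- vapply(1:5000, function(i)
    ncol(simulate_coalescent_probe(10, theta, seed = 10000 + i)$haplotypes),
    0)
  a1 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - theta * a1), 3 * stats::sd(S) / sqrt(length(S)))

  # infinite sites: every column segregates once; positions increasing
  p <- simulate_coalescent_probe(8, 5, seed = 99)
  cs <- colSums(p$haplotypes)
  expect_true(all(cs > 0 & cs < 8))
  expect_true(all(diff(p$site_positions) > 0))
  expect_identical(simulate_coalescent_probe(8, 5, seed = 42)$haplotypes,
                   simulate_coalescent_probe(8, 5, seed = 42)$haplotypes)

  # tiny theta: most replicates are monomorphic
  S0 <- vapply(1:200, function(i)
    ncol(simulate_coalescent_probe(10, 0.01, seed = i)$haplotypes), 0)
  expect_gt(mean(S0 == 0), 0.9)

  expect_error(simulate_coalescent_probe(1, 1), "n_samples")
  expect_error(simulate_coalescent_probe(5, 0), "theta")
})
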