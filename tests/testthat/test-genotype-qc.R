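test_that("heterozygote collapse converts calls and scores contamination", {
  calls <- matrix(c(0L, 1L, 2L, NA, 1L, 0L,
                    0L, 0L, 0L, 0L, 0L, 0L), nrow = 6,
                  dimnames = list(paste0("m", 1:6), c("s1", "s2")))
  hap <- collapse_heterozygous_calls(calls)
  expect_equal(hap$sample_qc$het_fraction, c(1 / 5, 0))
  expect_true(is.na(hap$alleles["m3", "s1"]))
  expect_equal(hap$alleles[, "s2"], setNames(rep(0L, 6), paste0("m", 1:6)))

  # 3 het of 10 non-missing -> 0.3, and those calls become missing
  calls10 <- matrix(c(rep(0L, 4), rep(1L, 3), rep(2L, 3)), ncol = 1,
                    dimnames = list(paste0("m", 1:10), "s"))
  hap10 <- collapse_heterozygous_calls(calls10)
  expect_equal(hap10$sample_qc$het_fraction, 0.3)
  expect_equal(sum(is.na(hap10$alleles)), 3L)

  # collapse is idempotent: re-collapsing the collapsed matrix changes nothing
  again <- collapse_heterozygous_calls(hap10$alleles)
  expect_identical(again$alleles, hap10$alleles)
  expect_equal(again$sample_qc$het_fraction, 0)

  # contamination recovered per sample from a simulated mixture
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 50, loci_per_chr = 200,
                          seed = 31)
  fam <- simulate_haploid_family(tm, "f", 50, seed = 32)
  mix <- simulate_mixture(list(fam), contamination_rate = 0.06, seed = 33)
  hf <- collapse_heterozygous_calls(mix$calls)$sample_qc$het_fraction
  expect_lt(abs(mean(hf) - 0.06), 3 * sqrt(0.06 * 0.94 / (200 * 50)))
})

test_that("sample filters use strict thresholds and are idempotent", {
  mk <- function(n_het, n_miss, n = 100) {
    v <- c(rep(2L, n_het), rep(NA_integer_, n_miss),
           rep(0L, n - n_het - n_miss))
    v
  }
  calls <- cbind(a = mk(11, 0), b = mk(0, 20), c = mk(10, 0), d = mk(0, 21))
  rownames(calls) <- paste0("m", 1:100)
  hap <- collapse_heterozygous_calls(calls)
  flt <- filter_samples(hap)
  # het 0.11 > 0.10 removed; missing exactly 0.20 retained (strict >)
  expect_setequal(colnames(flt$alleles), c("b", "c"))
  expect_setequal(flt$exclusions$sample_id, c("a", "d"))
  expect_equal(flt$exclusions$reason[flt$exclusions$sample_id == "a"],
               "het_fraction")
  # filtering an already filtered matrix is a no-op
  flt2 <- filter_samples(flt)
  expect_identical(flt2$alleles, flt$alleles)
  expect_equal(nrow(flt2$exclusions), 0L)

  expect_warning(filter_samples(hap, het_max = 0, miss_max = 0), "all samples")
})

test_that("clean simulated families pass the sample filters", {
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 50, loci_per_chr = 60,
                          seed = 41)
  fam <- simulate_haploid_family(tm, "f", 40, missing_rate = 0.05, seed = 42)
  mix <- simulate_mixture(list(fam), 0, seed = 43)
  flt <- filter_samples(collapse_heterozygous_calls(mix$calls))
  expect_equal(nrow(flt$exclusions), 0L)
  expect_equal(ncol(flt$alleles), 40L)
})

test_that("family clustering recovers planted families exactly", {
  # 12 chromosomes: with few chromosomes the shared maternal haplotype
  # blocks themselves form clusters within a family
  tm <- simulate_true_map(n_chr = 12, chr_length_cM = 80, loci_per_chr = 30,
                          seed = 51)
  mothers <- simulate_maternal_genotypes(tm, 3, seed = 52)
  fams <- lapply(1:3, function(i)
    simulate_haploid_family(tm, paste0("fam", i), 100, seed = 52 + i,
                            maternal = mothers[[i]]))
  mix <- simulate_mixture(fams, 0, seed = 56)
  hap <- collapse_heterozygous_calls(mix$calls)
  cl <- cluster_families(hap$alleles, max_k = 6)
  expect_equal(cl$k, 3L)
  ari <- mclust::adjustedRandIndex(cl$assignment,
                                   mix$true_labels[names(cl$assignment)])
  expect_equal(ari, 1)

  # a single family yields k = 1
  solo <- cluster_families(fams[[1]]$alleles, max_k = 5)
  expect_equal(solo$k, 1L)

  # duplicated sample columns co-cluster
  dup <- cbind(hap$alleles, DUP1 = hap$alleles[, 1], DUP2 = hap$alleles[, 1])
  cl2 <- cluster_families(dup, max_k = 6)
  expect_equal(length(unique(cl2$assignment[c(colnames(hap$alleles)[1],
                                              "DUP1", "DUP2")])), 1L)
})

test_that("testcross recoding keeps exactly the informative markers", {
  alleles <- rbind(m_both = c(0L, 1L, 0L, 1L, 1L),
                   m_mono = c(0L, 0L, 0L, 0L, 0L),
                   m_miss = rep(NA_integer_, 5))
  colnames(alleles) <- paste0("s", 1:5)
  fam <- setNames(rep("A", 5), colnames(alleles))
  rec <- recode_testcross(alleles, fam)
  expect_equal(rownames(rec$A$alleles), "m_both")
  expect_setequal(rec$A$dropped$marker_id, c("m_mono", "m_miss"))
  expect_equal(rec$A$dropped$reason[rec$A$dropped$marker_id == "m_miss"],
               "all-missing")
  # dropped + retained = input
  expect_equal(nrow(rec$A$alleles) + nrow(rec$A$dropped), nrow(alleles))

  # on an error-free family the informative markers are the maternal hets
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 60, loci_per_chr = 80,
                          seed = 61)
  mo <- simulate_maternal_genotypes(tm, 1, seed = 62)[[1]]
  famS <- simulate_haploid_family(tm, "f", 60, seed = 63, maternal = mo)
  recS <- recode_testcross(famS$alleles,
                           setNames(rep("f", 60), colnames(famS$alleles)))
  expect_setequal(rownames(recS$f$alleles), names(mo$het)[mo$het])
})

test_that("segregation distortion test matches the chi-square oracle", {
  bins <- rbind(fair = c(rep(0L, 50), rep(1L, 50)),
                skew = c(rep(0L, 80), rep(1L, 20)))
  res <- test_segregation_distortion(bins)
  expect_equal(res$chisq, c(0, 36))
  expect_equal(res$p[1], 1)
  expect_false(res$distorted[1])
  expect_true(res$distorted[2])
  # an 80/20 split stays significant even under a genome-wide Bonferroni
  expect_lt(res$p[2], 0.05 / 3924)

  # untestable bin flagged, not counted
  bins2 <- rbind(bins, empty = rep(NA_integer_, 100))
  res2 <- test_segregation_distortion(bins2)
  expect_false(res2$testable[3])
  expect_true(is.na(res2$p[3]))

  # type-I error at nominal alpha on fair segregation (no correction)
  set.seed(71)
  fair <- matrix(rbinom(2000 * 1000, 1, 0.5), nrow = 2000)
  rownames(fair) <- paste0("b", 1:2000)
  rf <- test_segregation_distortion(fair)
  frac <- mean(rf$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
  # with Bonferroni over 100 fair bins, expect no flags
  r100 <- test_segregation_distortion(fair[1:100, ])
  expect_equal(sum(r100$distorted), 0L)
})
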