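test_that("marker binning is exact on signatures including missingness", {
  sig <- rbind(a = c(0L, 1L, 0L, 1L),
               b = c(0L, 1L, 0L, 1L),          # duplicate of a
               c = c(0L, 1L, 1L, 1L),          # differs at one call
               d = c(0L, 1L, NA, 1L))          # missing where a is observed
  colnames(sig) <- paste0("s", 1:4)
  bn <- bin_markers(sig)
  members <- bn$members
  expect_equal(sort(members[["a"]]), c("a", "b"))
  expect_true(all(c("c", "d") %in% bn$bins$bin_id))
  expect_equal(nrow(bn$bins), 3L)
  # representative has fewest missing calls, ties broken lexicographically
  expect_equal(bn$bins$representative[bn$bins$bin_id == "a"], "a")
})

test_that("two-point estimates match closed forms and are symmetric", {
  a <- rep(c(0L, 1L), 5)
  est <- estimate_rf(a, a)
  expect_equal(est$r, 0)
  expect_equal(est$lod, 10 * log10(2), tolerance = 1e-12)
  expect_equal(est$n_informative, 10L)

  b <- a; b[1:2] <- 1L - b[1:2]
  est2 <- estimate_rf(a, b)
  expect_equal(est2$r, 0.2)
  expect_equal(est2$lod, 2 * log10(0.4) + 8 * log10(1.6), tolerance = 1e-12)
  expect_equal(round(est2$lod, 3), 0.837)

  # a vector versus its complement: r = 0 via phase flip
  comp <- estimate_rf(a, 1L - a)
  expect_equal(comp$r, 0)
  expect_equal(comp$phase, "repulsion")

  # symmetry
  set.seed(81)
  x <- sample(c(0L, 1L, NA), 30, replace = TRUE)
  y <- sample(c(0L, 1L, NA), 30, replace = TRUE)
  expect_identical(estimate_rf(x, y)[c("r", "lod", "n_informative")],
                   estimate_rf(y, x)[c("r", "lod", "n_informative")])

  none <- estimate_rf(c(NA, NA), c(0L, 1L))
  expect_true(is.na(none$r))
  expect_equal(none$n_informative, 0L)
})

test_that("linkage_data matrices agree with pairwise estimate_rf", {
  set.seed(82)
  sig <- matrix(sample(c(0L, 1L, NA), 8 * 40, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)), nrow = 8,
                dimnames = list(paste0("m", 1:8), NULL))
  ld <- linkage_data(sig)
  for (i in 1:7) for (j in (i + 1):8) {
    e <- estimate_rf(sig[i, ], sig[j, ])
    if (e$n_informative == 0) next
    expect_equal(ld$rfrac[i, j], e$r)
    expect_equal(ld$lod[i, j], e$lod)
    expect_equal(ld$n[i, j], e$n_informative)
  }
})

test_that("grouping uses transitive closure and isolates unlinked markers", {
  set.seed(83)
  n <- 300
  a <- rep(c(0L, 1L), n / 2)
  b <- a; b[1:75] <- 1L - b[1:75]          # r(a,b) = 0.25
  c <- b; c[76:150] <- 1L - c[76:150]      # r(b,c) = 0.25, r(a,c) = 0.5
  u <- rbinom(n, 1, 0.5)                   # unlinked
  sig <- rbind(a = a, b = b, c = c, u = u)
  storage.mode(sig) <- "integer"
  ld <- linkage_data(sig)
  expect_equal(unname(ld$rfrac["a", "c"]), 0.5)  # no direct a-c edge
  grp <- group_markers(ld)
  expect_equal(length(grp$groups), 1L)
  expect_setequal(grp$groups[[1]], c("a", "b", "c"))
  expect_equal(grp$singletons, "u")
})

test_that("grouping separates simulated chromosomes", {
  tm <- simulate_true_map(n_chr = 2, chr_length_cM = 100, loci_per_chr = 20,
                          seed = 84)
  fam <- simulate_haploid_family(tm, "f", 300, seed = 85)
  bn <- bin_markers(fam$alleles)
  ld <- linkage_data(bn$signatures)
  grp <- group_markers(ld)
  expect_equal(length(grp$groups), 2L)
  for (g in grp$groups) {
    reps <- bn$bins$representative[match(g, bn$bins$bin_id)]
    chr_of <- tm$loci$chr_id[match(reps, tm$loci$marker_id)]
    expect_equal(length(unique(chr_of)), 1L)
  }
})

test_that("RECORD finds the exhaustive-minimum order on clean data", {
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 60, loci_per_chr = 6,
                          seed = 91)
  fam <- simulate_haploid_family(tm, "f", 400, seed = 92)
  ld <- linkage_data(fam$alleles)
  om <- order_record(ld, rownames(fam$alleles), n_counts = 16, seed = 93)

  perms <- haplomap:::all_perms(6)
  counts <- apply(perms, 1, function(p)
    oracle_count(rownames(fam$alleles)[p], fam$alleles))
  expect_equal(om$count_score, min(counts))
  truth <- tm$loci$marker_id[order(tm$loci$true_cM)]
  expect_true(identical(om$bins, truth) || identical(om$bins, rev(truth)))
  # reversal ambiguity fixed: lower id end first
  expect_true(om$bins[1] < om$bins[length(om$bins)])

  # two markers: the single possible order
  om2 <- order_record(ld, rownames(fam$alleles)[1:2], seed = 1)
  expect_equal(length(om2$bins), 2L)

  # optimization property: never worse than a random shuffle
  set.seed(94)
  for (i in 1:5) {
    sh <- sample(rownames(fam$alleles))
    expect_lte(om$count_score, oracle_count(sh, fam$alleles))
  }
})

test_that("ripple repairs a planted adjacent swap and never raises COUNT", {
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 80, loci_per_chr = 12,
                          seed = 101)
  fam <- simulate_haploid_family(tm, "f", 400, seed = 102)
  ld <- linkage_data(fam$alleles)
  truth <- tm$loci$marker_id[order(tm$loci$true_cM)]
  swapped <- truth
  swapped[6:7] <- swapped[7:6]
  bad <- structure(list(lg_id = NA_character_, bins = swapped,
                        count_score = oracle_count(swapped, fam$alleles),
                        adj_r = numeric(), cM = numeric()),
                   class = "ordered_map")
  fixed <- ripple_window(bad, ld, window = 4, step = 1)
  expect_true(identical(fixed$bins, truth) ||
                identical(fixed$bins, rev(truth)))
  expect_lte(fixed$count_score, bad$count_score)

  # an already optimal small order is unchanged
  again <- ripple_window(fixed, ld, window = 4, step = 1)
  expect_identical(again$bins, fixed$bins)

  # window larger than the group spans the whole group
  small <- order_record(ld, truth[1:3], seed = 1)
  rip <- ripple_window(small, ld, window = 10, step = 1)
  expect_equal(length(rip$bins), 3L)
})

test_that("Kosambi mapping matches closed forms and its invariants", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.5))
  expect_equal(round(kosambi(0.1), 2), 10.14)
  expect_equal(kosambi(0.25), 25 * log(3))
  expect_equal(round(kosambi(0.25), 2), 27.47)
  expect_error(kosambi(0.5), "0.5")

  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi(r)
  expect_true(all(d >= 100 * r - 1e-9))
  expect_true(all(diff(d) > 0))
})

test_that("cM positions are cumulative Kosambi distances along the order", {
  tm <- simulate_true_map(n_chr = 1, chr_length_cM = 40, loci_per_chr = 5,
                          seed = 111)
  fam <- simulate_haploid_family(tm, "f", 300, seed = 112)
  ld <- linkage_data(fam$alleles)
  om <- kosambi_map(order_record(ld, rownames(fam$alleles), seed = 113), ld)
  expect_equal(om$cM[1], 0)
  expect_true(all(diff(om$cM) >= 0))
  expect_equal(om$cM, cumsum(c(0, kosambi(om$adj_r))))

  pm <- pairwise_matrices(om, ld)
  expect_equal(dim(pm$rfrac), c(5L, 5L))
  expect_equal(unname(diag(pm$rfrac)), rep(0, 5))
  e <- estimate_rf(fam$alleles[om$bins[1], ], fam$alleles[om$bins[2], ])
  expect_equal(unname(pm$rfrac[1, 2]), e$r)
  expect_equal(unname(pm$heat[2, 1]), e$r)       # lower triangle: rfrac
  expect_equal(unname(pm$heat[1, 2]), e$lod)     # upper triangle: LOD
})
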