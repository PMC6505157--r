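make_consensus <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(marker_id = r[[1]], lg = r[[2]], cM = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)))
}

test_that("scaffold classification follows the 5 cM split rule", {
  consensus <- make_consensus(
    list("a1", "LG01", 3.0), list("a2", "LG01", 7.9),     # span 4.9
    list("b1", "LG01", 3.0), list("b2", "LG01", 8.5),     # span 5.5
    list("c1", "LG01", 1.0), list("c2", "LG03", 1.0),     # two LGs
    list("d1", "LG02", 10.0),                             # single marker
    list("e1", "LG01", 0.0), list("e2", "LG01", 5.0))     # span exactly 5
  meta <- data.frame(
    marker_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "e1", "e2"),
    scaffold_id = c("A", "A", "B", "B", "C", "C", "D", "E", "E"),
    stringsAsFactors = FALSE)
  cl <- classify_scaffolds(consensus, meta)
  classes <- setNames(cl$classes$class, cl$classes$scaffold_id)
  expect_equal(classes[["A"]], "consistent")
  expect_equal(classes[["B"]], "intra-split")
  expect_equal(classes[["C"]], "inter-split-2")
  expect_equal(classes[["D"]], "single-marker")
  expect_equal(classes[["E"]], "consistent")   # exactly 5 cM stays together
  # the classes partition the multi-marker scaffolds
  s <- setNames(cl$summary$value, cl$summary$quantity)
  expect_equal(s[["consistent"]] + s[["intra_split"]] + s[["inter_split"]],
               s[["multi_marker_scaffolds"]])
  # markers without a consensus position are reported, not classified
  meta2 <- rbind(meta, data.frame(marker_id = "zz", scaffold_id = "Z"))
  expect_equal(classify_scaffolds(consensus, meta2)$unplaced, "zz")
})

test_that("component-map cross-checking labels split support correctly", {
  meta <- data.frame(marker_id = c("x1", "x2", "y1", "y2", "z1", "z2"),
                     scaffold_id = c("X", "X", "Y", "Y", "Z", "Z"),
                     stringsAsFactors = FALSE)
  # component 1 reproduces X's split; co-locates Y; contains only z1
  comp1 <- make_consensus(list("x1", "LG01", 0), list("x2", "LG02", 0),
                          list("y1", "LG01", 1), list("y2", "LG01", 2),
                          list("z1", "LG01", 5))
  # component 2 contains only z2
  comp2 <- make_consensus(list("z2", "LG02", 8))
  res <- crosscheck_component_support(
    c("X", "Y", "Z"), list(c1 = comp1, c2 = comp2), meta)
  verdict <- setNames(res$component_support, res$scaffold_id)
  expect_equal(verdict[["X"]], "supported")
  expect_equal(verdict[["Y"]], "artifact")
  expect_equal(verdict[["Z"]], "unverifiable")
})

test_that("split annotation localizes joins against genes and gaps", {
  # hand-built scaffold: two 5 kb contigs around a 100 bp gap; markers at
  # 2500/4500 (contig 1) and 5600/8000 (contig 2); a gene spans the gap
  sset <- list(
    genes = data.frame(scaffold_id = "S", gene_id = c("gA", "gB"),
                       start_bp = c(4000, 9000), end_bp = c(6500, 9500),
                       confidence = "high", stringsAsFactors = FALSE),
    gaps = data.frame(scaffold_id = "S", start = 5000, end = 5100),
    marker_loci = data.frame(
      marker_id = c("m1", "m2", "m3", "m4"), scaffold_id = "S",
      scaffold_bp = c(2500, 4500, 5600, 8000), stringsAsFactors = FALSE))
  consensus <- make_consensus(list("m1", "LG01", 0), list("m2", "LG01", 1),
                              list("m3", "LG05", 0), list("m4", "LG05", 1))
  ann <- annotate_splits("S", consensus, sset)
  expect_equal(nrow(ann$annotations), 1L)
  a <- ann$annotations
  expect_equal(a$split_start_bp, 4500)
  expect_equal(a$split_end_bp, 5600)
  expect_equal(a$category, "within-gene")
  expect_equal(a$gene_id, "gA")
  expect_true(a$at_contig_join)

  # interior-region: 5' and 3' markers co-map, interior maps elsewhere
  consensus2 <- make_consensus(list("m1", "LG02", 0), list("m2", "LG07", 0),
                               list("m3", "LG07", 1), list("m4", "LG02", 1))
  ann2 <- annotate_splits("S", consensus2, sset)
  expect_true(all(ann2$annotations$category == "interior-region"))

  # split interval away from any gap is not at a contig join
  sset3 <- sset
  sset3$gaps <- data.frame(scaffold_id = "S", start = 9000, end = 9100)
  ann3 <- annotate_splits("S", consensus, sset3)
  expect_false(ann3$annotations$at_contig_join)
})

test_that("planted chimeras round-trip through assembly and annotation", {
  tm <- simulate_true_map(n_chr = 4, chr_length_cM = 90, loci_per_chr = 60,
                          clusters_per_chr = 20, seed = 171)
  sset <- simulate_assembly(tm, 80, inter_chimera_rate = 0.2, seed = 172,
                            markers_per_scaffold_dist =
                              c(0.3, 0.3, 0.2, 0.1, 0.1, 0, 0, 0, 0, 0, 0))
  tm2 <- assign_scaffolds(tm, sset)
  fam <- simulate_haploid_family(tm2, "f", 300, seed = 173)
  cm <- build_component_map(fam$alleles, seed = 174)
  mp <- map_positions(cm)
  cl <- classify_scaffolds(mp, tm2$loci)
  truthful <- merge(cl$classes,
                    sset$scaffolds[, c("scaffold_id", "chimera_label")])
  multi <- truthful[truthful$class != "single-marker", ]
  chim <- multi[multi$chimera_label == "inter", ]
  expect_gte(mean(grepl("inter-split", chim$class)), 0.9)
  clean <- multi[multi$chimera_label == "none", ]
  expect_equal(sum(grepl("split", clean$class)), 0L)
  # planted joins sit at gap spans, and the annotator finds them there
  ann <- annotate_splits(cl$classes, mp, sset)
  located <- ann$annotations[ann$annotations$category != "unlocalizable", ]
  expect_true(all(located$at_contig_join))
})

test_that("Welch comparison of scaffold lengths matches hand computation", {
  lengths <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  res <- compare_scaffold_lengths(split_ids = paste0("s", 4:6),
                                  multimarker_ids = paste0("s", 1:3),
                                  lengths = lengths)
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(round(res$df, 0), 4)
  expect_equal(round(res$p, 4), 0.0213)
  # identical groups: t = 0, p = 1
  same <- compare_scaffold_lengths(paste0("s", 1:3), paste0("s", 1:3),
                                   lengths)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_scaffold_lengths("s1", paste0("s", 1:3), lengths),
               "at least 2")
})

test_that("published scaffold accounting identities reproduce", {
  counts <- spruce_reference_tables()$assembly_counts
  acc <- scaffold_accounting(c(
    mapped = counts[["mapped_scaffolds"]],
    multi_marker = counts[["multi_marker_scaffolds"]],
    inter_split = counts[["inter_split"]],
    intra_split = counts[["intra_split"]],
    splits_total = counts[["splits_total"]],
    splits_at_join = counts[["splits_at_join"]]))
  v <- setNames(acc$value, acc$quantity)
  expect_equal(round(v[["multi_marker_pct_of_mapped"]], 1), 33.9)
  expect_equal(round(v[["inter_split_pct_of_mapped"]], 2), 1.14)
  expect_equal(round(v[["inter_split_pct_of_multi"]], 2), 3.38)
  expect_equal(round(v[["intra_split_pct_of_mapped"]], 2), 0.18)
  expect_equal(round(v[["intra_split_pct_of_multi"]], 2), 0.54)
  expect_equal(v[["split_scaffolds_total"]], 190)
  expect_equal(round(v[["pct_splits_at_contig_join"]], 0), 84)
})
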