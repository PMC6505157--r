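# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

# COUNT of a marker order: adjacent phase-aligned mismatch counts, naive loop
oracle_count <- function(ord, alleles) {
  total <- 0
  for (i in seq_len(length(ord) - 1)) {
    a <- alleles[ord[i], ]
    b <- alleles[ord[i + 1], ]
    ok <- !is.na(a) & !is.na(b)
    k <- sum(a[ok] != b[ok])
    total <- total + min(k, sum(ok) - k)
  }
  total
}

# Kendall tau-b by explicit pair counting
oracle_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i])
    dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# mean pairwise difference count between haplotype rows, naive loop
oracle_pairwise_diffs <- function(H) {
  n <- nrow(H)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(H[i, ] != H[j, ])
  tot / (n * (n - 1) / 2)
}

# Tajima's D recomputed from first principles (Tajima 1989)
oracle_tajima_d <- function(S, pi_total, n) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# squared allele-frequency correlation between two complete binary vectors
oracle_r2 <- function(x, y) {
  p <- mean(x); q <- mean(y)
  D <- mean(x * y) - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}

# Kendall tau of a recovered LG order against true positions, reversal-proof
truth_tau <- function(positions_cM, marker_ids, true_map) {
  truth <- true_map$loci$true_cM[match(marker_ids, true_map$loci$marker_id)]
  abs(stats::cor(positions_cM, truth, method = "kendall"))
}

# ten-site VCF where each of seven sites violates exactly one hard filter
# and three survive; sample S4 is 2/3 missing over the surviving sites
write_filter_fixture_vcf <- function(path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"))
  row <- function(chrom, pos, id, ref, alt, info, gts)
    paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT", gts),
          collapse = "\t")
  gt_ok <- c("0/0", "0/1", "1/1", "0/0")
  gt_na <- c("0/0", "1/1", "0/1", "./.")
  lines <- c(
    row("sc1", 150, "keep1", "A", "T", "QD=10;MQ=60;DP=5000", gt_ok),
    row("sc1", 160, "keep2", "C", "G", "QD=8;MQ=55;DP=4000", gt_na),
    row("sc1", 170, "qd_low", "A", "G", "QD=4;MQ=60;DP=5000", gt_ok),
    row("sc1", 180, "mq_low", "A", "G", "QD=10;MQ=45;DP=5000", gt_ok),
    row("sc1", 190, "dp_low", "A", "G", "QD=10;MQ=60;DP=2000", gt_ok),
    row("sc1", 200, "dp_high", "A", "G", "QD=10;MQ=60;DP=20000", gt_ok),
    row("sc1", 210, "indel", "AT", "A", "QD=10;MQ=60;DP=5000", gt_ok),
    row("sc1", 900, "outside", "A", "G", "QD=10;MQ=60;DP=5000", gt_ok),
    row("sc1", 220, "no_anno", "A", "G", "MQ=60;DP=5000", gt_ok),
    row("sc1", 230, "keep3", "G", "T", "QD=6;MQ=51;DP=3000", gt_na))
  writeLines(c(hdr, lines), path)
  path
}
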