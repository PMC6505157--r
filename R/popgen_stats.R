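# Per-probe neutrality statistics from a diversity panel, anchored to the
# genetic map.  Genotype matrices are sites x samples; haploid panels carry
# 0/1 allele counts, diploid panels 0/1/2 dosages (treated as 2n haplotypes
# of unknown phase: pi/S/D are allele-frequency based, r^2 is the composite
# genotype correlation).

#' Hard-filter a diversity-panel VCF to usable bi-allelic probe SNPs
#'
#' Site filters (in order, each removal counted in the ledger): missing
#' QD/MQ/DP annotation; not a bi-allelic SNP; outside every extended probe
#' region; `QD <= qd_min`; `MQ <= mq_min`; total `DP` outside `dp_range`
#' (inclusive).  Afterwards, samples whose missing fraction over the kept
#' sites exceeds `sample_miss_max` are dropped.
#'
#' @param vcf a `vcfR` object or path to a VCF file.
#' @param regions data frame of extended probe regions: `probe_id`, `chrom`,
#'   `start`, `end` (1-based inclusive; see [read_probe_bed()]).
#' @param qd_min,mq_min exclusive lower bounds (defaults 5 and 50).
#' @param dp_range inclusive total-depth range (default `c(3000, 16000)`).
#' @param sample_miss_max maximum per-sample missing fraction (default
#'   0.25; strict >).
#' @return list with `gt` (site x sample allele-dosage matrix, NA =
#'   missing), `sites` (data frame `chrom`, `pos`, `probe_id`), `ledger`
#'   (data frame `rule`, `n_removed`), `samples_removed`.
#' @export
filter_variants <- function(vcf, regions, qd_min = 5, mq_min = 50,
                            dp_range = c(3000, 16000),
                            sample_miss_max = 0.25) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  chrom <- fix[, "CHROM"]; pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD")))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  n <- length(chrom)
  keep <- rep(TRUE, n)
  ledger <- list()
  drop_rule <- function(bad, rule) {
    bad <- bad & keep
    ledger[[length(ledger) + 1L]] <<- data.frame(rule = rule,
                                                 n_removed = sum(bad))
    keep <<- keep & !bad
  }
  drop_rule(is.na(qd) | is.na(mq) | is.na(dp), "missing_annotation")
  biallelic <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 &
    nchar(alt) == 1 & alt %in% c("A", "C", "G", "T")
  drop_rule(!biallelic, "not_biallelic_snp")
  probe <- rep(NA_character_, n)
  for (i in seq_len(nrow(regions))) {
    hit <- chrom == regions$chrom[i] & pos >= regions$start[i] &
      pos <= regions$end[i]
    probe[hit & is.na(probe)] <- regions$probe_id[i]
  }
  drop_rule(is.na(probe), "outside_probe_regions")
  drop_rule(qd <= qd_min, "QD")
  drop_rule(mq <= mq_min, "MQ")
  drop_rule(dp < dp_range[1] | dp > dp_range[2], "DP")
  gt_raw <- vcfR::extract.gt(vcf)[keep, , drop = FALSE]
  gt <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  clean <- gsub("\\|", "/", gt_raw)
  # haploid GT ("0"/"1") maps to dosage 0/1; diploid to 0/1/2
  gt[clean %in% c("0", "0/0")] <- 0
  gt[clean %in% c("0/1", "1/0")] <- 1
  gt[clean == "1"] <- 1
  gt[clean == "1/1"] <- 2
  miss <- colMeans(is.na(gt))
  bad_sample <- miss > sample_miss_max
  list(gt = gt[, !bad_sample, drop = FALSE],
       sites = data.frame(chrom = chrom[keep], pos = pos[keep],
                          probe_id = probe[keep], stringsAsFactors = FALSE),
       ledger = do.call(rbind, ledger),
       samples_removed = colnames(gt)[bad_sample])
}

# allele frequencies and chromosome counts per site
site_freqs <- function(gt, ploidy) {
  n_chrom <- ploidy * rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  list(p = ifelse(n_chrom > 0, alt / n_chrom, NA_real_), n = n_chrom)
}

# Tajima (1989) constants for sample size n (chromosomes)
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Per-region neutrality statistics: S, pi and Tajima's D
#'
#' `S` is the count of segregating sites; `pi` is the average pairwise
#' diversity per site, `sum(2 p (1 - p) n / (n - 1)) / callable_sites`
#' (the unbiased per-site heterozygosity summed over sites, divided by the
#' callable length); Tajima's D follows the 1989 definition with constants
#' computed from the mean per-segregating-site chromosome count.  D is
#' undefined (`NA`) when `S = 0`.
#'
#' @param gt site x sample genotype matrix: 0/1 (haploid haplotypes) or
#'   0/1/2 dosages (diploid), NA = missing.
#' @param callable_sites denominator for per-site pi (default: number of
#'   rows of `gt`).
#' @param ploidy 1 or 2; default guesses 2 when any dosage equals 2.
#' @return one-row data frame: `S`, `pi`, `pi_total`, `theta_w`,
#'   `tajima_d`, `n_mean` (mean chromosomes per segregating site),
#'   `callable_sites`.
#' @export
neutrality_stats <- function(gt, callable_sites = nrow(gt), ploidy = NULL) {
  if (!is.matrix(gt)) gt <- as.matrix(gt)
  if (is.null(ploidy)) ploidy <- if (any(gt == 2, na.rm = TRUE)) 2L else 1L
  if (nrow(gt) == 0 || all(is.na(gt)))
    return(data.frame(S = 0L, pi = 0, pi_total = 0, theta_w = 0,
                      tajima_d = NA_real_, n_mean = NA_real_,
                      callable_sites = callable_sites))
  fr <- site_freqs(gt, ploidy)
  seg <- !is.na(fr$p) & fr$p > 0 & fr$p < 1 & fr$n >= 2
  S <- sum(seg)
  pi_site <- ifelse(seg & fr$n >= 2,
                    2 * fr$p * (1 - fr$p) * fr$n / (fr$n - 1), 0)
  pi_total <- sum(pi_site, na.rm = TRUE)
  if (S == 0)
    return(data.frame(S = 0L, pi = 0, pi_total = 0, theta_w = 0,
                      tajima_d = NA_real_, n_mean = NA_real_,
                      callable_sites = callable_sites))
  n_mean <- mean(fr$n[seg])
  k <- tajima_constants(round(n_mean))
  theta_w <- S / k$a1
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  D <- if (denom > 0) (pi_total - theta_w) / denom else NA_real_
  data.frame(S = S, pi = pi_total / callable_sites, pi_total = pi_total,
             theta_w = theta_w, tajima_d = D, n_mean = n_mean,
             callable_sites = callable_sites)
}

#' Kelly's ZnS: mean pairwise r-squared across segregating sites
#'
#' The mean of the squared allele-frequency correlation r^2 over all
#' unordered pairs of segregating sites in a region, computed over
#' pairwise-complete samples.  For unphased diploid dosages this is the
#' composite (genotype-correlation) LD.  Undefined (`NA`) with fewer than
#' two segregating sites.
#'
#' @param gt site x sample genotype matrix (0/1 or 0/1/2 with NA).
#' @param ploidy see [neutrality_stats()].
#' @return scalar ZnS in `[0, 1]`, or `NA`.
#' @export
zns <- function(gt, ploidy = NULL) {
  if (!is.matrix(gt)) gt <- as.matrix(gt)
  if (is.null(ploidy)) ploidy <- if (any(gt == 2, na.rm = TRUE)) 2L else 1L
  fr <- site_freqs(gt, ploidy)
  seg <- !is.na(fr$p) & fr$p > 0 & fr$p < 1
  if (sum(seg) < 2) return(NA_real_)
  sub <- t(gt[seg, , drop = FALSE])
  r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  r2 <- r[upper.tri(r)]^2
  mean(r2, na.rm = TRUE)
}

#' Anchor probes to consensus cM coordinates
#'
#' A probe that is itself a mapped marker anchors directly; otherwise it
#' takes the coordinates of the physically closest (in bp) mapped probe on
#' the same scaffold.  A bp tie anchors to the candidate with the smaller
#' cM, then the lexicographically smaller probe id.  Probes on scaffolds
#' without any mapped probe are left unassigned.
#'
#' @param probes data frame `probe_id`, `scaffold_id`, `bp`.
#' @param consensus data frame `marker_id`, `lg`, `cM` (marker ids are
#'   probe ids).
#' @param marker_bp data frame `marker_id`, `scaffold_id`, `bp` for the
#'   mapped markers.
#' @return data frame `probe_id`, `lg`, `cM`, `anchor_source` in
#'   {direct, nearest-bp, unassigned}, `anchor_marker`.
#' @export
anchor_probes <- function(probes, consensus, marker_bp) {
  mapped <- merge(marker_bp, consensus[, c("marker_id", "lg", "cM")],
                  by = "marker_id")
  out <- lapply(seq_len(nrow(probes)), function(i) {
    pid <- probes$probe_id[i]
    direct <- mapped[mapped$marker_id == pid, ]
    if (nrow(direct))
      return(data.frame(probe_id = pid, lg = direct$lg[1],
                        cM = direct$cM[1], anchor_source = "direct",
                        anchor_marker = pid, stringsAsFactors = FALSE))
    cand <- mapped[mapped$scaffold_id == probes$scaffold_id[i], ]
    if (!nrow(cand))
      return(data.frame(probe_id = pid, lg = NA_character_, cM = NA_real_,
                        anchor_source = "unassigned",
                        anchor_marker = NA_character_,
                        stringsAsFactors = FALSE))
    d <- abs(cand$bp - probes$bp[i])
    cand <- cand[order(d, cand$cM, cand$marker_id), ]
    data.frame(probe_id = pid, lg = cand$lg[1], cM = cand$cM[1],
               anchor_source = "nearest-bp", anchor_marker = cand$marker_id[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sliding-window track of a per-probe statistic along linkage groups
#'
#' Windows are half-open `[k step, k step + width)` for
#' `k = 0 .. ceiling((L - width) / step)` with `L` the largest anchored cM
#' on the LG; the window mean is the unweighted mean over probes with a
#' defined value; empty windows are reported with `n_probes = 0` and a
#' missing mean.
#'
#' @param anchored data frame with `lg`, `cM` and one or more statistic
#'   columns.
#' @param stats character vector of statistic column names.
#' @param width_cM,step_cM window width and step (defaults 10 and 1; must
#'   be > 0).
#' @param lg_lengths optional named vector of LG lengths in cM; the track of
#'   an LG runs to its full length (default: the largest anchored cM).
#' @return data frame `lg`, `start_cM`, `end_cM`, `n_probes`, one mean
#'   column per statistic.
#' @export
sliding_windows <- function(anchored, stats, width_cM = 10, step_cM = 1,
                            lg_lengths = NULL) {
  if (width_cM <= 0 || step_cM <= 0)
    stop("width_cM and step_cM must be > 0")
  anchored <- anchored[!is.na(anchored$lg) & !is.na(anchored$cM), ]
  out <- list()
  for (lg in sort(unique(anchored$lg))) {
    sub <- anchored[anchored$lg == lg, ]
    L <- if (!is.null(lg_lengths) && lg %in% names(lg_lengths))
      lg_lengths[[lg]] else max(sub$cM)
    ks <- 0:max(0, ceiling((L - width_cM) / step_cM))
    for (k in ks) {
      s <- k * step_cM
      inwin <- sub$cM >= s & sub$cM < s + width_cM
      row <- data.frame(lg = lg, start_cM = s, end_cM = s + width_cM,
                        n_probes = sum(inwin), stringsAsFactors = FALSE)
      for (st in stats) {
        v <- sub[[st]][inwin]
        row[[paste0("mean_", st)]] <- if (any(!is.na(v))) mean(v, na.rm = TRUE)
        else NA_real_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
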