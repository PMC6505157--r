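#' Collapse heterozygous diploid calls to haploid genotypes
#'
#' Megagametophytes are haploid, so any heterozygous call under the diploid
#' genotyping model indicates contamination or genotyping error and is
#' treated as missing data.  Hom-ref becomes allele 0, hom-alt allele 1.  The
#' per-sample heterozygous fraction is computed over non-missing diploid
#' calls *before* the collapse: contamination is a per-genotyped-call
#' property.
#'
#' @param calls marker x sample integer matrix coded 0 = hom-ref,
#'   1 = hom-alt, 2 = het, NA = missing (e.g. from [simulate_mixture()]).
#' @return list with `alleles` (marker x sample 0/1/NA matrix) and
#'   `sample_qc` (data frame: `sample_id`, `het_fraction`,
#'   `missing_fraction`; the missing fraction is computed after collapse).
#' @export
collapse_heterozygous_calls <- function(calls) {
  stopifnot(is.matrix(calls))
  non_missing <- colSums(!is.na(calls))
  n_het <- colSums(calls == 2L, na.rm = TRUE)
  het_fraction <- ifelse(non_missing > 0, n_het / non_missing, 0)
  alleles <- calls
  alleles[alleles == 2L] <- NA_integer_
  missing_fraction <- if (nrow(calls)) colMeans(is.na(alleles)) else
    rep(0, ncol(calls))
  list(alleles = alleles,
       sample_qc = data.frame(
         sample_id = colnames(calls) %||% sprintf("S%d", seq_len(ncol(calls))),
         het_fraction = het_fraction,
         missing_fraction = missing_fraction,
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Exclude contaminated or poorly genotyped samples
#'
#' Samples with a heterozygous-call fraction strictly above `het_max` or a
#' missing fraction strictly above `miss_max` are removed.  The comparisons
#' are strict (">"), so a sample at exactly the threshold is retained.
#'
#' @param hap result of [collapse_heterozygous_calls()] (list with `alleles`
#'   and `sample_qc`).
#' @param het_max,miss_max thresholds in `[0, 1]`; defaults 0.10 and 0.20.
#' @return list with filtered `alleles`, `sample_qc` and an `exclusions`
#'   data frame (`sample_id`, `reason`, `value`).
#' @export
filter_samples <- function(hap, het_max = 0.10, miss_max = 0.20) {
  stopifnot(het_max >= 0, het_max <= 1, miss_max >= 0, miss_max <= 1)
  qc <- hap$sample_qc
  bad_het <- qc$het_fraction > het_max
  bad_miss <- qc$missing_fraction > miss_max
  excl <- rbind(
    data.frame(sample_id = qc$sample_id[bad_het],
               reason = rep("het_fraction", sum(bad_het)),
               value = qc$het_fraction[bad_het], stringsAsFactors = FALSE),
    data.frame(sample_id = qc$sample_id[bad_miss & !bad_het],
               reason = rep("missing_fraction", sum(bad_miss & !bad_het)),
               value = qc$missing_fraction[bad_miss & !bad_het],
               stringsAsFactors = FALSE))
  keep <- !(bad_het | bad_miss)
  if (!any(keep)) warning("all samples removed by QC filters")
  list(alleles = hap$alleles[, keep, drop = FALSE],
       sample_qc = qc[keep, , drop = FALSE],
       exclusions = excl)
}

#' Assign samples to maternal families by PCA and hierarchical clustering
#'
#' PCA is run on the sample-by-marker allele matrix (missing calls
#' mean-imputed per marker), followed by average-linkage hierarchical
#' clustering on the Euclidean distances of the leading principal
#' components.  The number of families k is chosen as the cut of the tree
#' with the largest average silhouette width over 2..`max_k`; if no cut
#' reaches `min_silhouette` the samples are treated as a single family
#' (the silhouette is undefined at k = 1, so a weak-structure floor stands
#' in for it).  The procedure is deterministic given its input.
#'
#' @param alleles marker x sample 0/1/NA matrix.
#' @param max_k maximum number of families to consider.
#' @param n_components number of leading principal components used
#'   (reduced with a warning when fewer are available).
#' @param min_silhouette minimum average silhouette width required to accept
#'   k > 1.
#' @return list with `assignment` (named integer vector sample -> family),
#'   `k`, `sizes`, `silhouette` (per-k average width), and `pca`
#'   (sample scores on the leading components, for reporting).
#' @export
cluster_families <- function(alleles, max_k = 6, n_components = 10,
                             min_silhouette = 0.25) {
  stopifnot(is.matrix(alleles), max_k >= 1)
  n <- ncol(alleles)
  if (n < 2) stop("need at least 2 samples to cluster")
  X <- t(alleles)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mu[j]
  }
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  nc <- min(n_components, n - 1, ncol(X))
  if (nc < n_components)
    warning("reducing PCA components to ", nc)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  d <- stats::dist(scores)
  hc <- stats::hclust(d, method = "average")
  ks <- seq(2, min(max_k, n - 1))
  sil <- stats::setNames(rep(NA_real_, length(ks)), ks)
  cuts <- list()
  for (i in seq_along(ks)) {
    cl <- stats::cutree(hc, k = ks[i])
    cuts[[i]] <- cl
    sil[i] <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  }
  if (length(ks) && max(sil) >= min_silhouette) {
    best <- which.max(sil)
    cl <- cuts[[best]]
    k <- ks[best]
  } else {
    cl <- stats::setNames(rep(1L, n), rownames(X))
    k <- 1L
  }
  names(cl) <- colnames(alleles)
  list(assignment = cl, k = k, sizes = table(cl), silhouette = sil,
       pca = scores)
}

#' Recode markers to testcross (D1.11) form within each family
#'
#' Within a family a marker is informative iff both alleles are observed
#' (mother heterozygous, 1:1 segregation expected).  Monomorphic and
#' all-missing markers are dropped; alleles are kept as 0/1 with phase
#' resolved later during linkage analysis.
#'
#' @param alleles marker x sample 0/1/NA matrix.
#' @param assignment named vector sample -> family (e.g. from
#'   [cluster_families()]); only samples named here are used.
#' @return named list per family: list with `alleles` (informative markers
#'   only) and `dropped` (data frame `marker_id`, `reason`).
#' @export
recode_testcross <- function(alleles, assignment) {
  if (!length(assignment)) stop("family assignment is empty")
  samples <- intersect(colnames(alleles), names(assignment))
  out <- list()
  for (fam in unique(assignment[samples])) {
    cols <- samples[assignment[samples] == fam]
    sub <- alleles[, cols, drop = FALSE]
    n0 <- rowSums(sub == 0L, na.rm = TRUE)
    n1 <- rowSums(sub == 1L, na.rm = TRUE)
    informative <- n0 > 0 & n1 > 0
    reason <- ifelse(n0 + n1 == 0, "all-missing", "monomorphic")
    out[[as.character(fam)]] <- list(
      alleles = sub[informative, , drop = FALSE],
      dropped = data.frame(marker_id = rownames(sub)[!informative],
                           reason = reason[!informative],
                           stringsAsFactors = FALSE))
  }
  out
}

#' Test marker bins for segregation distortion
#'
#' Chi-square goodness-of-fit of the non-missing allele counts against the
#' 1:1 haploid testcross expectation (df = 1), with a Bonferroni flag using
#' the number of testable bins as the correction denominator.
#'
#' @param alleles marker(-bin) x sample 0/1/NA matrix; one row per tested
#'   bin.
#' @param alpha nominal significance level before correction.
#' @return data frame with `marker_id`, `n0`, `n1`, `chisq`, `p`,
#'   `distorted` (Bonferroni-adjusted flag) and `testable`.
#' @export
test_segregation_distortion <- function(alleles, alpha = 0.05) {
  stopifnot(is.matrix(alleles))
  n0 <- rowSums(alleles == 0L, na.rm = TRUE)
  n1 <- rowSums(alleles == 1L, na.rm = TRUE)
  n <- n0 + n1
  testable <- n > 0
  chisq <- ifelse(testable, (n0 - n1)^2 / n, NA_real_)
  p <- ifelse(testable, stats::pchisq(chisq, df = 1, lower.tail = FALSE),
              NA_real_)
  n_tests <- sum(testable)
  data.frame(marker_id = rownames(alleles) %||% as.character(seq_len(nrow(alleles))),
             n0 = n0, n1 = n1, chisq = chisq, p = p,
             distorted = testable & p < alpha / max(n_tests, 1L),
             testable = testable, row.names = NULL,
             stringsAsFactors = FALSE)
}
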