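# Diploid call codes used throughout: 0 = hom-ref, 1 = hom-alt, 2 = het,
# NA = missing.  Haploid alleles: 0/1/NA.

#' Simulate one haploid megagametophyte family
#'
#' Each sample is an independent meiotic product (gamete) of the mother: per
#' chromosome the number of crossovers is Poisson with mean `length_cM / 100`
#' and breakpoints are uniform (no crossover interference, i.e. a
#' Haldane-consistent process).  The gamete alternates between the two
#' maternal haplotypes across breakpoints.  `truth_phase` records, per marker,
#' the allele carried on maternal haplotype "A"; at loci where the mother is
#' homozygous (see `maternal`) both haplotypes carry the same allele and the
#' locus is uninformative.
#'
#' After the gamete is formed, each call is independently flipped with
#' probability `error_rate` (allele-flip genotyping error, the mechanism that
#' inflates map length) and set missing with probability `missing_rate`.
#'
#' @param true_map a [simulate_true_map()] object.
#' @param family_id family label used to name samples.
#' @param n_samples number of megagametophytes (>= 1).
#' @param error_rate,missing_rate probabilities in `[0, 1)`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param maternal optional maternal genotype (one element of
#'   [simulate_maternal_genotypes()]); default: mother heterozygous at every
#'   locus (pure testcross).
#' @return object of class `sim_family`: list with `alleles` (marker x sample
#'   integer matrix in 0/1/NA), `truth_phase` (named 0/1 vector),
#'   `family_id`, rates and `seed`.
#' @export
simulate_haploid_family <- function(true_map, family_id, n_samples,
                                    error_rate = 0, missing_rate = 0,
                                    seed = 1L, maternal = NULL) {
  stopifnot(inherits(true_map, "true_map"))
  if (nrow(true_map$loci) < 1) stop("true map has no loci")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 || missing_rate >= 1)
    stop("rates must lie in [0, 1)")
  set.seed(seed)
  loci <- true_map$loci
  m <- nrow(loci)
  phase <- stats::rbinom(m, 1, 0.5)
  names(phase) <- loci$marker_id
  if (!is.null(maternal)) {
    hom <- !maternal$het[loci$marker_id]
    phase[hom] <- maternal$hom_allele[loci$marker_id][hom]
  }
  alleles <- matrix(NA_integer_, m, n_samples,
                    dimnames = list(loci$marker_id,
                                    sprintf("%s_S%04d", family_id,
                                            seq_len(n_samples))))
  for (ci in seq_len(nrow(true_map$chromosomes))) {
    chr <- true_map$chromosomes$chr_id[ci]
    L <- true_map$chromosomes$length_cM[ci]
    idx <- which(loci$chr_id == chr)
    if (!length(idx)) next
    pos <- loci$true_cM[idx]
    for (s in seq_len(n_samples)) {
      n_xo <- stats::rpois(1, L / 100)
      start <- stats::rbinom(1, 1, 0.5)
      parity <- if (n_xo == 0) rep(start, length(idx)) else
        (findInterval(pos, sort(stats::runif(n_xo, 0, L))) + start) %% 2
      g <- ifelse(parity == 0L, phase[idx], 1L - phase[idx])
      alleles[idx, s] <- g
    }
  }
  if (!is.null(maternal)) {
    hom <- !maternal$het[loci$marker_id]
    if (any(hom))
      alleles[hom, ] <- maternal$hom_allele[loci$marker_id][hom]
  }
  if (error_rate > 0) {
    flip <- matrix(stats::runif(m * n_samples) < error_rate, m, n_samples)
    alleles[flip] <- 1L - alleles[flip]
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(m * n_samples) < missing_rate, m, n_samples)
    alleles[miss] <- NA_integer_
  }
  structure(list(alleles = alleles, truth_phase = phase,
                 family_id = family_id, error_rate = error_rate,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_family")
}

#' @export
print.sim_family <- function(x, ...) {
  cat("sim_family", x$family_id, ":", nrow(x$alleles), "markers x",
      ncol(x$alleles), "samples (error", x$error_rate,
      ", missing", x$missing_rate, ")\n")
  invisible(x)
}

#' Pool families into a diploid-coded call matrix with contamination
#'
#' Emulates the delivered genotype matrix before family assignment is known:
#' family matrices are concatenated column-wise in shuffled order and coded as
#' diploid calls (hom-ref/hom-alt).  With probability `contamination_rate`,
#' each non-missing haploid call is replaced by a heterozygous diploid call,
#' emulating residual diploid seed-coat tissue in a megagametophyte extract.
#' Dimensions are preserved; true family labels are returned separately for
#' scoring.
#'
#' @param families list of [simulate_haploid_family()] objects sharing one
#'   marker list.
#' @param contamination_rate probability in `[0, 1)`.
#' @param seed integer seed (controls shuffle and contamination).
#' @return list with `calls` (marker x sample integer matrix coded
#'   0 = hom-ref, 1 = hom-alt, 2 = het, NA = missing) and `true_labels`
#'   (named character vector, sample -> family).
#' @export
simulate_mixture <- function(families, contamination_rate = 0, seed = 1L) {
  if (!length(families)) stop("need at least one family")
  if (contamination_rate < 0 || contamination_rate >= 1)
    stop("contamination_rate must lie in [0, 1)")
  ref <- rownames(families[[1]]$alleles)
  for (f in families)
    if (!identical(rownames(f$alleles), ref))
      stop("families have conflicting marker lists")
  set.seed(seed)
  calls <- do.call(cbind, lapply(families, function(f) f$alleles))
  labels <- stats::setNames(
    rep(vapply(families, function(f) f$family_id, ""),
        vapply(families, function(f) ncol(f$alleles), 0L)),
    colnames(calls))
  ord <- sample(ncol(calls))
  calls <- calls[, ord, drop = FALSE]
  labels <- labels[ord]
  if (contamination_rate > 0) {
    hit <- matrix(stats::runif(length(calls)) < contamination_rate,
                  nrow(calls), ncol(calls)) & !is.na(calls)
    calls[hit] <- 2L
  }
  list(calls = calls, true_labels = labels)
}
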