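#' Simulate a ground-truth genetic map
#'
#' Builds the "true map" used as the oracle for all downstream recovery tests:
#' a set of chromosomes (linkage groups) with loci placed at known cM
#' positions.  Norway spruce has 12 chromosomes, which is the default.  Each
#' locus initially sits on its own single-marker scaffold; a call to
#' [simulate_assembly()] followed by [assign_scaffolds()] replaces this with a
#' multi-marker scaffold layout.
#'
#' Locus positions are drawn uniformly on each chromosome and sorted, with a
#' small guard distance so that no two loci coincide (coincident loci are
#' recombinationally inseparable and would bin together, which is exercised
#' separately).
#'
#' Physical scaffolds are tiny relative to a chromosome (tens to hundreds of
#' kb against several Mb per cM), so the loci carried by one scaffold are
#' genetically near-coincident.  With `clusters_per_chr` set, loci are
#' placed in that many tight clusters (each spanning `cluster_span_cM`)
#' whose centres are spread over the chromosome — the geometry a
#' gene-bearing-scaffold capture design produces.  The default
#' (`clusters_per_chr = NULL`) places loci uniformly.
#'
#' @param n_chr number of chromosomes.
#' @param chr_length_cM chromosome length(s) in centiMorgan; recycled to
#'   `n_chr`.
#' @param loci_per_chr number of loci per chromosome; recycled.
#' @param families named integer vector of family sizes (megagametophytes per
#'   maternal family), e.g. `c(fam1 = 300)`.
#' @param clusters_per_chr optional number of scaffold-scale locus clusters
#'   per chromosome.
#' @param cluster_span_cM genetic span of one cluster (default 0.4 cM).
#' @param seed integer seed; identical seeds give identical maps.
#' @return an object of class `true_map`: a list with data frames
#'   `chromosomes` (`chr_id`, `length_cM`), `loci` (`marker_id`, `chr_id`,
#'   `true_cM`, `scaffold_id`, `scaffold_bp`) and `families`
#'   (`family_id`, `n_samples`).
#' @export
simulate_true_map <- function(n_chr = 12, chr_length_cM = 100,
                              loci_per_chr = 80,
                              families = c(fam1 = 100),
                              clusters_per_chr = NULL,
                              cluster_span_cM = 0.4, seed = 1L) {
  stopifnot(n_chr >= 1, all(chr_length_cM > 0), all(loci_per_chr >= 1))
  set.seed(seed)
  chr_length_cM <- rep_len(chr_length_cM, n_chr)
  loci_per_chr <- rep_len(loci_per_chr, n_chr)
  chr_id <- sprintf("LG%02d", seq_len(n_chr))
  loci <- do.call(rbind, lapply(seq_len(n_chr), function(i) {
    k <- loci_per_chr[i]
    L <- chr_length_cM[i]
    if (is.null(clusters_per_chr)) {
      # jittered grid keeps loci distinct and roughly evenly covered
      pos <- sort(stats::runif(k, 0, L))
      min_gap <- L / (20 * k)
      pos <- cummax(pos + min_gap * (seq_len(k) - 1))
      pos <- pos / max(pos[k], 1e-9) * L * (k - 0.5) / k
    } else {
      nc <- clusters_per_chr
      centres <- (seq_len(nc) - 0.5) / nc * L +
        stats::runif(nc, -0.2, 0.2) * L / nc
      sizes <- stats::rmultinom(1, k, rep(1, nc))[, 1]
      pos <- sort(unlist(lapply(seq_len(nc), function(ci) {
        if (sizes[ci] == 0) return(numeric())
        centres[ci] + sort(stats::runif(sizes[ci], -cluster_span_cM / 2,
                                        cluster_span_cM / 2))
      })))
      pos <- pmin(pmax(pos, 0), L)
      pos <- cummax(pos + 1e-4 * (seq_len(k) - 1))  # keep loci distinct
    }
    data.frame(chr_id = chr_id[i], true_cM = pos, stringsAsFactors = FALSE)
  }))
  n <- nrow(loci)
  loci$marker_id <- sprintf("M%05d", seq_len(n))
  loci$scaffold_id <- sprintf("SC%05d", seq_len(n))
  loci$scaffold_bp <- 500L
  loci <- loci[, c("marker_id", "chr_id", "true_cM", "scaffold_id", "scaffold_bp")]
  fam <- data.frame(family_id = names(families), n_samples = as.integer(families),
                    stringsAsFactors = FALSE)
  structure(list(
    chromosomes = data.frame(chr_id = chr_id, length_cM = chr_length_cM,
                             stringsAsFactors = FALSE),
    loci = loci, families = fam, seed = seed),
    class = "true_map")
}

#' @export
print.true_map <- function(x, ...) {
  cat("true_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$loci), "loci,", nrow(x$families), "families\n")
  invisible(x)
}

#' Simulate maternal genotypes for a set of unrelated mothers
#'
#' Each mother is assigned a diploid genotype at every locus of the true map,
#' drawing both alleles independently from a population allele frequency.
#' Loci where the mother is heterozygous segregate 1:1 in her megagametophytes
#' (the testcross-informative loci); homozygous loci are monomorphic within
#' the family.  Unrelated mothers therefore differ at their homozygous loci,
#' which is what separates families in a genotype PCA.
#'
#' @param true_map a [simulate_true_map()] object.
#' @param n_families number of unrelated mothers.
#' @param maf_range range of population alternative-allele frequencies.
#' @param seed integer seed.
#' @return list of per-family maternal genotypes, each a list with logical
#'   `het` (marker is heterozygous in the mother) and integer `hom_allele`
#'   (allele carried when homozygous; `NA` at het loci), both named by
#'   marker id.
#' @export
simulate_maternal_genotypes <- function(true_map, n_families,
                                        maf_range = c(0.2, 0.5), seed = 1L) {
  stopifnot(inherits(true_map, "true_map"), n_families >= 1)
  set.seed(seed)
  m <- nrow(true_map$loci)
  ids <- true_map$loci$marker_id
  lapply(seq_len(n_families), function(f) {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    a1 <- stats::rbinom(m, 1, p)
    a2 <- stats::rbinom(m, 1, p)
    het <- a1 != a2
    hom <- ifelse(het, NA_integer_, a1)
    list(het = stats::setNames(het, ids),
         hom_allele = stats::setNames(as.integer(hom), ids))
  })
}

#' Write a true map to TSV
#'
#' Columns: `marker_id`, `chr_id`, `true_cM`, `scaffold_id`, `scaffold_bp`.
#' @param true_map a `true_map` object.
#' @param path output file.
#' @export
write_true_map <- function(true_map, path) {
  stopifnot(inherits(true_map, "true_map"))
  utils::write.table(true_map$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
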