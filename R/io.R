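# Plain-text interchange: VCF/TSV/BED.  Reading of VCF goes through vcfR;
# writing emits VCFv4.2 text directly (round-trip is covered by tests).

#' Write a haploid genotype matrix as VCFv4.2
#'
#' Haploid GT field (`0`, `1`, `.`); one line per marker.  Alleles are
#' reported as REF=A, ALT=T placeholders since the simulation tracks allele
#' state, not nucleotide identity.  Optional per-site INFO annotations (e.g.
#' QD/MQ/DP) are written as `KEY=value` pairs.
#'
#' @param alleles marker x sample matrix in 0/1/NA.
#' @param chrom,pos per-marker CHROM and POS vectors.
#' @param path output file.
#' @param ids marker ids (default rownames).
#' @param info optional data frame of INFO fields (one row per marker).
#' @export
write_genotypes_vcf <- function(alleles, chrom, pos, path,
                                ids = rownames(alleles), info = NULL) {
  stopifnot(is.matrix(alleles), length(chrom) == nrow(alleles),
            length(pos) == nrow(alleles))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=haplomap",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  if (!is.null(info))
    for (k in names(info))
      writeLines(sprintf(
        "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(alleles)), collapse = "\t"),
             con)
  gt <- matrix(".", nrow(alleles), ncol(alleles))
  gt[which(alleles == 0L)] <- "0"
  gt[which(alleles == 1L)] <- "1"
  info_str <- if (is.null(info)) rep(".", nrow(alleles)) else
    apply(info, 1, function(row)
      paste(sprintf("%s=%s", names(info), row), collapse = ";"))
  lines <- paste(chrom, pos, ids, "A", "T", ".", "PASS", info_str, "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a haploid genotype VCF back into a 0/1/NA matrix
#'
#' @param path VCF file.
#' @return list with `alleles` (marker x sample 0/1/NA matrix) and `sites`
#'   (data frame `chrom`, `pos`, `id`).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  alleles <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  alleles[gt == "0"] <- 0L
  alleles[gt == "1"] <- 1L
  fix <- vcfR::getFIX(v)
  list(alleles = alleles,
       sites = data.frame(chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          id = fix[, "ID"], stringsAsFactors = FALSE))
}

#' Write a genotype matrix as TSV (markers in rows)
#' @param alleles marker x sample matrix.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(alleles, path) {
  utils::write.table(cbind(marker_id = rownames(alleles), alleles), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe regions from BED (0-based half-open) into 1-based intervals
#'
#' @param path BED file with columns chrom, start, end, name.
#' @param extend_bp extension added on both sides (default 0; use 100 for
#'   extended probe regions).
#' @return data frame `probe_id`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_probe_bed <- function(path, extend_bp = 0) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(probe_id = bed[[4]], chrom = bed[[1]],
             start = pmax(1L, bed[[2]] + 1L - extend_bp),
             end = bed[[3]] + extend_bp, stringsAsFactors = FALSE)
}

#' Write / read a consensus (or component) position table as TSV
#'
#' Columns: `marker_id`, `scaffold_id` (optional), `lg`, `cM`.
#' @param positions data frame.
#' @param path file path.
#' @export
write_positions_tsv <- function(positions, path) {
  utils::write.table(positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions_tsv
#' @export
read_positions_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
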