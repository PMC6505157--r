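# Bundled reference tables: published per-LG summaries of the ultra-dense
# Norway spruce haploid map (three megagametophyte component maps and their
# consensus).  These are inputs for the accounting report generators, which
# recompute every derived quantity (totals, percentages, inflation per bin)
# from the printed counts rather than restating it.

#' Load the bundled Norway spruce map reference tables
#'
#' @return list with `map_summary` (per-LG marker/bin counts, lengths,
#'   maximum gaps for the three component maps and the consensus),
#'   `inflation_summary` (per-LG observed and subsample-estimated lengths),
#'   `assembly_counts` and `synteny_counts` (named numeric vectors of raw
#'   counts).
#' @export
spruce_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "haplomap",
                                  mustWork = TRUE)
  counts <- function(f) {
    tab <- utils::read.delim(path(f), stringsAsFactors = FALSE)
    stats::setNames(tab$value, tab$quantity)
  }
  list(map_summary = utils::read.delim(path("spruce_map_summary.tsv"),
                                       stringsAsFactors = FALSE),
       inflation_summary = utils::read.delim(
         path("spruce_inflation_summary.tsv"), stringsAsFactors = FALSE),
       assembly_counts = counts("spruce_assembly_counts.tsv"),
       synteny_counts = counts("spruce_synteny_counts.tsv"))
}

#' Recompute map-summary totals from per-LG rows
#'
#' Sums markers, bins and map length per component map (and the consensus)
#' from the per-linkage-group rows of a map summary table.
#'
#' @param map_summary data frame with `lg`, `cluster`, `markers`, `bins`,
#'   `length_cM`.
#' @return data frame `cluster`, `n_lgs`, `markers`, `bins`, `length_cM`.
#' @export
map_summary_totals <- function(map_summary) {
  out <- lapply(split(map_summary, map_summary$cluster), function(s)
    data.frame(cluster = s$cluster[1], n_lgs = nrow(s),
               markers = sum(s$markers), bins = sum(s$bins),
               length_cM = sum(s$length_cM), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recompute per-bin inflation from an inflation summary table
#'
#' Joins the per-LG bin counts from a map summary onto an inflation summary
#' and applies [inflation_per_bin()].
#'
#' @param inflation_summary data frame `lg`, `cluster`, `observed_cM`,
#'   `estimated_cM`.
#' @param map_summary data frame providing `lg`, `cluster`, `bins`.
#' @return the inflation summary with `bins` and computed
#'   `inflation_per_bin_cM` columns.
#' @export
inflation_from_summary <- function(inflation_summary, map_summary) {
  key <- paste(inflation_summary$lg, inflation_summary$cluster)
  mkey <- paste(map_summary$lg, map_summary$cluster)
  inflation_summary$bins <- map_summary$bins[match(key, mkey)]
  inflation_summary$inflation_per_bin_cM <- inflation_per_bin(
    inflation_summary$observed_cM, inflation_summary$estimated_cM,
    inflation_summary$bins)
  inflation_summary
}
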