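#' Load a marker-correspondence table
#'
#' The correspondence table is the output of an external reciprocal-best-hit
#' homology search (e.g. tblastn of array probe sequences against the
#' assembly): one row per comparison with the query marker, the matched
#' scaffold/marker in the target map, the percent identity and the
#' reciprocal-best flag.  Rows at or below the identity threshold and rows
#' that are not reciprocal best hits are excluded at load.
#'
#' @param path TSV with columns `query_marker_id`, `query_scaffold_id`,
#'   `target_marker_id`, `identity_pct`, `reciprocal_best`.
#' @param min_identity exclusive identity threshold (default 95: keep
#'   `identity_pct > 95`).
#' @return the filtered data frame.
#' @export
read_correspondence_table <- function(path, min_identity = 95) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_marker_id", "query_scaffold_id", "target_marker_id",
            "identity_pct", "reciprocal_best")
  if (!all(need %in% names(tab)))
    stop("correspondence table must have columns: ",
         paste(need, collapse = ", "))
  tab[tab$identity_pct > min_identity & as.logical(tab$reciprocal_best), ,
      drop = FALSE]
}

#' Linkage-group correspondence between two maps
#'
#' Every correspondence row whose query and target markers are placed in
#' both maps becomes a comparison `(LG_a, LG_b)`.  For each query LG the
#' homologous target LG is the majority vote over its comparisons (ties
#' broken by the larger Kendall tau of shared marker orders, then by target
#' LG id); the homologous fraction is the share of comparisons falling on a
#' majority pair.  Off-diagonal comparisons are returned with a flag for
#' whether the query scaffold is a split scaffold (when `split_scaffolds`
#' is given).
#'
#' @param map_a,map_b data frames `marker_id`, `lg`, `cM`.
#' @param table correspondence data frame (see
#'   [read_correspondence_table()]); already identity-filtered.
#' @param split_scaffolds optional character vector of split scaffold ids in
#'   map a.
#' @return list with `contingency` (LG_a x LG_b count table), `homologous`
#'   (data frame `lg_a`, `lg_b`, `n`), `homologous_fraction`,
#'   `n_comparisons`, `n_dropped` (rows whose markers are absent from a
#'   map) and `off_diagonal` (comparison rows on non-majority pairs).
#' @export
lg_correspondence <- function(map_a, map_b, table, split_scaffolds = NULL) {
  if (!nrow(table)) stop("empty correspondence table after filtering")
  ia <- match(table$query_marker_id, map_a$marker_id)
  ib <- match(table$target_marker_id, map_b$marker_id)
  ok <- !is.na(ia) & !is.na(ib)
  n_dropped <- sum(!ok)
  if (!any(ok)) stop("no correspondence rows shared between the maps")
  comp <- data.frame(query_marker_id = table$query_marker_id[ok],
                     query_scaffold_id = table$query_scaffold_id[ok],
                     target_marker_id = table$target_marker_id[ok],
                     lg_a = map_a$lg[ia[ok]], lg_b = map_b$lg[ib[ok]],
                     cM_a = map_a$cM[ia[ok]], cM_b = map_b$cM[ib[ok]],
                     stringsAsFactors = FALSE)
  cont <- table(comp$lg_a, comp$lg_b)
  maj <- lapply(rownames(cont), function(lga) {
    counts <- stats::setNames(as.vector(cont[lga, ]), colnames(cont))
    top <- which(counts == max(counts))
    if (length(top) > 1) {
      taus <- vapply(names(top), function(lgb) {
        sub <- comp[comp$lg_a == lga & comp$lg_b == lgb, ]
        if (nrow(sub) < 2) return(-Inf)
        stats::cor(sub$cM_a, sub$cM_b, method = "kendall")
      }, 0)
      top <- top[order(-taus, names(top))][1]
    }
    data.frame(lg_a = lga, lg_b = names(counts)[top[1]],
               n = max(counts), stringsAsFactors = FALSE)
  })
  maj <- do.call(rbind, maj)
  on_major <- comp$lg_b == maj$lg_b[match(comp$lg_a, maj$lg_a)]
  off <- comp[!on_major, , drop = FALSE]
  if (!is.null(split_scaffolds))
    off$query_split_scaffold <- off$query_scaffold_id %in% split_scaffolds
  list(contingency = cont, homologous = maj,
       homologous_fraction = mean(on_major),
       n_comparisons = nrow(comp), n_dropped = n_dropped,
       off_diagonal = off)
}

#' Kendall tau of marker order per homologous LG pair
#'
#' Tau-b on the cM positions of the correspondence markers restricted to
#' each majority (homologous) LG pair.
#'
#' @inheritParams lg_correspondence
#' @return data frame `lg_a`, `lg_b`, `tau`, `n_shared` (`tau` `NA` when
#'   fewer than 2 shared markers).
#' @export
marker_order_tau <- function(map_a, map_b, table) {
  lc <- lg_correspondence(map_a, map_b, table)
  comp_rows <- merge(
    data.frame(query_marker_id = table$query_marker_id,
               target_marker_id = table$target_marker_id,
               stringsAsFactors = FALSE),
    map_a[, c("marker_id", "lg", "cM")],
    by.x = "query_marker_id", by.y = "marker_id")
  names(comp_rows)[names(comp_rows) == "lg"] <- "lg_a"
  names(comp_rows)[names(comp_rows) == "cM"] <- "cM_a"
  comp_rows <- merge(comp_rows, map_b[, c("marker_id", "lg", "cM")],
                     by.x = "target_marker_id", by.y = "marker_id")
  names(comp_rows)[names(comp_rows) == "lg"] <- "lg_b"
  names(comp_rows)[names(comp_rows) == "cM"] <- "cM_b"
  out <- lapply(seq_len(nrow(lc$homologous)), function(i) {
    lga <- lc$homologous$lg_a[i]; lgb <- lc$homologous$lg_b[i]
    sub <- comp_rows[comp_rows$lg_a == lga & comp_rows$lg_b == lgb, ]
    tau <- if (nrow(sub) < 2) NA_real_ else
      stats::cor(sub$cM_a, sub$cM_b, method = "kendall")
    data.frame(lg_a = lga, lg_b = lgb, tau = tau, n_shared = nrow(sub),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Accounting identities from printed synteny comparison counts
#'
#' Recomputes the percentage identities of an inter-map comparison report
#' from raw counts.
#'
#' @param counts named numeric vector with `comparisons_total`,
#'   `comparisons_homologous`, and optionally `split_comparisons_total`,
#'   `split_comparisons_nonhomologous`.
#' @return data frame of derived quantities.
#' @export
synteny_accounting <- function(counts) {
  stopifnot(all(c("comparisons_total", "comparisons_homologous") %in%
                  names(counts)))
  vals <- c(homologous_pct = 100 * counts[["comparisons_homologous"]] /
              counts[["comparisons_total"]],
            nonhomologous_pct = 100 *
              (counts[["comparisons_total"]] -
                 counts[["comparisons_homologous"]]) /
              counts[["comparisons_total"]])
  if (all(c("split_comparisons_total", "split_comparisons_nonhomologous")
          %in% names(counts)))
    vals <- c(vals, split_nonhomologous_pct = 100 *
                counts[["split_comparisons_nonhomologous"]] /
                counts[["split_comparisons_total"]])
  data.frame(quantity = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}
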