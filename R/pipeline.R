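#' Build a component linkage map from a family's informative markers
#'
#' Convenience pipeline for one maternal family: bin markers, compute
#' pairwise two-point estimates on the bin representatives, group into
#' linkage groups (LOD >= `lod_min`, r <= `rf_max`), order each group with
#' RECORD, optionally ripple-refine, and assign Kosambi cM positions.
#' Linkage groups are labelled `LG01`, `LG02`, ... in decreasing bin count
#' (ties by smallest bin id).
#'
#' @param alleles marker x sample 0/1/NA matrix of informative testcross
#'   markers (e.g. one family from [recode_testcross()]).
#' @param lod_min,rf_max grouping thresholds (defaults 8 and 0.35).
#' @param n_counts RECORD counting repetitions (default 16).
#' @param ripple logical; run the sliding-window ripple refinement.
#' @param window,step ripple window and step in bins.
#' @param seed integer seed.
#' @return object of class `component_map`: list with `maps` (named list of
#'   `ordered_map` per LG), `binning`, `ld` (the [linkage_data()]),
#'   `singletons` and `seed`.
#' @export
build_component_map <- function(alleles, lod_min = 8, rf_max = 0.35,
                                n_counts = 16, ripple = FALSE, window = 10,
                                step = 1, seed = 1L) {
  binning <- bin_markers(alleles)
  ld <- linkage_data(binning$signatures)
  grp <- group_markers(ld, lod_min = lod_min, rf_max = rf_max)
  maps <- list()
  for (i in seq_along(grp$groups)) {
    om <- order_record(ld, grp$groups[[i]], n_counts = n_counts,
                       seed = seed + i)
    if (ripple)
      om <- ripple_window(om, ld, window = window, step = step,
                          seed = seed + i)
    om <- kosambi_map(om, ld)
    om$lg_id <- sprintf("LG%02d", i)
    maps[[om$lg_id]] <- om
  }
  structure(list(maps = maps, binning = binning, ld = ld,
                 singletons = grp$singletons, seed = seed),
            class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  cat("component_map:", length(x$maps), "linkage groups,",
      nrow(x$binning$bins), "bins,", length(x$singletons), "singletons\n")
  for (m in x$maps) print(m)
  invisible(x)
}

#' Flatten a component or consensus map to a marker position table
#'
#' Expands bins to their member markers so the table has one row per marker.
#'
#' @param cm a `component_map`.
#' @param expand_bins logical; if `FALSE`, one row per bin.
#' @return data frame with `marker_id`, `bin_id`, `lg`, `cM`.
#' @export
map_positions <- function(cm, expand_bins = TRUE) {
  stopifnot(inherits(cm, "component_map"))
  out <- list()
  for (m in cm$maps) {
    pos <- data.frame(bin_id = m$bins, lg = m$lg_id, cM = m$cM,
                      stringsAsFactors = FALSE)
    if (expand_bins) {
      members <- cm$binning$members[pos$bin_id]
      pos <- data.frame(
        marker_id = unlist(members, use.names = FALSE),
        bin_id = rep(pos$bin_id, lengths(members)),
        lg = m$lg_id,
        cM = rep(pos$cM, lengths(members)),
        stringsAsFactors = FALSE)
    } else {
      pos <- cbind(marker_id = pos$bin_id, pos)
    }
    out[[m$lg_id]] <- pos
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-LG summary of a component map
#'
#' @param cm a `component_map`.
#' @return data frame with `lg`, `n_bins`, `n_markers`, `length_cM`,
#'   `max_gap_cM`.
#' @export
map_summary <- function(cm) {
  stopifnot(inherits(cm, "component_map"))
  rows <- lapply(cm$maps, function(m) {
    members <- cm$binning$members[m$bins]
    data.frame(lg = m$lg_id, n_bins = length(m$bins),
               n_markers = sum(lengths(members)),
               length_cM = max(m$cM),
               max_gap_cM = if (length(m$cM) > 1) max(diff(m$cM)) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
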