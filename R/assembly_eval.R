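#' Classify multi-marker scaffolds against a genetic map
#'
#' A scaffold whose mapped markers all fall on one linkage group within a
#' 5 cM interval is `consistent`; with all markers on one LG but a span
#' exceeding 5 cM it is an `intra-split`; with markers on k >= 2 LGs it is
#' an `inter-split-k` — both split classes flag putative assembly
#' mis-joins.  The interval rule is strict: span < `span_cM` is consistent,
#' span exceeding `span_cM` is split, and a span of exactly `span_cM`
#' counts as consistent.
#'
#' @param consensus data frame with `marker_id`, `lg`, `cM` (a consensus or
#'   component position table).
#' @param marker_meta data frame with `marker_id`, `scaffold_id` (and
#'   optionally `bp`).
#' @param span_cM split threshold (default 5).
#' @return list with `classes` (data frame `scaffold_id`, `n_markers`,
#'   `n_lgs`, `lg_set`, `span_cM`, `class`), `summary` (counts and
#'   percentages over mapped and multi-marker scaffolds) and `unplaced`
#'   (markers without a map position).
#' @export
classify_scaffolds <- function(consensus, marker_meta, span_cM = 5) {
  meta <- marker_meta[, intersect(c("marker_id", "scaffold_id"),
                                  names(marker_meta))]
  tab <- merge(meta, consensus[, c("marker_id", "lg", "cM")],
               by = "marker_id")
  unplaced <- setdiff(meta$marker_id, tab$marker_id)
  cls <- lapply(split(tab, tab$scaffold_id), function(s) {
    lgs <- sort(unique(s$lg))
    span <- if (length(lgs) == 1) max(s$cM) - min(s$cM) else NA_real_
    klass <- if (nrow(s) == 1) "single-marker"
    else if (length(lgs) >= 2) sprintf("inter-split-%d", min(length(lgs), 3L))
    else if (span > span_cM) "intra-split"
    else "consistent"
    data.frame(scaffold_id = s$scaffold_id[1], n_markers = nrow(s),
               n_lgs = length(lgs), lg_set = paste(lgs, collapse = ","),
               span_cM = span, class = klass, stringsAsFactors = FALSE)
  })
  classes <- do.call(rbind, cls)
  rownames(classes) <- NULL
  n_mapped <- nrow(classes)
  multi <- classes$class != "single-marker"
  n_multi <- sum(multi)
  count_of <- function(k) sum(classes$class == k)
  n_inter <- sum(grepl("^inter-split", classes$class))
  n_intra <- count_of("intra-split")
  summary <- data.frame(
    quantity = c("mapped_scaffolds", "multi_marker_scaffolds",
                 "consistent", "intra_split", "inter_split",
                 "multi_marker_pct_of_mapped",
                 "intra_split_pct_of_mapped", "intra_split_pct_of_multi",
                 "inter_split_pct_of_mapped", "inter_split_pct_of_multi"),
    value = c(n_mapped, n_multi, count_of("consistent"), n_intra, n_inter,
              100 * n_multi / n_mapped,
              100 * n_intra / n_mapped, 100 * n_intra / max(n_multi, 1),
              100 * n_inter / n_mapped, 100 * n_inter / max(n_multi, 1)),
    stringsAsFactors = FALSE)
  list(classes = classes, summary = summary, unplaced = unplaced)
}

#' Cross-check consensus-map splits against component maps
#'
#' A split seen in the consensus map is `supported` when some component map
#' itself contains at least two of the scaffold's markers reproducing the
#' split (different LGs, or same LG more than `span_cM` apart); it is an
#' `artifact` when at least one component co-locates two or more of the
#' markers (same LG, within `span_cM`) and no component reproduces the
#' split; it is `unverifiable` when no component map contains two or more
#' of the markers (e.g. each marker segregates in a different family).
#'
#' @param splits character vector of split scaffold ids (or the `classes`
#'   data frame from [classify_scaffolds()], from which split rows are
#'   taken).
#' @param component_positions named list of component position tables
#'   (data frames `marker_id`, `lg`, `cM`).
#' @param marker_meta data frame with `marker_id`, `scaffold_id`.
#' @param span_cM split threshold (default 5).
#' @return data frame `scaffold_id`, `component_support` in
#'   {supported, artifact, unverifiable}, `supporting_component`.
#' @export
crosscheck_component_support <- function(splits, component_positions,
                                         marker_meta, span_cM = 5) {
  if (is.data.frame(splits))
    splits <- splits$scaffold_id[grepl("split", splits$class)]
  out <- list()
  for (sc in splits) {
    mk <- marker_meta$marker_id[marker_meta$scaffold_id == sc]
    verdict <- "unverifiable"
    support_comp <- NA_character_
    colocated <- FALSE
    for (ci in seq_along(component_positions)) {
      tab <- component_positions[[ci]]
      sub <- tab[tab$marker_id %in% mk, ]
      if (nrow(sub) < 2) next
      reproduces <- length(unique(sub$lg)) >= 2 ||
        (max(sub$cM) - min(sub$cM)) > span_cM
      if (reproduces) {
        verdict <- "supported"
        support_comp <- names(component_positions)[ci] %||% as.character(ci)
        break
      }
      colocated <- TRUE
    }
    if (verdict != "supported" && colocated) verdict <- "artifact"
    out[[length(out) + 1L]] <- data.frame(
      scaffold_id = sc, component_support = verdict,
      supporting_component = support_comp, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scaffold_id = character(),
                      component_support = character(),
                      supporting_component = character())
  res
}

#' Localize splits relative to gene models and contig joins
#'
#' For every split scaffold, the split locus is the bp interval between the
#' two markers, adjacent in scaffold bp order, that disagree in map position
#' (different LGs, or more than `span_cM` apart on one LG) — the tightest
#' localizable interval.  Each split is categorized as `within-gene` (both
#' flanking markers inside one gene model), `between-genes`, or
#' `interior-region` (the scaffold's 5' and 3' markers co-map while an
#' interior marker maps elsewhere), and flagged `at_contig_join` when the
#' split interval overlaps an N-gap span.
#'
#' @param splits character vector of split scaffold ids or the `classes`
#'   data frame from [classify_scaffolds()].
#' @param consensus data frame `marker_id`, `lg`, `cM`.
#' @param scaffold_set a [simulate_assembly()] object, or any list with
#'   `genes` (1-based inclusive `start_bp`, `end_bp`), `gaps` (0-based
#'   half-open `start`, `end`) and `marker_loci` (`marker_id`,
#'   `scaffold_id`, `scaffold_bp`).
#' @param span_cM split threshold (default 5).
#' @return list with `annotations` (data frame `scaffold_id`, `split_start_bp`,
#'   `split_end_bp`, `category`, `at_contig_join`, `gene_id`) and `summary`
#'   (counts per category and the fraction of splits at contig joins).
#' @export
annotate_splits <- function(splits, consensus, scaffold_set, span_cM = 5) {
  if (is.data.frame(splits))
    splits <- splits$scaffold_id[grepl("split", splits$class)]
  genes <- scaffold_set$genes
  gaps <- scaffold_set$gaps
  ml <- scaffold_set$marker_loci
  out <- list()
  for (sc in splits) {
    mk <- ml[ml$scaffold_id == sc, ]
    mk <- merge(mk, consensus[, c("marker_id", "lg", "cM")],
                by = "marker_id")
    mk <- mk[order(mk$scaffold_bp), ]
    if (nrow(mk) < 2 || any(is.na(mk$scaffold_bp))) {
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = sc, split_start_bp = NA_integer_,
        split_end_bp = NA_integer_, category = "unlocalizable",
        at_contig_join = NA, gene_id = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    disagree <- function(i, j)
      mk$lg[i] != mk$lg[j] || abs(mk$cM[i] - mk$cM[j]) > span_cM
    # interior-region pattern: scaffold ends co-map, an interior marker does not
    n <- nrow(mk)
    ends_agree <- !disagree(1, n)
    interior_breaks <- n > 2 && ends_agree &&
      any(vapply(2:(n - 1), function(i) disagree(1, i), TRUE))
    sgenes <- genes[genes$scaffold_id == sc, , drop = FALSE]
    sgaps <- gaps[gaps$scaffold_id == sc, , drop = FALSE]
    for (i in seq_len(n - 1)) {
      if (!disagree(i, i + 1)) next
      a <- mk$scaffold_bp[i]; b <- mk$scaffold_bp[i + 1]
      # gene containing both flanking markers (1-based inclusive spans)
      inside <- sgenes$start_bp <= a & sgenes$end_bp >= b
      category <- if (interior_breaks) "interior-region"
      else if (any(inside)) "within-gene" else "between-genes"
      # gap spans are 0-based half-open; the open interval (a, b) in 1-based
      # bp overlaps gap [gs, ge) iff gs < b - 1 and ge > a
      at_join <- any(sgaps$start < (b - 1) & sgaps$end > a)
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = sc, split_start_bp = a, split_end_bp = b,
        category = category, at_contig_join = at_join,
        gene_id = if (any(inside)) sgenes$gene_id[which(inside)[1]] else
          NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, out)
  if (is.null(ann))
    ann <- data.frame(scaffold_id = character(), split_start_bp = integer(),
                      split_end_bp = integer(), category = character(),
                      at_contig_join = logical(), gene_id = character())
  located <- ann[ann$category != "unlocalizable", , drop = FALSE]
  summary <- data.frame(
    quantity = c("n_splits", "between_genes", "within_gene",
                 "interior_region", "at_contig_join",
                 "pct_at_contig_join"),
    value = c(nrow(located),
              sum(located$category == "between-genes"),
              sum(located$category == "within-gene"),
              sum(located$category == "interior-region"),
              sum(located$at_contig_join),
              100 * mean(located$at_contig_join)),
    stringsAsFactors = FALSE)
  list(annotations = ann, summary = summary)
}

#' Welch t-test comparing split and multi-marker scaffold lengths
#'
#' Two-sided Welch two-sample t-test (unequal variances) of scaffold
#' lengths, multi-marker scaffolds as the first group and split scaffolds as
#' the second; a negative t therefore means split scaffolds are longer.
#'
#' @param split_ids,multimarker_ids scaffold id vectors (>= 2 each).
#' @param lengths named numeric vector scaffold id -> length (bp).
#' @return list with `t`, `df`, `p`, `median_split`, `median_multimarker`.
#' @export
compare_scaffold_lengths <- function(split_ids, multimarker_ids, lengths) {
  x <- lengths[multimarker_ids]
  y <- lengths[split_ids]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 scaffolds")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, median_split = stats::median(y),
       median_multimarker = stats::median(x))
}

#' Accounting identities from printed scaffold-classification counts
#'
#' Recomputes the derived percentages of a scaffold classification report
#' from raw counts (mapped scaffolds, multi-marker scaffolds, split counts,
#' splits at contig joins), so that published summary tables can be checked
#' arithmetically.
#'
#' @param counts named numeric vector with elements `mapped`, `multi_marker`,
#'   `inter_split`, `intra_split`, `splits_total`, `splits_at_join`.
#' @return data frame of derived quantities (`quantity`, `value`).
#' @export
scaffold_accounting <- function(counts) {
  need <- c("mapped", "multi_marker", "inter_split", "intra_split",
            "splits_total", "splits_at_join")
  stopifnot(all(need %in% names(counts)))
  with(as.list(counts), data.frame(
    quantity = c("multi_marker_pct_of_mapped",
                 "inter_split_pct_of_mapped", "inter_split_pct_of_multi",
                 "intra_split_pct_of_mapped", "intra_split_pct_of_multi",
                 "split_scaffolds_total", "pct_splits_at_contig_join"),
    value = c(100 * multi_marker / mapped,
              100 * inter_split / mapped, 100 * inter_split / multi_marker,
              100 * intra_split / mapped, 100 * intra_split / multi_marker,
              inter_split + intra_split,
              100 * splits_at_join / splits_total),
    stringsAsFactors = FALSE))
}
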