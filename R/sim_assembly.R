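#' Simulate a fragmented genome assembly over the true map
#'
#' Builds an artificial scaffold set in the style of a draft conifer assembly:
#' scaffolds carry 1-11 markers, are composed of contigs separated by N-gap
#' spans ("contig joins"), and a configurable fraction are chimeric
#' (mis-joined).  An *inter*-chimera concatenates marker runs from 2-3
#' different true chromosomes; an *intra*-chimera joins two runs more than
#' 5 cM apart on the same chromosome.  Chimera joins sit at a gap span by
#' default (`join_at_gap = TRUE`), mirroring the observation that most real
#' splits localize between contig joins; set it to `FALSE` to place joins
#' inside a contig.
#'
#' Coordinate conventions (stated once, tested): marker loci and gene models
#' are 1-based inclusive bp; contig and gap spans are 0-based half-open and
#' tile `[0, length_bp)` without overlap.
#'
#' Gene models are placed inside contigs; on every multi-contig scaffold one
#' additional gene spans the first gap, so that a chimeric join there falls
#' *within* a gene model (the worst-case assembly error).
#'
#' @param true_map a [simulate_true_map()] object.
#' @param n_scaffolds number of scaffolds to build.
#' @param markers_per_scaffold_dist probability vector over 1..11 markers per
#'   scaffold.
#' @param inter_chimera_rate,intra_chimera_rate probabilities in `[0, 1)`.
#' @param gap_spec list with `gap_bp` (N-gap length), `marker_spacing_bp`
#'   (marker spacing inside a contig) and `join_at_gap`.
#' @param run_span_cM maximum genetic span of one non-chimeric contig run
#'   (default 1 cM): a physical scaffold covers a near-point genetic
#'   interval, so a run is truncated (the scaffold simply carries fewer
#'   markers) rather than allowed to spread further.  Set to `Inf` to
#'   disable.
#' @param seed integer seed.
#' @return object of class `scaffold_set`: list of data frames `scaffolds`
#'   (`scaffold_id`, `length_bp`, `n_markers`, `chimera_label`), `contigs` and
#'   `gaps` (`scaffold_id`, `start`, `end`; 0-based half-open), `genes`
#'   (`scaffold_id`, `gene_id`, `start_bp`, `end_bp`, `confidence`;
#'   1-based inclusive) and `marker_loci` (`marker_id`, `scaffold_id`,
#'   `scaffold_bp`, `chr_id`, `true_cM`).
#' @export
simulate_assembly <- function(true_map, n_scaffolds,
                              markers_per_scaffold_dist = c(0.45, 0.2, 0.12,
                                                            0.08, 0.05, 0.04,
                                                            0.02, 0.02, 0.01,
                                                            0.005, 0.005),
                              inter_chimera_rate = 0, intra_chimera_rate = 0,
                              gap_spec = list(gap_bp = 100L,
                                              marker_spacing_bp = 1000L,
                                              join_at_gap = TRUE),
                              run_span_cM = 1, seed = 1L) {
  stopifnot(inherits(true_map, "true_map"))
  if (inter_chimera_rate < 0 || inter_chimera_rate >= 1 ||
      intra_chimera_rate < 0 || intra_chimera_rate >= 1)
    stop("chimera rates must lie in [0, 1)")
  if (length(markers_per_scaffold_dist) != 11 ||
      any(markers_per_scaffold_dist < 0))
    stop("markers_per_scaffold_dist must be a probability vector over 1..11")
  set.seed(seed)
  gap_bp <- as.integer(gap_spec$gap_bp %||% 100L)
  spacing <- as.integer(gap_spec$marker_spacing_bp %||% 1000L)
  join_at_gap <- isTRUE(gap_spec$join_at_gap %||% TRUE)

  loci <- true_map$loci
  sizes <- sample(1:11, n_scaffolds, replace = TRUE,
                  prob = markers_per_scaffold_dist)
  if (sum(sizes) > nrow(loci))
    stop("requested markers (", sum(sizes), ") exceed available loci (",
         nrow(loci), ")")
  # per-chromosome queues of unassigned loci, in map order
  queues <- lapply(split(seq_len(nrow(loci)), loci$chr_id),
                   function(i) i[order(loci$true_cM[i])])

  take_front <- function(chr, k) {
    q <- queues[[chr]]
    take <- min(k, length(q))
    if (is.finite(run_span_cM) && take > 1) {
      span_ok <- loci$true_cM[q[seq_len(take)]] <=
        loci$true_cM[q[1]] + run_span_cM
      take <- max(1L, sum(span_ok))
    }
    run <- q[seq_len(take)]
    queues[[chr]] <<- q[-seq_len(take)]
    run
  }
  nonempty <- function() names(queues)[vapply(queues, length, 0L) > 0]

  scaffolds <- contigs <- gaps <- genes <- mloci <- list()
  gene_n <- 0L
  for (si in seq_len(n_scaffolds)) {
    chrs <- nonempty()
    if (!length(chrs)) break
    size <- sizes[si]
    u <- stats::runif(1)
    label <- "none"
    runs <- NULL
    if (u < inter_chimera_rate && size >= 2 && length(chrs) >= 2) {
      k <- min(sample(2:3, 1), length(chrs), size)
      picks <- sample(chrs, k)
      part <- diff(c(0, sort(sample(size - 1, k - 1)), size))
      runs <- mapply(take_front, picks, part, SIMPLIFY = FALSE)
      runs <- runs[vapply(runs, length, 0L) > 0]
      if (length(runs) >= 2) label <- "inter"
    } else if (u < inter_chimera_rate + intra_chimera_rate && size >= 2) {
      chr <- sample(chrs, 1)
      k1 <- max(1L, size %/% 2L)
      run1 <- take_front(chr, k1)
      q <- queues[[chr]]
      # plant the second run well beyond the 5 cM split threshold
      far <- which(loci$true_cM[q] > max(loci$true_cM[run1]) + 8)
      if (length(run1) && length(far)) {
        pick <- far[seq_len(min(size - length(run1), length(far)))]
        pick <- pick[loci$true_cM[q[pick]] <=
                       loci$true_cM[q[pick[1]]] + run_span_cM]
        run2 <- q[pick]
        queues[[chr]] <- q[-pick]
        runs <- list(run1, run2)
        label <- "intra"
      } else {
        runs <- list(run1)
      }
    }
    if (is.null(runs) || label == "none") {
      if (is.null(runs)) runs <- list(take_front(sample(chrs, 1), size))
      label <- "none"
    }
    runs <- runs[vapply(runs, length, 0L) > 0]
    if (!length(runs)) next

    sc_id <- sprintf("SC%05d", si)
    # layout: contig per run; gaps between contigs unless a chimera join is
    # forced inside a contig (join_at_gap = FALSE merges the first two runs)
    merged_join <- (label != "none" && !join_at_gap && length(runs) >= 2)
    if (merged_join) {
      runs <- c(list(c(runs[[1]], runs[[2]])), runs[-(1:2)])
    }
    cursor <- 0L
    for (ri in seq_along(runs)) {
      run <- runs[[ri]]
      clen <- length(run) * spacing
      contigs[[length(contigs) + 1L]] <-
        data.frame(scaffold_id = sc_id, start = cursor, end = cursor + clen)
      bp <- cursor + as.integer((seq_along(run) - 0.5) * spacing)
      mloci[[length(mloci) + 1L]] <- data.frame(
        marker_id = loci$marker_id[run], scaffold_id = sc_id,
        scaffold_bp = bp + 1L,  # 1-based inclusive
        chr_id = loci$chr_id[run], true_cM = loci$true_cM[run],
        stringsAsFactors = FALSE)
      # one gene model inside the contig
      gene_n <- gene_n + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        scaffold_id = sc_id, gene_id = sprintf("G%05d", gene_n),
        start_bp = cursor + as.integer(0.1 * clen) + 1L,
        end_bp = cursor + as.integer(0.9 * clen),
        confidence = sample(c("high", "medium", "low"), 1,
                            prob = c(0.5, 0.38, 0.12)),
        stringsAsFactors = FALSE)
      cursor <- cursor + clen
      if (ri < length(runs)) {
        gaps[[length(gaps) + 1L]] <-
          data.frame(scaffold_id = sc_id, start = cursor,
                     end = cursor + gap_bp)
        cursor <- cursor + gap_bp
      }
    }
    if (length(runs) >= 2) {
      # gene spanning the first gap: a join there splits within a gene model
      g1 <- gaps[[length(gaps) - (length(runs) - 2L)]]
      gene_n <- gene_n + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        scaffold_id = sc_id, gene_id = sprintf("G%05d", gene_n),
        start_bp = max(1L, g1$start - spacing %/% 2L),
        end_bp = min(cursor, g1$end + spacing %/% 2L + 1L),
        confidence = "high", stringsAsFactors = FALSE)
    }
    scaffolds[[length(scaffolds) + 1L]] <- data.frame(
      scaffold_id = sc_id, length_bp = cursor,
      n_markers = sum(vapply(runs, length, 0L)),
      chimera_label = label, stringsAsFactors = FALSE)
  }
  structure(list(scaffolds = do.call(rbind, scaffolds),
                 contigs = do.call(rbind, contigs),
                 gaps = if (length(gaps)) do.call(rbind, gaps) else
                   data.frame(scaffold_id = character(), start = integer(),
                              end = integer()),
                 genes = do.call(rbind, genes),
                 marker_loci = do.call(rbind, mloci),
                 seed = seed),
            class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("scaffold_set:", nrow(x$scaffolds), "scaffolds,",
      nrow(x$marker_loci), "marker loci,",
      sum(x$scaffolds$chimera_label != "none"), "chimeric\n")
  invisible(x)
}

#' Apply a simulated assembly's marker placement back to the true map
#'
#' Replaces the provisional one-marker-per-scaffold placement in a
#' [simulate_true_map()] object with the layout produced by
#' [simulate_assembly()].  Markers not placed on any scaffold are dropped from
#' the returned map.
#'
#' @param true_map a `true_map` object.
#' @param scaffold_set a `scaffold_set` object derived from it.
#' @return updated `true_map`.
#' @export
assign_scaffolds <- function(true_map, scaffold_set) {
  stopifnot(inherits(true_map, "true_map"),
            inherits(scaffold_set, "scaffold_set"))
  ml <- scaffold_set$marker_loci
  keep <- true_map$loci$marker_id %in% ml$marker_id
  loci <- true_map$loci[keep, ]
  i <- match(loci$marker_id, ml$marker_id)
  loci$scaffold_id <- ml$scaffold_id[i]
  loci$scaffold_bp <- ml$scaffold_bp[i]
  true_map$loci <- loci
  true_map
}

#' Write a scaffold set as AGP v2.1
#'
#' One row per contig (component type `W`) and per gap (type `N`,
#' `scaffold`/`yes` linkage).  AGP object coordinates are 1-based inclusive.
#' @param scaffold_set a `scaffold_set`.
#' @param path output file.
#' @export
write_scaffold_agp <- function(scaffold_set, path) {
  rows <- list()
  for (sc in scaffold_set$scaffolds$scaffold_id) {
    ctg <- scaffold_set$contigs[scaffold_set$contigs$scaffold_id == sc,
                                c("start", "end")]
    gap <- scaffold_set$gaps[scaffold_set$gaps$scaffold_id == sc,
                             c("start", "end")]
    ctg$type <- "W"
    if (nrow(gap)) gap$type <- "N" else gap <- ctg[0, ]
    parts <- rbind(ctg, gap)
    parts <- parts[order(parts$start), ]
    for (k in seq_len(nrow(parts))) {
      p <- parts[k, ]
      rows[[length(rows) + 1L]] <- if (p$type == "W")
        c(sc, p$start + 1L, p$end, k, "W",
          sprintf("%s_ctg%d", sc, k), 1L, p$end - p$start, "+")
      else
        c(sc, p$start + 1L, p$end, k, "N",
          p$end - p$start, "scaffold", "yes", "na")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  writeLines(vapply(rows, paste, "", collapse = "\t"), con)
  invisible(path)
}

#' Write gene models of a scaffold set as GFF3
#'
#' @param scaffold_set a `scaffold_set`.
#' @param path output file.
#' @export
write_scaffold_gff3 <- function(scaffold_set, path) {
  g <- scaffold_set$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf(
    "%s\thaplomap\tgene\t%d\t%d\t.\t+\t.\tID=%s;confidence=%s",
    g$scaffold_id, g$start_bp, g$end_bp, g$gene_id, g$confidence), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
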