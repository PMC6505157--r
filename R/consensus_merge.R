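# Consensus map construction: merge component maps of one linkage group by
# constrained L1 optimization.  For a maximum-interval setting K, every
# component contributes ordinal constraints x_j - x_i >= 0 for marker pairs
# at most K intervals apart in its order; the consensus positions x (with a
# free additive shift per component) minimize the weighted sum of absolute
# deviations from the component positions.  Conflicting constraints (cycles
# in the precedence digraph) are deleted from lower-ranked components first.

# edges (from, to, rank) for one component's ordered positions
component_edges <- function(pos, K, rank) {
  ord <- names(sort(pos))
  p <- pos[ord]
  n <- length(ord)
  if (n < 2) return(NULL)
  from <- to <- character(0)
  for (d in seq_len(min(K, n - 1))) {
    i <- seq_len(n - d)
    strict <- p[i + d] > p[i]   # ties carry no order information
    from <- c(from, ord[i][strict])
    to <- c(to, ord[i + d][strict])
  }
  if (!length(from)) return(NULL)
  data.frame(from = unname(from), to = unname(to), rank = unname(rank),
             stringsAsFactors = FALSE)
}

# delete cycle-forming edges, lowest-ranked components first
resolve_conflicts <- function(edges) {
  deleted <- 0L
  repeat {
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")])
    scc <- igraph::components(g, mode = "strong")
    if (max(scc$csize) == 1) break
    mem <- scc$membership[edges$from]
    in_cycle <- mem == scc$membership[edges$to] &
      scc$csize[mem] > 1
    worst <- max(edges$rank[in_cycle])
    drop <- in_cycle & edges$rank == worst
    if (!any(drop)) break  # defensive; cannot happen
    deleted <- deleted + sum(drop)
    edges <- edges[!drop, , drop = FALSE]
  }
  list(edges = edges, deleted = deleted)
}

# transitive reduction of a DAG edge list (keeps the feasible region, shrinks
# the constraint matrix)
reduce_edges <- function(edges, nodes) {
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  A <- matrix(FALSE, n, n)
  A[cbind(idx[edges$from], idx[edges$to])] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  two_step <- (A %*% R) > 0   # path of length >= 2
  keep <- A & !two_step
  w <- which(keep, arr.ind = TRUE)
  data.frame(from = nodes[w[, 1]], to = nodes[w[, 2]],
             stringsAsFactors = FALSE)
}

#' Build consensus-map candidates over a range of maximum-interval settings
#'
#' For each K in `K_range`, solves the constrained weighted-L1 merge of the
#' component maps of one linkage group (see the package vignette for the
#' model).  Components are ranked by marker number (rank 1 = most markers);
#' when components conflict, ordinal constraints are deleted from
#' lower-ranked components until the precedence digraph is acyclic.  The LP
#' is solved as a constrained median regression
#' (`quantreg::rq.fit.fnc`).  Per-component RMSE is computed over shared
#' markers after the optimal L1 shift.
#'
#' @param positions named list, one element per component: named numeric
#'   vector of marker cM positions on this linkage group.
#' @param weights numeric vector of component map weights (normalized to sum
#'   to 1); default proportional weights of 1 each.
#' @param K_range integer vector of maximum-interval settings (default
#'   1..10).
#' @return list of candidates, each a list with `K`, `positions` (named,
#'   starting at 0), `rmse_per_component`, `mean_rmse`,
#'   `n_deleted_constraints` and `failed`.
#' @export
build_consensus_candidates <- function(positions, weights = NULL,
                                       K_range = 1:10) {
  stopifnot(length(positions) >= 1)
  C <- length(positions)
  if (is.null(weights)) weights <- rep(1, C)
  stopifnot(length(weights) == C, all(weights > 0))
  weights <- weights / sum(weights)
  n_mark <- vapply(positions, length, 0L)
  rank_of <- rank(-n_mark, ties.method = "first")
  markers <- sort(unique(unlist(lapply(positions, names),
                                use.names = FALSE)))
  M <- length(markers)

  finalize <- function(x, K, deleted) {
    x <- x - min(x)
    rmse <- vapply(positions, function(y) {
      sh <- intersect(names(y), names(x))
      s <- stats::median(x[sh] - y[sh])
      sqrt(mean((x[sh] - y[sh] - s)^2))
    }, 0)
    list(K = K, positions = sort(x), rmse_per_component = rmse,
         mean_rmse = mean(rmse), n_deleted_constraints = deleted,
         failed = FALSE)
  }

  if (C == 1) {
    y <- positions[[1]]
    return(lapply(K_range, function(K) finalize(y, K, 0L)))
  }

  lapply(K_range, function(K) {
    edges <- do.call(rbind, lapply(seq_len(C), function(ci)
      component_edges(positions[[ci]], K, rank_of[ci])))
    deleted <- 0L
    if (!is.null(edges) && nrow(edges)) {
      res <- resolve_conflicts(edges)
      edges <- reduce_edges(res$edges, markers)
      deleted <- res$deleted
    }
    # parameters: x_1..x_M, shifts s_2..s_C (s_1 fixed at 0)
    np <- M + C - 1L
    rows <- sum(n_mark)
    X <- matrix(0, rows, np)
    y <- numeric(rows)
    wt <- numeric(rows)
    ri <- 0L
    for (ci in seq_len(C)) {
      pc <- positions[[ci]]
      for (j in seq_along(pc)) {
        ri <- ri + 1L
        X[ri, match(names(pc)[j], markers)] <- 1
        if (ci > 1) X[ri, M + ci - 1L] <- -1
        y[ri] <- pc[j]
        wt[ri] <- weights[ci]
      }
    }
    nR <- if (is.null(edges)) 0L else nrow(edges)
    R <- matrix(0, nR, np)
    if (nR) {
      R[cbind(seq_len(nR), match(edges$to, markers))] <- 1
      R[cbind(seq_len(nR), match(edges$from, markers))] <-
        R[cbind(seq_len(nR), match(edges$from, markers))] - 1
    }
    fit <- tryCatch(
      quantreg::rq.fit.fnc(X * wt, y * wt, R = R, r = rep(0, nR), tau = 0.5),
      error = function(e) NULL)
    if (is.null(fit))
      return(list(K = K, positions = NULL, rmse_per_component = NULL,
                  mean_rmse = NA_real_, n_deleted_constraints = deleted,
                  failed = TRUE))
    x <- stats::setNames(fit$coefficients[seq_len(M)], markers)
    out <- finalize(x, K, deleted)
    out$objective <- consensus_objective(out$positions, positions, weights)
    out
  })
}

#' Weighted L1 objective of a consensus solution
#'
#' Sum over components of the weighted absolute deviations between consensus
#' and component positions at the optimal per-component shift (L1-median
#' shift).  Used by tests to compare the solver with exhaustive oracles.
#'
#' @param x named consensus positions.
#' @param positions component position list (as in
#'   [build_consensus_candidates()]).
#' @param weights normalized component weights.
#' @return scalar objective value.
#' @export
consensus_objective <- function(x, positions, weights) {
  weights <- weights / sum(weights)
  obj <- 0
  for (ci in seq_along(positions)) {
    y <- positions[[ci]]
    sh <- intersect(names(y), names(x))
    s <- stats::median(x[sh] - y[sh])
    obj <- obj + weights[ci] * sum(abs(x[sh] - y[sh] - s))
  }
  obj
}

#' Select the consensus candidate with the lowest mean RMSE
#'
#' Ties are broken toward the smallest maximum-interval setting K.
#'
#' @param candidates list from [build_consensus_candidates()].
#' @return the winning candidate (list), with a `positions` element.
#' @export
select_consensus <- function(candidates) {
  ok <- !vapply(candidates, function(cc) isTRUE(cc$failed), TRUE)
  if (!any(ok))
    stop("all consensus candidates failed; diagnostics: ",
         paste(vapply(candidates, function(cc) as.character(cc$K), ""),
               collapse = ", "))
  cand <- candidates[ok]
  rmse <- vapply(cand, function(cc) cc$mean_rmse, 0)
  Ks <- vapply(cand, function(cc) cc$K, 0)
  cand[[order(rmse, Ks)[1]]]
}

#' Kendall rank correlation of marker order between two maps
#'
#' Tau-b (tie-corrected), computed over the markers shared between the two
#' maps.  Binned markers at identical cM make ties common, hence tau-b.
#'
#' @param pos_a,pos_b named numeric vectors of positions (cM).
#' @return list with `tau`, `n_shared`; `tau` is `NA` when fewer than two
#'   shared markers exist.
#' @export
order_correlation <- function(pos_a, pos_b) {
  shared <- intersect(names(pos_a), names(pos_b))
  if (length(shared) < 2)
    return(list(tau = NA_real_, n_shared = length(shared)))
  list(tau = stats::cor(pos_a[shared], pos_b[shared], method = "kendall"),
       n_shared = length(shared))
}

#' Match linkage groups across component maps by shared scaffolds
#'
#' The component with the most mapped markers is the reference; every other
#' component LG is assigned to the reference LG with which it shares the
#' largest number of unique scaffolds (majority vote; ties broken by the
#' larger shared count, then by reference LG id).
#'
#' @param components named list of `component_map` objects.
#' @param marker_meta data frame with `marker_id`, `scaffold_id`.
#' @return data frame with `component`, `lg`, `consensus_lg`, `n_shared`.
#' @export
match_linkage_groups <- function(components, marker_meta) {
  stopifnot(length(components) >= 1)
  tabs <- lapply(components, function(cm) {
    mp <- map_positions(cm)
    mp$scaffold_id <- marker_meta$scaffold_id[match(mp$marker_id,
                                                    marker_meta$marker_id)]
    mp
  })
  sizes <- vapply(tabs, nrow, 0L)
  ref_i <- which.max(sizes)
  ref <- tabs[[ref_i]]
  out <- list()
  for (ci in seq_along(components)) {
    tab <- tabs[[ci]]
    for (lg in unique(tab$lg)) {
      sc <- unique(tab$scaffold_id[tab$lg == lg])
      shared <- vapply(split(ref$scaffold_id, ref$lg),
                       function(s) length(intersect(sc, unique(s))), 0L)
      best <- names(shared)[order(-shared, names(shared))][1]
      out[[length(out) + 1L]] <- data.frame(
        component = names(components)[ci] %||% as.character(ci),
        lg = lg, consensus_lg = best, n_shared = max(shared),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge component maps into a consensus map
#'
#' Matches linkage groups across components ([match_linkage_groups()]), then
#' for each consensus LG builds candidates over `K_range` and selects the
#' lowest mean-RMSE candidate.  The consensus marker set of an LG is the
#' union of the component marker sets.
#'
#' @param components named list of `component_map` objects.
#' @param marker_meta data frame with `marker_id`, `scaffold_id`.
#' @param weights component map weights (e.g. mapping-population sizes);
#'   normalized internally.
#' @param K_range maximum-interval settings to try (default 1..10).
#' @return object of class `consensus_map`: list with `positions` (data
#'   frame `marker_id`, `lg`, `cM`), `selected` (per-LG chosen K and mean
#'   RMSE), `lg_match`, and `candidates` (per-LG candidate summaries).
#' @export
build_consensus <- function(components, marker_meta, weights = NULL,
                            K_range = 1:10) {
  match_tab <- match_linkage_groups(components, marker_meta)
  if (is.null(weights)) weights <- rep(1, length(components))
  pos_tabs <- lapply(components, map_positions)
  lgs <- sort(unique(match_tab$consensus_lg))
  positions <- list()
  selected <- list()
  cand_summary <- list()
  for (lg in lgs) {
    plist <- list()
    w <- numeric(0)
    for (ci in seq_along(components)) {
      comp_name <- names(components)[ci] %||% as.character(ci)
      comp_lgs <- match_tab$lg[match_tab$component == comp_name &
                                 match_tab$consensus_lg == lg]
      if (!length(comp_lgs)) next
      tab <- pos_tabs[[ci]]
      tab <- tab[tab$lg %in% comp_lgs, ]
      if (!nrow(tab)) next
      plist[[comp_name]] <- stats::setNames(tab$cM, tab$marker_id)
      w <- c(w, weights[ci])
    }
    if (!length(plist)) next
    cands <- build_consensus_candidates(plist, weights = w,
                                        K_range = K_range)
    win <- select_consensus(cands)
    positions[[lg]] <- data.frame(marker_id = names(win$positions), lg = lg,
                                  cM = unname(win$positions),
                                  stringsAsFactors = FALSE)
    selected[[lg]] <- data.frame(lg = lg, K = win$K,
                                 mean_rmse = win$mean_rmse,
                                 n_deleted_constraints =
                                   win$n_deleted_constraints,
                                 stringsAsFactors = FALSE)
    cand_summary[[lg]] <- data.frame(
      lg = lg, K = vapply(cands, function(cc) cc$K, 0),
      mean_rmse = vapply(cands, function(cc) cc$mean_rmse, 0),
      failed = vapply(cands, function(cc) isTRUE(cc$failed), TRUE),
      stringsAsFactors = FALSE)
  }
  structure(list(positions = do.call(rbind, c(positions,
                                              make.row.names = FALSE)),
                 selected = do.call(rbind, c(selected,
                                             make.row.names = FALSE)),
                 lg_match = match_tab,
                 candidates = do.call(rbind, c(cand_summary,
                                               make.row.names = FALSE))),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("consensus_map:", length(unique(x$positions$lg)), "linkage groups,",
      nrow(x$positions), "markers\n")
  invisible(x)
}
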