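#' Group markers into bins of identical segregation signatures
#'
#' Two markers share a bin iff their allele vectors are identical at every
#' sample (including an identical missing pattern; "exact" binning).  The
#' representative of a bin is the member with the fewest missing calls, ties
#' broken by lexicographic marker id; the bin id is the representative's id.
#'
#' @param alleles marker x sample 0/1/NA matrix of informative testcross
#'   markers.
#' @return list with `bins` (data frame `bin_id`, `representative`,
#'   `n_members`, `n_missing`), `members` (named list bin id -> member ids)
#'   and `signatures` (representative rows of `alleles`, one per bin).
#' @export
bin_markers <- function(alleles) {
  stopifnot(is.matrix(alleles), nrow(alleles) >= 1)
  key <- apply(alleles, 1, function(v) paste(ifelse(is.na(v), "N", v),
                                             collapse = ""))
  groups <- split(rownames(alleles), key)
  n_miss <- rowSums(is.na(alleles))
  reps <- vapply(groups, function(ids) {
    ids[order(n_miss[ids], ids)][1]
  }, "")
  ord <- order(reps)
  groups <- groups[ord]
  reps <- reps[ord]
  bins <- data.frame(bin_id = reps, representative = reps,
                     n_members = vapply(groups, length, 0L),
                     n_missing = n_miss[reps],
                     row.names = NULL, stringsAsFactors = FALSE)
  list(bins = bins,
       members = stats::setNames(groups, reps),
       signatures = alleles[reps, , drop = FALSE])
}

#' Two-point recombination fraction and LOD for a haploid testcross
#'
#' Over the `n` pairwise-complete samples with `k` mismatches between the two
#' signatures, the linkage phase is chosen so that the recombinant count is
#' `min(k, n - k)` (phase "coupling" when `k <= n - k`, else "repulsion").
#' Then `r = recombinants / n` and
#' `LOD = k' log10(2 r) + (n - k') log10(2 (1 - r))` with `k'` the
#' recombinant count, which equals `n log10(2)` when `r = 0`.
#'
#' @param sig_a,sig_b allele vectors in 0/1/NA.
#' @return list with `r`, `lod`, `n_informative`, `phase`; `r` and `lod` are
#'   `NA` (flagged undefined) when no pairwise-complete samples exist.
#' @export
estimate_rf <- function(sig_a, sig_b) {
  ok <- !is.na(sig_a) & !is.na(sig_b)
  n <- sum(ok)
  if (n == 0)
    return(list(r = NA_real_, lod = NA_real_, n_informative = 0L,
                phase = NA_character_))
  k <- sum(sig_a[ok] != sig_b[ok])
  rec <- min(k, n - k)
  phase <- if (k <= n - k) "coupling" else "repulsion"
  r <- rec / n
  lod <- if (rec == 0) n * log10(2) else
    rec * log10(2 * r) + (n - rec) * log10(2 * (1 - r))
  list(r = r, lod = lod, n_informative = as.integer(n), phase = phase)
}

#' Pairwise two-point estimates for a set of bin signatures
#'
#' Dense matrix version of [estimate_rf()] over all bin pairs, computed with
#' matrix products.  This object carries everything the grouping, ordering
#' and mapping steps need: recombinant counts (the COUNT criterion operates
#' on these), informative sample counts, recombination fractions and LODs.
#'
#' @param signatures bin x sample 0/1/NA matrix (e.g. `$signatures` from
#'   [bin_markers()]).
#' @return object of class `linkage_data`: list of square matrices `rec`
#'   (phase-aligned recombinant counts), `n` (pairwise-complete counts),
#'   `rfrac`, `lod`, plus `ids`.
#' @export
linkage_data <- function(signatures) {
  stopifnot(is.matrix(signatures))
  ids <- rownames(signatures)
  A <- (signatures == 1L); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- (signatures == 0L); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  M <- !is.na(signatures); storage.mode(M) <- "double"
  mism <- tcrossprod(A, B); mism <- mism + t(mism)
  n <- tcrossprod(M)
  rec <- pmin(mism, n - mism)
  rfrac <- ifelse(n > 0, rec / n, NA_real_)
  lod <- matrix(NA_real_, nrow(n), ncol(n))
  pos <- n > 0
  r0 <- pos & rec == 0
  lod[r0] <- n[r0] * log10(2)
  rmid <- pos & rec > 0
  lod[rmid] <- rec[rmid] * log10(2 * rfrac[rmid]) +
    (n[rmid] - rec[rmid]) * log10(2 * (1 - rfrac[rmid]))
  diag(rfrac) <- 0
  diag(rec) <- 0
  dimnames(rec) <- dimnames(n) <- dimnames(rfrac) <- dimnames(lod) <-
    list(ids, ids)
  structure(list(ids = ids, rec = rec, n = n, rfrac = rfrac, lod = lod),
            class = "linkage_data")
}

#' Partition bins into linkage groups
#'
#' Builds a graph with an edge between two bins when `LOD >= lod_min` and
#' `r <= rf_max`, and returns its connected components (transitive closure):
#' a chain a-b-c with both adjacent pairs linked forms one group even if a-c
#' itself is not linked.
#'
#' @param ld a [linkage_data()] object.
#' @param lod_min minimum LOD for an edge (default 8).
#' @param rf_max maximum recombination fraction for an edge (default 0.35).
#' @return list with `groups` (list of bin-id vectors, size >= 2, ordered by
#'   decreasing size then smallest member id) and `singletons`.
#' @export
group_markers <- function(ld, lod_min = 8, rf_max = 0.35) {
  stopifnot(inherits(ld, "linkage_data"))
  adj <- !is.na(ld$lod) & ld$lod >= lod_min &
    !is.na(ld$rfrac) & ld$rfrac <= rf_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(ld$ids, comp$membership)
  sizes <- vapply(groups, length, 0L)
  singletons <- unlist(groups[sizes == 1], use.names = FALSE)
  groups <- groups[sizes >= 2]
  first_id <- vapply(groups, min, "")
  groups <- groups[order(-vapply(groups, length, 0L), first_id)]
  list(groups = unname(groups),
       singletons = sort(singletons %||% character()))
}

# COUNT of an order: total recombinant events between adjacent bins
count_of_order <- function(ord, rec) {
  if (length(ord) < 2) return(0)
  sum(rec[cbind(ord[-length(ord)], ord[-1])])
}

#' Order a linkage group with the RECORD algorithm
#'
#' RECORD builds an order by greedy sequential insertion: bins are taken in a
#' random sequence and each is inserted at the position that minimally
#' increases COUNT, the total number of observed recombination events between
#' adjacent bins (mismatches counted over pairwise-complete samples, phase
#' aligned).  The procedure is repeated `n_counts` times with different
#' random insertion sequences and the order with the smallest COUNT is
#' returned (ties broken by the per-informative-sample normalized count,
#' then by the earlier repetition).  The returned order is reported with its
#' lexicographically lower bin id first, fixing the reversal ambiguity.
#'
#' @param ld a [linkage_data()] object.
#' @param ids bin ids of the group (>= 1).
#' @param n_counts number of counting repetitions (default 16).
#' @param seed integer seed; identical seeds give identical orders.
#' @return object of class `ordered_map`: list with `lg_id` (NA until
#'   assigned), `bins` (ordered bin ids), `count_score`, and empty `adj_r` /
#'   `cM` slots until [kosambi_map()] is applied.
#' @export
order_record <- function(ld, ids, n_counts = 16, seed = 1L) {
  stopifnot(inherits(ld, "linkage_data"))
  if (length(ids) == 1)
    return(structure(list(lg_id = NA_character_, bins = ids,
                          count_score = 0, adj_r = numeric(), cM = 0),
                     class = "ordered_map"))
  rec <- ld$rec[ids, ids, drop = FALSE]
  nmat <- ld$n[ids, ids, drop = FALSE]
  norm <- ifelse(nmat > 0, rec / nmat, 0.5)
  set.seed(seed)
  best <- NULL
  for (rep_i in seq_len(n_counts)) {
    seqn <- sample(ids)
    ord <- seqn[1:2]
    for (x in seqn[-(1:2)]) {
      L <- length(ord)
      left <- ord[-L]; right <- ord[-1]
      delta <- c(rec[x, ord[1]],
                 rec[left, x] + rec[x, right] - rec[cbind(left, right)],
                 rec[ord[L], x])
      dnorm <- c(norm[x, ord[1]],
                 norm[left, x] + norm[x, right] - norm[cbind(left, right)],
                 norm[ord[L], x])
      pick <- order(delta, dnorm)[1]
      ord <- append(ord, x, after = pick - 1L)
    }
    cnt <- count_of_order(ord, rec)
    cnorm <- count_of_order(ord, norm)
    if (is.null(best) || cnt < best$cnt ||
        (cnt == best$cnt && cnorm < best$cnorm)) {
      best <- list(ord = ord, cnt = cnt, cnorm = cnorm)
    }
  }
  ord <- best$ord
  if (ord[1] > ord[length(ord)]) ord <- rev(ord)
  structure(list(lg_id = NA_character_, bins = ord, count_score = best$cnt,
                 adj_r = numeric(), cM = numeric()),
            class = "ordered_map")
}

#' @export
print.ordered_map <- function(x, ...) {
  cat("ordered_map", if (!is.na(x$lg_id)) x$lg_id else "", ":",
      length(x$bins), "bins, COUNT =", x$count_score,
      if (length(x$cM) == length(x$bins))
        paste0(", length ", round(max(x$cM), 1), " cM") else "", "\n")
  invisible(x)
}

# all permutations of 1..n as a matrix (rows); cached
perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- if (n == 1) matrix(1L, 1, 1) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(i, matrix(rest[sub], nrow(sub)))
    }))
  }
  storage.mode(p) <- "integer"
  perm_cache[[key]] <- p
  p
}

# candidate in-window permutations under the ripple policy
ripple_perms <- function(w, n_sample = 5000) {
  if (w <= 8) return(all_perms(w))
  base <- seq_len(w)
  shifts <- do.call(rbind, lapply(seq_len(w) - 1L, function(s)
    c(base[-seq_len(s)], base[seq_len(s)])))
  swaps <- do.call(rbind, lapply(seq_len(w - 1L), function(i) {
    p <- base; p[c(i, i + 1L)] <- p[c(i + 1L, i)]; p
  }))
  rand <- matrix(unlist(lapply(seq_len(n_sample), function(i) sample(w))),
                 ncol = w, byrow = TRUE)
  unique(rbind(shifts, swaps, rand))
}

#' Refine a marker order with a sliding-window ripple
#'
#' Slides a window of `window` bins along the order in steps of `step` bins.
#' Within each window all permutations are tried when `window <= 8`;
#' for larger windows a bounded candidate set is used instead (all circular
#' shifts, all adjacent transpositions, and `n_sample` seeded random
#' permutations).  A permutation is accepted only if it strictly lowers
#' COUNT; passes repeat until a full pass makes no change, so COUNT never
#' increases.
#'
#' @param ordered an [order_record()] result.
#' @param ld the [linkage_data()] object.
#' @param window window size in bins (default 10).
#' @param step step size in bins (default 1).
#' @param n_sample number of random permutations per window when
#'   `window > 8`.
#' @param seed integer seed (used only for the sampled policy).
#' @param max_pass safety cap on full passes.
#' @return the refined `ordered_map` (cM slots cleared; re-map with
#'   [kosambi_map()]).
#' @export
ripple_window <- function(ordered, ld, window = 10, step = 1,
                          n_sample = 5000, seed = 1L, max_pass = 25) {
  stopifnot(inherits(ordered, "ordered_map"), inherits(ld, "linkage_data"))
  ord <- ordered$bins
  n <- length(ord)
  if (n < 3) return(ordered)
  w <- min(window, n)
  rec <- ld$rec  # full matrix, indexed by bin id
  set.seed(seed)
  perms <- ripple_perms(w, n_sample)
  starts <- unique(c(seq(1, n - w + 1, by = step), n - w + 1))
  changed <- TRUE
  pass <- 0
  while (changed && pass < max_pass) {
    changed <- FALSE
    pass <- pass + 1
    for (s in starts) {
      win <- s:(s + w - 1)
      seg <- ord[win]
      left <- if (s > 1) ord[s - 1] else NA
      right <- if (s + w - 1 < n) ord[s + w] else NA
      cand <- matrix(seg[perms], nrow(perms))
      cost <- numeric(nrow(cand))
      for (j in seq_len(w - 1))
        cost <- cost + rec[cbind(cand[, j], cand[, j + 1])]
      if (!is.na(left)) cost <- cost + rec[left, cand[, 1]]
      if (!is.na(right)) cost <- cost + rec[cbind(cand[, w], right)]
      cur <- sum(rec[cbind(seg[-w], seg[-1])]) +
        (if (!is.na(left)) rec[left, seg[1]] else 0) +
        (if (!is.na(right)) rec[seg[w], right] else 0)
      jbest <- which.min(cost)
      if (cost[jbest] < cur - 1e-12) {
        ord[win] <- seg[perms[jbest, ]]
        changed <- TRUE
      }
    }
  }
  if (ord[1] > ord[n]) ord <- rev(ord)
  structure(list(lg_id = ordered$lg_id, bins = ord,
                 count_score = count_of_order(ord, ld$rec),
                 adj_r = numeric(), cM = numeric()),
            class = "ordered_map")
}

#' Kosambi map function
#'
#' Converts a recombination fraction to a map distance in cM:
#' `d = 25 ln((1 + 2 r) / (1 - 2 r))`.  Accounts for moderate positive
#' crossover interference; `d(r) >= 100 r`, `d(0) = 0`, and `d` diverges as
#' `r -> 0.5`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return distance(s) in cM.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("Kosambi distance requires r in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Assign Kosambi cM positions along an ordered map
#'
#' Adjacent recombination fractions are taken from the two-point estimates in
#' map order and converted with [kosambi()]; positions are cumulative from 0.
#' An adjacency at `r = 0.5` has infinite distance and signals a grouping or
#' ordering failure, so it is rejected.
#'
#' @param ordered an `ordered_map`.
#' @param ld the [linkage_data()] object.
#' @return the `ordered_map` with `adj_r` and `cM` filled in.
#' @export
kosambi_map <- function(ordered, ld) {
  stopifnot(inherits(ordered, "ordered_map"), inherits(ld, "linkage_data"))
  ord <- ordered$bins
  if (length(ord) < 2) {
    ordered$adj_r <- numeric()
    ordered$cM <- 0
    return(ordered)
  }
  adj_r <- ld$rfrac[cbind(ord[-length(ord)], ord[-1])]
  if (any(is.na(adj_r)))
    stop("adjacent pair with no informative samples; cannot map")
  if (any(adj_r >= 0.5))
    stop("adjacent recombination fraction at 0.5; grouping/ordering failure")
  ordered$adj_r <- adj_r
  ordered$cM <- cumsum(c(0, kosambi(adj_r)))
  ordered
}

#' Pairwise recombination-fraction and LOD matrices in map order
#'
#' Diagnostic export behind the classic two-panel heat map (recombination
#' fraction in the lower triangle, phase LOD in the upper triangle).
#'
#' @param ordered an `ordered_map`.
#' @param ld the [linkage_data()] object.
#' @return list with `rfrac` and `lod` matrices whose rows/columns follow the
#'   map order, plus `heat` (single matrix with rfrac below and LOD above the
#'   diagonal).
#' @export
pairwise_matrices <- function(ordered, ld) {
  ord <- ordered$bins
  rf <- ld$rfrac[ord, ord, drop = FALSE]
  lod <- ld$lod[ord, ord, drop = FALSE]
  heat <- rf
  heat[upper.tri(heat)] <- lod[upper.tri(lod)]
  list(rfrac = rf, lod = lod, heat = heat)
}
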