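#' Simulate a neutral coalescent haplotype panel for one probe region
#'
#' Standard single-population neutral coalescent under the infinite-sites
#' model: with `k` active lineages the waiting time to the next coalescence
#' is exponential with rate `k (k - 1) / 2` (time in units of 2N
#' generations); mutations are dropped on each branch as a Poisson process
#' with rate `theta / 2` per unit branch length, each mutation creating one
#' new segregating site.  Site positions are uniform on the region and
#' strictly increasing after sorting.  Under this scaling the expected number
#' of segregating sites is `theta * a1(n)` with `a1(n) = sum(1/(1:(n-1)))`,
#' and the expected pairwise difference count is `theta`.
#'
#' @param n_samples number of haplotypes (>= 2).
#' @param theta scaled mutation rate (`4 N mu` per region), > 0.
#' @param region_length_bp length of the probe region in bp.
#' @param seed integer seed.
#' @return object of class `haplotype_panel`: list with `haplotypes`
#'   (`n_samples` x `n_sites` 0/1 matrix), `site_positions` (strictly
#'   increasing bp), `theta`, `seed`.
#' @export
simulate_coalescent_probe <- function(n_samples, theta,
                                      region_length_bp = 320, seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (theta <= 0) stop("theta must be > 0")
  set.seed(seed)
  # active lineages as tip sets; accumulate branch length per lineage
  tips <- lapply(seq_len(n_samples), identity)
  blen <- numeric(n_samples)
  branches <- list()   # each: list(tips, length)
  while (length(tips) > 1) {
    k <- length(tips)
    dt <- stats::rexp(1, k * (k - 1) / 2)
    blen <- blen + dt
    pair <- sample(k, 2)
    branches <- c(branches,
                  list(list(tips = tips[[pair[1]]], len = blen[pair[1]]),
                       list(tips = tips[[pair[2]]], len = blen[pair[2]])))
    merged <- c(tips[[pair[1]]], tips[[pair[2]]])
    tips <- c(tips[-pair], list(merged))
    blen <- c(blen[-pair], 0)
  }
  cols <- list()
  for (b in branches) {
    n_mut <- stats::rpois(1, theta / 2 * b$len)
    if (n_mut > 0) for (j in seq_len(n_mut)) {
      v <- integer(n_samples)
      v[b$tips] <- 1L
      cols[[length(cols) + 1L]] <- v
    }
  }
  n_sites <- length(cols)
  H <- if (n_sites) do.call(cbind, cols) else
    matrix(integer(), n_samples, 0)
  pos <- sort(stats::runif(n_sites, 0, region_length_bp))
  if (n_sites) {
    ord <- sample(n_sites)  # decouple site order from branch enumeration
    H <- H[, ord, drop = FALSE]
  }
  structure(list(haplotypes = H, site_positions = pos, theta = theta,
                 seed = seed),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$haplotypes), "haplotypes,",
      ncol(x$haplotypes), "segregating sites (theta =", x$theta, ")\n")
  invisible(x)
}
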