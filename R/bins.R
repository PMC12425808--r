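#' Genomic bin partition for the threading HMMs
#'
#' The genome is tiled with equal-sized bins; the bin size is chosen as
#' `4e-3 / (4 * Ne * r)` base pairs (clamped below at 1 bp), so that the
#' per-bin recombination probability of a typical branch is small and at
#' most one recombination event needs to be modelled per bin boundary.
#' The last bin is truncated when the bin size does not divide `L`.
#'
#' @param L Sequence length in base pairs.
#' @param params A [model_params()] object.
#' @param positions Optional 0-based polymorphic-site positions; when given,
#'   a site index (bin of each site) is included.
#' @return An object of class `bin_partition`: list with `bin_size`,
#'   `edges` (bin left edges plus `L`), `n_bins`, and optionally
#'   `site_bin`.
#' @examples
#' b <- make_bins(100, model_params(1e4, 2e-8, 2e-8))
#' b$bin_size   # 5 bp
#' @export
make_bins <- function(L, params, positions = NULL) {
  stopifnot(L >= 1)
  bs <- max(1, round(4e-3 / (4 * params$Ne * params$r)))
  edges <- unique(c(seq(0, L, by = bs), L))
  out <- list(bin_size = bs, edges = edges, n_bins = length(edges) - 1L)
  if (!is.null(positions)) {
    out$site_bin <- findInterval(positions, edges,
                                 rightmost.closed = TRUE)
  }
  class(out) <- "bin_partition"
  out
}

#' @export
print.bin_partition <- function(x, ...) {
  cat("bin_partition:", x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

## bin index (1-based) of position x
.bin_of <- function(bins, x) findInterval(x, bins$edges, rightmost.closed = TRUE)

## Snap all ARG breakpoints to the bin grid (nearest edge, keeping at most
## one breakpoint per boundary).  Used to bring externally simulated ARGs
## onto the sampler's bin-aligned representation.
#' Snap ARG breakpoints to the threading bin grid
#'
#' Moves every tree-change position to the nearest bin edge (dropping
#' collisions), so the ARG satisfies the sampler's "at most one
#' recombination per bin boundary" convention.
#'
#' @param arg An `arg_tables` object.
#' @param bins A [make_bins()] partition for the same sequence length.
#' @return An `arg_tables` object with bin-aligned breakpoints.
#' @export
snap_to_bins <- function(arg, bins) {
  ats <- .ats_from_tables(arg)
  bs <- bins$bin_size
  ## carrier sets under the original tree assignment, before any shift
  carriers <- lapply(seq_along(ats$mut_pos), function(s) {
    tr <- ats$trees[[.ats_tree_at(ats, ats$mut_pos[s])]]
    .tree_leaves_below(tr, ats$mut_node[s], ats$n)
  })
  newb <- round(ats$breaks / bs) * bs
  newb[1] <- 0
  keep <- !duplicated(newb) & newb < ats$L
  ats$breaks <- newb[keep]
  ats$trees <- ats$trees[keep]
  ## re-anchor mutations whose local tree changed under the snap
  if (length(ats$mut_pos)) {
    pat <- matrix(0L, ats$n, length(ats$mut_pos))
    for (s in seq_along(ats$mut_pos)) pat[carriers[[s]], s] <- 1L
    for (s in seq_along(ats$mut_pos)) {
      tr <- ats$trees[[.ats_tree_at(ats, ats$mut_pos[s])]]
      mi <- match(ats$mut_node[s], tr$ids)
      ok <- !is.na(mi) && tr$parent[mi] != 0L &&
        identical(.tree_leaves_below(tr, ats$mut_node[s], ats$n),
                  carriers[[s]])
      if (!ok) {
        ats$mut_node[s] <- .best_mut_node(tr, ats$time, pat[, s], ats$n,
                                          mu = 1e-8)
      }
    }
  }
  .ats_to_tables(ats)
}
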