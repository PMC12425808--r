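#' Pairwise coalescence time at a position
#'
#' Time (generations) of the most recent common ancestor of samples
#' `i` and `j` in the marginal tree at `position`.
#'
#' @param arg An `arg_tables` object.
#' @param i,j Distinct sample ids.
#' @param position 0-based position.
#' @return MRCA time in generations.
#' @export
pairwise_tmrca <- function(arg, i, j, position) {
  if (i == j) stop("i and j must be distinct samples")
  ats <- .ats_from_tables(arg)
  .ats_tmrca(ats, i, j, position)
}

.ats_tmrca <- function(ats, i, j, position) {
  tr <- ats$trees[[.ats_tree_at(ats, position)]]
  ats$time[.tree_mrca(tr, i, j)]
}

#' Windowed mean pairwise diversity implied by an ARG
#'
#' For each genomic window, the span-weighted average over all sample pairs
#' and positions of the pairwise coalescence time, scaled by twice the
#' mutation rate.  Under the model this equals the expected per-site
#' nucleotide diversity (`theta = 4*Ne*mu` for a constant-size population),
#' so the values are directly comparable to SNP-based diversity in the same
#' windows.  The last window is truncated if `window` does not divide the
#' sequence length.
#'
#' @param arg An `arg_tables` object.
#' @param window Window size in base pairs.
#' @param params A [model_params()] object (only `mu` is used).
#' @return Data frame with `left`, `right`, `diversity`.
#' @export
windowed_diversity <- function(arg, window, params) {
  if (window <= 0) stop("window must be positive")
  L <- arg$sequence_length
  if (window > L) stop("window exceeds sequence length")
  ats <- .ats_from_tables(arg)
  n <- ats$n
  starts <- window * (seq_len(ceiling(L / window)) - 1)
  ends <- pmin(starts + window, L)
  npair <- n * (n - 1) / 2
  ## mean pairwise TMRCA per tree, then span-weight within windows
  tbar <- vapply(ats$trees, function(tr) {
    M <- .tree_pair_times(tr, ats$time, n)
    sum(M[upper.tri(M)]) / npair
  }, numeric(1))
  lefts <- ats$breaks
  rights <- c(ats$breaks[-1], L)
  div <- numeric(length(starts))
  for (w in seq_along(starts)) {
    ov <- pmax(0, pmin(rights, ends[w]) - pmax(lefts, starts[w]))
    div[w] <- sum(ov * tbar) / (ends[w] - starts[w])
  }
  data.frame(left = starts, right = ends, diversity = 2 * params$mu * div)
}

#' Triplet distance between two marginal trees
#'
#' The fraction of unordered leaf triples whose induced rooted topology
#' differs between the two trees.  For each triple the induced topology is
#' determined by which pair coalesces first.
#'
#' @param t1,t2 `marginal_tree` objects on the same leaf set.
#' @return A fraction in `[0, 1]`.
#' @export
triplet_distance <- function(t1, t2) {
  if (!setequal(t1$leaves, t2$leaves)) stop("trees have different leaf sets")
  n <- length(t1$leaves)
  if (n < 3) stop("need at least 3 leaves")
  M1 <- .mt_pair_times(t1)
  M2 <- .mt_pair_times(t2)
  leaves <- sort(t1$leaves)
  bad <- 0L; tot <- 0L
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    i <- leaves[a]; j <- leaves[b]; k <- leaves[cc]
    tot <- tot + 1L
    if (.triple_top(M1, i, j, k) != .triple_top(M2, i, j, k)) bad <- bad + 1L
  }
  bad / tot
}

.mt_pair_times <- function(mt) {
  tr <- .mt_to_tree(mt)
  time <- rep(NA_real_, max(tr$ids))
  time[mt$branches$child] <- mt$branches$child_time
  time[mt$branches$parent] <- mt$branches$parent_time
  n <- length(mt$leaves)
  .tree_pair_times(tr, time, n)
}

## which pair of {i,j,k} is the cherry (coalesces first); 0 = unresolved
.triple_top <- function(M, i, j, k) {
  tij <- M[i, j]; tik <- M[i, k]; tjk <- M[j, k]
  which.min(c(tij, tik, tjk))
}

#' Span-weighted mean number of lineages through time
#'
#' For each time in `grid`, the average (weighted by marginal-tree span)
#' number of ancestral lineages at that time; `n` at time 0, non-increasing,
#' and 1 at or beyond the oldest root.
#'
#' @param arg An `arg_tables` object.
#' @param grid Sorted non-negative times (generations).
#' @return Numeric vector of mean lineage counts, one per grid time.
#' @export
lineages_through_time <- function(arg, grid) {
  stopifnot(all(grid >= 0), !is.unsorted(grid))
  ats <- .ats_from_tables(arg)
  spans <- .ats_spans(ats)
  out <- numeric(length(grid))
  for (k in seq_along(ats$trees)) {
    tr <- ats$trees[[k]]
    itimes <- sort(ats$time[setdiff(tr$ids, .tree_leaf_ids(tr))])
    ## lineage count at t: 1 + number of coalescences strictly above t
    kk <- 1 + length(itimes) - findInterval(grid, itimes,
                                            rightmost.closed = FALSE)
    out <- out + spans[k] * kk
  }
  out / sum(spans)
}

#' IBD segments for a pair of samples
#'
#' Maximal half-open genomic intervals over which the MRCA *node* of the
#' pair is unchanged (node identity persists across marginal trees).  The
#' intervals partition `[0, sequence_length)`.
#'
#' @param arg An `arg_tables` object.
#' @param i,j Distinct sample ids.
#' @return Data frame with `left`, `right`, `mrca`.
#' @export
ibd_segments <- function(arg, i, j) {
  if (i == j) stop("i and j must be distinct samples")
  ats <- .ats_from_tables(arg)
  mrcas <- vapply(ats$trees, function(tr) .tree_mrca(tr, i, j), integer(1))
  lefts <- ats$breaks
  rights <- c(ats$breaks[-1], ats$L)
  keep <- c(TRUE, mrcas[-1] != mrcas[-length(mrcas)])
  runs <- cumsum(keep)
  data.frame(
    left = tapply(lefts, runs, min),
    right = tapply(rights, runs, max),
    mrca = mrcas[keep],
    row.names = NULL
  )
}

#' Recombination breakpoints per genomic window
#'
#' Counts the distinct tree-change positions (excluding 0) per window of
#' size `window`; the counts sum to the total number of breakpoints.
#'
#' @param arg An `arg_tables` object.
#' @param window Window size in base pairs.
#' @return Data frame with `left`, `right`, `breakpoints`.
#' @export
breakpoints_in_windows <- function(arg, window) {
  if (window <= 0) stop("window must be positive")
  L <- arg$sequence_length
  ats <- .ats_from_tables(arg)
  bp <- ats$breaks[ats$breaks > 0]
  starts <- window * (seq_len(ceiling(L / window)) - 1)
  ends <- pmin(starts + window, L)
  cnt <- vapply(seq_along(starts), function(w)
    sum(bp >= starts[w] & bp < ends[w]), numeric(1))
  data.frame(left = starts, right = ends, breakpoints = cnt)
}

#' Point estimate of a derived allele's age
#'
#' The default estimator is the midpoint of the branch carrying the site's
#' mutation in the site's local tree; `method = "sample"` instead draws a
#' uniform time on that branch (useful for averaging over posterior ARG
#' samples).
#'
#' @param arg An `arg_tables` object.
#' @param site 0-based site position carrying exactly one mutation.
#' @param method `"midpoint"` (default) or `"sample"`.
#' @return Age in generations, strictly between the child and parent times
#'   of the carrying branch.
#' @export
allele_age <- function(arg, site, method = c("midpoint", "sample")) {
  method <- match.arg(method)
  hit <- which(arg$mutations$position == site)
  if (length(hit) != 1L) stop("site must carry exactly one mapped mutation")
  node <- arg$mutations$node[hit]
  ats <- .ats_from_tables(arg)
  tr <- ats$trees[[.ats_tree_at(ats, site)]]
  pa <- .tree_parent(tr, node)
  if (is.na(pa) || pa == 0L) stop("mutation node has no branch at its site")
  lo <- ats$time[node]; hi <- ats$time[pa]
  if (method == "midpoint") (lo + hi) / 2 else stats::runif(1, lo, hi)
}
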