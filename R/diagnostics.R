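#' Pairwise coalescence times across a posterior set
#'
#' Evaluates `pairwise_tmrca` for each posterior ARG sample at each
#' requested (pair, position) draw, converting each sample once.
#'
#' @param ps A `posterior_set` (or plain list of `arg_tables`).
#' @param pairs Two-column matrix of sample ids.
#' @param positions Vector of 0-based positions (same length as
#'   `nrow(pairs)`).
#' @return Matrix with one row per draw and one column per posterior
#'   sample.
#' @export
posterior_tmrca <- function(ps, pairs, positions) {
  samples <- if (inherits(ps, "posterior_set")) ps$samples else ps
  out <- matrix(NA_real_, nrow(pairs), length(samples))
  for (k in seq_along(samples)) {
    ats <- .ats_from_tables(samples[[k]])
    for (d in seq_len(nrow(pairs))) {
      out[d, k] <- .ats_tmrca(ats, pairs[d, 1], pairs[d, 2], positions[d])
    }
  }
  out
}

#' Empirical credible interval for a pairwise coalescence time
#'
#' The level-`level` CI is the central percentile interval of the sampled
#' coalescence times: for level 0.9, the 5th to the 95th percentile.
#'
#' @param ps A `posterior_set`.
#' @param i,j Distinct sample ids.
#' @param position 0-based position.
#' @param level Coverage level in (0, 1).
#' @return Named vector `c(lo, hi)`.
#' @export
empirical_ci <- function(ps, i, j, position, level = 0.9) {
  stopifnot(level > 0, level < 1)
  samples <- if (inherits(ps, "posterior_set")) ps$samples else ps
  if (length(samples) < 2) stop("need at least 2 posterior samples")
  v <- vapply(samples, function(s) pairwise_tmrca(s, i, j, position),
              numeric(1))
  qs <- stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(lo = qs[1], hi = qs[2])
}

#' Empirical CI coverage of ground-truth coalescence times
#'
#' Given posterior TMRCA draws (rows = (pair, position) instances,
#' columns = posterior samples) and the true values, the fraction of
#' instances whose truth lies inside the central `level` interval.
#'
#' @param draws Matrix from [posterior_tmrca()] (rows may pool replicates).
#' @param truth Numeric vector of true coalescence times (one per row).
#' @param level CI level (default 0.9).
#' @return Fraction in `[0, 1]`.
#' @export
ci_coverage <- function(draws, truth, level = 0.9) {
  stopifnot(nrow(draws) == length(truth))
  a <- (1 - level) / 2
  inside <- vapply(seq_len(nrow(draws)), function(d) {
    qs <- stats::quantile(draws[d, ], c(a, 1 - a), names = FALSE)
    truth[d] >= qs[1] && truth[d] <= qs[2]
  }, logical(1))
  mean(inside)
}

#' Simulation-based-calibration rank histogram
#'
#' For each replicate, the rank of the ground-truth (prior-drawn) value
#' among its posterior samples; a correct sampler yields uniform ranks on
#' `{0, ..., m}`.  Ties are broken by random jitter.  The histogram is
#' binned and its KL divergence to the uniform distribution reported
#' (zero-count protection by +0.5 pseudo-counts).
#'
#' @param truth Numeric vector, one ground-truth value per replicate.
#' @param post Matrix of posterior samples (rows = replicates).
#' @param bins Number of histogram bins (default 20).
#' @return List: `ranks`, `histogram` (counts per bin), `kl`.
#' @export
rank_histogram <- function(truth, post, bins = 20) {
  stopifnot(length(truth) == nrow(post))
  m <- ncol(post)
  ranks <- vapply(seq_along(truth), function(i) {
    x <- post[i, ] + stats::runif(m, -1e-9, 1e-9) * pmax(abs(post[i, ]), 1)
    sum(x < truth[i])
  }, numeric(1))
  brk <- seq(0, m + 1, length.out = bins + 1)
  h <- as.numeric(table(cut(ranks + 0.5, brk, include.lowest = TRUE)))
  p <- (h + 0.5) / sum(h + 0.5)
  q <- rep(1 / bins, bins)
  list(ranks = ranks, histogram = h, kl = sum(p * log(p / q)))
}

#' Coalescence-time distribution heatmap for a focal haplotype
#'
#' For each genomic window, the span- and sample-averaged distribution of
#' the focal haplotype's pairwise coalescence times with all other
#' haplotypes, binned on a time grid; columns (windows) sum to 1.
#' Averaging over posterior samples smooths the topology noise of any
#' single ARG.
#'
#' @param ps A `posterior_set` (or list of `arg_tables`).
#' @param focal Focal sample id.
#' @param window Window size in base pairs.
#' @param time_grid Increasing vector of time-bin edges (the last bin
#'   absorbs all older coalescences).
#' @return Matrix (length(time_grid) x number of windows), columns sum
#'   to 1; attribute `windows` holds the window left edges.
#' @export
coalescence_heatmap <- function(ps, focal, window, time_grid) {
  samples <- if (inherits(ps, "posterior_set")) ps$samples else ps
  L <- samples[[1]]$sequence_length
  starts <- window * (seq_len(ceiling(L / window)) - 1)
  ends <- pmin(starts + window, L)
  nb <- length(time_grid)
  M <- matrix(0, nb, length(starts))
  for (s in samples) {
    ats <- .ats_from_tables(s)
    others <- setdiff(s$sample_ids, focal)
    lefts <- ats$breaks
    rights <- c(ats$breaks[-1], L)
    for (k in seq_along(ats$trees)) {
      tms <- vapply(others, function(j)
        ats$time[.tree_mrca(ats$trees[[k]], focal, j)], numeric(1))
      tb <- pmax(pmin(findInterval(tms, time_grid), nb), 1L)
      for (w in which(starts < rights[k] & ends > lefts[k])) {
        ov <- min(rights[k], ends[w]) - max(lefts[k], starts[w])
        for (b in tb) M[b, w] <- M[b, w] + ov
      }
    }
  }
  sums <- colSums(M)
  sums[sums == 0] <- 1
  M <- sweep(M, 2, sums, "/")
  attr(M, "windows") <- starts
  M
}

#' Ancient-to-intermediate coalescence-density ratio per window
#'
#' The ratio of pairwise-coalescence mass above the population split time
#' to the mass between the introgression time and the split time; large
#' values flag windows whose lineages escape deep past the split, the
#' signature of archaic introgression.  Division by zero is capped.
#'
#' @param heatmap Output of [coalescence_heatmap()].
#' @param time_grid The time-bin edges used for the heatmap.
#' @param t_intro Introgression time (generations).
#' @param t_split Split time (generations), `t_intro < t_split`.
#' @param cap Value substituted for infinite ratios (default 100).
#' @return Numeric vector, one ratio per window.
#' @export
coalescence_ratio <- function(heatmap, time_grid, t_intro, t_split,
                              cap = 100) {
  stopifnot(t_intro > 0, t_split > t_intro)
  above <- which(time_grid >= t_split)
  mid <- which(time_grid >= t_intro & time_grid < t_split)
  num <- colSums(heatmap[above, , drop = FALSE])
  den <- colSums(heatmap[mid, , drop = FALSE])
  out <- num / den
  out[!is.finite(out) | out > cap] <- cap
  out
}
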