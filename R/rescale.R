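## ---------------------------------------------------------------------------
## ARG re-scaling: a monotonic piecewise-linear transform of node times
## fitted so that the expected mutation count in equal-branch-length time
## windows matches the observed (fractional) count.

## edge table view of the chain state / tables: child, parent, left, right,
## tc, tp
.edge_view <- function(arg) {
  tmap <- rep(NA_real_, max(arg$nodes$id))
  tmap[arg$nodes$id] <- arg$nodes$time
  e <- arg$edges
  data.frame(child = e$child, parent = e$parent, left = e$left,
             right = e$right, tc = tmap[e$child], tp = tmap[e$parent])
}

#' Equal-branch-length time windows of an ARG
#'
#' Partitions the time axis `(0, max node time]` into `K` windows such that
#' the span-weighted total branch length in each window is identical
#' (computed by exact piecewise-linear integration of the ARG's
#' lineage-count function).
#'
#' @param arg An `arg_tables` object.
#' @param K Number of windows (default 100).
#' @return Numeric vector of `K + 1` window boundaries starting at 0.
#' @export
time_windows <- function(arg, K = 100) {
  stopifnot(K >= 1)
  ev <- .edge_view(arg)
  .time_windows_core(ev, K)
}

.time_windows_core <- function(ev, K) {
  span <- ev$right - ev$left
  A <- sum(span * (ev$tp - ev$tc))
  if (A <= 0) stop("degenerate ARG: zero total branch length")
  knots <- sort(unique(c(ev$tc, ev$tp)))
  ## coverage (area density) between consecutive knots
  dens <- vapply(seq_len(length(knots) - 1L), function(i) {
    t0 <- knots[i]
    sum(span[ev$tc <= t0 & ev$tp > t0])
  }, numeric(1))
  cum <- c(0, cumsum(dens * diff(knots)))
  targ <- A * seq_len(K - 1) / K
  inner <- vapply(targ, function(a) {
    i <- findInterval(a, cum, rightmost.closed = TRUE)
    i <- min(i, length(dens))
    knots[i] + (a - cum[i]) / dens[i]
  }, numeric(1))
  c(0, inner, max(knots))
}

#' Fractional mutation counts per time window
#'
#' A mutation on a branch spanning several windows contributes to each
#' window in proportion to the branch fraction overlapping it; the counts
#' sum exactly to the total number of mutations.
#'
#' @param arg An `arg_tables` object with mapped mutations.
#' @param windows Boundaries as returned by [time_windows()].
#' @return Numeric vector of length `length(windows) - 1`.
#' @export
mutation_counts <- function(arg, windows) {
  ats <- .ats_from_tables(arg)
  .mutation_counts_core(ats, windows)
}

.mutation_counts_core <- function(ats, windows) {
  K <- length(windows) - 1L
  out <- numeric(K)
  for (s in seq_along(ats$mut_pos)) {
    tr <- ats$trees[[.ats_tree_at(ats, ats$mut_pos[s])]]
    node <- ats$mut_node[s]
    pa <- .tree_parent(tr, node)
    if (is.na(pa) || pa == 0L) next       # unmapped / above-root: skip
    tc <- ats$time[node]
    tp <- ats$time[pa]
    ov <- pmax(0, pmin(windows[-1L], tp) - pmax(windows[-(K + 1L)], tc))
    out <- out + ov / (tp - tc)
  }
  out
}

#' Fit and apply the mutation-clock re-scaling
#'
#' Computes equal-branch-length windows, compares observed (fractional)
#' mutation counts with their expectation `mu * area` per window, and
#' re-scales each window's width by `observed / expected` (floored at 0.05
#' for windows with no observed mutations, to keep the transform strictly
#' increasing).  The pass is iterated to its fixed point (window boundaries
#' are recomputed from the transformed ARG each time), which makes the
#' operation idempotent; one or two passes almost always suffice.
#'
#' @param arg An `arg_tables` object with mutations.
#' @param params A [model_params()] object (`mu` is used).
#' @param K Number of windows (default 100).
#' @param max_iter Maximum fixed-point iterations (default 400; the pass
#'   contracts geometrically, so convergence to machine precision is cheap).
#' @param tol Convergence tolerance on `max |scale - 1|` (default 1e-12).
#' @return A list: `arg` (re-scaled tables), `map` (data frame with
#'   `original` and `mapped` boundary columns), `scales` (last-pass scale
#'   factors), `iterations`.
#' @export
fit_and_apply <- function(arg, params, K = 100, max_iter = 400, tol = 1e-12) {
  ats <- .ats_from_tables(arg)
  res <- .rescale_ats(ats, params, K, max_iter, tol)
  list(arg = .ats_to_tables(res$ats), map = res$map,
       scales = res$scales, iterations = res$iterations)
}

.rescale_ats <- function(ats, params, K = 100, max_iter = 400, tol = 1e-12) {
  mu <- params$mu
  if (!length(ats$mut_pos)) {
    warning("no mutations: re-scaling is the identity")
    bmax <- max(ats$time, na.rm = TRUE)
    return(list(ats = ats, map = data.frame(original = c(0, bmax),
                                            mapped = c(0, bmax)),
                scales = 1, iterations = 0L))
  }
  used <- sort(unique(unlist(lapply(ats$trees, `[[`, "ids"))))
  orig_tau <- NULL
  scales <- NULL
  it <- 0L
  repeat {
    it <- it + 1L
    ev <- .edge_view_ats(ats)
    tau <- .time_windows_core(ev, K)
    obs <- .mutation_counts_core(ats, tau)
    A <- sum((ev$right - ev$left) * (ev$tp - ev$tc))
    expct <- mu * A / K
    scales <- pmax(obs / expct, 0.05)
    newtau <- c(0, cumsum(scales * diff(tau)))
    f <- stats::approxfun(tau, newtau, rule = 2)
    if (is.null(orig_tau)) {
      orig_tau <- tau
      mapped_tau <- newtau
    } else {
      mapped_tau <- f(mapped_tau)
    }
    ats$time[used] <- f(ats$time[used])
    if (max(abs(scales - 1)) < tol || it >= max_iter) break
  }
  list(ats = ats, map = data.frame(original = orig_tau, mapped = mapped_tau),
       scales = scales, iterations = it)
}

## edge view straight from the internal representation
.edge_view_ats <- function(ats) {
  ec <- ep <- el <- er <- numeric(0)
  rights <- c(ats$breaks[-1L], ats$L)
  for (k in seq_along(ats$trees)) {
    tr <- ats$trees[[k]]
    sel <- tr$parent != 0L
    ec <- c(ec, tr$ids[sel]); ep <- c(ep, tr$parent[sel])
    el <- c(el, rep(ats$breaks[k], sum(sel)))
    er <- c(er, rep(rights[k], sum(sel)))
  }
  data.frame(child = ec, parent = ep, left = el, right = er,
             tc = ats$time[ec], tp = ats$time[ep])
}

## in-place rescale of the chain state
.st_rescale <- function(st, K = 100) {
  ats <- .st_as_ats(st)
  ## a few passes suffice inside the chain; exact idempotence is only
  ## needed for the standalone fit
  res <- suppressWarnings(.rescale_ats(ats, st$params, K, max_iter = 3))
  st$time <- res$ats$time
  .st_refresh_cache(st)
  invisible(st)
}

## chain state -> internal ats (shares trees; mutations from mut_node)
.st_as_ats <- function(st) {
  ok <- which(!is.na(st$mut_node))
  .ats_new(st$n, st$L, st$breaks, st$trees, st$time,
           st$pos[ok], st$mut_node[ok])
}
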