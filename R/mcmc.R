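#' MCMC chain configuration
#'
#' Defaults follow the sampling scheme used throughout the benchmarks:
#' 100 posterior samples taken every 20 iterations after 1,000 burn-in
#' iterations, where one iteration performs `n` SGPR cuts (`n` = number of
#' haplotypes), and node times are re-scaled against the mutation clock
#' after initialization and at every thinning boundary.
#'
#' @param n_samples Number of posterior samples to record.
#' @param thin Iterations between recorded samples.
#' @param burn_in Burn-in iterations.
#' @param seed Integer seed (required for reproducible runs).
#' @param rescale_windows Number of time windows for re-scaling (`K`).
#' @param shuffle_order Randomize the threading order at initialization.
#' @param accept_mode `"mh"` for the exact Metropolis-Hastings correction,
#'   `"always"` to treat SGPR as a near-Gibbs move and accept every
#'   proposal.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_samples = 100, thin = 20, burn_in = 1000,
                         seed = 1L, rescale_windows = 100,
                         shuffle_order = FALSE,
                         accept_mode = c("mh", "always")) {
  accept_mode <- match.arg(accept_mode)
  stopifnot(n_samples >= 1, thin >= 1, burn_in >= 0, rescale_windows >= 1)
  structure(list(n_samples = as.integer(n_samples), thin = as.integer(thin),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 rescale_windows = as.integer(rescale_windows),
                 shuffle_order = isTRUE(shuffle_order),
                 accept_mode = accept_mode),
            class = "chain_config")
}

#' Posterior sampling of ARGs by threading + SGPR
#'
#' Initializes an ARG by sequentially threading the haplotypes, then
#' explores the posterior with sub-graph pruning and re-grafting (SGPR)
#' Metropolis-Hastings steps.  One iteration performs `n` cuts; node times
#' are re-scaled against the mutation clock after initialization and at
#' every thinning boundary.
#'
#' @param haplotypes n x S 0/1 matrix of phased haplotypes (0 = ancestral).
#' @param positions 0-based site positions (length S, sorted).
#' @param L Sequence length in base pairs.
#' @param params A [model_params()] object.
#' @param config A [chain_config()] object.
#' @param init_arg Optional `arg_tables` to start from (bin-aligned via
#'   [snap_to_bins()]); default is sequential-threading initialization.
#' @param rescale Apply mutation-clock re-scaling inside the chain
#'   (default TRUE).
#' @param progress Print a line per thinning boundary.
#' @return An object of class `posterior_set`: list with `samples` (list of
#'   `arg_tables`), `iterations` (iteration index of each sample), `trace`
#'   (data frame: iteration, log_posterior, acceptance, mean_tree_length,
#'   breakpoints), and the configuration.
#' @export
run_chain <- function(haplotypes, positions, L, params,
                      config = chain_config(), init_arg = NULL,
                      rescale = TRUE, progress = FALSE) {
  set.seed(config$seed)
  n <- nrow(haplotypes)
  st <- .st_build(haplotypes, positions, L, params)
  ord <- if (config$shuffle_order) sample.int(n) else seq_len(n)
  if (is.null(init_arg)) {
    done <- integer(0)
    for (hh in ord) {
      .thread_one(st, hh, done)
      done <- c(done, hh)
    }
  } else {
    snapped <- snap_to_bins(init_arg, st$bins)
    ats <- .ats_from_tables(snapped)
    st$trees <- ats$trees
    st$breaks <- ats$breaks
    st$time <- ats$time
    st$time[is.na(st$time)] <- 0
    st$next_id <- as.integer(max(snapped$nodes$id) + 1L)
    .st_refresh_cache(st)
    .st_remap_sites(st, seq_along(st$pos))
  }
  ## keep enough mutations per window for the clock fit to be meaningful
  K_eff <- min(config$rescale_windows,
               max(2L, floor(length(positions) / 8)))
  if (rescale) .st_rescale(st, K_eff)
  always <- config$accept_mode == "always"
  iterate <- function(niter) {
    acc <- 0L; tot <- 0L
    for (i in seq_len(niter)) {
      ## one iteration: n branch re-siting cuts plus one segment-structure
      ## move (which can create, merge or relocate recombination events)
      for (j in seq_len(n)) {
        r <- .sgpr_step(st, always_accept = always)
        tot <- tot + 1L
        if (r$accepted) acc <- acc + 1L
      }
      r <- .sgpr_step(st, always_accept = always, span = "existence")
      tot <- tot + 1L
      if (r$accepted) acc <- acc + 1L
    }
    c(acc, tot)
  }
  trace <- list()
  it <- 0L
  note <- function(acc) {
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = it, log_posterior = .st_logpi(st),
      acceptance = acc[1] / max(acc[2], 1),
      mean_tree_length = st$A / st$L,
      breakpoints = length(st$breaks) - 1L)
  }
  acc <- iterate(config$burn_in)
  it <- config$burn_in
  note(acc)
  samples <- vector("list", config$n_samples)
  iters <- integer(config$n_samples)
  for (k in seq_len(config$n_samples)) {
    acc <- iterate(config$thin)
    it <- it + config$thin
    if (rescale) .st_rescale(st, K_eff)
    note(acc)
    samples[[k]] <- .ats_to_tables(.st_as_ats(st))
    iters[k] <- it
    if (progress) message("sample ", k, "/", config$n_samples,
                          " (iteration ", it, ")")
  }
  structure(list(samples = samples, iterations = iters,
                 trace = do.call(rbind, trace), config = config,
                 params = params),
            class = "posterior_set")
}

#' @export
print.posterior_set <- function(x, ...) {
  cat("posterior_set:", length(x$samples), "ARG samples,",
      length(x$samples[[1]]$sample_ids), "haplotypes, L =",
      x$samples[[1]]$sequence_length, "bp\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Exported single-move operations (mainly for testing and inspection)

#' Sample an SGPR cut
#'
#' Chooses a marginal tree with probability proportional to span times
#' total branch length, a branch within it proportionally to its length,
#' and a cut height uniformly on the branch.  The extension interval is
#' the genomic span of the ancestral segment of the cut branch's child
#' node (for a single-tree ARG, the whole region).
#'
#' @param arg An `arg_tables` object.
#' @param seed Optional seed.
#' @return A list of class `sgpr_cut`: `position` (left edge of the cut
#'   tree), `child`, `parent`, `cut_time`, `extension` (c(left, right)).
#' @export
sample_cut <- function(arg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ats <- .ats_from_tables(arg)
  spans <- diff(c(ats$breaks, ats$L))
  lam <- vapply(ats$trees, .tree_lambda, numeric(1), time = ats$time)
  k0 <- sample.int(length(ats$trees), 1L, prob = spans * lam)
  tr0 <- ats$trees[[k0]]
  sel <- which(tr0$parent != 0L)
  blen <- ats$time[tr0$parent[sel]] - ats$time[tr0$ids[sel]]
  bi <- sel[sample.int(length(sel), 1L, prob = blen)]
  c_id <- tr0$ids[bi]
  j0 <- tr0$parent[bi]
  has_edge <- function(k) {
    ci <- match(c_id, ats$trees[[k]]$ids)
    !is.na(ci) && ats$trees[[k]]$parent[ci] == j0
  }
  kL <- k0; while (kL > 1L && has_edge(kL - 1L)) kL <- kL - 1L
  kR <- k0; while (kR < length(ats$trees) && has_edge(kR + 1L)) kR <- kR + 1L
  structure(list(position = ats$breaks[k0], child = c_id,
                 parent = tr0$parent[bi],
                 cut_time = stats::runif(1, ats$time[c_id],
                                         ats$time[tr0$parent[bi]]),
                 extension = c(ats$breaks[kL],
                               if (kR < length(ats$trees))
                                 ats$breaks[kR + 1L] else ats$L)),
            class = "sgpr_cut")
}

#' One SGPR Metropolis-Hastings step on an ARG
#'
#' Performs a single cut / prune / re-graft proposal with the exact MH
#' correction, given the data the ARG explains.  On rejection the input
#' tables are returned unchanged.
#'
#' @param arg An `arg_tables` object (bin-aligned; see [snap_to_bins()]).
#' @param haplotypes n x S 0/1 matrix.
#' @param positions 0-based site positions.
#' @param params A [model_params()] object.
#' @param seed Optional seed.
#' @param always_accept Skip the MH correction (near-Gibbs variant).
#' @return A list: `arg` (possibly updated tables), `accepted`.
#' @export
mh_step <- function(arg, haplotypes, positions, params, seed = NULL,
                    always_accept = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  st <- .st_from_arg(arg, haplotypes, positions, params)
  r <- .sgpr_step(st, always_accept = always_accept)
  list(arg = if (r$accepted) .ats_to_tables(.st_as_ats(st)) else arg,
       accepted = r$accepted)
}

## chain state from existing tables + data
.st_from_arg <- function(arg, H, positions, params) {
  st <- .st_build(H, positions, arg$sequence_length, params)
  snapped <- snap_to_bins(arg, st$bins)
  ats <- .ats_from_tables(snapped)
  st$trees <- ats$trees
  st$breaks <- ats$breaks
  st$time <- ats$time
  st$time[is.na(st$time)] <- 0
  st$next_id <- as.integer(max(snapped$nodes$id) + 1L)
  .st_refresh_cache(st)
  .st_remap_sites(st, seq_along(st$pos))
  st
}

#' Prune the branch segment above a cut
#'
#' Removes, over the cut's extension interval, the attachment of the cut
#' branch's child: the attachment node disappears and its other child is
#' re-attached to the grandparent.  The result is returned together with a
#' record of the detached lineage, sufficient to re-attach it at the
#' identical place.
#'
#' @param arg An `arg_tables` object.
#' @param cut An `sgpr_cut` from [sample_cut()].
#' @return A list: `arg` (tables of the remaining structure within the
#'   interval; the detached subtree keeps its internal edges), `detached`
#'   (record with child id, per-tree attachment node/target/time).
#' @export
prune_cut <- function(arg, cut) {
  ats <- .ats_from_tables(arg)
  x0 <- cut$extension[1]; x1 <- cut$extension[2]
  rec <- list()
  for (k in seq_along(ats$trees)) {
    lft <- ats$breaks[k]
    if (lft < x0 || lft >= x1) next
    tr <- ats$trees[[k]]
    ci <- match(cut$child, tr$ids)
    j <- tr$parent[ci]
    sib <- tr$ids[tr$parent == j & tr$ids != cut$child]
    rec[[length(rec) + 1L]] <- list(k = k, attach = j, target = sib,
                                    time = ats$time[j])
    ji <- match(j, tr$ids)
    parent <- tr$parent
    parent[tr$ids == sib] <- parent[ji]
    parent[ci] <- 0L
    ats$trees[[k]] <- list(ids = tr$ids[-ji], parent = parent[-ji])
  }
  list(ats = ats, detached = list(child = cut$child, records = rec),
       cut = cut)
}

#' Re-graft a cut lineage by threading (one SGPR proposal)
#'
#' Runs the full cut / prune / threading-regraft proposal for a given cut,
#' returning the proposed tables together with the forward proposal density
#' (of the sampled re-attachment) and the reverse density (of re-attaching
#' at the old location), as used in the Metropolis-Hastings ratio.
#'
#' @param arg An `arg_tables` object (bin-aligned).
#' @param haplotypes,positions,params Data and model as in [mh_step()].
#' @param cut Optional `sgpr_cut` (default: sampled internally).
#' @param seed Optional seed.
#' @return A list: `arg`, `accepted`, `logq_fwd`, `logq_rev`, `logalpha`.
#' @export
regraft <- function(arg, haplotypes, positions, params, cut = NULL,
                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- .st_from_arg(arg, haplotypes, positions, params)
  forced <- NULL
  if (!is.null(cut)) {
    k0 <- findInterval(cut$position, st$breaks)
    forced <- list(k0 = k0, c_id = cut$child, h = cut$cut_time)
  }
  r <- .sgpr_step(st, forced = forced)
  out <- list(arg = if (r$accepted) .ats_to_tables(.st_as_ats(st)) else arg,
              accepted = r$accepted)
  c(out, r[setdiff(names(r), "accepted")])
}

#' Re-attach a pruned lineage at its recorded location
#'
#' Inverse of [prune_cut()]: splices the detached lineage back onto its
#' original attachment points, reproducing the input tables exactly.
#'
#' @param pruned Output of [prune_cut()].
#' @return An `arg_tables` object.
#' @export
reattach_cut <- function(pruned) {
  ats <- pruned$ats
  for (rec in pruned$detached$records) {
    tr <- ats$trees[[rec$k]]
    ci <- match(pruned$detached$child, tr$ids)
    keep <- tr$ids != pruned$detached$child
    tr2 <- list(ids = tr$ids[keep], parent = tr$parent[keep])
    tre <- .spr_insert(tr2, pruned$detached$child, rec$target, rec$attach)
    ats$trees[[rec$k]] <- tre
  }
  .ats_to_tables(ats)
}
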