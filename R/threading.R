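#' Threading state space for a marginal tree
#'
#' The candidate joining branches for one bin: every branch of the
#' marginal tree plus the semi-infinite lineage above the root (which
#' absorbs all re-coalescence mass beyond the root).  Each state carries
#' its joining interval, its branch-specific recombination probability
#' `r_i = 1 - exp(-r * bin_size * length_i)` (the root state uses `2*Ne`
#' as its effective length), and its re-joining weight `q_j`, the exact
#' probability that a lineage floating from `base` re-coalesces onto that
#' branch under the constant-Ne coalescent (the `q_j` sum to 1).
#'
#' @param mt A `marginal_tree` (see [marginal_tree()]).
#' @param params A [model_params()] object.
#' @param bin_size Bin size in base pairs (default from [make_bins()]).
#' @param base Lower bound for the joining time (0 for a new haplotype).
#' @return A list of class `threading_state`: `branches` (child node per
#'   state; the last state is the above-root lineage), `lo`, `hi`, `q`,
#'   `r`.
#' @export
threading_state <- function(mt, params, bin_size = NULL, base = 0) {
  if (is.null(bin_size))
    bin_size <- max(1, round(4e-3 / (4 * params$Ne * params$r)))
  tr <- .mt_to_tree(mt)
  time <- rep(NA_real_, max(tr$ids))
  time[mt$branches$child] <- mt$branches$child_time
  time[mt$branches$parent] <- mt$branches$parent_time
  rw <- .rejoin_weights(tr, time, base, params$Ne)
  len <- ifelse(is.finite(rw$hi), pmax(rw$hi - rw$lo, 0), 2 * params$Ne)
  ri <- pmin(pmax(1 - exp(-params$r * bin_size * len), 0), 1 - 1e-12)
  structure(list(branches = tr$ids, lo = rw$lo, hi = rw$hi,
                 q = rw$q / sum(rw$q), r = ri, base = base,
                 bin_size = bin_size),
            class = "threading_state")
}

#' Branch-specific recombination probability
#'
#' `r_i = 1 - exp(-r * bin_size * len)`, the probability that the new
#' lineage recombines off a candidate joining segment of time-length `len`
#' (generations) within one bin.
#'
#' @param len Time-length of the candidate joining segment, generations.
#' @param bin_size Bin size in base pairs.
#' @param params A [model_params()] object.
#' @return Probability in `[0, 1)`; increasing in both `len` and
#'   `bin_size`.
#' @export
branch_recomb_prob <- function(len, bin_size, params) {
  pmin(pmax(1 - exp(-params$r * bin_size * len), 0), 1 - 1e-12)
}

#' One row of the branch-sampling transition kernel
#'
#' `P(B_l = b_j | B_(l-1) = b_i) = (1 - r_i) * delta_ij + r_i * q_j / sum(q)`.
#' When `recomb_allowed = FALSE` (a recombination already exists at this
#' bin boundary) the transition is the deterministic carry-over map
#' instead: the lineage keeps its branch, or moves to `map[i]` when the
#' branch does not survive into the next tree.
#'
#' @param state A `threading_state` for the next bin.
#' @param from State index of the current branch.
#' @param recomb_allowed Logical; FALSE at boundaries that already carry a
#'   recombination event.
#' @param map Integer vector (carry-over map) used when
#'   `recomb_allowed = FALSE`; defaults to the identity.
#' @return A probability vector over the states, summing to 1.
#' @export
transition_row <- function(state, from, recomb_allowed = TRUE, map = NULL) {
  K <- length(state$q)
  if (!recomb_allowed) {
    j <- if (is.null(map)) from else map[from]
    out <- numeric(K); out[j] <- 1
    return(out)
  }
  out <- state$r[from] * state$q
  out[from] <- out[from] + (1 - state$r[from])
  out
}

#' Re-joining weights of a threading state
#'
#' @param state A `threading_state`.
#' @return The normalized `q_j` vector (sums to 1, root state included).
#' @export
rejoin_weight <- function(state) state$q

#' Per-state emission log-likelihood for one polymorphic site
#'
#' For each candidate joining branch, the new lineage's allele either
#' matches the allele implied by joining below that branch (no extra
#' mutation on the new branch: log-probability `-mu * tau`) or requires
#' one extra mutation (`log(1 - exp(-mu * tau))`), where `tau` is the
#' expected new-branch length: the joining-interval midpoint minus the
#' clock origin during branch sampling, or the exact joining time during
#' time sampling.
#'
#' @param state A `threading_state`.
#' @param implied Logical vector: allele implied by each state (derived =
#'   TRUE).
#' @param allele Observed allele of the lineage being threaded (0/1).
#' @param params A [model_params()] object.
#' @param tau Optional explicit new-branch lengths (otherwise interval
#'   midpoints are used).
#' @return Numeric vector of per-state log-likelihood contributions.
#' @export
emission_loglik <- function(state, implied, allele, params, tau = NULL) {
  if (is.null(tau)) {
    hi_cap <- ifelse(is.finite(state$hi), state$hi,
                     state$lo + 4 * params$Ne)
    tau <- pmax((state$lo + hi_cap) / 2 - state$base, 1e-9)
  }
  ifelse(implied == as.logical(allele), -params$mu * tau,
         log1p(-exp(-params$mu * tau)))
}

#' Sample a joining-branch path for a new haplotype
#'
#' Runs the branch-sampling HMM (Li-Stephens structure over the candidate
#' branches of each bin's marginal tree, with the one-recombination-per-
#' boundary constraint at pre-existing breakpoints) and draws a path from
#' its exact posterior by stochastic traceback.
#'
#' @param arg Partial ARG (`arg_tables`, bin-aligned) on the already
#'   threaded haplotypes.
#' @param hap 0/1 vector for the new haplotype at `positions`.
#' @param haplotypes Matrix of the already threaded haplotypes (rows in
#'   sample-id order).
#' @param positions 0-based site positions.
#' @param params A [model_params()] object.
#' @param seed Optional seed.
#' @return A list: `children` (joining branch per bin, identified by its
#'   child node; the tree root denotes the above-root lineage), `logq`
#'   (log proposal density of the path), `bins`.
#' @export
sample_branch_path <- function(arg, hap, haplotypes, positions, params,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- .thread_setup(arg, hap, haplotypes, positions, params)
  bY <- .branch_hmm(th$st, th$ctx, 0L)
  list(children = bY$children, logq = bY$logq, bins = th$st$bins)
}

#' Sample joining times given a branch path
#'
#' The conditional time-sampling HMM: per bin the state is a discretized
#' joining time on the current branch (40 log-spaced cells with exact
#' truncated-coalescent cell masses), with within-branch time
#' recombination at free boundaries and deterministic time continuity at
#' constrained ones.
#'
#' @inheritParams sample_branch_path
#' @param children Joining branch per bin, as returned by
#'   [sample_branch_path()].
#' @return A list: `times` (joining time per bin), `logq`.
#' @export
sample_times <- function(arg, children, hap, haplotypes, positions, params,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- .thread_setup(arg, hap, haplotypes, positions, params)
  tY <- .time_hmm(th$st, th$ctx, children, 0, 0, 0L)
  if (!is.finite(tY$logq)) return(list(times = NULL, logq = -Inf))
  cells <- tY$res$path
  times <- vapply(seq_along(cells), function(l)
    tY$grids[[tY$seg_of_bin[l]]]$atoms[cells[l]], numeric(1))
  list(times = times, logq = tY$logq, thmm = tY)
}

#' Thread one haplotype onto a partial ARG
#'
#' Composes branch sampling and time sampling, then splices the new
#' lineage into the tables and maps the new haplotype's private derived
#' alleles onto the new branch.  The output has one more leaf and passes
#' all ARG invariants, including at most one recombination per bin
#' boundary.
#'
#' @inheritParams sample_branch_path
#' @return A list: `arg` (tables on n+1 leaves), `logq` (total log
#'   proposal density of the threading path).
#' @export
thread_haplotype <- function(arg, hap, haplotypes, positions, params,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- .thread_setup(arg, hap, haplotypes, positions, params)
  st <- th$st
  new_leaf <- th$new_leaf
  for (attempt in 1:8) {
    bY <- .branch_hmm(st, th$ctx, 0L)
    if (!is.finite(bY$logq)) next
    tY <- .time_hmm(st, th$ctx, bY$children, 0, 0, 0L)
    if (!is.finite(tY$logq)) next
    pieces <- .path_to_pieces(st, th$ctx, bY$children, tY, 0, new_leaf,
                              0, st$L)
    if (is.null(pieces)) next
    .st_replace(st, 1L, length(st$trees), 0, st$L, pieces)
    .st_remap_sites(st, seq_along(st$pos))
    return(list(arg = .ats_to_tables(.st_as_ats(st)),
                logq = bY$logq + tY$logq))
  }
  stop("threading failed repeatedly (unspliceable paths)")
}

## Shared setup: state with n-1 threaded leaves + the new haplotype as the
## last row; runs decorated for threading (base 0, clock origin 0).
.thread_setup <- function(arg, hap, haplotypes, positions, params) {
  n_old <- length(arg$sample_ids)
  H <- rbind(haplotypes, matrix(hap, nrow = 1))
  new_leaf <- n_old + 1L
  st <- .st_build(H, positions, arg$sequence_length, params)
  snapped <- snap_to_bins(arg, st$bins)
  ats <- .ats_from_tables(snapped)
  ## make room for the new leaf id: shift all internal node ids up by one
  shift <- function(v) ifelse(v > n_old, v + 1L, v)
  ats$trees <- lapply(ats$trees, function(tr)
    list(ids = as.integer(shift(tr$ids)),
         parent = as.integer(shift(tr$parent))))
  old_time <- ats$time
  ats$time <- c(old_time[seq_len(n_old)], 0,
                old_time[-seq_len(n_old)])
  ats$mut_node <- as.integer(shift(ats$mut_node))
  st$trees <- ats$trees
  st$breaks <- ats$breaks
  tmax <- max(length(ats$time), 2L * new_leaf)
  st$time <- c(ats$time, numeric(tmax - length(ats$time)))
  st$time[is.na(st$time)] <- 0
  st$next_id <- as.integer(max(snapped$nodes$id) + 2L)
  .st_refresh_cache(st)
  .st_remap_sites(st, seq_along(st$pos), leaves = seq_len(n_old))
  runs <- .make_runs(st, 1L, length(st$trees), 0, st$L, NULL)
  runs <- .decorate_runs(st, runs, 0, 0, seq_len(st$n))
  list(st = st, ctx = list(runs = runs), new_leaf = new_leaf)
}
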