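#' Piecewise-constant population size histories
#'
#' `constant_history()` is the default single-epoch history; the
#' stylized `ceu_like_history()` has an ancestral epoch, a bottleneck and a
#' recent expansion, and is used for robustness experiments in which the
#' inference model's constant-Ne assumption is deliberately violated.  The
#' epoch values are a stylized stand-in chosen to reproduce the qualitative
#' features (bi-modal pairwise coalescence times) of a human CEU-like
#' history, not a fit to any published demography.
#'
#' @param Ne Diploid effective size for the constant history.
#' @return An object of class `ne_history`: a list with `breaks` (epoch
#'   start times, generations, first is 0), `sizes` (diploid Ne per epoch)
#'   and `at(t)`, a vectorized evaluator.
#' @export
constant_history <- function(Ne) {
  h <- list(breaks = 0, sizes = Ne)
  h$at <- function(t) rep(Ne, length(t))
  class(h) <- "ne_history"
  h
}

#' @rdname constant_history
#' @export
ceu_like_history <- function() {
  breaks <- c(0, 1000, 3000)       # generations
  sizes <- c(3e4, 2e3, 1e4)        # expansion, bottleneck, ancestral
  h <- list(breaks = breaks, sizes = sizes)
  h$at <- function(t) sizes[findInterval(t, breaks)]
  class(h) <- "ne_history"
  h
}

## Sample an event time with piecewise-constant hazard, starting at `base`.
## `fun_k(t)` gives the lineage-count factor (piecewise constant, knots in
## `knots`); hazard(t) = fun_k(t) / (2 * Ne(t)).  Returns the event time.
.sample_coal_time <- function(base, knots, kvals, history) {
  cuts <- sort(unique(c(base, knots[knots > base], history$breaks[history$breaks > base])))
  E <- stats::rexp(1)
  acc <- 0
  for (i in seq_along(cuts)) {
    t0 <- cuts[i]
    t1 <- if (i < length(cuts)) cuts[i + 1] else Inf
    k <- kvals[max(1L, findInterval(t0, knots))]
    haz <- k / (2 * history$at(t0))
    if (haz <= 0) { acc <- acc; next }
    seg <- (t1 - t0) * haz
    if (acc + seg >= E || !is.finite(t1)) {
      return(t0 + (E - acc) / haz)
    }
    acc <- acc + seg
  }
  stop("failed to sample coalescence time")   # unreachable: last hazard > 0
}

## First marginal tree: standard (time-rescaled) coalescent on n leaves.
.sim_first_tree <- function(n, history, next_id) {
  active <- seq_len(n)
  time <- rep(0, 2L * n - 1L)
  ids <- seq_len(n)
  parent <- rep(0L, 2L * n - 1L)
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- .sample_coal_time(t, t, choose(k, 2), history)
    pair <- sample(active, 2L)
    nid <- next_id
    next_id <- next_id + 1L
    ids <- c(ids, nid)
    time[nid] <- t
    parent[match(pair, ids)] <- nid
    active <- c(setdiff(active, pair), nid)
  }
  list(tree = list(ids = as.integer(ids), parent = as.integer(parent[seq_along(ids)])),
       time = time, next_id = next_id)
}

#' Simulate a ground-truth ARG under the SMC
#'
#' A minimal sequentially-Markov-coalescent simulator: the first marginal
#' tree is drawn from the (time-rescaled) standard coalescent; moving along
#' the genome, recombination breakpoints arise as a Poisson process with
#' rate `r` times the current total branch length, and at each breakpoint a
#' uniformly chosen point on the tree is detached and re-coalesced with the
#' remaining lineages.  Adjacent marginal trees therefore differ by exactly
#' one subtree-prune-regraft event.
#'
#' @param n Number of haplotypes (leaves), `n >= 2`.
#' @param L Sequence length in base pairs.
#' @param params A [model_params()] object (`Ne` is ignored when `history`
#'   is supplied).
#' @param seed Optional integer seed (sets the R RNG).
#' @param history Optional `ne_history`; defaults to a constant history at
#'   `params$Ne`.
#' @return An `arg_tables` object (no mutations; see [drop_mutations()]).
#' @export
sim_arg <- function(n, L, params, seed = NULL, history = NULL) {
  stopifnot(n >= 2, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(history)) history <- constant_history(params$Ne)
  ft <- .sim_first_tree(n, history, n + 1L)
  time <- c(ft$time, numeric(0))
  trees <- list(ft$tree)
  breaks <- 0
  next_id <- ft$next_id
  x <- 0
  grow <- function(v, upto) { length(v) <- max(length(v), upto); v }
  repeat {
    tr <- trees[[length(trees)]]
    sel <- tr$parent != 0L
    blen <- time[tr$parent[sel]] - time[tr$ids[sel]]
    lambda <- sum(blen)
    x <- x + stats::rexp(1, rate = params$r * lambda)
    if (x >= L) break
    ## detach point: branch prop. to length, height uniform on branch
    bi <- sample(which(sel), 1L, prob = blen / lambda)
    c_id <- tr$ids[bi]
    w <- stats::runif(1, time[c_id], time[tr$parent[bi]])
    rem <- .spr_remaining(tr, c_id)
    ## re-coalescence time: hazard k(t)/(2Ne(t)) with k from remaining tree
    itimes <- sort(time[setdiff(rem$ids, .tree_leaf_ids(rem))])
    m <- length(.tree_leaf_ids(rem))
    knots <- c(0, itimes)
    kvals <- c(m, m - seq_along(itimes))
    tnew <- .sample_coal_time(w, knots, kvals, history)
    targ <- .branches_crossing(rem, time, tnew)
    target <- if (length(targ)) targ[sample.int(length(targ), 1L)] else .tree_root(rem)
    nid <- next_id; next_id <- next_id + 1L
    time <- grow(time, nid)
    time[nid] <- tnew
    trees[[length(trees) + 1L]] <- .spr_move(tr, c_id, target, nid)
    breaks <- c(breaks, x)
  }
  ats <- .ats_new(n, L, breaks, trees, time)
  .ats_to_tables(ats)
}

.tree_leaf_ids <- function(tr) tr$ids[!(tr$ids %in% tr$parent)]

## node ids whose branch (to parent) crosses time t, plus the root lineage
## if t is above the root
.branches_crossing <- function(tr, time, t) {
  sel <- tr$parent != 0L
  ch <- tr$ids[sel]
  ch[time[ch] <= t & t < time[tr$parent[sel]]]
}

## All nodes in the subtree rooted at `id` (inclusive).
.tree_desc <- function(tr, id) {
  below <- id
  repeat {
    kids <- tr$ids[tr$parent %in% below & !(tr$ids %in% below)]
    if (!length(kids)) break
    below <- c(below, kids)
  }
  below
}

## The tree that remains when the subtree rooted at `c_id` is detached:
## the subtree and c's parent j disappear, c's sibling re-attaches to
## j's parent (0 if j was the root).
.spr_remaining <- function(tr, c_id) {
  ci <- match(c_id, tr$ids)
  j <- tr$parent[ci]
  ji <- match(j, tr$ids)
  sib_i <- which(tr$parent == j & tr$ids != c_id)
  parent <- tr$parent
  parent[sib_i] <- parent[ji]
  drop <- c(match(.tree_desc(tr, c_id), tr$ids), ji)
  list(ids = tr$ids[-drop], parent = parent[-drop])
}

## SPR: move the subtree rooted at `c_id` so that it joins `target`'s
## branch at new node `nid` (time set by caller).  `target` may be the
## remaining tree's root (join above the root).
.spr_move <- function(tr, c_id, target, nid) {
  ci <- match(c_id, tr$ids)
  j <- tr$parent[ci]
  ji <- match(j, tr$ids)
  sib_i <- which(tr$parent == j & tr$ids != c_id)
  ids <- tr$ids; parent <- tr$parent
  parent[sib_i] <- parent[ji]
  tp <- parent[match(target, ids)]
  parent[match(target, ids)] <- nid
  parent[ci] <- nid
  ids <- c(ids[-ji], nid)
  parent <- c(parent[-ji], tp)
  list(ids = as.integer(ids), parent = as.integer(parent))
}

#' Drop infinite-sites mutations on an ARG
#'
#' Mutations fall on each edge as a Poisson process with intensity
#' `mu` per base pair per generation (edge time-length times genomic span);
#' each mutation creates a new integer site (collisions re-drawn), with the
#' derived allele carried by exactly the leaves below the edge.
#'
#' @param arg An `arg_tables` object.
#' @param mu Mutation rate per base pair per generation.
#' @param seed Optional integer seed.
#' @return A list: `arg` (tables with the mutation table filled in),
#'   `haplotypes` (n x S 0/1 matrix, 0 = ancestral), `positions`
#'   (0-based site positions, sorted).
#' @export
drop_mutations <- function(arg, mu, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- arg$edges
  tmap <- rep(NA_real_, max(arg$nodes$id))
  tmap[arg$nodes$id] <- arg$nodes$time
  n <- length(arg$sample_ids)
  area <- (tmap[e$parent] - tmap[e$child]) * (e$right - e$left)
  counts <- stats::rpois(nrow(e), mu * area)
  pos <- integer(0); node <- integer(0)
  for (i in which(counts > 0)) {
    for (m in seq_len(counts[i])) {
      repeat {
        p <- floor(stats::runif(1, e$left[i], e$right[i]))
        if (!(p %in% pos)) break
      }
      pos <- c(pos, p); node <- c(node, e$child[i])
    }
  }
  o <- order(pos)
  pos <- pos[o]; node <- node[o]
  muts <- data.frame(position = as.numeric(pos), node = as.integer(node),
                     derived = rep("1", length(pos)))
  out <- arg_tables(arg$nodes, arg$edges, muts, arg$sequence_length,
                    arg$sample_ids)
  ats <- .ats_from_tables(out)
  H <- matrix(0L, n, length(pos))
  for (s in seq_along(pos)) {
    tr <- ats$trees[[.ats_tree_at(ats, pos[s])]]
    H[.tree_leaves_below(tr, node[s], n), s] <- 1L
  }
  rownames(H) <- paste0("hap", seq_len(n))
  list(arg = out, haplotypes = H, positions = as.numeric(pos))
}

#' Write phased haplotypes as a VCF
#'
#' Emits a minimal VCF 4.2 with phased diploid genotypes (haplotype
#' columns paired in order) and the ancestral allele in `INFO/AA`.
#' Positions are written 1-based, as VCF requires.
#'
#' @param haplotypes n x S 0/1 matrix (rows = haplotypes), 0 = ancestral.
#' @param positions 0-based site positions.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @return The path, invisibly.
#' @export
write_vcf <- function(haplotypes, positions, path, chrom = "1") {
  n <- nrow(haplotypes)
  if (n %% 2L != 0L) stop("need an even number of haplotypes for diploid VCF")
  ndip <- n %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##contig=<ID=", chrom, ">")), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("ind", seq_len(ndip))),
                   collapse = "\t"), con)
  for (s in seq_along(positions)) {
    gt <- paste(haplotypes[seq(1, n, by = 2), s],
                haplotypes[seq(2, n, by = 2), s], sep = "|")
    writeLines(paste(c(chrom, format(positions[s] + 1, scientific = FALSE),
                       ".", "A", "T", ".", "PASS", "AA=A", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
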