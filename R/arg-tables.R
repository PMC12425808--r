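#' ARG tables: the core data model
#'
#' An ancestral recombination graph (ARG) is stored tskit-style as three
#' tables: nodes (id, time in generations), edges (child, parent, left,
#' right) with half-open 0-based genomic spans, and mutations (position,
#' node, derived allele), plus the sequence length and the sample
#' (leaf) node ids. Restricting the edge table to any position yields the
#' marginal coalescent tree at that position; adjacent marginal trees
#' differ by a single subtree-prune-regraft event.
#'
#' Coordinates are 0-based half-open `[left, right)` everywhere; node times
#' are in generations, with samples at time 0.
#'
#' @param nodes Data frame with columns `id` (integer) and `time` (numeric).
#' @param edges Data frame with columns `child`, `parent`, `left`, `right`.
#' @param mutations Data frame with columns `position`, `node`, `derived`
#'   (may have zero rows).
#' @param sequence_length Sequence length in base pairs.
#' @param sample_ids Integer vector of leaf node ids (time 0).
#' @return An object of class `arg_tables`.
#' @seealso [validate_arg()], [marginal_tree()], [write_arg_tables()]
#' @export
arg_tables <- function(nodes, edges, mutations = NULL, sequence_length,
                       sample_ids) {
  if (is.null(mutations)) {
    mutations <- data.frame(position = numeric(0), node = integer(0),
                            derived = character(0))
  }
  obj <- structure(
    list(nodes = as.data.frame(nodes), edges = as.data.frame(edges),
         mutations = as.data.frame(mutations),
         sequence_length = as.numeric(sequence_length),
         sample_ids = as.integer(sample_ids)),
    class = "arg_tables"
  )
  obj
}

#' @export
print.arg_tables <- function(x, ...) {
  cat("arg_tables:", length(x$sample_ids), "samples,",
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$mutations), "mutations, L =", x$sequence_length, "bp\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Internal tree-run representation (".ats"): an ordered list of marginal
## trees with their left break positions.  Each tree is a pair of aligned
## integer vectors: `ids` (global node ids) and `parent` (global parent id,
## 0 for the root).  Node times live in one dense numeric vector indexed by
## node id; samples are ids 1..n with time 0.

.ats_new <- function(n, L, breaks, trees, time, mut_pos = numeric(0),
                     mut_node = integer(0)) {
  structure(list(n = as.integer(n), L = as.numeric(L),
                 breaks = as.numeric(breaks), trees = trees,
                 time = as.numeric(time),
                 mut_pos = as.numeric(mut_pos),
                 mut_node = as.integer(mut_node)),
            class = "ats")
}

.tree_root <- function(tr) tr$ids[tr$parent == 0L]

## Index of the tree covering position x (0-based).
.ats_tree_at <- function(ats, x) findInterval(x, ats$breaks)

## Right edge of tree k.
.ats_right <- function(ats, k) {
  if (k < length(ats$breaks)) ats$breaks[k + 1L] else ats$L
}

.ats_spans <- function(ats) diff(c(ats$breaks, ats$L))

## Parent id of node `id` in tree `tr` (NA if absent).
.tree_parent <- function(tr, id) {
  i <- match(id, tr$ids)
  if (is.na(i)) NA_integer_ else tr$parent[i]
}

## MRCA node of samples i, j in tree `tr`.
.tree_mrca <- function(tr, i, j) {
  anc <- integer(0)
  v <- i
  while (!is.na(v) && v != 0L) {
    anc <- c(anc, v)
    v <- .tree_parent(tr, v)
  }
  v <- j
  while (!is.na(v) && v != 0L) {
    if (v %in% anc) return(v)
    v <- .tree_parent(tr, v)
  }
  stop("no common ancestor found; corrupt tree")
}

## Leaves (sample ids) below node `id` in tree `tr` (inclusive if id is leaf).
.tree_leaves_below <- function(tr, id, n) {
  below <- id
  repeat {
    kids <- tr$ids[tr$parent %in% below & !(tr$ids %in% below)]
    if (!length(kids)) break
    below <- c(below, kids)
  }
  sort(below[below <= n])
}

## All-pairs MRCA times among the n samples of tree `tr`; returns n x n
## symmetric matrix (generations), diagonal 0.  O(n^2) by clade merging.
.tree_pair_times <- function(tr, time, n) {
  M <- matrix(0, n, n)
  ids <- tr$ids
  ord <- order(time[ids])             # children strictly before parents
  clade <- vector("list", length(ids))
  pos <- match(seq_along(ids), ord)   # not used; clade keyed by index
  for (k in ord) {
    id <- ids[k]
    if (id <= n) { clade[[k]] <- id; next }
    kidx <- which(tr$parent == id)
    stopifnot(length(kidx) == 2L)
    a <- clade[[kidx[1]]]; b <- clade[[kidx[2]]]
    M[a, b] <- time[id]; M[b, a] <- time[id]
    clade[[k]] <- c(a, b)
  }
  M
}

## ---------------------------------------------------------------------------
## Conversions

## Internal trees -> public tables.  Adjacent identical (child,parent)
## branches are merged into maximal edges.
.ats_to_tables <- function(ats) {
  Tn <- length(ats$trees)
  active <- new.env(parent = emptyenv())   # key "child|parent" -> left
  ec <- ep <- el <- er <- numeric(0)
  rights <- c(ats$breaks[-1], ats$L)
  prev_keys <- character(0)
  for (k in seq_len(Tn)) {
    tr <- ats$trees[[k]]
    sel <- tr$parent != 0L
    keys <- paste0(tr$ids[sel], "|", tr$parent[sel])
    gone <- setdiff(prev_keys, keys)
    for (g in gone) {
      cp <- as.integer(strsplit(g, "|", fixed = TRUE)[[1]])
      ec <- c(ec, cp[1]); ep <- c(ep, cp[2])
      el <- c(el, get(g, envir = active)); er <- c(er, ats$breaks[k])
      rm(list = g, envir = active)
    }
    for (nw in setdiff(keys, prev_keys)) {
      assign(nw, ats$breaks[k], envir = active)
    }
    prev_keys <- keys
  }
  for (g in prev_keys) {
    cp <- as.integer(strsplit(g, "|", fixed = TRUE)[[1]])
    ec <- c(ec, cp[1]); ep <- c(ep, cp[2])
    el <- c(el, get(g, envir = active)); er <- c(er, ats$L)
  }
  used <- sort(unique(c(ec, ep, seq_len(ats$n))))
  nodes <- data.frame(id = as.integer(used), time = ats$time[used])
  o <- order(el, ec)
  edges <- data.frame(child = as.integer(ec[o]), parent = as.integer(ep[o]),
                      left = el[o], right = er[o])
  o2 <- order(ats$mut_pos)
  muts <- data.frame(position = ats$mut_pos[o2],
                     node = ats$mut_node[o2],
                     derived = rep("1", length(o2)))
  arg_tables(nodes, edges, muts, ats$L, seq_len(ats$n))
}

## Public tables -> internal trees.
.ats_from_tables <- function(arg) {
  stopifnot(inherits(arg, "arg_tables"))
  L <- arg$sequence_length
  n <- length(arg$sample_ids)
  if (!identical(sort(arg$sample_ids), seq_len(n)))
    stop("sample ids must be 1..n")
  e <- arg$edges
  brk <- sort(unique(c(0, e$left, e$right)))
  brk <- brk[brk < L]
  trees <- vector("list", length(brk))
  for (k in seq_along(brk)) {
    x <- brk[k]
    sel <- e$left <= x & x < e$right
    child <- e$child[sel]; parent <- e$parent[sel]
    ids <- unique(c(child, parent))
    par <- parent[match(ids, child)]
    par[is.na(par)] <- 0L
    trees[[k]] <- list(ids = as.integer(ids), parent = as.integer(par))
  }
  tmax <- max(arg$nodes$id)
  time <- rep(NA_real_, tmax)
  time[arg$nodes$id] <- arg$nodes$time
  mo <- order(arg$mutations$position)
  .ats_new(n, L, brk, trees, time,
           arg$mutations$position[mo], arg$mutations$node[mo])
}

## ---------------------------------------------------------------------------

#' Validate ARG tables
#'
#' Checks every structural invariant of the ARG encoding: each marginal tree
#' is a rooted binary tree on all samples; parent times strictly exceed
#' child times; edge spans are non-empty and lie within the sequence;
#' each site carries at most one mutation and the mutation's node is present
#' in the local tree; and adjacent marginal trees differ by exactly one
#' subtree-prune-regraft event.
#'
#' @param arg An `arg_tables` object.
#' @return Invisibly `TRUE`; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_arg <- function(arg) {
  stopifnot(inherits(arg, "arg_tables"))
  n <- length(arg$sample_ids)
  L <- arg$sequence_length
  e <- arg$edges
  if (nrow(e) == 0) stop("ARG has no edges")
  if (any(e$right <= e$left)) stop("empty or inverted edge span")
  if (any(e$left < 0) || any(e$right > L)) stop("edge span outside [0, L)")
  tmap <- rep(NA_real_, max(arg$nodes$id))
  tmap[arg$nodes$id] <- arg$nodes$time
  if (any(tmap[arg$sample_ids] != 0)) stop("sample nodes must have time 0")
  if (any(tmap[e$parent] <= tmap[e$child]))
    stop("parent time must strictly exceed child time")
  ats <- .ats_from_tables(arg)
  prev <- NULL
  for (k in seq_along(ats$trees)) {
    tr <- ats$trees[[k]]
    .check_binary_tree(tr, n, sprintf("tree %d (left=%g)", k, ats$breaks[k]))
    if (!is.null(prev)) .check_one_spr(prev, tr, k)
    prev <- tr
  }
  if (anyDuplicated(arg$mutations$position))
    stop("more than one mutation at a site (infinite sites violated)")
  if (nrow(arg$mutations)) {
    for (i in seq_len(nrow(arg$mutations))) {
      tr <- ats$trees[[.ats_tree_at(ats, arg$mutations$position[i])]]
      mi <- match(arg$mutations$node[i], tr$ids)
      if (is.na(mi) || tr$parent[mi] == 0L)
        stop("mutation node absent (or root) in its local tree")
    }
  }
  invisible(TRUE)
}

.check_binary_tree <- function(tr, n, what) {
  if (sum(tr$parent == 0L) != 1L) stop(what, ": not singly rooted")
  leaves <- tr$ids[!(tr$ids %in% tr$parent)]
  if (!setequal(leaves, seq_len(n)))
    stop(what, ": leaf set is not the sample set")
  internal <- setdiff(tr$ids, leaves)
  deg <- table(factor(tr$parent[tr$parent != 0L], levels = internal))
  if (any(deg != 2L)) stop(what, ": non-binary node (degree != 2)")
  if (length(tr$ids) != 2L * n - 1L) stop(what, ": wrong node count")
}

## Adjacent marginal trees must differ by exactly one SPR: at most one node
## lost, at most one node gained, and the set of children with a changed
## parent must be explainable by a single prune-regraft.
.check_one_spr <- function(a, b, k) {
  lost <- setdiff(a$ids, b$ids)
  gained <- setdiff(b$ids, a$ids)
  if (length(lost) > 1L || length(gained) > 1L)
    stop(sprintf("trees %d-%d: more than one SPR event", k - 1L, k))
  common <- intersect(a$ids, b$ids)
  pa <- a$parent[match(common, a$ids)]
  pb <- b$parent[match(common, b$ids)]
  changed <- sum(pa != pb)
  if (length(lost) == 0L && length(gained) == 0L && changed == 0L)
    stop(sprintf("trees %d-%d: identical adjacent trees", k - 1L, k))
  if (changed > 3L)
    stop(sprintf("trees %d-%d: too many re-attached children for one SPR",
                 k - 1L, k))
}

## ---------------------------------------------------------------------------

#' Extract the marginal tree at a genomic position
#'
#' @param arg An `arg_tables` object.
#' @param position 0-based position in `[0, sequence_length)`.
#' @return An object of class `marginal_tree` with fields `position`,
#'   `branches` (data frame: child, parent, child_time, parent_time),
#'   `root`, and `leaves`.
#' @export
marginal_tree <- function(arg, position) {
  if (position < 0 || position >= arg$sequence_length)
    stop("position out of range [0, sequence_length)")
  e <- arg$edges
  sel <- e$left <= position & position < e$right
  child <- e$child[sel]; parent <- e$parent[sel]
  tmap <- rep(NA_real_, max(arg$nodes$id))
  tmap[arg$nodes$id] <- arg$nodes$time
  n <- length(arg$sample_ids)
  br <- data.frame(child = child, parent = parent,
                   child_time = tmap[child], parent_time = tmap[parent])
  root <- setdiff(parent, child)
  if (length(root) != 1L) stop("corrupt ARG: marginal tree not singly rooted")
  tr <- list(ids = c(child, root),
             parent = c(parent, 0L))
  .check_binary_tree(tr, n, sprintf("tree at %g", position))
  structure(list(position = position, branches = br, root = root,
                 leaves = arg$sample_ids,
                 times = stats::setNames(tmap[c(child, root)],
                                         c(child, root))),
            class = "marginal_tree")
}

#' @export
print.marginal_tree <- function(x, ...) {
  cat("marginal_tree at", x$position, "bp:", length(x$leaves), "leaves, root",
      x$root, "at", max(x$branches$parent_time), "generations\n")
  invisible(x)
}

## internal tree from a marginal_tree object
.mt_to_tree <- function(mt) {
  list(ids = c(mt$branches$child, mt$root),
       parent = c(mt$branches$parent, 0L))
}

## ---------------------------------------------------------------------------
## TSV serialization and newick export

#' Write / read ARG tables as TSV files
#'
#' Serializes an ARG to `<prefix>.nodes.tsv`, `<prefix>.edges.tsv` and
#' `<prefix>.mutations.tsv` (tab-separated, with headers), and reads the
#' same triplet back.
#'
#' @param arg An `arg_tables` object.
#' @param prefix Path prefix for the three files.
#' @return `write_arg_tables` returns the three file paths invisibly;
#'   `read_arg_tables` returns an `arg_tables` object.
#' @export
write_arg_tables <- function(arg, prefix) {
  paths <- paste0(prefix, c(".nodes.tsv", ".edges.tsv", ".mutations.tsv"))
  nd <- arg$nodes
  nd$sequence_length <- c(arg$sequence_length,
                          rep(NA, nrow(nd) - 1L))
  nd$is_sample <- as.integer(nd$id %in% arg$sample_ids)
  utils::write.table(nd, paths[1], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(arg$edges, paths[2], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(arg$mutations, paths[3], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' @rdname write_arg_tables
#' @export
read_arg_tables <- function(prefix) {
  paths <- paste0(prefix, c(".nodes.tsv", ".edges.tsv", ".mutations.tsv"))
  nd <- utils::read.table(paths[1], header = TRUE, sep = "\t")
  ed <- utils::read.table(paths[2], header = TRUE, sep = "\t")
  mu <- utils::read.table(paths[3], header = TRUE, sep = "\t",
                          colClasses = c(derived = "character"))
  L <- nd$sequence_length[1]
  samples <- sort(nd$id[nd$is_sample == 1L])
  arg_tables(nd[c("id", "time")], ed, mu, L, samples)
}

#' Newick string for the marginal tree at a position
#'
#' Builds an `ape::phylo` object for the marginal tree and returns its
#' newick serialization (branch lengths in generations, tips labelled by
#' sample node id).
#'
#' @inheritParams marginal_tree
#' @return A newick string.
#' @export
marginal_newick <- function(arg, position) {
  mt <- marginal_tree(arg, position)
  n <- length(mt$leaves)
  ids <- c(mt$branches$child, mt$root)
  tips <- sort(ids[ids %in% mt$leaves])
  internals <- c(mt$root, setdiff(ids[!(ids %in% mt$leaves)], mt$root))
  ix <- function(id) {
    ifelse(id %in% tips, match(id, tips), n + match(id, internals))
  }
  edge <- cbind(ix(mt$branches$parent), ix(mt$branches$child))
  storage.mode(edge) <- "integer"
  elen <- mt$branches$parent_time - mt$branches$child_time
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = as.character(tips),
                        Nnode = length(internals)),
                   class = "phylo")
  ape::write.tree(phy)
}
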