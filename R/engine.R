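## ---------------------------------------------------------------------------
## Sampler engine: chain state, threading plans, HMM orchestration, splicing
## and the SMC-posterior density.  All genomic coordinates are bin-aligned
## inside the sampler (see make_bins / snap_to_bins).
## ---------------------------------------------------------------------------

## Mutable chain state.  `trees`/`breaks` hold the current ARG, `time` the
## node times (dense by node id, holes allowed), `mut_node` the current
## single-branch placement of each data site (NA = no carriers among the
## threaded leaves, root id = carried by all of them).
.st_build <- function(H, positions, L, params, bins = NULL) {
  st <- new.env(parent = emptyenv())
  st$H <- H
  st$pos <- as.numeric(positions)
  st$L <- as.numeric(L)
  st$params <- params
  st$n <- nrow(H)
  if (is.null(bins)) bins <- make_bins(L, params, positions)
  st$bins <- bins
  st$bs <- bins$bin_size
  st$trees <- list()
  st$breaks <- numeric(0)
  st$time <- numeric(2L * st$n + 16L)
  st$next_id <- st$n + 1L
  st$lambda <- numeric(0)
  st$A <- 0
  st$mut_node <- rep(NA_integer_, length(positions))
  st$block_bins <- 256L
  st
}

.st_spans <- function(st) diff(c(st$breaks, st$L))

.st_fresh_id <- function(st) {
  id <- st$next_id
  st$next_id <- id + 1L
  if (id > length(st$time)) length(st$time) <- 2L * id
  id
}

.st_refresh_cache <- function(st) {
  st$lambda <- vapply(st$trees, .tree_lambda, numeric(1), time = st$time)
  st$A <- sum(.st_spans(st) * st$lambda)
}

## canonical tree equality (id sets and parent assignments)
.tree_equal <- function(a, b) {
  if (length(a$ids) != length(b$ids)) return(FALSE)
  m <- match(a$ids, b$ids)
  !anyNA(m) && all(b$parent[m] == a$parent)
}

## Re-fit the single-branch placement of data sites given the current trees.
## `sites` indexes st$pos; `leaves` are the currently threaded sample ids.
.st_remap_sites <- function(st, sites, leaves = seq_len(st$n)) {
  for (s in sites) {
    y <- st$H[leaves, s]
    k <- findInterval(st$pos[s], st$breaks)
    tr <- st$trees[[k]]
    if (all(y == 0L)) { st$mut_node[s] <- NA_integer_; next }
    if (all(y == 1L)) { st$mut_node[s] <- .tree_root(tr); next }
    yy <- integer(st$n)
    yy[leaves[y == 1L]] <- 1L
    ## prefer the exact clade when one matches
    cl <- .tree_clades(tr, st$time, st$n)
    want <- as.logical(yy)
    hit <- 0L
    for (ii in seq_along(tr$ids)) {
      if (tr$parent[ii] != 0L &&
          identical(unname(cl[leaves, ii]), unname(want[leaves]))) {
        hit <- tr$ids[ii]; break
      }
    }
    st$mut_node[s] <- if (hit > 0L) hit else
      .best_mut_node(tr, st$time, yy, st$n, st$params$mu)
  }
  invisible(st)
}

## ---------------------------------------------------------------------------
## Interval construction

## Group original trees kfrom..kto into runs of identical remaining trees
## after detaching the subtree below `c_id` (c_id NULL = init threading:
## nothing detached).  Spans are clipped to [x0, x1).
.make_runs <- function(st, kfrom, kto, x0, x1, c_id = NULL) {
  runs <- list()
  cur <- NULL
  for (k in kfrom:kto) {
    tr <- st$trees[[k]]
    if (is.null(c_id)) {
      rem <- tr; jid <- NA_integer_; sib <- NA_integer_
    } else {
      ci <- match(c_id, tr$ids)
      jid <- tr$parent[ci]
      sib <- tr$ids[tr$parent == jid & tr$ids != c_id]
      rem <- .spr_remaining(tr, c_id)
    }
    lft <- max(st$breaks[k], x0)
    rgt <- min(.ats_right_st(st, k), x1)
    if (!is.null(cur) && .tree_equal(cur$rem, rem) &&
        identical(cur$jid, jid)) {
      cur$right <- rgt
      cur$ktrees <- c(cur$ktrees, k)
      runs[[length(runs)]] <- cur
    } else if (!is.null(cur) && .tree_equal(cur$rem, rem)) {
      ## same remaining structure but the detached lineage re-attached
      ## elsewhere: the boundary is free once pruned -> same run, but the
      ## old attachment differs; keep per-tree attachment info
      cur$right <- rgt
      cur$ktrees <- c(cur$ktrees, k)
      cur$att_extra <- c(cur$att_extra,
                         list(list(k = k, jid = jid, sib = sib)))
      runs[[length(runs)]] <- cur
    } else {
      cur <- list(rem = rem, jid = jid, sib = sib, left = lft, right = rgt,
                  ktrees = k, att_extra = list())
      runs[[length(runs) + 1L]] <- cur
    }
  }
  runs
}

.ats_right_st <- function(st, k) {
  if (k < length(st$breaks)) st$breaks[k + 1L] else st$L
}

## Decorate runs with HMM state data.  `base` is the lower attachment bound
## (cut height; 0 for init threading), `clock0` the mutation-clock origin
## (time of the detached subtree's root), `leaves_all` the sample ids that
## should be accounted for (threaded leaves plus the one being threaded);
## the detached leaf set D of each run is leaves_all minus the remaining
## tree's leaves.
.decorate_runs <- function(st, runs, base, clock0, leaves_all) {
  p <- st$params
  for (i in seq_along(runs)) {
    ru <- runs[[i]]
    rem <- ru$rem
    D <- setdiff(leaves_all, rem$ids[rem$ids %in% leaves_all])
    rw <- .rejoin_weights(rem, st$time, base, p$Ne)
    K <- length(rem$ids)
    qs <- rw$q
    qs <- if (sum(qs) > 0) qs / sum(qs) else rep(1 / K, K)
    len <- ifelse(is.finite(rw$hi), pmax(rw$hi - rw$lo, 0), 2 * p$Ne)
    ri <- 1 - exp(-p$r * st$bs * len)
    ri <- pmin(pmax(ri, 0), 1 - 1e-12)
    hi_cap <- ifelse(is.finite(rw$hi), rw$hi, rw$lo + 4 * p$Ne)
    mid <- (rw$lo + hi_cap) / 2
    ## a join above the remaining root also extends the root lineage up to
    ## the joining time, doubling the exposed branch length there
    taubar <- pmax(mid - clock0, 1e-9) +
      ifelse(rem$parent == 0L, pmax(mid - st$time[.tree_root(rem)], 0), 0)
    ru$states <- rem$ids
    ru$lo <- rw$lo; ru$hi <- rw$hi
    ru$q <- qs; ru$r <- ri; ru$ch <- rw$ch
    ru$taubar <- taubar
    ru$nb <- as.integer(ceiling((ru$right - ru$left) / st$bs))
    ## sites within the run
    sid <- which(st$pos >= ru$left & st$pos < ru$right)
    ru$sites_idx <- sid
    ru$site_bin <- as.integer(floor((st$pos[sid] - ru$left) / st$bs)) + 1L
    ru$ahat <- vapply(sid, function(s) all(st$H[D, s] == 1L), logical(1))
    ru$implied <- lapply(sid, function(s) {
      mn <- st$mut_node[s]
      if (is.na(mn)) return(rep(FALSE, K))
      if (!is.na(ru$jid) && mn == ru$jid) mn <- ru$sib
      if (length(ru$att_extra)) {
        for (ax in ru$att_extra) if (mn == ax$jid) mn <- ax$sib
      }
      if (is.na(match(mn, rem$ids))) return(rep(FALSE, K))
      rem$ids %in% .tree_desc(rem, mn)
    })
    runs[[i]] <- ru
  }
  runs
}

## Deterministic carry-over of a state (child node id) across a
## pre-existing recombination.  A surviving child keeps its state.  A
## removed node was the old parent of the moved lineage: its state maps
## down to the stayed child, whose lineage (with the extended time grid)
## covers the removed branch's time span, so a carried attachment keeps
## its joining time.
.map_child <- function(v, rem_from, rem_to) {
  repeat {
    if (!is.na(match(v, rem_to$ids))) return(v)
    kids <- rem_from$ids[rem_from$parent == v]
    kids <- kids[kids %in% rem_to$ids]
    if (length(kids)) {
      pv <- rem_from$parent[match(v, rem_from$ids)]
      stay <- kids[vapply(kids, function(k)
        rem_to$parent[match(k, rem_to$ids)] == pv, logical(1))]
      return(if (length(stay)) min(stay) else min(kids))
    }
    pi <- match(v, rem_from$ids)
    if (is.na(pi) || rem_from$parent[pi] == 0L) return(.tree_root(rem_to))
    v <- rem_from$parent[pi]
  }
}

## state-index map between consecutive runs
.run_map <- function(ru_from, ru_to) {
  vapply(seq_along(ru_from$states), function(i)
    match(.map_child(ru_from$states[i], ru_from$rem, ru_to$rem),
          ru_to$states), integer(1))
}

## The single SPR between two adjacent remaining trees, when its moved
## lineage is unambiguous: returns list(m = moved child id, tg = new
## coalescence time), else NULL.  Used to forbid carrying an attachment
## across a boundary on the moved lineage's dissolved branch segment
## (time above the new coalescence), which would require a second
## recombination at the same boundary.
.rem_spr <- function(a, b, time) {
  lost <- setdiff(a$ids, b$ids)
  gained <- setdiff(b$ids, a$ids)
  if (length(lost) != 1L || length(gained) != 1L) return(NULL)
  cand <- intersect(a$ids[a$parent == lost], b$ids[b$parent == gained])
  if (length(cand) != 1L) return(NULL)
  list(m = cand, tg = time[gained])
}

## TRUE when carrying an attachment at time t with current target child
## x across the boundary a -> b keeps the combined change a single SPR
.carry_clean <- function(x, t, sprd) {
  is.null(sprd) || x != sprd$m || t <= sprd$tg
}

## ---------------------------------------------------------------------------
## Branch HMM

## ctx: list(runs, edgeL, edgeR) where edgeL/edgeR describe continuity
## conditioning at block-split edges: NULL or list(state = child id,
## time = attachment time, jid = attachment node id).
.branch_hmm <- function(st, ctx, mode, old_children = NULL) {
  runs <- ctx$runs
  p <- st$params
  nb_tot <- sum(vapply(runs, `[[`, integer(1), "nb"))
  seg_of_bin <- integer(nb_tot)
  emit_of_bin <- integer(nb_tot)
  emits <- list()
  seg_a <- seg_r <- seg_w <- vector("list", length(runs))
  btype <- integer(length(runs))
  bmap <- vector("list", length(runs))
  off <- 0L
  for (i in seq_along(runs)) {
    ru <- runs[[i]]
    K <- length(ru$states)
    seg_of_bin[off + seq_len(ru$nb)] <- i
    seg_a[[i]] <- 1 - ru$r
    seg_r[[i]] <- ru$r
    seg_w[[i]] <- ru$q
    btype[i] <- if (i == 1L) 0L else 1L
    if (i > 1L) bmap[[i]] <- .run_map(runs[[i - 1L]], ru)
    ## per-bin emissions: every bin carries the no-mutation factor for the
    ## new branch over its monomorphic positions; polymorphic sites add
    ## their match / extra-mutation terms
    base_v <- -p$mu * ru$taubar * st$bs
    emits[[length(emits) + 1L]] <- base_v
    emit_of_bin[off + seq_len(ru$nb)] <- length(emits)
    if (length(ru$sites_idx)) {
      for (b in unique(ru$site_bin)) {
        v <- base_v
        for (si in which(ru$site_bin == b)) {
          ## a matched site is covered by the no-mutation base factor; a
          ## mismatch swaps it for the extra-mutation probability
          extra <- log1p(-exp(-p$mu * ru$taubar)) + p$mu * ru$taubar
          v <- v + ifelse(ru$implied[[si]] == ru$ahat[si], 0, extra)
        }
        emits[[length(emits) + 1L]] <- v
        emit_of_bin[off + b] <- length(emits)
      }
    }
    off <- off + ru$nb
  }
  ## right-edge continuity factor
  if (!is.null(ctx$edgeR) && !isTRUE(ctx$edgeR$couple)) {
    ru <- runs[[length(runs)]]
    iout <- match(ctx$edgeR$state, ru$states)
    if (isTRUE(ctx$edgeR$free)) {
      v <- log(pmax(ru$r * ru$q[iout], 1e-300))
      v[iout] <- log(pmax((1 - ru$r[iout]) + ru$r[iout] * ru$q[iout],
                          1e-300))
    } else {
      v <- rep(log(1e-300), length(ru$states))
      v[iout] <- 0
    }
    idxR <- emit_of_bin[nb_tot]
    if (idxR > 0L && sum(emit_of_bin == idxR) > 1L) {
      emits[[length(emits) + 1L]] <- emits[[idxR]] + v
      emit_of_bin[nb_tot] <- length(emits)
    } else if (idxR > 0L) {
      emits[[idxR]] <- emits[[idxR]] + v
    } else {
      emits[[length(emits) + 1L]] <- v
      emit_of_bin[nb_tot] <- length(emits)
    }
  }
  ru1 <- runs[[1L]]
  if (!is.null(ctx$edgeL) && !isTRUE(ctx$edgeL$couple)) {
    iout <- match(ctx$edgeL$state, ru1$states)
    if (isTRUE(ctx$edgeL$free)) {
      init <- ru1$r[iout] * ru1$q
      init[iout] <- init[iout] + (1 - ru1$r[iout])
    } else {
      init <- numeric(length(ru1$states))
      init[iout] <- 1
    }
  } else {
    init <- ru1$q
  }
  gp <- integer(0)
  gp_ok <- TRUE
  if (mode %in% c(1L, 2L)) {
    ## old_children: per-bin child node ids of the old attachment path
    gp <- integer(nb_tot)
    off <- 0L
    for (i in seq_along(runs)) {
      ru <- runs[[i]]
      idx <- match(old_children[off + seq_len(ru$nb)], ru$states)
      if (anyNA(idx)) { gp_ok <- FALSE; break }
      gp[off + seq_len(ru$nb)] <- idx
      off <- off + ru$nb
    }
    if (!gp_ok) {
      if (mode == 1L) return(list(logq = -Inf, logq_given = -Inf))
      mode <- 0L
      gp <- integer(0)
    }
  }
  res <- hmm_pass(seg_of_bin, seg_a, seg_r, seg_w, btype, bmap, init,
                  emit_of_bin, emits, mode, gp)
  path_children <- integer(nb_tot)
  if (is.finite(res$logq)) {
    off <- 0L
    for (i in seq_along(runs)) {
      ru <- runs[[i]]
      path_children[off + seq_len(ru$nb)] <-
        ru$states[res$path[off + seq_len(ru$nb)]]
      off <- off + ru$nb
    }
  }
  list(children = path_children, logq = res$logq,
       logq_given = if (gp_ok) res$logq_given else -Inf,
       seg_of_bin = seg_of_bin)
}

## ---------------------------------------------------------------------------
## Time HMM, conditioned on a branch path (child id per bin)

## Build the per-(run x branch-piece) segments of the time HMM.
.time_segments <- function(st, ctx, children) {
  runs <- ctx$runs
  nbs <- vapply(runs, `[[`, integer(1), "nb")
  run_of_bin <- rep(seq_along(runs), nbs)
  B <- length(children)
  new_run <- c(TRUE, run_of_bin[-1] != run_of_bin[-B])
  chg <- c(TRUE, children[-1] != children[-B])
  starts <- which(new_run | chg)
  ends <- c(starts[-1] - 1L, B)
  lapply(seq_along(starts), function(s) list(
    run = run_of_bin[starts[s]], child = children[starts[s]],
    from = starts[s], to = ends[s],
    jump = chg[starts[s]] && !new_run[starts[s]]))
}

.time_hmm <- function(st, ctx, children, base, clock0, mode,
                      old_times = NULL) {
  runs <- ctx$runs
  p <- st$params
  segs <- .time_segments(st, ctx, children)
  S <- length(segs)
  nb_tot <- length(children)
  seg_of_bin <- integer(nb_tot)
  seg_a <- seg_r <- seg_w <- vector("list", S)
  btype <- integer(S)
  bmap <- vector("list", S)
  emits <- list()
  emit_of_bin <- integer(nb_tot)
  grids <- vector("list", S)
  for (s in seq_len(S)) {
    sg <- segs[[s]]
    ru <- runs[[sg$run]]
    g <- .ext_grid(ru$rem, st$time, sg$child, base, p$Ne, ru$ch)
    if (g$K == 0L) return(list(logq = -Inf))
    root_id <- .tree_root(ru$rem)
    tau_eff <- pmax(g$atoms - clock0, 1e-9) +
      ifelse(g$child == root_id, pmax(g$atoms - st$time[root_id], 0), 0)
    rho <- 1 - exp(-p$r * st$bs * tau_eff)
    rho <- pmin(pmax(rho, 0), 1 - 1e-12)
    if (!g$own_ok) rho[] <- 0     # jump target infeasible: stay only
    grids[[s]] <- g
    seg_of_bin[sg$from:sg$to] <- s
    seg_a[[s]] <- 1 - rho
    seg_r[[s]] <- rho
    seg_w[[s]] <- g$w
    if (s == 1L) {
      btype[s] <- 0L
    } else if (sg$jump) {
      btype[s] <- 2L
      if (!g$own_ok) return(list(logq = -Inf))
    } else {
      ## constrained run boundary: value-preserving remap; atoms riding the
      ## dissolved part of the boundary's moved lineage cannot carry over
      btype[s] <- 1L
      gprev <- grids[[s - 1L]]
      sprd <- .rem_spr(runs[[segs[[s - 1L]]$run]]$rem, ru$rem, st$time)
      mp <- .ext_cells(g, gprev$atoms)
      if (!is.null(sprd))
        mp[gprev$child == sprd$m & gprev$atoms > sprd$tg] <- 0L
      bmap[[s]] <- mp
    }
    ## per-bin no-mutation factor over the bin's positions, plus per-site
    ## match / extra-mutation terms with the exact time clock (the implied
    ## allele follows the branch containing each cell)
    tau <- tau_eff
    base_v <- -p$mu * tau * st$bs
    emits[[length(emits) + 1L]] <- base_v
    base_idx <- length(emits)
    emit_of_bin[sg$from:sg$to] <- base_idx
    if (length(ru$sites_idx)) {
      roff <- sum(vapply(runs[seq_len(sg$run - 1L)], `[[`, integer(1), "nb"))
      for (si in seq_along(ru$sites_idx)) {
        gb <- roff + ru$site_bin[si]
        if (gb < sg$from || gb > sg$to) next
        imp <- ru$implied[[si]][match(g$child, ru$states)]
        extra <- log1p(-exp(-p$mu * tau)) + p$mu * tau
        v <- ifelse(imp == ru$ahat[si], 0, extra)
        if (emit_of_bin[gb] == base_idx) {
          emits[[length(emits) + 1L]] <- base_v + v
          emit_of_bin[gb] <- length(emits)
        } else {
          emits[[emit_of_bin[gb]]] <- emits[[emit_of_bin[gb]]] + v
        }
      }
    }
  }
  ## edge conditioning
  g1 <- grids[[1L]]
  if (!is.null(ctx$edgeL) && isTRUE(ctx$edgeL$couple)) {
    ## re-coalescence coupling to the outside attachment
    ru1 <- runs[[segs[[1L]]$run]]
    cw <- .couple_weights(g1$atoms, g1$widths, ru1$ch, ctx$edgeL$time, base)
    cw[g1$w <= 0] <- 0
    init <- if (sum(cw) > 0) cw / sum(cw) else seg_w[[1L]]
  } else if (!is.null(ctx$edgeL)) {
    cell <- if (segs[[1L]]$child == ctx$edgeL$state)
      .ext_cell(g1, ctx$edgeL$time) else 0L
    if (isTRUE(ctx$edgeL$free)) {
      rho_out <- 1 - exp(-p$r * st$bs * max(ctx$edgeL$time - clock0, 0))
      if (cell > 0L) {
        init <- rho_out * seg_w[[1L]]
        init[cell] <- init[cell] + (1 - rho_out)
      } else {
        init <- seg_w[[1L]]      # branch changed at the edge: pure jump
      }
    } else {
      if (cell == 0L) return(list(logq = -Inf))
      init <- numeric(g1$K); init[cell] <- 1
    }
  } else {
    init <- seg_w[[1L]]
  }
  if (!is.null(ctx$edgeR) && isTRUE(ctx$edgeR$couple)) {
    sS <- segs[[S]]
    ruS <- runs[[sS$run]]
    gS <- grids[[S]]
    cw <- .couple_weights(gS$atoms, gS$widths, ruS$ch, ctx$edgeR$time, base)
    v <- log(pmax(cw, 1e-300))
    idxR <- emit_of_bin[nb_tot]
    if (idxR > 0L && sum(emit_of_bin == idxR) > 1L) {
      emits[[length(emits) + 1L]] <- emits[[idxR]] + v
      emit_of_bin[nb_tot] <- length(emits)
    } else if (idxR > 0L) {
      emits[[idxR]] <- emits[[idxR]] + v
    } else {
      emits[[length(emits) + 1L]] <- v
      emit_of_bin[nb_tot] <- length(emits)
    }
  } else if (!is.null(ctx$edgeR)) {
    sS <- segs[[S]]
    ruS <- runs[[sS$run]]
    gS <- grids[[S]]
    if (isTRUE(ctx$edgeR$free)) {
      gout <- .ext_grid(ruS$rem, st$time, ctx$edgeR$state, base, p$Ne,
                        ruS$ch)
      cellout <- .ext_cell(gout, ctx$edgeR$time)
      if (cellout == 0L || !gout$own_ok) return(list(logq = -Inf))
      wtgt <- gout$w[cellout]
      if (sS$child == ctx$edgeR$state) {
        v <- log(pmax(seg_r[[S]] * wtgt, 1e-300))
        hit <- .ext_cell(gS, ctx$edgeR$time)
        if (hit > 0L)
          v[hit] <- log(pmax((1 - seg_r[[S]][hit]) +
                               seg_r[[S]][hit] * wtgt, 1e-300))
      } else {
        v <- rep(log(pmax(wtgt, 1e-300)), gS$K)
      }
    } else {
      ## constrained right edge: the path must end at the carried-over
      ## image of the outside attachment
      cellout <- if (sS$child == ctx$edgeR$state)
        .ext_cell(gS, ctx$edgeR$time) else 0L
      if (cellout == 0L) return(list(logq = -Inf))
      v <- rep(-Inf, gS$K); v[cellout] <- 0
      v[v == -Inf] <- log(1e-300)
    }
    idxR <- emit_of_bin[nb_tot]
    if (idxR > 0L && sum(emit_of_bin == idxR) > 1L) {
      emits[[length(emits) + 1L]] <- emits[[idxR]] + v
      emit_of_bin[nb_tot] <- length(emits)
    } else if (idxR > 0L) {
      emits[[idxR]] <- emits[[idxR]] + v
    } else {
      emits[[length(emits) + 1L]] <- v
      emit_of_bin[nb_tot] <- length(emits)
    }
  }
  gp <- integer(0)
  if (mode == 1L) {
    gp <- integer(nb_tot)
    for (s in seq_len(S)) {
      rng <- segs[[s]]$from:segs[[s]]$to
      gp[rng] <- .ext_cells(grids[[s]], old_times[rng])
    }
    if (any(gp == 0L)) return(list(logq = -Inf))
  }
  res <- hmm_pass(seg_of_bin, seg_a, seg_r, seg_w, btype, bmap, init,
                  emit_of_bin, emits, mode, gp)
  list(res = res, segs = segs, grids = grids, logq = res$logq,
       seg_of_bin = seg_of_bin)
}

## ---------------------------------------------------------------------------
## Mapping a sampled (branch, time) path to ARG pieces

.spr_insert <- function(tr, c_id, target, nid) {
  ti <- match(target, tr$ids)
  gp <- tr$parent[ti]
  ids <- c(tr$ids, c_id, nid)
  parent <- c(tr$parent, nid, gp)
  parent[ti] <- nid
  list(ids = as.integer(ids), parent = as.integer(parent))
}

## attachment-start flags per bin, given segment ids and sampled cells
.att_starts <- function(segs, seg_of_bin, cells) {
  B <- length(seg_of_bin)
  out <- logical(B)
  for (l in seq_len(B)) {
    if (l == 1L) { out[l] <- TRUE; next }
    s <- seg_of_bin[l]
    if (s != seg_of_bin[l - 1L]) {
      out[l] <- segs[[s]]$jump          # jump = new attachment; remap = not
    } else if (cells[l] != cells[l - 1L]) {
      out[l] <- TRUE                    # within-branch time recombination
    }
  }
  out
}

## sum of log cell widths of the attachment atoms created strictly inside
## the interval (lattice-measure correction for the MH ratio)
.path_logdelta <- function(thmm, ctx, children, cells) {
  segs <- thmm$segs; grids <- thmm$grids; sob <- thmm$seg_of_bin
  starts <- which(.att_starts(segs, sob, cells))
  tot <- 0
  B <- length(sob)
  for (ai in seq_along(starts)) {
    l <- starts[ai]
    lend <- if (ai < length(starts)) starts[ai + 1L] - 1L else B
    contL <- ai == 1L && !is.null(ctx$edgeL) &&
      !isTRUE(ctx$edgeL$couple) &&
      children[l] == ctx$edgeL$state &&
      cells[l] == .ext_cell(grids[[sob[l]]], ctx$edgeL$time)
    contR <- lend == B && !is.null(ctx$edgeR) &&
      !isTRUE(ctx$edgeR$couple) &&
      children[lend] == ctx$edgeR$state &&
      cells[lend] == .ext_cell(grids[[sob[lend]]], ctx$edgeR$time)
    if (contL || contR) next
    tot <- tot + log(grids[[sob[l]]]$widths[cells[l]])
  }
  tot
}

## Turn a sampled/scored path into ARG pieces over [x0, x1).  Returns NULL
## when the path is unspliceable (time infeasible at some bin, or edge
## continuations contradictory).
.path_to_pieces <- function(st, ctx, children, thmm, base, c_id, x0, x1) {
  runs <- ctx$runs
  segs <- thmm$segs; grids <- thmm$grids; sob <- thmm$seg_of_bin
  cells <- thmm$res$path
  B <- length(sob)
  starts <- which(.att_starts(segs, sob, cells))
  natt <- length(starts)
  att_from <- starts
  att_to <- c(starts[-1L] - 1L, B)
  att_val <- numeric(natt)
  att_id <- integer(natt)
  for (ai in seq_len(natt)) {
    l <- att_from[ai]
    g <- grids[[sob[l]]]
    val <- g$atoms[cells[l]]
    id <- NA_integer_
    contL <- ai == 1L && !is.null(ctx$edgeL) &&
      !isTRUE(ctx$edgeL$couple) &&
      children[l] == ctx$edgeL$state &&
      cells[l] == .ext_cell(g, ctx$edgeL$time)
    lend <- att_to[ai]
    gend <- grids[[sob[lend]]]
    contR <- lend == B && !is.null(ctx$edgeR) &&
      !isTRUE(ctx$edgeR$couple) &&
      children[lend] == ctx$edgeR$state &&
      cells[lend] == .ext_cell(gend, ctx$edgeR$time)
    if (contL && contR &&
        (ctx$edgeL$jid != ctx$edgeR$jid ||
         ctx$edgeL$time != ctx$edgeR$time)) return(NULL)
    if (contL) { val <- ctx$edgeL$time; id <- ctx$edgeL$jid }
    if (contR) { val <- ctx$edgeR$time; id <- ctx$edgeR$jid }
    att_val[ai] <- val
    att_id[ai] <- id
  }
  run_of_bin <- integer(B)
  off <- 0L
  for (i in seq_along(runs)) {
    run_of_bin[off + seq_len(runs[[i]]$nb)] <- i
    off <- off + runs[[i]]$nb
  }
  att_of_bin <- rep(seq_len(natt), att_to - att_from + 1L)
  ## assign fresh ids and times
  for (ai in seq_len(natt)) {
    if (is.na(att_id[ai])) {
      att_id[ai] <- .st_fresh_id(st)
      st$time[att_id[ai]] <- att_val[ai]
    }
  }
  ## pieces: intersect runs with attachments, in genomic order; the target
  ## branch is the one containing the attachment time on the lineage above
  ## the base child
  pieces <- list()
  bp_of_bin_left <- function(l) min(x0 + (l - 1) * st$bs, x1)
  l <- 1L
  while (l <= B) {
    i <- run_of_bin[l]; ai <- att_of_bin[l]
    lend <- l
    while (lend < B && run_of_bin[lend + 1L] == i &&
           att_of_bin[lend + 1L] == ai) lend <- lend + 1L
    ru <- runs[[i]]
    orig <- st$trees[[ru$ktrees[1L]]]
    tval <- att_val[ai]
    target <- .climb_target(ru$rem, st$time, children[l], tval)
    ii <- match(target, ru$rem$ids)
    pa <- ru$rem$parent[ii]
    hi <- if (pa == 0L) Inf else st$time[pa]
    if (!(tval > max(st$time[target], base) && tval < hi)) return(NULL)
    nid <- att_id[ai]
    tre <- if (c_id %in% orig$ids) .spr_move(orig, c_id, target, nid)
           else .spr_insert(orig, c_id, target, nid)
    pieces[[length(pieces) + 1L]] <-
      list(left = bp_of_bin_left(l),
           right = if (lend == B) x1 else bp_of_bin_left(lend + 1L),
           tree = tre)
    l <- lend + 1L
  }
  pieces
}

## ---------------------------------------------------------------------------
## SMC-posterior log density of an interval

## `pieces`: list of (left, right, tree) covering [x0, x1) in order.
## `outL`/`outR`: full trees immediately outside (NULL at 0 / L).
.interval_logpi <- function(st, pieces, x0, x1, outL, outR) {
  p <- st$params
  lp <- 0
  ## Lattice SMC factorization: the chain of marginal trees over bins, with
  ## one transition per bin boundary.  A boundary with no tree change
  ## contributes the survival log(1 - rho), rho = 1 - exp(-r * bs * Lambda)
  ## of the left tree; a breakpoint contributes the jump mass
  ## rho * (recoal density) / Lambda.  Mutations contribute a -mu * area
  ## term plus per-site placement terms.
  bk_lp <- function(trL, trR) {
    lam <- .tree_lambda(trL, st$time)
    rho <- -expm1(-p$r * st$bs * lam)
    log(rho) - log(lam) + .recoal_loglik(trL, trR, st$time, p$Ne)
  }
  surv_lp <- function(tr, nbound) {
    if (nbound <= 0) return(0)
    lam <- .tree_lambda(tr, st$time)
    nbound * log1p(-(-expm1(-p$r * st$bs * lam)))
  }
  for (pc in pieces) {
    lam <- .tree_lambda(pc$tree, st$time)
    lp <- lp - p$mu * lam * (pc$right - pc$left)
    nb_p <- ceiling((pc$right - pc$left) / st$bs)
    lp <- lp + surv_lp(pc$tree, nb_p - 1L)
  }
  if (x0 == 0) {
    lp <- lp + .kingman_loglik(pieces[[1L]]$tree, st$time, p$Ne)
  } else if (!is.null(outL)) {
    lp <- lp + if (.tree_equal(outL, pieces[[1L]]$tree))
      surv_lp(outL, 1L) else bk_lp(outL, pieces[[1L]]$tree)
  }
  if (length(pieces) > 1L) {
    for (i in seq_len(length(pieces) - 1L)) {
      lp <- lp + bk_lp(pieces[[i]]$tree, pieces[[i + 1L]]$tree)
    }
  }
  if (x1 < st$L && !is.null(outR)) {
    lp <- lp + if (.tree_equal(pieces[[length(pieces)]]$tree, outR))
      surv_lp(pieces[[length(pieces)]]$tree, 1L)
      else bk_lp(pieces[[length(pieces)]]$tree, outR)
  }
  ## site likelihood terms
  sites <- which(st$pos >= x0 & st$pos < x1)
  if (length(sites)) {
    lefts <- vapply(pieces, `[[`, numeric(1), "left")
    for (s in sites) {
      k <- findInterval(st$pos[s], lefts)
      tre <- pieces[[k]]$tree
      y <- st$H[seq_len(st$n), s]
      lp <- lp + .site_loglik(tre, st$time, y, p$mu, st$n)$loglik
    }
  }
  lp
}

## full-ARG log posterior (for traces and diagnostics)
.st_logpi <- function(st) {
  pieces <- lapply(seq_along(st$trees), function(k)
    list(left = st$breaks[k], right = .ats_right_st(st, k),
         tree = st$trees[[k]]))
  .interval_logpi(st, pieces, 0, st$L, NULL, NULL)
}

## ---------------------------------------------------------------------------
## Replace the genomic range [x0, x1) of the current ARG with `pieces`

.st_replace <- function(st, t0, t1, x0, x1, pieces) {
  Tn <- length(st$trees)
  pre_t <- if (t0 > 1L) st$trees[seq_len(t0 - 1L)] else list()
  pre_b <- if (t0 > 1L) st$breaks[seq_len(t0 - 1L)] else numeric(0)
  if (x0 > st$breaks[t0]) {
    pre_t <- c(pre_t, st$trees[t0])
    pre_b <- c(pre_b, st$breaks[t0])
  }
  post_t <- if (t1 < Tn) st$trees[(t1 + 1L):Tn] else list()
  post_b <- if (t1 < Tn) st$breaks[(t1 + 1L):Tn] else numeric(0)
  if (x1 < .ats_right_st(st, t1)) {
    post_t <- c(st$trees[t1], post_t)
    post_b <- c(x1, post_b)
  }
  mid_t <- lapply(pieces, `[[`, "tree")
  mid_b <- vapply(pieces, `[[`, numeric(1), "left")
  trees <- c(pre_t, mid_t, post_t)
  breaks <- c(pre_b, mid_b, post_b)
  ## merge adjacent identical trees (edge continuations)
  keep <- rep(TRUE, length(trees))
  for (k in seq_along(trees)[-1L]) {
    prev <- max(which(keep[seq_len(k - 1L)]))
    if (.tree_equal(trees[[prev]], trees[[k]])) keep[k] <- FALSE
  }
  st$trees <- trees[keep]
  st$breaks <- breaks[keep]
  .st_refresh_cache(st)
  invisible(st)
}

## ---------------------------------------------------------------------------
## One SGPR Metropolis-Hastings step

.sgpr_step <- function(st, forced = NULL, always_accept = FALSE,
                       span = c("edge", "existence")) {
  span <- match.arg(span)
  reject <- function() list(accepted = FALSE)
  Tn <- length(st$trees)
  spans <- .st_spans(st)
  if (is.null(forced)) {
    k0 <- sample.int(Tn, 1L, prob = spans * st$lambda)
    tr0 <- st$trees[[k0]]
    sel <- which(tr0$parent != 0L)
    blen <- st$time[tr0$parent[sel]] - st$time[tr0$ids[sel]]
    bi <- sel[sample.int(length(sel), 1L, prob = blen)]
    c_id <- tr0$ids[bi]
    j0 <- tr0$parent[bi]
    h <- stats::runif(1, st$time[c_id], st$time[j0])
  } else {
    k0 <- forced$k0
    c_id <- forced$c_id
    h <- forced$h
  }
  att_of <- function(k) {
    trk <- st$trees[[k]]
    jk <- trk$parent[match(c_id, trk$ids)]
    list(j = jk, sib = trk$ids[trk$parent == jk & trk$ids != c_id],
         tr = trk)
  }
  j0 <- att_of(k0)$j
  if (h >= st$time[j0]) return(reject())
  trimL <- FALSE; trimR <- FALSE
  Wfac <- 0
  if (span == "edge") {
    ## re-siting move: the genomic span of the cut branch's ancestral
    ## segment (maximal run of trees in which c keeps attachment j0);
    ## the proposal is restricted to a single re-attachment over the span,
    ## so the reverse move uses the identical kernel
    has_edge <- function(k) {
      ci <- match(c_id, st$trees[[k]]$ids)
      !is.na(ci) && st$trees[[k]]$parent[ci] == j0
    }
    kL <- k0; while (kL > 1L && has_edge(kL - 1L)) kL <- kL - 1L
    kR <- k0; while (kR < Tn && has_edge(kR + 1L)) kR <- kR + 1L
    maxw <- 2048 * st$bs
    t0 <- kL; t1 <- kR
    while (.ats_right_st(st, t1) - st$breaks[t0] > maxw &&
           (t0 < k0 || t1 > k0)) {
      if (t1 - k0 >= k0 - t0 && t1 > k0) { t1 <- t1 - 1L; trimR <- TRUE }
      else { t0 <- t0 + 1L; trimL <- TRUE }
    }
    x0 <- st$breaks[t0]
    x1 <- .ats_right_st(st, t1)
  } else {
    ## segment-structure move: c's whole attachment path within a fixed
    ## genomic block, so splits and merges of attachment segments are
    ## proposed and reversed by the same kernel
    has_att <- function(k) {
      ci <- match(c_id, st$trees[[k]]$ids)
      !is.na(ci) && st$trees[[k]]$parent[ci] != 0L
    }
    kL <- k0; while (kL > 1L && has_att(kL - 1L)) kL <- kL - 1L
    kR <- k0; while (kR < Tn && has_att(kR + 1L)) kR <- kR + 1L
    blkw <- 4096 * st$bs
    xb0 <- floor(st$breaks[k0] / blkw) * blkw
    x0 <- max(st$breaks[kL], xb0)
    x1 <- min(.ats_right_st(st, kR), xb0 + blkw)
    if (x1 <= x0) return(reject())
    t0 <- findInterval(x0, st$breaks)
    t1 <- findInterval(x1 - 1e-9, st$breaks)
    trimL <- x0 == xb0 && st$breaks[kL] < xb0
    trimR <- x1 == xb0 + blkw && .ats_right_st(st, kR) > x1
    ## the cut height must sit below every attachment in the interval:
    ## this kernel draws it uniformly on that valid range
    lo_c <- st$time[c_id]
    mX <- Inf
    for (k in t0:t1) mX <- min(mX, st$time[att_of(k)$j])
    if (mX <= lo_c) return(reject())
    h <- stats::runif(1, lo_c, mX)
    ## cut weight (branch area) inside the block, for the reverse density
    WX <- 0
    for (k in t0:t1) if (st$breaks[k] >= xb0)
      WX <- WX + (min(.ats_right_st(st, k), x1) - max(st$breaks[k], x0)) *
        (st$time[att_of(k)$j] - lo_c)
    if (WX <= 0) return(reject())
    Wfac <- -log(WX) + log(mX - lo_c)
  }
  if (x1 <= x0) return(reject())
  base <- h
  clock0 <- st$time[c_id]
  runs <- .make_runs(st, t0, t1, x0, x1, c_id)
  runs <- .decorate_runs(st, runs, base, clock0, seq_len(st$n))
  ctx <- list(runs = runs)
  ## Edge handling.  At a trimmed end the same attachment continues
  ## outside, so it is pinned.  At the span's natural left/right end the
  ## boundary event is c's own attachment change (free, with continuity
  ## mixture towards the outside attachment), unless c does not exist
  ## outside (its clade is assembled/disassembled at the boundary, and
  ## the attachment node persists outside: pinned) or c is the outside
  ## root (no condition).
  make_edge <- function(kout, kin, run) {
    ao_in <- att_of(kin)
    if (is.null(kout)) {                       # trimmed: pin own attachment
      return(list(state = .map_into_run(ao_in$sib,
                                        .spr_remaining(ao_in$tr, c_id), run),
                  time = st$time[ao_in$j], jid = ao_in$j, free = FALSE))
    }
    tr_out <- st$trees[[kout]]
    ci <- match(c_id, tr_out$ids)
    if (is.na(ci)) {                           # c assembled here: pin
      return(list(state = .map_into_run(ao_in$sib,
                                        .spr_remaining(ao_in$tr, c_id), run),
                  time = st$time[ao_in$j], jid = ao_in$j, free = FALSE))
    }
    if (tr_out$parent[ci] == 0L) return(NULL)  # c is root outside: free
    ao <- att_of(kout)
    rem_out <- .spr_remaining(ao$tr, c_id)
    list(state = .map_into_run(ao$sib, rem_out, run),
         time = st$time[ao$j], jid = ao$j, free = TRUE)
  }
  if (x0 > 0) {
    ctx$edgeL <- make_edge(if (trimL) NULL else t0 - 1L, t0, runs[[1L]])
    ## the re-siting kernel keeps the span's end breakpoints; a free edge
    ## contributes a re-coalescence coupling to the outside attachment
    ## instead of a continuity mixture
    if (span == "edge" && isTRUE(ctx$edgeL$free)) ctx$edgeL$couple <- TRUE
  }
  if (x1 < st$L) {
    ctx$edgeR <- make_edge(if (trimR) NULL else t1 + 1L, t1,
                           runs[[length(runs)]])
    if (span == "edge" && isTRUE(ctx$edgeR$free)) ctx$edgeR$couple <- TRUE
  }
  ## ---- old path: canonical per-bin representation
  nb_tot <- sum(vapply(runs, `[[`, integer(1), "nb"))
  old_children <- integer(nb_tot)
  old_times <- numeric(nb_tot)
  off <- 0L
  cur <- NA_integer_
  prev_run <- NULL
  prev_j <- NA_integer_
  for (i in seq_along(runs)) {
    ru <- runs[[i]]
    for (k in ru$ktrees) {
      ao <- att_of(k)
      if (is.na(cur)) {
        ## first tree: an attachment continuing in from outside the
        ## interval keeps its carried (edge) representation
        cur <- if (!is.null(ctx$edgeL) && ao$j == ctx$edgeL$jid)
          ctx$edgeL$state else ao$sib
      } else if (!is.na(prev_j) && ao$j != prev_j) {
        cur <- ao$sib
      } else if (k == ru$ktrees[1L] && !is.null(prev_run)) {
        idx <- .run_map(prev_run, ru)[match(cur, prev_run$states)]
        cur <- ru$states[idx]
      }
      lftk <- max(st$breaks[k], ru$left)
      rgtk <- min(.ats_right_st(st, k), ru$right)
      b0 <- as.integer(floor((lftk - ru$left) / st$bs)) + 1L
      b1 <- as.integer(ceiling((rgtk - ru$left) / st$bs))
      old_children[off + b0:b1] <- cur
      old_times[off + b0:b1] <- st$time[ao$j]
      prev_j <- ao$j
    }
    prev_run <- ru
    off <- off + ru$nb
  }
  ## ---- forward proposal + reverse branch density on the shared filter
  bY <- .branch_hmm(st, ctx, 2L, old_children)
  if (!is.finite(bY$logq)) return(reject())
  tY <- .time_hmm(st, ctx, bY$children, base, clock0, 0L)
  if (!is.finite(tY$logq)) return(reject())
  piecesY <- .path_to_pieces(st, ctx, bY$children, tY, base, c_id, x0, x1)
  if (is.null(piecesY)) return(reject())
  if (span == "edge") {
    ## the re-siting kernel proposes a single re-attachment over the span
    cells <- tY$res$path
    if (sum(.att_starts(tY$segs, tY$seg_of_bin, cells)) > 1L)
      return(reject())
  }
  if (!is.finite(bY$logq_given)) return(reject())
  tX <- .time_hmm(st, ctx, old_children, base, clock0, 1L, old_times)
  if (!is.finite(tX$logq)) return(reject())
  ## ---- posterior + lattice terms
  ldY <- .path_logdelta(tY, ctx, bY$children, tY$res$path)
  ldX <- .path_logdelta(tX, ctx, old_children, tX$res$path)
  outL <- if (x0 > 0) st$trees[[if (x0 > st$breaks[t0]) t0 else t0 - 1L]]
          else NULL
  outR <- if (x1 < st$L) st$trees[[if (x1 < .ats_right_st(st, t1)) t1
                                   else t1 + 1L]] else NULL
  piecesX <- lapply(t0:t1, function(k)
    list(left = max(st$breaks[k], x0),
         right = min(.ats_right_st(st, k), x1), tree = st$trees[[k]]))
  piX <- .interval_logpi(st, piecesX, x0, x1, outL, outR) + ldX
  piY <- .interval_logpi(st, piecesY, x0, x1, outL, outR) + ldY
  lamX <- sum(vapply(piecesX, function(pc)
    .tree_lambda(pc$tree, st$time) * (pc$right - pc$left), numeric(1)))
  lamY <- sum(vapply(piecesY, function(pc)
    .tree_lambda(pc$tree, st$time) * (pc$right - pc$left), numeric(1)))
  A_X <- st$A
  A_Y <- st$A - lamX + lamY
  if (span == "existence") {
    WY <- 0
    mY <- Inf
    lo_c <- st$time[c_id]
    for (pi_ in seq_along(piecesY)) {
      pc <- piecesY[[pi_]]
      tatt <- st$time[pc$tree$parent[match(c_id, pc$tree$ids)]]
      mY <- min(mY, tatt)
      if (pi_ == 1L && !is.null(outL) && .tree_equal(pc$tree, outL)) next
      WY <- WY + (pc$right - pc$left) * (tatt - lo_c)
    }
    if (WY <= 0 || mY <= h) return(reject())
    Wfac <- Wfac + log(WY) - log(mY - lo_c)
  }
  logalpha <- (piY - piX) +
    (bY$logq_given + tX$logq - bY$logq - tY$logq) +
    (log(A_X) - log(A_Y)) + Wfac
  if (is.nan(logalpha)) return(reject())
  if (always_accept && !is.finite(piY)) return(reject())
  info <- list(logalpha = logalpha,
               logq_fwd = bY$logq + tY$logq,
               logq_rev = bY$logq_given + tX$logq,
               logpi_old = piX, logpi_new = piY,
               interval = c(x0, x1), child = c_id, cut_time = h,
               parts = c(bq_f = bY$logq, tq_f = tY$logq,
                         bq_r = bY$logq_given, tq_r = tX$logq,
                         ldX = ldX, ldY = ldY,
                         piX0 = piX - ldX, piY0 = piY - ldY))
  if (always_accept) logalpha <- Inf
  if (log(stats::runif(1)) < logalpha) {
    .st_replace(st, t0, t1, x0, x1, piecesY)
    .st_remap_sites(st, which(st$pos >= x0 & st$pos < x1))
    c(list(accepted = TRUE), info)
  } else {
    c(list(accepted = FALSE), info)
  }
}

## map a child id from an outside remaining tree into a run's state space
.map_into_run <- function(v, rem_out, run) {
  .map_child(v, rem_out, run$rem)
}

## ---------------------------------------------------------------------------
## Initialization: sequential threading

.thread_one <- function(st, leaf, threaded) {
  if (length(threaded) == 0L) {
    st$trees <- list(list(ids = as.integer(leaf), parent = 0L))
    st$breaks <- 0
    .st_refresh_cache(st)
    .st_remap_sites(st, which(st$H[leaf, ] > 0L), leaf)
    return(invisible(st))
  }
  for (attempt in 1:8) {
    runs <- .make_runs(st, 1L, length(st$trees), 0, st$L, NULL)
    runs <- .decorate_runs(st, runs, 0, 0, c(threaded, leaf))
    ctx <- list(runs = runs)
    bY <- .branch_hmm(st, ctx, 0L)
    if (!is.finite(bY$logq)) next
    tY <- .time_hmm(st, ctx, bY$children, 0, 0, 0L)
    if (!is.finite(tY$logq)) next
    pieces <- .path_to_pieces(st, ctx, bY$children, tY, 0, leaf, 0, st$L)
    if (is.null(pieces)) next
    .st_replace(st, 1L, length(st$trees), 0, st$L, pieces)
    seg <- which(colSums(st$H[c(threaded, leaf), , drop = FALSE]) > 0L)
    .st_remap_sites(st, seg, c(threaded, leaf))
    return(invisible(st))
  }
  stop("threading failed repeatedly (unspliceable paths)")
}
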