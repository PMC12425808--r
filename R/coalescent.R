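## Exact piecewise integration under the constant-Ne coalescent.
##
## For a marginal tree with all leaves at time 0, the lineage count seen by
## a floating lineage is k(t) = 1 + #{internal node times > t} (the root
## lineage is counted above the root).  A lineage detached at `base`
## re-coalesces onto any *specific* contemporary branch with hazard
## 1/(2Ne), and survives with the total hazard k(t)/(2Ne).  All of the
## rejoin weights, time-grid cell masses and prior factors below are exact
## epoch-wise integrals of this process.

## cumulative-hazard structure from `base`: boundaries b, per-epoch k,
## cumulative hazard M at boundaries
.ch_make <- function(itimes, base, Ne) {
  up <- sort(itimes[itimes > base])
  b <- c(base, up)
  k <- 1 + length(up) - seq(0, length(up))     # k in epoch starting at b[i]
  M <- c(0, cumsum(k[-length(k)] * diff(b) / (2 * Ne)))
  Sb <- exp(-M)
  E <- length(b)
  contrib <- if (E > 1) (Sb[-E] - Sb[-1]) / k[-E] else numeric(0)
  Fcum <- c(0, cumsum(contrib))
  list(b = b, k = k, M = M, Sb = Sb, Fcum = Fcum, Ne = Ne)
}

## F(t) = integral of exp(-M(s)) / (2Ne) ds from base to t, vectorized;
## F(Inf) is the total mass (equals 1 by construction)
.ch_F <- function(ch, t) {
  i <- findInterval(t, ch$b)
  i[i < 1L] <- 1L
  St <- exp(-(ch$M[i] + ch$k[i] * (t - ch$b[i]) / (2 * ch$Ne)))
  ch$Fcum[i] + (ch$Sb[i] - St) / ch$k[i]
}

## integral of exp(+M(s)) ds from base to t, vectorized (for coupling a
## re-coalescence to a recombination height on a neighbouring branch)
.ch_Fexp <- function(ch, t) {
  E <- length(ch$b)
  contrib <- if (E > 1)
    (exp(ch$M[-1]) - exp(ch$M[-E])) * (2 * ch$Ne) / ch$k[-E] else numeric(0)
  Gcum <- c(0, cumsum(contrib))
  i <- findInterval(t, ch$b)
  i[i < 1L] <- 1L
  Gcum[i] + (exp(ch$M[i] + ch$k[i] * (t - ch$b[i]) / (2 * ch$Ne)) -
               exp(ch$M[i])) * (2 * ch$Ne) / ch$k[i]
}

## Per-atom density (times cell width) of re-coalescing at t, given that
## the lineage detached at a uniform recombination height on a
## neighbouring attachment that reaches up to t_out: proportional to
## exp(-M(t)) * integral_{base}^{min(t, t_out)} exp(M(w)) dw.
.couple_weights <- function(atoms, widths, ch, t_out, base) {
  hi <- pmin(atoms, t_out)
  inner <- pmax(.ch_Fexp(ch, pmax(hi, base)), 0)
  Mt <- ch$M[pmax(findInterval(atoms, ch$b), 1L)]
  i <- pmax(findInterval(atoms, ch$b), 1L)
  Mt <- ch$M[i] + ch$k[i] * (atoms - ch$b[i]) / (2 * ch$Ne)
  w <- exp(-Mt) * inner * widths
  w[!is.finite(w) | w < 0] <- 0
  w
}

## M(t) = integral of k/(2Ne) from base to t (t >= base, scalar or vector)
.ch_M <- function(ch, t) {
  i <- findInterval(t, ch$b)
  i[i < 1L] <- 1L
  ch$M[i] + ch$k[i] * (t - ch$b[i]) / (2 * ch$Ne)
}

## integral of exp(-M(t)) / (2Ne) dt over [a, b]; b may be Inf
.ch_int <- function(ch, a, b) {
  if (b <= a) return(0)
  a <- max(a, ch$b[1])
  if (b <= a) return(0)
  tot <- 0
  E <- length(ch$b)
  for (e in seq_len(E)) {
    x0 <- max(a, ch$b[e])
    x1 <- if (e < E) min(b, ch$b[e + 1]) else b
    if (x1 <= x0) next
    k <- ch$k[e]
    S0 <- exp(-.ch_M(ch, x0))
    d <- if (is.finite(x1)) 1 - exp(-k * (x1 - x0) / (2 * ch$Ne)) else 1
    tot <- tot + S0 * d / k
  }
  tot
}

## total branch length (generations) of a tree
.tree_lambda <- function(tr, time) {
  sel <- tr$parent != 0L
  sum(time[tr$parent[sel]] - time[tr$ids[sel]])
}

## internal node times of a tree, ascending
.tree_itimes <- function(tr, time) {
  sort(time[tr$ids[tr$ids %in% tr$parent]])
}

## Per-state joining intervals for a tree: for each node (state = branch
## above it; the root's state is the semi-infinite lineage above the root),
## lo = max(child time, base) and hi = parent time (Inf for root).
.state_intervals <- function(tr, time, base) {
  hi <- rep(Inf, length(tr$ids))
  sel <- tr$parent != 0L
  hi[sel] <- time[tr$parent[sel]]
  lo <- pmax(time[tr$ids], base)
  list(lo = lo, hi = hi)
}

## Rejoin weights q: probability that a lineage floating from `base`
## re-coalesces onto each state's branch; sums to 1 (the root state
## absorbs all mass above the root).
.rejoin_weights <- function(tr, time, base, Ne) {
  ch <- .ch_make(.tree_itimes(tr, time), base, Ne)
  iv <- .state_intervals(tr, time, base)
  lo <- pmax(iv$lo, base)
  q <- pmax(0, .ch_F(ch, iv$hi) - .ch_F(ch, pmin(lo, iv$hi)))
  list(q = q, ch = ch, lo = iv$lo, hi = iv$hi)
}

## Discrete time grid on a branch interval: 40 cells, log-spaced (finer
## near the lower endpoint, where the re-coalescence density concentrates);
## for the semi-infinite root state the edges are exponential quantiles
## truncated at 99.9%.  Atoms are cell midpoints; endpoints are excluded.
.n_atoms <- 40L
.n_atoms_ext <- 12L   # coarser cells on carry-only ancestor branches

.atom_grid <- function(lo, hi, Ne, K = .n_atoms) {
  if (is.finite(hi)) {
    cc <- 3
    g <- (exp(cc * (0:K) / K) - 1) / (exp(cc) - 1)
    edges <- lo + (hi - lo) * g
  } else {
    u <- (0:K) / K * 0.999
    edges <- lo - 2 * Ne * log(1 - u)
  }
  list(edges = edges, atoms = (edges[-1] + edges[-(K + 1)]) / 2)
}

## cell index of value t in a grid (0 = outside)
.grid_cell <- function(grid, t) {
  K <- length(grid$atoms)
  i <- findInterval(t, grid$edges)
  if (i < 1L || i > K) 0L else i
}

## Extended time grid for a base child v: the concatenated per-branch grids
## of the whole lineage above v (v's own branch, then each ancestor branch,
## then the semi-infinite above-root lineage).  Joining times proposed by
## jumps are restricted to v's own branch (`w` is zero on extended cells);
## the extended cells exist so that an attachment carried across a
## pre-existing recombination can keep its time even when the local branch
## above v was subdivided or re-arranged.
.ext_grid <- function(rem, time, v, base, Ne, ch) {
  chain_child <- integer(0)
  lo <- hi <- numeric(0)
  cur <- v
  repeat {
    ci <- match(cur, rem$ids)
    pa <- rem$parent[ci]
    h <- if (pa == 0L) Inf else time[pa]
    l <- max(time[cur], base)
    if (h > l) {
      chain_child <- c(chain_child, cur)
      lo <- c(lo, l); hi <- c(hi, h)
    }
    if (pa == 0L) break
    cur <- pa
  }
  atoms <- widths <- masses <- numeric(0)
  child_of <- integer(0)
  sub_edges <- vector("list", length(chain_child))
  for (i in seq_along(chain_child)) {
    g <- .atom_grid(lo[i], hi[i], Ne,
                    K = if (i == 1L && chain_child[1] == v) .n_atoms
                        else .n_atoms_ext)
    sub_edges[[i]] <- g$edges
    atoms <- c(atoms, g$atoms)
    widths <- c(widths, diff(g$edges))
    masses <- c(masses, pmax(0, diff(.ch_F(ch, g$edges))))
    child_of <- c(child_of, rep(chain_child[i], length(g$atoms)))
  }
  Kown <- if (length(chain_child) && chain_child[1] == v)
    length(sub_edges[[1]]) - 1L else 0L
  w <- numeric(length(atoms))
  own_ok <- Kown > 0L && sum(masses[seq_len(Kown)]) > 0
  if (own_ok) w[seq_len(Kown)] <- masses[seq_len(Kown)] /
      sum(masses[seq_len(Kown)])
  list(atoms = atoms, widths = widths, child = child_of,
       sub_child = chain_child, sub_lo = lo, sub_hi = hi,
       sub_edges = sub_edges, w = w, own_ok = own_ok,
       K = length(atoms))
}

## cell indices of values in an extended grid, vectorized (0 = outside)
.ext_cells <- function(eg, tv) {
  out <- integer(length(tv))
  bounds <- c(eg$sub_lo[1], eg$sub_hi)
  si <- findInterval(tv, bounds)
  off <- 0L
  for (i in seq_along(eg$sub_child)) {
    ne <- length(eg$sub_edges[[i]]) - 1L
    sel <- which(si == i)
    if (length(sel)) {
      j <- findInterval(tv[sel], eg$sub_edges[[i]])
      ok <- j >= 1L & j <= ne
      out[sel[ok]] <- off + j[ok]
    }
    off <- off + ne
  }
  out
}

.ext_cell <- function(eg, t) .ext_cells(eg, t)

## target branch (child id) containing time t on the lineage above v
.climb_target <- function(rem, time, v, t) {
  cur <- v
  repeat {
    ci <- match(cur, rem$ids)
    pa <- rem$parent[ci]
    if (pa == 0L || time[pa] > t) return(cur)
    cur <- pa
  }
}

## exact cell masses of the truncated re-coalescence density on a grid
.grid_masses <- function(grid, ch) {
  m <- pmax(0, diff(.ch_F(ch, grid$edges)))
  s <- sum(m)
  if (s <= 0) rep(1 / length(grid$atoms), length(grid$atoms)) else m / s
}

## Kingman (labelled-history) log density of a single tree under constant Ne
.kingman_loglik <- function(tr, time, Ne) {
  it <- .tree_itimes(tr, time)
  m <- length(it) + 1L
  kk <- m:2
  dt <- diff(c(0, it))
  sum(-choose(kk, 2) * dt / (2 * Ne) - log(2 * Ne))
}

## Marginal log density of the SMC transition from trL to trR (one SPR):
## integrates over the recombination height w on the moved lineage's old
## branch the product (uniform point on trL) x (survival of the floating
## lineage) x (coalescence hazard onto the target at the new node's time).
.recoal_loglik <- function(trL, trR, time, Ne) {
  lost <- setdiff(trL$ids, trR$ids)
  gained <- setdiff(trR$ids, trL$ids)
  if (length(lost) != 1L || length(gained) != 1L) return(-Inf)
  j <- lost; g <- gained
  chL <- trL$ids[trL$parent == j]
  chR <- trR$ids[trR$parent == g]
  cand <- intersect(chL, chR)
  if (!length(cand)) return(-Inf)
  tp <- time[g]; tj <- time[j]
  lamL <- .tree_lambda(trL, time)
  itL <- .tree_itimes(trL, time)
  ## k_rem(s) = k_L(s) - 1 below tj, k_L(s) above
  b <- c(0, itL)
  kL <- 1 + length(itL) - seq(0, length(itL))
  krem <- kL - as.numeric(b < tj)
  krem[krem < 1] <- 1            # guard (only the final epoch can hit this)
  Mb <- c(0, cumsum(krem[-length(krem)] * diff(b) / (2 * Ne)))
  Mfun <- function(t) {
    i <- findInterval(t, b)
    Mb[i] + krem[i] * (t - b[i]) / (2 * Ne)
  }
  tot <- 0
  for (cs in cand) {
    w0 <- time[cs]; w1 <- min(tj, tp)
    if (w1 <= w0) next
    ## integral over w of exp(-(M(tp) - M(w))) dw, epoch-wise
    acc <- 0
    E <- length(b)
    for (e in seq_len(E)) {
      x0 <- max(w0, b[e])
      x1 <- if (e < E) min(w1, b[e + 1]) else w1
      if (x1 <= x0) next
      k <- krem[e]
      acc <- acc + exp(Mfun(x0)) * (exp(k * (x1 - x0) / (2 * Ne)) - 1) *
        (2 * Ne / k)
    }
    tot <- tot + exp(-Mfun(tp)) * acc
  }
  if (tot <= 0) return(-Inf)
  ## the SMC breakpoint rate r*L_tree and the uniform recombination-point
  ## density 1/L_tree cancel: the per-outcome density is r * bs * the
  ## absolute integral over the recombination height w
  log(tot) - log(2 * Ne)
}

## ---------------------------------------------------------------------------
## Infinite-sites mutation likelihood

## leaf-set indicator matrix (n x length(ids)) for all nodes of a tree
.tree_clades <- function(tr, time, n) {
  ids <- tr$ids
  C <- matrix(FALSE, n, length(ids))
  ord <- order(time[ids])
  kid_rows <- split(seq_along(ids), tr$parent)
  for (k in ord) {
    id <- ids[k]
    if (id <= n) { C[id, k] <- TRUE; next }
    for (ki in kid_rows[[as.character(id)]]) C[, k] <- C[, k] | C[, ki]
  }
  C
}

## Per-site log likelihood: log-sum-exp over single-branch placements of
## the Poisson point weight log(1 - exp(-mu*l)) + mu*l, with mismatched
## leaves charged an extra mutation on their terminal branch.  Also
## returns the best placement (node id).
.site_loglik <- function(tr, time, y, mu, n, clades = NULL) {
  if (is.null(clades)) clades <- .tree_clades(tr, time, n)
  ids <- tr$ids
  sel <- which(tr$parent != 0L)
  blen <- time[tr$parent[sel]] - time[ids[sel]]
  rho <- function(l) log1p(-exp(-mu * pmax(l, 1e-12))) + mu * l
  leaf_pen <- numeric(n)
  for (lf in seq_len(n)) {
    pi <- tr$parent[match(lf, ids)]
    leaf_pen[lf] <- rho(time[pi])
  }
  yl <- as.logical(y)
  scores <- vapply(sel, function(k) {
    mism <- which(clades[, k] != yl)
    rho(time[tr$parent[k]] - time[ids[k]]) + sum(leaf_pen[mism])
  }, numeric(1))
  mx <- max(scores)
  list(loglik = mx + log(sum(exp(scores - mx))),
       best = ids[sel[which.max(scores)]])
}

.best_mut_node <- function(tr, time, y, n, mu) {
  .site_loglik(tr, time, y, mu, n)$best
}
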