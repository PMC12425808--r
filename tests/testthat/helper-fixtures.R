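## Shared fixtures: standard human-like rates, a few small simulated ARGs
## (built once per test run), and an independent fine-grid posterior oracle
## for the two-haplotype case.

P_STD <- model_params(Ne = 1e4, mu = 2e-8, r = 2e-8)

fix_arg <- local({
  cache <- list()
  function(n, L, seed, mutations = TRUE) {
    key <- paste(n, L, seed, mutations, sep = "_")
    if (is.null(cache[[key]])) {
      arg <- sim_arg(n, L, P_STD, seed = seed)
      cache[[key]] <<- if (mutations) {
        set.seed(seed + 1e6)
        drop_mutations(arg, P_STD$mu)
      } else list(arg = arg)
    }
    cache[[key]]
  }
})

## Independent fine-grid forward-backward oracle for the pair (n = 2)
## lattice model: per-bin TMRCA states, Li-Stephens-style transitions with
## the recombination-height-marginalized re-coalescence kernel, Poisson
## mutation emissions.  Used to validate both the threading proposal and
## the MCMC stationary distribution.
pair_oracle <- function(positions, L, params, bs, ngrid = 400,
                        model = c("target", "proposal"), edges = NULL) {
  model <- match.arg(model)
  Ne <- params$Ne; mu <- params$mu; r <- params$r
  if (is.null(edges))
    edges <- -2 * Ne * log(1 - seq(0, 0.9995, length.out = ngrid + 1))
  ngrid <- length(edges) - 1L
  atoms <- (edges[-1] + edges[-(ngrid + 1)]) / 2
  nb <- ceiling(L / bs)
  site_bin <- floor(positions / bs) + 1
  w0 <- diff(1 - exp(-edges / (2 * Ne)))
  cellmass <- function(t) {
    lo <- edges[-(ngrid + 1)]; hi <- edges[-1]
    out <- numeric(ngrid)
    for (j in seq_len(ngrid)) {
      a <- lo[j]; b <- hi[j]
      if (b <= t) {
        out[j] <- ((b + 2 * Ne * exp(-b / (2 * Ne))) -
                     (a + 2 * Ne * exp(-a / (2 * Ne)))) / t
      } else if (a >= t) {
        cc <- 2 * Ne * (exp(t / (2 * Ne)) - 1)
        out[j] <- cc * (exp(-a / (2 * Ne)) - exp(-b / (2 * Ne))) / t
      } else {
        p1 <- ((t + 2 * Ne * exp(-t / (2 * Ne))) -
                 (a + 2 * Ne * exp(-a / (2 * Ne)))) / t
        cc <- 2 * Ne * (exp(t / (2 * Ne)) - 1)
        p2 <- cc * (exp(-t / (2 * Ne)) - exp(-b / (2 * Ne))) / t
        out[j] <- p1 + p2
      }
    }
    out
  }
  if (model == "target") {
    K <- t(vapply(atoms, cellmass, numeric(ngrid)))
  } else {
    ## the threading proposal re-joins from the stationary distribution
    K <- matrix(rep(w0, each = ngrid), ngrid, ngrid)
  }
  rho <- 1 - exp(-2 * r * bs * atoms)
  area <- exp(-mu * 2 * atoms * bs)
  site_f <- (1 - exp(-mu * 2 * atoms)) * exp(mu * 2 * atoms)
  FF <- matrix(0, nb, ngrid)
  f <- w0 * area
  ns1 <- sum(site_bin == 1)
  if (ns1 > 0) f <- f * site_f^ns1
  f <- f / sum(f); FF[1, ] <- f
  if (nb > 1) for (l in 2:nb) {
    f <- (1 - rho) * f + as.numeric(crossprod(f * rho, K))
    f <- f * area
    nsl <- sum(site_bin == l)
    if (nsl > 0) f <- f * site_f^nsl
    f <- f / sum(f)
    FF[l, ] <- f
  }
  B <- matrix(1, nb, ngrid)
  if (nb > 1) {
    b <- rep(1, ngrid)
    for (l in (nb - 1):1) {
      nsl <- sum(site_bin == l + 1)
      e <- area * if (nsl > 0) site_f^nsl else 1
      v <- b * e
      b <- (1 - rho) * v + rho * as.numeric(K %*% v)
      b <- b / max(b)
      B[l, ] <- b
    }
  }
  marg <- FF * B
  marg <- marg / rowSums(marg)
  list(edges = edges, atoms = atoms, marginal = marg, nb = nb)
}

## brute-force MRCA by walking both leaves' ancestor paths in the edge table
brute_mrca_time <- function(arg, i, j, x) {
  e <- arg$edges
  tmap <- rep(NA_real_, max(arg$nodes$id))
  tmap[arg$nodes$id] <- arg$nodes$time
  up <- function(v) {
    path <- v
    repeat {
      sel <- e$child == v & e$left <= x & e$right > x
      if (!any(sel)) break
      v <- e$parent[which(sel)[1]]
      path <- c(path, v)
    }
    path
  }
  pi <- up(i); pj <- up(j)
  tmap[intersect(pi, pj)[which.min(tmap[intersect(pi, pj)])]]
}
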