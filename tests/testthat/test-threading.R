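test_that("bin partition follows the 4e-3/(4 Ne r) rule with clamping", {
  b <- make_bins(100, P_STD)
  expect_equal(b$bin_size, 5)   # 4e-3 / (4 * 1e4 * 2e-8)
  phuge <- model_params(1e6, 2e-8, 1e-4)
  expect_equal(make_bins(10, phuge)$bin_size, 1)
  b2 <- make_bins(10, model_params(1e4, 2e-8, 3.3e-8))
  expect_equal(b2$bin_size, 3)
  expect_equal(b2$edges, c(0, 3, 6, 9, 10))
})

test_that("transition rows follow the Li-Stephens form and sum to one", {
  fx <- fix_arg(4, 1000, 21)
  mt <- marginal_tree(fx$arg, 500)
  stt <- threading_state(mt, P_STD)
  expect_equal(sum(stt$q), 1)
  for (i in seq_along(stt$q)) {
    row <- transition_row(stt, i)
    expect_equal(sum(row), 1)
    expect_true(row[i] >= 1 - stt$r[i])
  }
  ## r_i = 0 collapses to a point mass
  stt0 <- stt; stt0$r[] <- 0
  expect_equal(transition_row(stt0, 2), replace(numeric(length(stt$q)), 2, 1))
  ## hand evaluation on a 3-state system with r_i = 0.1, q = (1,2,1)/4
  stt3 <- list(q = c(1, 2, 1) / 4, r = c(0.1, 0.1, 0.1))
  class(stt3) <- "threading_state"
  expect_equal(transition_row(stt3, 1),
               c(0.9 + 0.1 * 0.25, 0.1 * 0.5, 0.1 * 0.25))
  ## constrained boundary: deterministic carry-over
  expect_equal(transition_row(stt3, 1, recomb_allowed = FALSE,
                              map = c(2, 2, 3)),
               c(0, 1, 0))
})

test_that("branch recombination probability behaves like 1 - exp(-r b l)", {
  expect_equal(branch_recomb_prob(2e4, 5, P_STD), 1 - exp(-0.002))
  expect_equal(branch_recomb_prob(1000, 0, P_STD), 0)
  l <- c(1e3, 2e3, 4e3, 8e3)
  expect_true(all(diff(branch_recomb_prob(l, 5, P_STD)) > 0))
  expect_true(all(diff(branch_recomb_prob(2e3, c(1, 5, 25), P_STD)) > 0))
})

test_that("rejoin weights are exact re-coalescence probabilities", {
  ## 3-leaf tree with printed node times; quadrature oracle per branch
  nodes <- data.frame(id = 1:5, time = c(0, 0, 0, 4000, 15000))
  edges <- data.frame(child = c(1, 2, 4, 3), parent = c(4, 4, 5, 5),
                      left = 0, right = 100)
  arg <- arg_tables(nodes, edges, NULL, 100, 1:3)
  mt <- marginal_tree(arg, 0)
  stt <- threading_state(mt, P_STD)
  expect_equal(sum(stt$q), 1)
  ## survival of a floating lineage: k(t) lineages at rate 1/(2Ne) each;
  ## hand-derived cumulative hazard, composite-Simpson integration
  cumhaz <- function(t) ifelse(t < 4000, 3 * t,
                        ifelse(t < 15000, 12000 + 2 * (t - 4000),
                               34000 + (t - 15000))) / 2e4
  qnum <- function(lo, hi) {
    x <- seq(lo, hi, length.out = 4001)
    y <- exp(-cumhaz(x)) / 2e4
    h <- x[2] - x[1]
    h / 3 * (y[1] + y[4001] + 4 * sum(y[seq(2, 4000, 2)]) +
               2 * sum(y[seq(3, 3999, 2)]))
  }
  for (i in seq_along(stt$branches)) {
    lo <- stt$lo[i]
    hi <- if (is.finite(stt$hi[i])) stt$hi[i] else 6e5
    expect_equal(stt$q[i], qnum(lo, hi), tolerance = 1e-7)
  }
  ## symmetry: the two terminal branches of a pair get equal weight
  nodes2 <- data.frame(id = 1:3, time = c(0, 0, 9000))
  edges2 <- data.frame(child = 1:2, parent = 3, left = 0, right = 10)
  stt2 <- threading_state(marginal_tree(arg_tables(nodes2, edges2, NULL,
                                                   10, 1:2), 0), P_STD)
  expect_equal(stt2$q[1], stt2$q[2])
})

test_that("emission log-likelihoods follow the extra-mutation clock", {
  fx <- fix_arg(4, 1000, 21)
  mt <- marginal_tree(fx$arg, 500)
  stt <- threading_state(mt, P_STD)
  K <- length(stt$q)
  em0 <- emission_loglik(stt, rep(TRUE, K), 1, P_STD)
  expect_true(all(em0 <= 0))
  em1 <- emission_loglik(stt, rep(FALSE, K), 1, P_STD)
  expect_true(all(em1 < em0))   # a mismatch is always less likely
  tau <- 5e3
  expect_equal(emission_loglik(stt, TRUE, 1, P_STD, tau = tau)[1],
               -P_STD$mu * tau)
  expect_equal(emission_loglik(stt, FALSE, 1, P_STD, tau = tau)[1],
               log(1 - exp(-P_STD$mu * tau)))
})

test_that("a single-bin branch path is drawn from normalized emission weights", {
  ## one bin, flat prior over branches times emissions
  nodes <- data.frame(id = 1:5, time = c(0, 0, 0, 4000, 15000))
  edges <- data.frame(child = c(1, 2, 4, 3), parent = c(4, 4, 5, 5),
                      left = 0, right = 5)
  arg <- arg_tables(nodes, edges, NULL, 5, 1:3)
  H <- matrix(c(1L, 0L, 0L), nrow = 3)   # hap 1 derived at the site
  hap <- 1L
  set.seed(31)
  draws <- replicate(3000, sample_branch_path(arg, hap, H, 2, P_STD)$children)
  frq <- table(factor(draws, levels = c(1, 2, 4, 3, 5))) / 3000
  ## expected: q weights x emission for the new hap matching leaf 1
  mt <- marginal_tree(arg, 0)
  stt <- threading_state(mt, P_STD)
  implied <- stt$branches %in% c(1)   # joining below the mutation on leaf 1
  ## site is carried by leaf 1 only; mutation maps to branch above leaf 1
  w <- stt$q * exp(emission_loglik(stt, implied, hap, P_STD)) *
    exp(-P_STD$mu * (ifelse(is.finite(stt$hi), (stt$lo + stt$hi) / 2,
                            stt$lo + 2e4)) * 4)
  w <- w / sum(w)
  ord <- match(c(1, 2, 4, 3, 5), stt$branches)
  expect_lt(max(abs(as.numeric(frq) - w[ord])), 0.03)
})

test_that("time sampling matches the truncated stationary density", {
  ## n = 2, no data, tiny genome: the joining time of the second lineage
  ## is drawn from the stationary coalescent density with the weak
  ## no-mutation penalty
  ns <- asNamespace("argthread")
  H <- matrix(integer(0), nrow = 2, ncol = 0)
  set.seed(33)
  tm <- replicate(1500, {
    st <- ns$.st_build(H, numeric(0), 50, P_STD)
    ns$.thread_one(st, 1L, integer(0))
    ns$.thread_one(st, 2L, 1L)
    max(st$time[unlist(lapply(st$trees, `[[`, "ids"))], na.rm = TRUE)
  })
  lam <- 1 / 2e4 + 2 * P_STD$mu * 50
  expect_lt(abs(mean(tm) - 1 / lam) / (1 / lam), 0.12)
  expect_true(all(tm > 0))
})

test_that("threading a duplicate haplotype joins its twin's terminal branch", {
  ## data-rich fixture so the copy signal dominates the coalescent prior
  p_rich <- model_params(1e4, 1e-6, 2e-8)
  arg <- sim_arg(4, 2000, p_rich, seed = 21)
  set.seed(22)
  dm <- drop_mutations(arg, p_rich$mu)
  set.seed(35)
  bp <- sample_branch_path(dm$arg, dm$haplotypes[1, ], dm$haplotypes,
                           dm$positions, p_rich)
  expect_gt(mean(bp$children == 1), 0.8)
})

test_that("threading adds one leaf and keeps breakpoints on bin boundaries", {
  fx <- fix_arg(4, 2000, 21)
  set.seed(36)
  th <- thread_haplotype(fx$arg, fx$haplotypes[2, ], fx$haplotypes,
                         fx$positions, P_STD)
  expect_equal(length(th$arg$sample_ids), 5)
  expect_true(validate_arg(th$arg))
  lefts <- unique(th$arg$edges$left)
  olds <- unique(fx$arg$edges$left)
  news <- setdiff(lefts, olds)
  if (length(news)) expect_true(all(news %% 5 == 0))
})

test_that("branch-path law matches exhaustive enumeration on a tiny instance", {
  ## 3 leaves, one tree, 4 bins, one segregating site: enumerate all
  ## K^4 paths under the stated transition x emission model
  nodes <- data.frame(id = 1:5, time = c(0, 0, 0, 4000, 15000))
  edges <- data.frame(child = c(1, 2, 4, 3), parent = c(4, 4, 5, 5),
                      left = 0, right = 20)
  muts <- data.frame(position = 7, node = 1L, derived = "1")
  arg <- arg_tables(nodes, edges, muts, 20, 1:3)
  H <- matrix(c(1L, 0L, 0L), nrow = 3)
  hap <- 1L   # new haplotype carries the derived allele
  mt <- marginal_tree(arg, 0)
  stt <- threading_state(mt, P_STD)
  K <- length(stt$q)
  ## per-bin per-state log emission, replicating the model: no-mutation
  ## base over the bin plus the site term in bin 2
  hi_cap <- ifelse(is.finite(stt$hi), stt$hi, stt$lo + 4e4)
  mid <- (stt$lo + hi_cap) / 2
  tau <- pmax(mid, 1e-9) +
    ifelse(stt$branches == 5, pmax(mid - 15000, 0), 0)
  base <- -P_STD$mu * tau * 5
  implied <- stt$branches %in% c(1)
  extra <- log(1 - exp(-P_STD$mu * tau)) + P_STD$mu * tau
  esite <- base + ifelse(implied == TRUE, 0, extra)
  emis <- list(base, esite, base, base)
  Tm <- t(vapply(seq_len(K), function(i) transition_row(stt, i),
                 numeric(K)))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), 4)))
  lp <- apply(paths, 1, function(pp) {
    v <- log(stt$q[pp[1]]) + emis[[1]][pp[1]]
    for (l in 2:4) v <- v + log(Tm[pp[l - 1], pp[l]]) + emis[[l]][pp[l]]
    v
  })
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  set.seed(41)
  draws <- replicate(8000,
    paste(match(sample_branch_path(arg, hap, H, 7, P_STD)$children,
                stt$branches), collapse = "-"))
  key <- apply(paths, 1, paste, collapse = "-")
  obs <- as.numeric(table(factor(draws, levels = key)))
  keep <- pr * 8000 >= 4
  chi <- sum((obs[keep] - 8000 * pr[keep])^2 / (8000 * pr[keep]))
  df <- sum(keep) - 1
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.001)
})
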