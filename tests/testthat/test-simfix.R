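test_that("pairwise coalescence times match the coalescent expectation", {
  set.seed(101)
  tm <- replicate(400, {
    arg <- sim_arg(2, 100, P_STD)
    max(arg$nodes$time[arg$nodes$id %in%
                         marginal_tree(arg, 0)$branches$parent])
  })
  ## E[T2] = 2 Ne; SE = 2 Ne / sqrt(n)
  expect_lt(abs(mean(tm) - 2e4), 3 * 2e4 / sqrt(length(tm)))
})

test_that("no recombination yields a single tree; breakpoints scale with r", {
  p0 <- model_params(1e4, 2e-8, 1e-15)
  arg <- sim_arg(4, 50000, p0, seed = 2)
  expect_equal(length(unique(arg$edges$left)), 1)
  set.seed(103)
  nb <- replicate(60, length(unique(sim_arg(2, 50000, P_STD)$edges$left)) - 1)
  ## SMC breakpoint rate for a pair: r * E[2 T2] per bp, with E[T2|new tree]
  ## stationary, so E[breakpoints] ~ r * 2 * 2Ne * L
  expected <- P_STD$r * 2 * 2 * 1e4 * 50000
  expect_lt(abs(mean(nb) - expected), 3 * sd(nb) / sqrt(length(nb)) + 2)
})

test_that("segregating-site density matches theta for pairs", {
  set.seed(104)
  ns <- replicate(200, {
    arg <- sim_arg(2, 5000, P_STD)
    length(drop_mutations(arg, P_STD$mu)$positions)
  })
  expect_lt(abs(mean(ns) - P_STD$theta * 5000),
            3 * sd(ns) / sqrt(length(ns)))
})

test_that("variant carriers equal the mutation edge's descendant leaves", {
  fx <- fix_arg(6, 20000, 11)
  for (s in seq_along(fx$positions)) {
    node <- fx$arg$mutations$node[s]
    mt <- marginal_tree(fx$arg, fx$positions[s])
    ## descendants of node in the marginal tree
    below <- node
    repeat {
      kids <- mt$branches$child[mt$branches$parent %in% below &
                                  !(mt$branches$child %in% below)]
      if (!length(kids)) break
      below <- c(below, kids)
    }
    carriers <- sort(intersect(below, fx$arg$sample_ids))
    expect_equal(unname(which(fx$haplotypes[, s] == 1L)), carriers)
  }
})

test_that("adjacent marginal trees differ by exactly one SPR", {
  fx <- fix_arg(6, 20000, 11)
  expect_true(validate_arg(fx$arg))   # includes the one-SPR adjacency check
  ## stronger: each boundary carries positive transition density
  ats <- argthread:::.ats_from_tables(fx$arg)
  for (k in seq_len(length(ats$trees) - 1)) {
    expect_true(is.finite(argthread:::.recoal_loglik(
      ats$trees[[k]], ats$trees[[k + 1]], ats$time, P_STD$Ne)))
  }
})

test_that("stylized bottleneck history produces bimodal pair coalescence times", {
  h <- ceu_like_history()
  expect_true(all(h$at(c(0, 500, 2000, 5000, 1e6)) > 0))
  expect_equal(h$at(1500), 2e3)
  set.seed(105)
  tm <- replicate(600, {
    arg <- sim_arg(2, 100, P_STD, history = h)
    max(arg$nodes$time)
  })
  ## mass both within the bottleneck epoch and well past it, with a valley
  ## in between (the bottleneck absorbs lineages that failed to coalesce
  ## during the expansion; survivors coalesce on the ancestral scale)
  p_recent <- mean(tm < 3000)
  p_old <- mean(tm > 6000)
  expect_gt(p_recent, 0.25)
  expect_gt(p_old, 0.1)
  d <- density(tm, from = 0, to = 20000)
  at <- function(x) d$y[which.min(abs(d$x - x))]
  expect_gt(at(2000), at(4500))
  expect_gt(at(9000), 0)
})

test_that("constant history reproduces the plain simulator", {
  set.seed(106)
  a1 <- sim_arg(3, 1000, P_STD, seed = 9)
  a2 <- sim_arg(3, 1000, P_STD, seed = 9, history = constant_history(1e4))
  expect_equal(a1$nodes, a2$nodes)
  expect_equal(a1$edges, a2$edges)
})
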