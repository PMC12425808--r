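test_that("empirical CIs follow the percentile rule and nest", {
  fx <- fix_arg(4, 5000, 7)
  ## fake posterior set: copies with scaled node times
  mk <- function(f) {
    a <- fx$arg
    a$nodes$time <- a$nodes$time * f
    a
  }
  fac <- seq(0.5, 1.5, length.out = 100)
  ps <- structure(list(samples = lapply(fac, mk)), class = "posterior_set")
  base <- pairwise_tmrca(fx$arg, 1, 2, 1000)
  ci9 <- empirical_ci(ps, 1, 2, 1000, 0.9)
  vals <- sort(fac * base)
  expect_equal(unname(ci9["lo"]), unname(quantile(vals, 0.05)))
  expect_equal(unname(ci9["hi"]), unname(quantile(vals, 0.95)))
  ci5 <- empirical_ci(ps, 1, 2, 1000, 0.5)
  ci7 <- empirical_ci(ps, 1, 2, 1000, 0.7)
  expect_true(ci5["lo"] >= ci7["lo"] && ci7["lo"] >= ci9["lo"])
  expect_true(ci5["hi"] <= ci7["hi"] && ci7["hi"] <= ci9["hi"])
  ## identical samples collapse to a point
  ps1 <- structure(list(samples = lapply(1:10, function(i) mk(1))),
                   class = "posterior_set")
  ci <- empirical_ci(ps1, 1, 2, 1000, 0.9)
  expect_equal(unname(ci["lo"]), unname(ci["hi"]))
})

test_that("coverage counts truths inside the CI and is monotone in level", {
  set.seed(81)
  draws <- matrix(rnorm(50 * 100), 50, 100)
  truth_in <- rowMeans(draws)          # central: always covered
  expect_equal(ci_coverage(draws, truth_in, 0.9), 1)
  truth_out <- apply(draws, 1, max) + 1
  expect_equal(ci_coverage(draws, truth_out, 0.9), 0)
  truth <- rnorm(50)
  c5 <- ci_coverage(draws, truth, 0.5)
  c9 <- ci_coverage(draws, truth, 0.9)
  expect_true(c9 >= c5)
})

test_that("rank histograms are uniform for a correct sampler, U-shaped when
           under-dispersed, and KL matches the closed form", {
  set.seed(82)
  m <- 39
  truth <- rnorm(400)
  post_ok <- matrix(rnorm(400 * m), 400, m)
  rh <- rank_histogram(truth, post_ok, bins = 20)
  expect_lt(rh$kl, 0.05)
  chi <- sum((rh$histogram - 20)^2 / 20)
  expect_gt(pchisq(chi, 19, lower.tail = FALSE), 0.001)
  ## under-dispersed posterior piles ranks at the ends
  post_narrow <- matrix(rnorm(400 * m, sd = 0.3), 400, m)
  rh2 <- rank_histogram(truth, post_narrow, bins = 20)
  expect_gt(rh2$kl, rh$kl)
  ends <- sum(rh2$histogram[c(1, 20)])
  expect_gt(ends, sum(rh2$histogram[9:12]))
  ## KL closed form on a hand-built histogram
  h <- c(10, 30)
  p <- (h + 0.5) / sum(h + 0.5)
  expect_equal(rank_histogram(c(rep(-1, 10), rep(1, 30)),
                              matrix(0, 40, 1), bins = 2)$kl,
               sum(p * log(p / 0.5)))
})

test_that("coalescence heatmaps are normalized and sharpen with averaging", {
  fx <- fix_arg(4, 5000, 7)
  grid <- c(0, 2000, 8000, 20000, 50000)
  hm <- coalescence_heatmap(list(fx$arg), 1, 1000, grid)
  expect_true(all(abs(colSums(hm) - 1) < 1e-9))
  ## n = 2 single sample: point mass at the pair's TMRCA bin
  nodes <- data.frame(id = 1:3, time = c(0, 0, 9000))
  edges <- data.frame(child = 1:2, parent = 3, left = 0, right = 100)
  arg2 <- arg_tables(nodes, edges, NULL, 100, 1:2)
  hm2 <- coalescence_heatmap(list(arg2), 1, 100, grid)
  expect_equal(as.numeric(hm2), c(0, 0, 1, 0, 0))
})

test_that("coalescence ratios flag deep-coalescing windows", {
  grid <- c(0, 1000, 3000, 10000, 30000)
  hm <- cbind(c(0, 0.5, 0.5, 0, 0), c(0, 0, 0, 0.2, 0.8),
              c(0, 0, 0.5, 0.25, 0.25))
  ## t_intro 1000, t_split 10000: mid mass = bins [1000,10000),
  ## deep mass = bins >= 10000
  cr <- coalescence_ratio(hm, grid, 1000, 10000)
  expect_equal(cr[1], 0)
  expect_equal(cr[2], 100)          # all mass deep: capped
  expect_equal(cr[3], 1)            # evenly split
})

test_that("posterior tmrca matrix matches per-sample queries", {
  fx <- fix_arg(4, 5000, 7)
  ps <- structure(list(samples = list(fx$arg, fx$arg)),
                  class = "posterior_set")
  prs <- rbind(c(1, 2), c(3, 4))
  pos <- c(100, 4000)
  M <- posterior_tmrca(ps, prs, pos)
  expect_equal(M[1, 1], pairwise_tmrca(fx$arg, 1, 2, 100))
  expect_equal(M[2, 2], pairwise_tmrca(fx$arg, 3, 4, 4000))
})
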