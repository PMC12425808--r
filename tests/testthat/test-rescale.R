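test_that("time windows have equal span-weighted branch mass", {
  fx <- fix_arg(6, 20000, 11)
  tw <- time_windows(fx$arg, 10)
  expect_length(tw, 11)
  expect_equal(tw[1], 0)
  ## numerical-integration oracle for the per-window area
  e <- fx$arg$edges
  tmap <- rep(NA_real_, max(fx$arg$nodes$id))
  tmap[fx$arg$nodes$id] <- fx$arg$nodes$time
  span <- e$right - e$left
  area_in <- function(a, b) sum(span * pmax(0, pmin(tmap[e$parent], b) -
                                              pmax(tmap[e$child], a)))
  A <- area_in(0, Inf)
  for (w in 1:10) {
    expect_equal(area_in(tw[w], tw[w + 1]), A / 10, tolerance = 1e-9)
  }
  expect_length(time_windows(fx$arg, 1), 2)
})

test_that("pair windows split at half the root time", {
  nodes <- data.frame(id = 1:3, time = c(0, 0, 9000))
  edges <- data.frame(child = 1:2, parent = 3, left = 0, right = 100)
  arg <- arg_tables(nodes, edges, NULL, 100, 1:2)
  expect_equal(time_windows(arg, 2), c(0, 4500, 9000))
})

test_that("fractional mutation counts conserve the total", {
  fx <- fix_arg(6, 20000, 11)
  tw <- time_windows(fx$arg, 10)
  mc <- mutation_counts(fx$arg, tw)
  expect_equal(sum(mc), nrow(fx$arg$mutations))
  ## a mutation on a branch fully inside one window counts once there
  tmap <- rep(NA_real_, max(fx$arg$nodes$id))
  tmap[fx$arg$nodes$id] <- fx$arg$nodes$time
  ## stated rule on a constructed case: branch spans windows 30/70
  nodes <- data.frame(id = 1:3, time = c(0, 0, 1000))
  edges <- data.frame(child = 1:2, parent = 3, left = 0, right = 10)
  muts <- data.frame(position = 3, node = 1L, derived = "1")
  arg2 <- arg_tables(nodes, edges, muts, 10, 1:2)
  mc2 <- mutation_counts(arg2, c(0, 300, 1000))
  expect_equal(mc2, c(0.3, 0.7))
})

test_that("re-scaling matches expected to observed counts and is idempotent", {
  fx <- fix_arg(6, 20000, 11)
  K <- 6
  fa <- fit_and_apply(fx$arg, P_STD, K = K)
  expect_true(validate_arg(fa$arg))
  ## conservation of total mutation count
  expect_equal(nrow(fa$arg$mutations), nrow(fx$arg$mutations))
  ## per-window expected = observed after the fit (excluding floored)
  tw <- time_windows(fa$arg, K)
  obs <- mutation_counts(fa$arg, tw)
  e <- fa$arg$edges
  tmap <- rep(NA_real_, max(fa$arg$nodes$id))
  tmap[fa$arg$nodes$id] <- fa$arg$nodes$time
  span <- e$right - e$left
  area_in <- function(a, b) sum(span * pmax(0, pmin(tmap[e$parent], b) -
                                              pmax(tmap[e$child], a)))
  floored <- fa$scales <= 0.0500001
  for (w in which(!floored)) {
    expect_equal(P_STD$mu * area_in(tw[w], tw[w + 1]), obs[w],
                 tolerance = 1e-6)
  }
  ## idempotence: a second application moves node times negligibly
  fa2 <- fit_and_apply(fa$arg, P_STD, K = K)
  rel <- abs(fa2$arg$nodes$time - fa$arg$nodes$time) /
    pmax(fa$arg$nodes$time, 1)
  expect_lt(max(rel), 1e-9)
  ## monotone: node order preserved
  expect_true(all(order(fa$arg$nodes$time) == order(fx$arg$nodes$time)))
  ## map is strictly increasing from 0
  expect_equal(fa$map$mapped[1], 0)
  expect_true(all(diff(fa$map$mapped) > 0))
})

test_that("re-scaling is the identity when counts already match", {
  fx <- fix_arg(6, 20000, 11)
  fa <- fit_and_apply(fx$arg, P_STD, K = 4)
  fa2 <- fit_and_apply(fa$arg, P_STD, K = 4)
  expect_lt(max(abs(fa2$scales - 1)), 1e-9)
})

test_that("re-scaling recovers a five-fold population-size misfit", {
  ## ARG shaped at Ne but mutations dropped as if times were 5x larger:
  ## the fitted transform should stretch total tree height ~5x
  set.seed(71)
  arg <- sim_arg(6, 40000, P_STD)
  big <- arg
  big$nodes$time <- big$nodes$time * 5
  set.seed(72)
  dmb <- drop_mutations(big, P_STD$mu)
  shrunk <- dmb$arg
  shrunk$nodes$time <- shrunk$nodes$time / 5   # misfit ARG, correct data
  fa <- fit_and_apply(shrunk, P_STD, K = 8)
  ratio <- max(fa$arg$nodes$time) / max(shrunk$nodes$time)
  expect_gt(ratio, 3)
  expect_lt(ratio, 7)
})
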