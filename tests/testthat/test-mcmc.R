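test_that("cuts hit branches proportionally to length and stay inside", {
  ## two-leaf single tree: both terminal branches equal length
  nodes <- data.frame(id = 1:3, time = c(0, 0, 12000))
  edges <- data.frame(child = 1:2, parent = 3, left = 0, right = 1000)
  arg <- arg_tables(nodes, edges, NULL, 1000, 1:2)
  set.seed(51)
  cuts <- replicate(2000, sample_cut(arg)$child)
  p1 <- mean(cuts == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 2000))
  cc <- sample_cut(arg, seed = 5)
  expect_true(cc$cut_time > 0 && cc$cut_time < 12000)
  expect_equal(cc$extension, c(0, 1000))  # single tree: whole region
})

test_that("prune followed by re-attachment restores the tables", {
  fx <- fix_arg(5, 10000, 3)
  set.seed(53)
  for (rep in 1:5) {
    cut <- sample_cut(fx$arg)
    pruned <- prune_cut(fx$arg, cut)
    back <- reattach_cut(pruned)
    expect_equal(back$edges, fx$arg$edges)
    expect_equal(sort(back$nodes$id), sort(fx$arg$nodes$id))
  }
})

test_that("a rejected MH step leaves the tables untouched", {
  fx <- fix_arg(4, 5000, 7)
  bins <- make_bins(5000, P_STD)
  snapped <- snap_to_bins(fx$arg, bins)
  found_reject <- FALSE
  for (s in 1:30) {
    r <- mh_step(snapped, fx$haplotypes, fx$positions, P_STD, seed = 100 + s)
    if (!r$accepted) {
      found_reject <- TRUE
      expect_identical(r$arg, snapped)
    }
  }
  expect_true(found_reject)
})

test_that("regraft reports finite forward and reverse densities", {
  fx <- fix_arg(4, 5000, 7)
  bins <- make_bins(5000, P_STD)
  snapped <- snap_to_bins(fx$arg, bins)
  got <- FALSE
  for (s in 1:30) {
    r <- regraft(snapped, fx$haplotypes, fx$positions, P_STD, seed = 300 + s)
    if (!is.null(r$logq_fwd)) {
      got <- TRUE
      expect_true(is.finite(r$logq_fwd))
      expect_true(is.finite(r$logq_rev))
      expect_true(is.finite(r$logalpha) || r$logalpha == -Inf)
      break
    }
  }
  expect_true(got)
})

test_that("chains are reproducible and emit valid samples with finite traces", {
  fx <- fix_arg(4, 5000, 7)
  cfg <- chain_config(n_samples = 4, thin = 3, burn_in = 10, seed = 77)
  ps1 <- run_chain(fx$haplotypes, fx$positions, 5000, P_STD, cfg)
  ps2 <- run_chain(fx$haplotypes, fx$positions, 5000, P_STD, cfg)
  expect_identical(ps1$samples, ps2$samples)
  expect_identical(ps1$trace, ps2$trace)
  expect_true(all(is.finite(ps1$trace$log_posterior)))
  for (s in ps1$samples) expect_true(validate_arg(s))
  ## default configuration mirrors the published sampling scheme
  cfg0 <- chain_config()
  expect_equal(cfg0$n_samples, 100L)
  expect_equal(cfg0$thin, 20L)
  expect_equal(cfg0$burn_in, 1000L)
})

test_that("SGPR acceptance rate is healthy on simulated data", {
  set.seed(61)
  truth <- sim_arg(6, 20000, P_STD)
  dm <- drop_mutations(truth, P_STD$mu)
  ns <- asNamespace("argthread")
  st <- ns$.st_from_arg(dm$arg, dm$haplotypes, dm$positions, P_STD)
  set.seed(62)
  acc <- 0
  for (i in 1:600) if (ns$.sgpr_step(st)$accepted) acc <- acc + 1
  expect_gt(acc / 600, 0.1)
})
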