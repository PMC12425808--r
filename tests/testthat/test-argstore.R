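test_that("model parameters validate and derive scaled rates", {
  p <- model_params(1e4, 2e-8, 2e-8)
  expect_equal(p$theta, 8e-4)
  expect_equal(p$rho, 8e-4)
  expect_error(model_params(0, 1e-8, 1e-8), "positive")
})

test_that("simulated ARGs pass validation and marginal trees are binary", {
  fx <- fix_arg(6, 20000, 11)
  expect_true(validate_arg(fx$arg))
  set.seed(42)
  for (x in runif(25, 0, 20000)) {
    mt <- marginal_tree(fx$arg, x)
    expect_length(mt$branches$child, 2 * 6 - 2)
    expect_true(all(mt$branches$parent_time > mt$branches$child_time))
  }
  expect_error(marginal_tree(fx$arg, 20000), "range")
})

test_that("single-tree ARG gives the same marginal tree everywhere", {
  p2 <- model_params(1e4, 2e-8, 1e-12)   # essentially no recombination
  arg <- sim_arg(4, 2000, p2, seed = 5)
  expect_equal(nrow(arg$edges), 6)       # one tree: 2n - 2 edges
  t1 <- marginal_tree(arg, 0)
  t2 <- marginal_tree(arg, 1999)
  expect_identical(t1$branches, t2$branches)
})

test_that("pairwise TMRCA agrees with a brute-force path walk", {
  fx <- fix_arg(6, 20000, 11)
  set.seed(7)
  for (d in 1:20) {
    ij <- sample.int(6, 2)
    x <- runif(1, 0, 20000)
    expect_equal(pairwise_tmrca(fx$arg, ij[1], ij[2], x),
                 brute_mrca_time(fx$arg, ij[1], ij[2], x))
  }
  expect_error(pairwise_tmrca(fx$arg, 2, 2, 0), "distinct")
})

test_that("cherry TMRCA is the cherry node time regardless of deeper topology", {
  nodes <- data.frame(id = 1:7, time = c(0, 0, 0, 0, 1000, 5000, 20000))
  edges <- data.frame(child = c(1, 2, 5, 3, 4, 6),
                      parent = c(5, 5, 6, 6, 7, 7),
                      left = 0, right = 100)
  arg <- arg_tables(nodes, edges, NULL, 100, 1:4)
  expect_true(validate_arg(arg))
  expect_equal(pairwise_tmrca(arg, 1, 2, 50), 1000)
  expect_equal(pairwise_tmrca(arg, 1, 4, 50), 20000)
})

test_that("triplet distance matches induced-topology comparison via ape", {
  fx <- fix_arg(6, 20000, 11)
  t1 <- marginal_tree(fx$arg, 100)
  t2 <- marginal_tree(fx$arg, 19000)
  expect_equal(triplet_distance(t1, t1), 0)
  d <- triplet_distance(t1, t2)
  expect_true(d >= 0 && d <= 1)
  expect_equal(d, triplet_distance(t2, t1))
  ## independent oracle: prune each tree to every triple with ape and
  ## compare the induced rooted topologies
  phy1 <- ape::read.tree(text = marginal_newick(fx$arg, 100))
  phy2 <- ape::read.tree(text = marginal_newick(fx$arg, 19000))
  cherry_of <- function(phy, tp) {
    s <- ape::keep.tip(phy, tp)
    ## the cherry pair is the one whose MRCA is not the root
    prs <- utils::combn(3, 2)
    anc <- ape::mrca(s)
    root <- ape::Ntip(s) + 1L
    for (k in 1:3) {
      a <- prs[1, k]; b <- prs[2, k]
      if (anc[a, b] != root)
        return(paste(sort(s$tip.label[c(a, b)]), collapse = "-"))
    }
    "star"
  }
  triples <- utils::combn(6, 3)
  bad <- 0
  for (k in seq_len(ncol(triples))) {
    tp <- as.character(triples[, k])
    if (cherry_of(phy1, tp) != cherry_of(phy2, tp)) bad <- bad + 1
  }
  expect_equal(d, bad / ncol(triples))
})

test_that("lineages through time is n at 0, non-increasing, 1 beyond root", {
  fx <- fix_arg(6, 20000, 11)
  grid <- c(0, 10^seq(2, 6, length.out = 30))
  ltt <- lineages_through_time(fx$arg, grid)
  expect_equal(ltt[1], 6)
  expect_true(all(diff(ltt) <= 1e-12))
  expect_equal(ltt[length(ltt)], 1)
  ## interval-stabbing oracle on the edge table: span-weighted branches
  ## crossing t0, plus the root lineage wherever the root is at or below t0
  tmap <- rep(NA_real_, max(fx$arg$nodes$id))
  tmap[fx$arg$nodes$id] <- fx$arg$nodes$time
  e <- fx$arg$edges
  for (t0 in c(2000, 8000, 30000)) {
    stab <- sum((e$right - e$left) *
                  (tmap[e$child] <= t0 & tmap[e$parent] > t0))
    brks <- sort(unique(c(0, e$left)))
    rights <- c(brks[-1], 20000)
    root_term <- sum(vapply(seq_along(brks), function(k) {
      mt <- marginal_tree(fx$arg, (brks[k] + rights[k]) / 2)
      (rights[k] - brks[k]) * (max(mt$branches$parent_time) <= t0)
    }, numeric(1)))
    expect_equal(lineages_through_time(fx$arg, t0),
                 (stab + root_term) / 20000)
  }
})

test_that("IBD segments partition the genome and match a positionwise scan", {
  fx <- fix_arg(5, 10000, 3)
  seg <- ibd_segments(fx$arg, 1, 2)
  expect_equal(seg$left[1], 0)
  expect_equal(seg$right[nrow(seg)], 10000)
  if (nrow(seg) > 1) {
    expect_equal(seg$left[-1], seg$right[-nrow(seg)])
    expect_true(all(seg$mrca[-1] != seg$mrca[-nrow(seg)]))
  }
  ## positionwise oracle at 1 bp resolution over a slice
  for (x in seq(0, 9999, by = 199)) {
    k <- findInterval(x, seg$left)
    mt <- marginal_tree(fx$arg, x)
    tm <- pairwise_tmrca(fx$arg, 1, 2, x)
    tmap <- rep(NA_real_, max(fx$arg$nodes$id))
    tmap[fx$arg$nodes$id] <- fx$arg$nodes$time
    expect_equal(tmap[seg$mrca[k]], tm)
  }
})

test_that("breakpoint counts per window sum to the total", {
  fx <- fix_arg(6, 20000, 11)
  bw <- breakpoints_in_windows(fx$arg, 5000)
  lefts <- sort(unique(fx$arg$edges$left))
  expect_equal(sum(bw$breakpoints), length(lefts[lefts > 0]))
  expect_equal(breakpoints_in_windows(fx$arg, 20000)$breakpoints,
               length(lefts[lefts > 0]))
})

test_that("allele age is the branch midpoint, strictly inside the branch", {
  fx <- fix_arg(5, 10000, 3)
  expect_gt(length(fx$positions), 0)
  tmap <- rep(NA_real_, max(fx$arg$nodes$id))
  tmap[fx$arg$nodes$id] <- fx$arg$nodes$time
  for (s in fx$positions[seq_len(min(10, length(fx$positions)))]) {
    a <- allele_age(fx$arg, s)
    hit <- which(fx$arg$mutations$position == s)
    node <- fx$arg$mutations$node[hit]
    lo <- tmap[node]
    expect_true(a > lo)
    mt <- marginal_tree(fx$arg, s)
    hi <- mt$branches$parent_time[match(node, mt$branches$child)]
    expect_true(a < hi)
    expect_equal(a, (lo + hi) / 2)
    a2 <- allele_age(fx$arg, s, method = "sample")
    expect_true(a2 > lo && a2 < hi)
  }
})

test_that("TSV serialization round-trips and newick export parses", {
  fx <- fix_arg(5, 10000, 3)
  pre <- file.path(tempdir(), "argtest")
  write_arg_tables(fx$arg, pre)
  back <- read_arg_tables(pre)
  expect_equal(back$edges, fx$arg$edges)
  expect_equal(back$nodes$time, fx$arg$nodes$time)
  expect_equal(back$mutations$position, fx$arg$mutations$position)
  expect_true(validate_arg(back))
  phy <- ape::read.tree(text = marginal_newick(fx$arg, 5000))
  expect_equal(ape::Ntip(phy), 5)
  ## total branch depth equals root time for every tip
  d <- ape::node.depth.edgelength(phy)
  expect_true(max(abs(d[1:5] - max(d))) < 1e-3)
})

test_that("validation rejects corrupt tables", {
  fx <- fix_arg(5, 10000, 3)
  bad <- fx$arg
  bad$nodes$time[bad$nodes$id == bad$edges$parent[1]] <- -1
  expect_error(validate_arg(bad))
  bad2 <- fx$arg
  bad2$mutations <- rbind(bad2$mutations, bad2$mutations[1, ])
  expect_error(validate_arg(bad2), "mutation")
})
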