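test_that("UPGMA node heights are half the join distance", {
  d2 <- matrix(c(0, 0.02, 0.02, 0), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  tr <- upgma_tree(d2)
  expect_equal(max(tr$heights$height), 0.01)

  d3 <- matrix(c(0, 0.02, 0.10,
                 0.02, 0, 0.10,
                 0.10, 0.10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma_tree(d3)
  expect_equal(sort(tr3$heights$height), c(0.01, 0.05))
})

test_that("UPGMA agrees with an independent average-linkage
           implementation", {
  set.seed(31)
  aln <- hap_alignment(paste0("t", 1:6), mutated_family(6, 200, 15))
  d <- k2p_matrix(aln)
  ours <- upgma_tree(d)
  ref <- phangorn::upgma(as.dist(d))
  expect_equal(sort(ours$heights$height),
               sort(unname(ape::branching.times(ref))), tolerance = 1e-10)
  expect_true(ape::all.equal.phylo(ours$phylo, ref,
                                   use.edge.length = FALSE))
})

test_that("clock trees are ultrametric with child below parent", {
  set.seed(32)
  aln <- hap_alignment(paste0("t", 1:8), mutated_family(8, 150, 12))
  tr <- upgma_tree(k2p_matrix(aln))
  expect_true(ape::is.ultrametric(tr$phylo, tol = 1e-8))
  # every internal node's height exceeds its children's heights
  ph <- tr$phylo
  depth <- ape::node.depth.edgelength(ph)
  height <- max(depth) - depth
  for (e in seq_len(nrow(ph$edge))) {
    expect_gte(height[ph$edge[e, 1]] + 1e-12, height[ph$edge[e, 2]])
  }
})

test_that("identical sequences collapse to a star at height zero", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- upgma_tree(d)
  expect_equal(max(tr$heights$height), 0)
})

test_that("ages scale inversely with rate and monotonically across the
           grid", {
  d3 <- matrix(c(0, 0.008, 0.10,
                 0.008, 0, 0.10,
                 0.10, 0.10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d3)
  ages <- ages_from_rates(tr, rates = c(0.03, 0.05, 0.10, 0.20, 0.40))
  # pairwise divergence 0.8% at 5%/Myr -> 0.16 Ma
  shallow <- ages[ages$height == min(ages$height), ]
  expect_equal(shallow$age_ma[shallow$rate == 0.05], 0.16,
               tolerance = 1e-12)
  # doubling the rate halves the age, exactly
  expect_equal(shallow$age_ma[shallow$rate == 0.10],
               shallow$age_ma[shallow$rate == 0.05] / 2, tolerance = 1e-12)
  # monotone decreasing along every node's row
  by_node <- split(ages, ages$node)
  for (tbl in by_node) {
    expect_true(all(diff(tbl$age_ma[order(tbl$rate)]) <= 0))
  }
  # per-lineage convention is exactly half the pairwise-divergence age
  ages_pl <- ages_from_rates(tr, rates = 0.05, per_lineage = TRUE)
  expect_equal(ages_pl$age_ma,
               ages$age_ma[ages$rate == 0.05] / 2, tolerance = 1e-12)
  # zero-height nodes date to zero
  d0 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(ages_from_rates(upgma_tree(d0), rates = 0.05)$age_ma, 0)
})

test_that("single-point calibration reproduces the calibration age
           exactly and scales other nodes proportionally", {
  d3 <- matrix(c(0, 0.02, 0.10,
                 0.02, 0, 0.10,
                 0.10, 0.10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d3)
  cal <- calibrate(tr, data.frame(tip_a = "A", tip_b = "C", age_ma = 1.7))
  expect_equal(max(cal$ages$age_ma), 1.7, tolerance = 1e-12)
  expect_equal(min(cal$ages$age_ma), 1.7 * 0.01 / 0.05, tolerance = 1e-12)
  expect_equal(cal$residual, 0, tolerance = 1e-12)
})

test_that("consistent multi-point calibrations fit exactly; conflicting
           ones take the least-squares compromise", {
  d3 <- matrix(c(0, 0.02, 0.10,
                 0.02, 0, 0.10,
                 0.10, 0.10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d3)
  consistent <- data.frame(tip_a = c("A", "A"), tip_b = c("C", "B"),
                           age_ma = c(1.0, 0.2))  # heights 0.05 / 0.01
  cal <- calibrate(tr, consistent)
  expect_equal(cal$residual, 0, tolerance = 1e-12)
  expect_equal(cal$scale, 20)

  conflicting <- data.frame(tip_a = c("A", "A"), tip_b = c("C", "B"),
                            age_ma = c(1.0, 0.5))
  cal2 <- calibrate(tr, conflicting)
  # closed-form weighted regression through the origin
  h <- c(0.05, 0.01); a <- c(1.0, 0.5)
  s <- sum(h * a) / sum(h^2)
  expect_equal(cal2$scale, s, tolerance = 1e-12)
  expect_gt(cal2$residual, 0)

  expect_error(calibrate(tr, data.frame(tip_a = "A", tip_b = "Z",
                                        age_ma = 1)), "Z")
})

test_that("newick and ages writers produce readable output", {
  d3 <- matrix(c(0, 0.02, 0.10,
                 0.02, 0, 0.10,
                 0.10, 0.10, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d3)
  nwk <- tempfile(fileext = ".nwk")
  write_clock_tree(tr, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, c("A", "B", "C"))

  ages <- ages_from_rates(tr)
  path <- tempfile(fileext = ".tsv")
  write_ages(ages, path)
  wide <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(wide), 2L)
  expect_true("rate_5%" %in% names(wide))
})
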