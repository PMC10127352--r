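# Brute-force minimal Steiner cost over a constrained candidate space: all
# sequences whose character at each position is one of the observed
# characters there, adding up to `max_extra` of them and taking the minimum
# spanning cost. Exact for the small cases used here.
oracle_steiner_cost <- function(seqs, max_extra = 2) {
  chars <- sapply(strsplit(seqs, ""), identity)
  per_site <- apply(chars, 1, function(col) unique(col), simplify = FALSE)
  grid <- expand.grid(per_site, stringsAsFactors = FALSE)
  cands <- setdiff(apply(grid, 1, paste0, collapse = ""), seqs)
  ham <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  cost_of <- function(set) {
    n <- length(set)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- ham(set[i], set[j])
    }
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }
  best <- cost_of(seqs)
  for (k in seq_len(max_extra)) {
    for (pick in utils::combn(length(cands), k, simplify = FALSE)) {
      best <- min(best, cost_of(c(seqs, cands[pick])))
    }
  }
  best
}

test_that("hamming matrix matches a per-site loop oracle", {
  expect_equal(hamming_matrix(c(a = "AAA", b = "AAA"))["a", "b"], 0)
  expect_equal(hamming_matrix(c(a = "AAA", b = "ATA"))["a", "b"], 1)
  set.seed(14)
  seqs <- stats::setNames(random_seqs(10, 25), paste0("h", 1:10))
  d <- hamming_matrix(seqs)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d[i, j],
                 sum(strsplit(seqs[i], "")[[1]] !=
                       strsplit(seqs[j], "")[[1]]))
  }
  expect_equal(d, t(d))
})

test_that("minimum spanning network is the union of all MSTs", {
  # three haplotypes at mutual distance 2: all three edges tie
  tri <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"),
                                         c("a", "b", "c")))
  diag(tri) <- 0
  net <- minimum_spanning_network(tri)
  expect_equal(nrow(net$edges), 3L)

  # chain: unique MST, no extra edge
  chain <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
                  dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  net2 <- minimum_spanning_network(chain)
  expect_equal(nrow(net2$edges), 2L)
  expect_false(any(net2$edges$weight > 1))

  # single haplotype: one node, no edges
  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  net3 <- minimum_spanning_network(one)
  expect_equal(nrow(net3$nodes), 1L)
  expect_equal(nrow(net3$edges), 0L)

  # epsilon relaxation admits near-minimal edges
  net4 <- minimum_spanning_network(chain, epsilon = 1)
  expect_equal(nrow(net4$edges), 3L)
})

test_that("the canonical three-haplotype triple gains exactly one median
           vector and reaches the Steiner optimum", {
  seqs <- c(h1 = "AAA", h2 = "GGA", h3 = "AGG")  # 000 / 110 / 011
  net <- median_joining(seqs)
  expect_equal(sum(net$nodes$type == "median"), 1L)
  expect_equal(net$nodes$sequence[net$nodes$type == "median"], "AGA")
  expect_equal(network_cost(net), 3)
  expect_equal(network_cost(net), oracle_steiner_cost(unname(seqs)))
})

test_that("two haplotypes connect by a single edge with no medians", {
  net <- median_joining(c(a = "AATTA", b = "AACTA"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1)
  expect_equal(sum(net$nodes$type == "median"), 0L)
})

test_that("star-like data with an observed centre needs no median
           vectors", {
  fx <- make_fixture("star")
  net <- median_joining(fx$alignment)
  expect_equal(sum(net$nodes$type == "median"), 0L)
  expect_equal(nrow(net$edges), 5L)
  expect_true(all(net$edges$weight == 1))
  # the observed centre is already Steiner-optimal (exhaustive check is
  # infeasible over 549 sites, but every satellite is 1 step from the
  # centre so cost 5 is a lower bound: one edge per additional node)
  expect_equal(network_cost(net), 5)
})

test_that("every observed haplotype appears exactly once and specimen
           counts are carried onto nodes", {
  fx <- make_fixture("table4_like")
  tab <- collapse_haplotypes(fx$alignment)
  net <- median_joining(tab)
  obs <- net$nodes[net$nodes$type == "observed", ]
  expect_setequal(obs$name, tab$haplotypes$haplotype_id)
  expect_equal(obs$count[match(tab$haplotypes$haplotype_id, obs$name)],
               tab$haplotypes$n_total)
})

test_that("network cost never exceeds the MST cost of the observed
           haplotypes and matches the brute-force Steiner oracle on small
           cases", {
  set.seed(23)
  for (rep in 1:4) {
    # binary character states keep the exhaustive oracle space small
    seqs <- unique(vapply(1:5, function(i) {
      paste0(sample(c("A", "G"), 6, replace = TRUE), collapse = "")
    }, ""))
    names(seqs) <- paste0("h", seq_along(seqs))
    net <- median_joining(seqs)
    d <- hamming_matrix(seqs)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    mst_cost <- sum(igraph::E(igraph::mst(g))$weight)
    expect_lte(network_cost(net), mst_cost)
    # greedy MJ is allowed a gap, but on these tiny cases it should be at
    # or very near the exhaustive optimum
    expect_lte(network_cost(net),
               oracle_steiner_cost(unname(seqs), max_extra = 2) + 1)
  }
})

test_that("median joining is order-invariant for untied inputs", {
  seqs <- c(h1 = "AAAAA", h2 = "GAAAA", h3 = "GGAAA", h4 = "GGGTA")
  n1 <- median_joining(seqs)
  n2 <- median_joining(rev(seqs))
  expect_setequal(n1$nodes$sequence, n2$nodes$sequence)
  expect_equal(network_cost(n1), network_cost(n2))
})

test_that("GraphML and GML exports load back with attributes", {
  fx <- make_fixture("star")
  net <- median_joining(fx$alignment)
  gpath <- tempfile(fileext = ".graphml")
  write_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_true("mutations" %in% igraph::edge_attr_names(g))
  expect_true("count" %in% igraph::vertex_attr_names(g))
  gml <- tempfile(fileext = ".gml")
  write_network(net, gml, "gml")
  expect_gt(file.size(gml), 0)
})
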