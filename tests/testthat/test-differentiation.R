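# Brute-force one-level AMOVA oracle computed term by term from a delta
# matrix, independent of the package implementation.
oracle_amova <- function(delta, pop) {
  N <- length(pop); K <- length(unique(pop))
  tot <- 0
  for (i in 1:N) for (j in 1:N) tot <- tot + delta[i, j]
  ssd_total <- tot / (2 * N)
  ssd_within <- 0
  for (g in unique(pop)) {
    idx <- which(pop == g); acc <- 0
    for (i in idx) for (j in idx) acc <- acc + delta[i, j]
    ssd_within <- ssd_within + acc / (2 * length(idx))
  }
  ms_a <- (ssd_total - ssd_within) / (K - 1)
  ms_w <- ssd_within / (N - K)
  np <- (N - sum(table(pop)^2) / N) / (K - 1)
  s2a <- (ms_a - ms_w) / np
  s2a / (s2a + ms_w)
}

test_that("complete fixation between demes gives Phi-st of exactly 1", {
  fx <- make_fixture("two_pop_fixed")
  res <- amova_phi(fx$alignment, metric = "differences")
  expect_equal(res$phi, 1)
  expect_equal(res$sigma2_within, 0)
  expect_equal(res$df_among, 1L)
  expect_equal(res$df_within, 2L)
  # hand AMOVA on the 0/1 metric: SSD_total = 1, sigma2_among = 0.5
  res_f <- amova_phi(fx$alignment, metric = "frequency")
  expect_equal(res_f$ssd_total, 1)
  expect_equal(res_f$sigma2_among, 0.5)
  expect_equal(res_f$phi, 1)
})

test_that("two samples from one urn give Phi-st of zero", {
  aln <- hap_alignment(paste0("s", 1:6), rep("ACGTACGT", 6),
                       population = rep(c("p1", "p2"), each = 3))
  expect_equal(amova_phi(aln, "differences")$phi, 0)
})

test_that("AMOVA matches the termwise brute-force oracle on 3+3 specimens
           with an arbitrary delta structure", {
  set.seed(33)
  seqs <- mutated_family(6, 40, 4)
  aln <- hap_alignment(paste0("s", 1:6), seqs,
                       population = rep(c("p1", "p2"), each = 3))
  for (metric in c("differences", "frequency", "k2p")) {
    delta <- delta_matrix(aln, metric)
    expect_equal(amova_phi(aln, metric)$phi,
                 oracle_amova(delta, aln$population), tolerance = 1e-12)
  }
})

test_that("negative estimates near zero differentiation are reported
           as-is", {
  set.seed(44)
  seqs <- sample(random_seqs(3, 50), 12, replace = TRUE)
  aln <- hap_alignment(paste0("s", 1:12), seqs,
                       population = rep(c("p1", "p2"), 6))
  phi <- amova_phi(aln, "differences")$phi
  expect_true(is.finite(phi))
  expect_lt(abs(phi), 0.5)  # panmictic draw: near zero, sign unconstrained
})

test_that("Phi is invariant under global scaling of delta", {
  set.seed(55)
  seqs <- random_seqs(8, 30)
  aln <- hap_alignment(paste0("s", 1:8), seqs,
                       population = rep(c("p1", "p2"), each = 4))
  delta <- delta_matrix(aln, "differences")
  phi1 <- oracle_amova(delta, aln$population)
  phi2 <- oracle_amova(delta * 7.3, aln$population)
  expect_equal(phi1, phi2, tolerance = 1e-12)
})

test_that("exhaustive permutation p matches full enumeration and the
           Monte-Carlo estimate agrees within binomial error", {
  fx <- make_fixture("two_pop_fixed")
  ex <- permutation_p(fx$alignment, "differences", exhaustive = TRUE)
  expect_equal(ex$p, 2 / 6, tolerance = 1e-12)
  expect_equal(ex$n_perm, 6L)

  mc <- permutation_p(fx$alignment, "differences", n_perm = 2000,
                      seed = 17)
  se <- sqrt(ex$p * (1 - ex$p) / 2000)
  expect_lt(abs(mc$p - ex$p), 3 * se + 1 / 2001)

  mc2 <- permutation_p(fx$alignment, "differences", n_perm = 2000,
                       seed = 17)
  expect_equal(mc$p, mc2$p)  # deterministic under seed
})

test_that("identical populations give p near 1", {
  aln <- hap_alignment(paste0("s", 1:8),
                       rep(c("ACGTACGT", "ACGAACGT"), 4),
                       population = rep(c("p1", "p2"), each = 4))
  p <- permutation_p(aln, "differences", n_perm = 500, seed = 3)$p
  expect_gt(p, 0.5)
})

test_that("pairwise differentiation fills the mixed-triangle layout and
           permutes consistently under relabelling", {
  set.seed(66)
  cfg <- sim_config(n_demes = 3, sample_sizes = c(4, 4, 4), theta = 0.01,
                    migration = 2, seq_length = 200, seed = 90)
  aln <- simulate_dataset(cfg)$alignment
  dm <- pairwise_differentiation(aln, "differences", n_perm = 200,
                                 seed = 12)
  expect_s3_class(dm, "hap_differentiation")
  td <- tidy(dm)
  expect_equal(nrow(td), 3L)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  expect_true(all(is.na(dm$stat[upper.tri(dm$stat)])))

  # relabelling oracle: permuting population names permutes the statistics
  relab <- c(deme1 = "B", deme2 = "C", deme3 = "A")
  aln2 <- hap_alignment(aln$id, aln$sequence,
                        population = unname(relab[aln$population]))
  dm2 <- pairwise_differentiation(aln2, "differences", n_perm = 200,
                                  seed = 12)
  t1 <- tidy(dm); t2 <- tidy(dm2)
  key1 <- apply(cbind(relab[t1$pop1], relab[t1$pop2]), 1,
                function(r) paste(sort(r), collapse = "~"))
  key2 <- paste(pmin(t2$pop1, t2$pop2), pmax(t2$pop1, t2$pop2), sep = "~")
  expect_equal(t1$statistic[order(key1)], t2$statistic[order(key2)],
               tolerance = 1e-12)
})

test_that("fixed fixture puts the statistic 1.0 in the lower triangle and
           the writer mirrors the table layout", {
  fx <- make_fixture("two_pop_fixed")
  dm <- pairwise_differentiation(fx$alignment, "differences",
                                 n_perm = 100, seed = 2)
  expect_equal(dm$stat[2, 1], 1)
  path <- tempfile(); longp <- tempfile()
  write_differentiation(dm, path, long = longp)
  tab <- read.delim(path, row.names = 1)
  expect_equal(tab["pop2", "pop1"], 1)
  expect_true(tab["pop1", "pop2"] >= 0 && tab["pop1", "pop2"] <= 1)
  expect_equal(nrow(read.delim(longp)), 1L)
})

test_that("frequency and differences metrics coincide when all distinct
           haplotypes are equidistant", {
  # three haplotypes, all pairs differ at exactly 2 sites
  seqs <- c("AAAA", "GGAA", "GAGA")
  aln <- hap_alignment(paste0("s", 1:6), rep(seqs, 2),
                       population = rep(c("p1", "p2"), each = 3))
  phi_f <- amova_phi(aln, "frequency")$phi
  phi_d <- amova_phi(aln, "differences")$phi
  expect_equal(phi_f, phi_d, tolerance = 1e-12)
})

test_that("undersized populations are rejected", {
  aln <- hap_alignment(paste0("s", 1:3), random_seqs(3, 10),
                       population = c("p1", "p1", "p2"))
  expect_error(amova_phi(aln, "differences"), "fewer than 2")
})
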