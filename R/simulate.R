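# Structured-coalescent simulator for haploid (mitochondrial) sequence
# data. Time is in coalescent units (N generations for a haploid
# population): two lineages in one deme coalesce at rate 1, so E[T2] = 1.
# Migration follows the island model: each lineage migrates at rate M and
# picks a destination deme uniformly. Mutations are laid on branches as a
# Poisson process with mean theta/2 * branch_length * seq_length, each
# mutation hitting a uniform site and being a transition with probability
# kappa/(kappa + 1).

#' Simulation configuration
#'
#' Defaults emulate a small-mammal mtDNA survey: four demes with uneven
#' sample sizes summing to 43 specimens, a 549-bp fragment, low within-
#' population diversity (theta per site 0.001; island-model structure
#' inflates within-deme coalescence times roughly K-fold, so expected
#' within-population nucleotide diversity is a few tenths of a percent)
#' and strong transition bias.
#'
#' @param n_demes Number of demes (island model).
#' @param sample_sizes Integer vector of per-deme sample sizes.
#' @param theta Scaled mutation rate per site.
#' @param migration Scaled migration rate M per lineage (0 = isolated demes;
#'   large M approaches panmixia).
#' @param seq_length Number of sites.
#' @param kappa Transition/transversion event ratio (transition probability
#'   `kappa/(kappa+1)` per mutation).
#' @param seed Integer seed; one seed drives genealogy then mutations, in
#'   that order, on R's default RNG stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 4, sample_sizes = c(3, 7, 17, 16),
                       theta = 0.001, migration = 10, seq_length = 549,
                       kappa = 10, seed = 1) {
  stopifnot(n_demes >= 1, length(sample_sizes) == n_demes,
            all(sample_sizes >= 1), theta >= 0, migration >= 0,
            seq_length >= 1, kappa > 0)
  if (n_demes > 1 && migration == 0) {
    stop("migration must be positive when n_demes > 1 (lineages in ",
         "isolated demes never coalesce)")
  }
  structure(list(n_demes = as.integer(n_demes),
                 sample_sizes = as.integer(sample_sizes),
                 theta = theta, migration = migration,
                 seq_length = as.integer(seq_length),
                 kappa = kappa, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured-coalescent genealogy
#'
#' Event-driven Kingman coalescent within demes with island-model migration.
#' Uses the current RNG state (seed management belongs to
#' [simulate_dataset()]).
#'
#' @param config A [sim_config()].
#' @return An object of class `genealogy`: list with `nodes` (tibble `node`,
#'   `parent`, `time`, `tip`, `label`, `deme`) and `n_tips`. Tips are nodes
#'   `1..n` at time 0; the root has `parent = NA`.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- sum(config$sample_sizes)
  deme_of <- rep(seq_len(config$n_demes), config$sample_sizes)
  node <- seq_len(n)
  parent <- rep(NA_integer_, 2L * n - 1L)
  time <- rep(0, 2L * n - 1L)
  tip_deme <- c(deme_of, rep(NA_integer_, n - 1L))
  active <- node                  # currently uncoalesced lineage node-ids
  active_deme <- deme_of
  t <- 0
  next_node <- n
  M <- config$migration
  while (length(active) > 1L) {
    k_per <- tabulate(active_deme, nbins = config$n_demes)
    coal_rates <- k_per * (k_per - 1) / 2
    mig_rate <- if (config$n_demes > 1L) M * length(active) else 0
    total <- sum(coal_rates) + mig_rate
    t <- t + stats::rexp(1L, rate = total)
    if (stats::runif(1L) < mig_rate / total) {
      i <- sample.int(length(active), 1L)
      dest <- sample.int(config$n_demes - 1L, 1L)
      if (dest >= active_deme[i]) dest <- dest + 1L
      active_deme[i] <- dest
    } else {
      deme <- sample.int(config$n_demes, 1L, prob = coal_rates)
      idx <- which(active_deme == deme)
      pair <- idx[sample.int(length(idx), 2L)]
      next_node <- next_node + 1L
      parent[active[pair]] <- next_node
      time[next_node] <- t
      tip_deme[next_node] <- deme
      active <- c(active[-pair], next_node)
      active_deme <- c(active_deme[-pair], deme)
    }
  }
  nodes <- tibble::tibble(
    node = seq_len(2L * n - 1L),
    parent = parent,
    time = time,
    tip = seq_len(2L * n - 1L) <= n,
    label = c(paste0("s", seq_len(n)), rep(NA_character_, n - 1L)),
    deme = tip_deme
  )
  structure(list(nodes = nodes, n_tips = n), class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d tips, TMRCA %.3f coalescent units\n",
              x$n_tips, max(x$nodes$time)))
  invisible(x)
}

#' Convert a genealogy to an ape phylo tree
#' @param genealogy A `genealogy`.
#' @return An `ape::phylo` object with branch lengths in coalescent units.
#' @export
genealogy_to_phylo <- function(genealogy) {
  nd <- genealogy$nodes
  newick <- build_newick(nd, which(is.na(nd$parent)))
  ape::read.tree(text = paste0(newick, ";"))
}

build_newick <- function(nd, node) {
  children <- which(nd$parent == node)
  blen <- function(ch) nd$time[node] - nd$time[ch]
  if (!length(children)) return(nd$label[node])
  parts <- vapply(children, function(ch) {
    sprintf("%s:%.8f", build_newick(nd, ch), blen(ch))
  }, "")
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Drop mutations on a genealogy and return the alignment
#'
#' Poisson(theta/2 x branch length x seq_length) mutations per branch;
#' mutated sites are uniform, transitions chosen with probability
#' `kappa/(kappa+1)`, the two possible transversions equiprobable
#' otherwise. The root sequence is uniform over A/C/G/T.
#'
#' @param genealogy A `genealogy`.
#' @param theta Scaled mutation rate per site.
#' @param kappa Transition/transversion event ratio.
#' @param seq_length Number of sites.
#' @return A [hap_alignment()] with populations `deme1..demeK`.
#' @export
mutate_sequences <- function(genealogy, theta, kappa, seq_length) {
  nd <- genealogy$nodes
  n <- genealogy$n_tips
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  root <- which(is.na(nd$parent))
  seqs <- vector("list", nrow(nd))
  seqs[[root]] <- sample(UNAMBIGUOUS, seq_length, replace = TRUE)
  # preorder: parents before children (decreasing time)
  order_nodes <- order(nd$time, decreasing = TRUE)
  for (v in order_nodes) {
    if (v == root) next
    s <- seqs[[nd$parent[v]]]
    blen <- nd$time[nd$parent[v]] - nd$time[v]
    n_mut <- stats::rpois(1L, theta / 2 * blen * seq_length)
    if (n_mut > 0L) {
      sites <- sample.int(seq_length, n_mut, replace = TRUE)
      is_ts <- stats::runif(n_mut) < kappa / (kappa + 1)
      for (m in seq_len(n_mut)) {
        base <- s[sites[m]]
        s[sites[m]] <- if (is_ts[m]) {
          transition[[base]]
        } else {
          sample(transversions[[base]], 1L)
        }
      }
    }
    seqs[[v]] <- s
  }
  tips <- seq_len(n)
  hap_alignment(nd$label[tips],
                vapply(seqs[tips], paste0, "", collapse = ""),
                population = paste0("deme", nd$deme[tips]))
}

#' Simulate a complete aligned dataset with known parameters
#'
#' Sets the RNG from `config$seed`, simulates the genealogy, then drops
#' mutations (in that order, one stream).
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset`: list with `alignment`,
#'   `genealogy` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen <- simulate_genealogy(config)
  aln <- mutate_sequences(gen, config$theta, config$kappa, config$seq_length)
  structure(list(alignment = aln, genealogy = gen, config = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' FASTA alignment, popmap TSV and a JSON file with the true parameters.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(dataset$alignment, file.path(dir, "alignment.fasta"))
  write_popmap(dataset$alignment, file.path(dir, "popmap.tsv"))
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "true_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Deterministic planted fixtures
#'
#' Small hand-constructed datasets with known downstream answers:
#' \describe{
#'   \item{table4_like}{One locality, two species. Species A: 7 specimens in
#'     3 haplotypes with counts 5/1/1 and pairwise differences 1/1/2 sites
#'     (H = 0.524). Species B: 3 singleton haplotypes (H = 1). 549 bp.}
#'   \item{two_pop_fixed}{Two demes of 2 specimens, each fixed for its own
#'     haplotype 5 sites apart: complete differentiation (Phi-st = 1).}
#'   \item{star}{One central haplotype (5 specimens) with 5 one-step
#'     satellites: the median-joining network adds no median vectors.}
#' }
#'
#' @param profile One of `"table4_like"`, `"two_pop_fixed"`, `"star"`.
#' @return A list with `alignment` and `profile`.
#' @export
make_fixture <- function(profile = c("table4_like", "two_pop_fixed",
                                     "star")) {
  profile <- match.arg(profile)
  base <- fixture_base_sequence(549L)
  flip <- function(s, sites) {
    ch <- strsplit(s, "")[[1L]]
    swap <- c(A = "G", G = "A", C = "T", T = "C")   # transition at site
    ch[sites] <- swap[ch[sites]]
    paste0(ch, collapse = "")
  }
  aln <- switch(profile,
    table4_like = {
      h1 <- base
      h2 <- flip(base, 10L)            # 1 diff to h1
      h3 <- flip(base, 20L)            # 1 diff to h1, 2 to h2
      spB <- flip(base, seq(5L, 545L, by = 15L))   # distinct species B core
      b1 <- spB; b2 <- flip(spB, 101L); b3 <- flip(spB, 202L)
      hap_alignment(
        paste0("s", 1:10),
        c(rep(h1, 5), h2, h3, b1, b2, b3),
        population = "locality1",
        species = c(rep("speciesA", 7), rep("speciesB", 3))
      )
    },
    two_pop_fixed = {
      h1 <- base
      h2 <- flip(base, c(3L, 60L, 120L, 240L, 480L))
      hap_alignment(paste0("s", 1:4), c(h1, h1, h2, h2),
                    population = c("pop1", "pop1", "pop2", "pop2"),
                    species = "speciesA")
    },
    star = {
      center <- base
      sats <- vapply(c(30L, 90L, 150L, 210L, 270L),
                     function(p) flip(base, p), "")
      hap_alignment(paste0("s", 1:10),
                    c(rep(center, 5), sats),
                    population = "locality1", species = "speciesA")
    }
  )
  list(alignment = aln, profile = profile)
}

# Deterministic, RNG-free pseudo-random base sequence.
fixture_base_sequence <- function(len) {
  idx <- (seq_len(len) * 7L + (seq_len(len)^2L) %% 13L) %% 4L + 1L
  paste0(UNAMBIGUOUS[idx], collapse = "")
}
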