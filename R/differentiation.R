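# Pairwise population differentiation by one-level AMOVA on specimen-level
# pairwise distances. With the 0/1 haplotype-identity metric the statistic
# is the haplotype-frequency Fst; with site-difference counts it is the
# distance-based Phi-st. Significance by permutation of specimens between
# the two populations.

#' Specimen-level distance matrix for a chosen metric
#'
#' @param alignment A [hap_alignment()].
#' @param metric `"frequency"` (0/1 by haplotype identity, giving Fst),
#'   `"differences"` (count of differing sites, giving Phi-st) or `"k2p"`.
#' @return A symmetric labelled matrix.
#' @export
delta_matrix <- function(alignment,
                         metric = c("differences", "frequency", "k2p")) {
  metric <- match.arg(metric)
  seqs <- align_sequences(alignment)
  switch(metric,
    frequency = {
      eq <- outer(seqs, seqs, "==")
      d <- 1 - eq * 1
      dimnames(d) <- list(names(seqs), names(seqs))
      diag(d) <- 0
      d
    },
    differences = hamming_matrix(seqs),
    k2p = k2p_matrix(seqs)
  )
}

# Core one-level AMOVA from a precomputed squared-distance analogue.
# delta: full symmetric matrix over specimens; pop: population factor.
amova_components <- function(delta, pop) {
  pop <- as.character(pop)
  N <- length(pop)
  sizes <- table(pop)
  K <- length(sizes)
  if (K < 2L) stop("need at least 2 populations")
  if (any(sizes < 2L)) {
    stop("populations with fewer than 2 specimens: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  ssd_total <- sum(delta) / (2 * N)
  ssd_within <- 0
  for (k in names(sizes)) {
    idx <- which(pop == k)
    ssd_within <- ssd_within + sum(delta[idx, idx]) / (2 * length(idx))
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- K - 1L
  df_within <- N - K
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n_prime <- (N - sum(sizes^2) / N) / (K - 1L)
  sigma2_within <- ms_within
  sigma2_among <- (ms_among - ms_within) / n_prime
  denom <- sigma2_among + sigma2_within
  phi <- if (denom > 0) sigma2_among / denom else 0
  list(ssd_total = ssd_total, ssd_among = ssd_among,
       ssd_within = ssd_within, df_among = df_among, df_within = df_within,
       n_prime = n_prime, sigma2_among = sigma2_among,
       sigma2_within = sigma2_within, phi = phi)
}

#' One-level AMOVA differentiation statistic
#'
#' Partitions the sum of squared distances between specimens into among- and
#' within-population components and returns the fixation index
#' `phi = sigma2_among / (sigma2_among + sigma2_within)`. Negative estimates
#' (sampling noise around zero differentiation) are reported as-is.
#'
#' @param alignment A [hap_alignment()] with population labels (each
#'   population needs at least 2 specimens).
#' @param metric See [delta_matrix()]; `"frequency"` yields Fst,
#'   `"differences"` yields Phi-st.
#' @return An object of class `hap_amova` with variance components, degrees
#'   of freedom, the average-sample-size coefficient `n_prime` and `phi`.
#' @examples
#' aln <- hap_alignment(paste0("s", 1:4), c("AAA", "AAA", "TTT", "TTT"),
#'                      population = c("p1", "p1", "p2", "p2"))
#' amova_phi(aln, metric = "frequency")$phi  # 1: complete differentiation
#' @export
amova_phi <- function(alignment,
                      metric = c("differences", "frequency", "k2p")) {
  metric <- match.arg(metric)
  delta <- delta_matrix(alignment, metric)
  res <- amova_components(delta, alignment$population)
  res$metric <- metric
  class(res) <- "hap_amova"
  res
}

#' @export
print.hap_amova <- function(x, ...) {
  cat(sprintf("<hap_amova> metric=%s  phi=%.4f\n", x$metric, x$phi))
  cat(sprintf("  sigma2 among=%.4g within=%.4g  df=%d/%d  n'=%.3f\n",
              x$sigma2_among, x$sigma2_within, x$df_among, x$df_within,
              x$n_prime))
  invisible(x)
}

#' Permutation p-value for a two-population differentiation statistic
#'
#' Specimens are shuffled between the two populations (sizes preserved) and
#' the statistic recomputed. The Monte-Carlo p-value uses the add-one
#' convention `p = (1 + #[perm >= obs]) / (1 + n_perm)`; ties count as
#' exceeding. With `exhaustive = TRUE` all distinct assignments are
#' enumerated and `p = #[perm >= obs] / n_assignments`.
#'
#' @param alignment A [hap_alignment()] with exactly 2 populations.
#' @param metric See [delta_matrix()].
#' @param n_perm Number of random permutations (ignored when exhaustive).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all assignments (feasible for small samples).
#' @return A list with `p`, `observed` (phi), `n_perm` and `exhaustive`.
#' @export
permutation_p <- function(alignment,
                          metric = c("differences", "frequency", "k2p"),
                          n_perm = 10000, seed = NULL, exhaustive = FALSE) {
  metric <- match.arg(metric)
  pop <- alignment$population
  if (length(unique(pop)) != 2L) stop("permutation test is pairwise: need exactly 2 populations")
  delta <- delta_matrix(alignment, metric)
  obs <- amova_components(delta, pop)$phi
  N <- length(pop)
  labels <- sort(unique(pop))
  n1 <- sum(pop == labels[1L])
  if (exhaustive) {
    picks <- utils::combn(N, n1)
    stats <- apply(picks, 2L, function(idx) {
      perm <- rep(labels[2L], N)
      perm[idx] <- labels[1L]
      amova_components(delta, perm)$phi
    })
    p <- sum(stats >= obs - 1e-12) / ncol(picks)
    n_used <- ncol(picks)
  } else {
    stopifnot(n_perm >= 1)
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample(pop)
      if (amova_components(delta, perm)$phi >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  list(p = p, observed = obs, n_perm = n_used, exhaustive = exhaustive)
}

#' Pairwise population differentiation matrix with permutation p-values
#'
#' Computes the differentiation statistic and its permutation significance
#' for every pair of populations. The result mirrors the mixed-triangle
#' convention of population-genetics tables: statistic in the lower
#' triangle, p-value in the upper.
#'
#' @param alignment A [hap_alignment()] with population labels (every
#'   population needs at least 2 specimens).
#' @param metric See [delta_matrix()].
#' @param n_perm Permutations per pair (default 10000).
#' @param seed Integer seed driving all permutations.
#' @return An object of class `hap_differentiation`: list with `populations`,
#'   `stat` and `pvalue` matrices, `metric`, `n_permutations`, `seed`.
#' @export
pairwise_differentiation <- function(alignment,
                                     metric = c("differences", "frequency",
                                                "k2p"),
                                     n_perm = 10000, seed = 1) {
  metric <- match.arg(metric)
  pops <- unique(alignment$population[!is.na(alignment$population)])
  if (length(pops) < 2L) stop("need at least 2 populations")
  K <- length(pops)
  stat <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  pval <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      sub <- subset_alignment(alignment,
                              alignment$population %in% pops[c(i, j)])
      res <- permutation_p(sub, metric = metric, n_perm = n_perm,
                           seed = NULL)
      stat[j, i] <- res$observed
      pval[i, j] <- res$p
    }
  }
  structure(list(populations = pops, stat = stat, pvalue = pval,
                 metric = metric, n_permutations = n_perm, seed = seed),
            class = "hap_differentiation")
}

#' @export
print.hap_differentiation <- function(x, ...) {
  cat(sprintf(
    "<hap_differentiation> metric=%s, %d populations, %d permutations\n",
    x$metric, length(x$populations), x$n_permutations))
  print(mixed_triangle(x), digits = 4)
  invisible(x)
}

# Statistic bottom-left, p-value top-right, in one matrix.
mixed_triangle <- function(x) {
  m <- x$stat
  m[upper.tri(m)] <- x$pvalue[upper.tri(x$pvalue)]
  diag(m) <- NA
  m
}

#' Write a differentiation result
#'
#' Writes the mixed-triangle table (statistic bottom-left, significance
#' top-right) and, optionally, a tidy long-format file.
#'
#' @param x A `hap_differentiation`.
#' @param path Output TSV path for the mixed-triangle table.
#' @param long Optional path for the long-format table.
#' @param percent Write the statistic multiplied by 100.
#' @return `path`, invisibly.
#' @export
write_differentiation <- function(x, path, long = NULL, percent = FALSE) {
  m <- mixed_triangle(x)
  if (percent) m[lower.tri(m)] <- m[lower.tri(m)] * 100
  utils::write.table(cbind(population = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long)) {
    utils::write.table(tidy.hap_differentiation(x), long, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
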