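# Nei diversity statistics: haplotype diversity H with the small-sample
# n/(n-1) correction, and nucleotide diversity pi as the unbiased expected
# per-site difference between two randomly drawn sequences.

#' Nei haplotype (gene) diversity
#'
#' `H = n/(n-1) * (1 - sum(p_i^2))` with `p_i` the haplotype relative
#' frequencies: the (bias-corrected) probability that two randomly drawn
#' specimens carry different haplotypes.
#'
#' @param counts Vector of haplotype counts (one entry per haplotype).
#' @return H in `[0, 1]`; 0 iff the sample is monomorphic.
#' @examples
#' haplotype_diversity(c(5, 1, 1))  # 0.524
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity requires at least 2 specimens")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Nucleotide diversity (pi)
#'
#' Unbiased estimator `pi = n/(n-1) * sum_{i<j} 2 p_i p_j d_ij` where `d_ij`
#' is the per-site proportion of differing sites between haplotypes i and j
#' (pairwise deletion) and `p_i` their sample frequencies. With
#' `corrected = TRUE` the K2P-corrected distance replaces the raw
#' proportion.
#'
#' @param x A [hap_alignment()] (specimen-level) or a `hap_table`.
#' @param corrected Use K2P-corrected distances instead of raw proportions.
#' @return Nucleotide diversity per site.
#' @export
nucleotide_diversity <- function(x, corrected = FALSE) {
  table <- if (inherits(x, "hap_table")) x else collapse_haplotypes(x)
  counts <- table$haplotypes$n_total
  n <- sum(counts)
  if (n < 2) stop("nucleotide diversity requires at least 2 specimens")
  if (length(counts) == 1L) return(0)
  seqs <- hap_sequences(table)
  d <- if (corrected) {
    k2p_matrix(seqs)
  } else {
    # proportion of differing sites: hamming / pairwise-deletion L
    prop_diff_matrix(seqs)
  }
  p <- counts / n
  acc <- 0
  k <- length(p)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) acc <- acc + 2 * p[i] * p[j] * d[i, j]
  }
  (n / (n - 1)) * acc
}

prop_diff_matrix <- function(seqs) {
  pairwise_matrix(seqs, function(cmp) cmp$raw_diffs / cmp$L)
}

#' Per-population diversity report
#'
#' One row per (species, population) stratum with sample size, haplotype
#' count, nucleotide diversity (per site and percent) and haplotype
#' diversity. Strata with a single specimen are reported with `H` and `pi`
#' undefined (`NA`).
#'
#' @param alignment A [hap_alignment()] with population (and optionally
#'   species) labels.
#' @param corrected Passed to [nucleotide_diversity()].
#' @return A tibble `species`, `population`, `n`, `n_haplotypes`, `pi`,
#'   `pi_percent`, `H`.
#' @export
diversity_report <- function(alignment, corrected = FALSE) {
  stopifnot(inherits(alignment, "hap_alignment"))
  if (all(is.na(alignment$population))) {
    stop("diversity_report needs population labels; see read_popmap()")
  }
  strata <- alignment |>
    dplyr::distinct(.data$species, .data$population)
  purrr::pmap_dfr(strata, function(species, population) {
    sub <- subset_alignment(alignment,
                            alignment$species %in% species &
                              alignment$population %in% population)
    tab <- collapse_haplotypes(sub)
    n <- nrow(sub)
    if (n < 2L) {
      pi <- NA_real_; H <- NA_real_
    } else {
      pi <- nucleotide_diversity(tab, corrected = corrected)
      H <- haplotype_diversity(tab$haplotypes$n_total)
    }
    tibble::tibble(species = species, population = population, n = n,
                   n_haplotypes = nrow(tab$haplotypes),
                   pi = pi, pi_percent = 100 * pi, H = H)
  })
}

#' Write a diversity report TSV
#' @param report Tibble from [diversity_report()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(report, path) {
  out <- dplyr::select(report, "species", "population", "n",
                       "n_haplotypes", "pi_percent", "H")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
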