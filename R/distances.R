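# Kimura 2-parameter distances. Transitions are the purine-purine (A<->G)
# and pyrimidine-pyrimidine (C<->T) exchanges; everything else among
# {A,C,G,T} is a transversion. Sites where either sequence carries a gap,
# N or other ambiguity code are excluded per pair (pairwise deletion).

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify differing sites between two aligned sequences
#'
#' Counts transitions and transversions between two equal-length sequences
#' under pairwise deletion and returns the proportions entering the K2P
#' formula.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return A list with `L` (compared sites after pairwise deletion),
#'   `P` (transition proportion), `Q` (transversion proportion) and
#'   `raw_diffs` (count of differing sites).
#' @examples
#' count_site_patterns("AAAA", "GAAA")  # one transition
#' @export
count_site_patterns <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("sequences differ in length")
  keep <- ca %in% UNAMBIGUOUS & cb %in% UNAMBIGUOUS
  L <- sum(keep)
  if (L == 0L) stop("no comparable sites after pairwise deletion")
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  ts <- diff & ((ca %in% PURINES & cb %in% PURINES) |
                (ca %in% PYRIMIDINES & cb %in% PYRIMIDINES))
  tv <- diff & !ts
  list(L = L, P = sum(ts) / L, Q = sum(tv) / L, raw_diffs = sum(diff))
}

#' Kimura 2-parameter distance from site-pattern proportions
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, in substitutions per site.
#' Saturated comparisons (non-positive log argument) return `NA` and are
#' dropped from group means with a warning.
#'
#' @param comparison A list with elements `P` and `Q`, as returned by
#'   [count_site_patterns()], or a transition proportion if `Q` is given.
#' @param Q Transversion proportion when `comparison` is given as the scalar
#'   transition proportion.
#' @return Distance in substitutions/site, or `NA_real_` if undefined.
#' @export
k2p_distance <- function(comparison, Q = NULL) {
  if (is.list(comparison)) {
    P <- comparison$P; Q <- comparison$Q
  } else {
    P <- comparison
  }
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise K2P distance matrix
#'
#' @param x A [hap_alignment()], a `hap_table` (one sequence per haplotype),
#'   or a named character vector of aligned sequences.
#' @return A symmetric labelled matrix of K2P distances (substitutions/site),
#'   zero diagonal; saturated pairs are `NA` with a warning.
#' @export
k2p_matrix <- function(x) {
  pairwise_matrix(x, function(cmp) k2p_distance(cmp))
}

#' Raw difference-count (Hamming) matrix
#'
#' Integer count of differing sites per pair, pairwise deletion; the edge
#' weights of haplotype networks.
#'
#' @inheritParams k2p_matrix
#' @return A symmetric labelled integer matrix.
#' @export
hamming_matrix <- function(x) {
  pairwise_matrix(x, function(cmp) cmp$raw_diffs)
}

pairwise_matrix <- function(x, f) {
  if (inherits(x, "hap_table")) x <- hap_sequences(x)
  m <- seq_matrix(x)
  n <- nrow(m)
  labels <- rownames(m)
  ok <- matrix(m %in% UNAMBIGUOUS, nrow = n)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  saturated <- 0L
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      keep <- ok[i, ] & ok[j, ]
      L <- sum(keep)
      if (L == 0L) stop(sprintf(
        "no comparable sites between '%s' and '%s'", labels[i], labels[j]))
      ai <- m[i, keep]; bj <- m[j, keep]
      diff <- ai != bj
      ts <- diff & ((ai %in% PURINES & bj %in% PURINES) |
                    (ai %in% PYRIMIDINES & bj %in% PYRIMIDINES))
      val <- f(list(L = L, P = sum(ts) / L, Q = sum(diff & !ts) / L,
                    raw_diffs = sum(diff)))
      if (is.na(val)) saturated <- saturated + 1L
      d[i, j] <- d[j, i] <- val
    }
  }
  if (saturated > 0L) {
    warning(saturated, " saturated pair(s) with undefined K2P distance")
  }
  d
}

#' Mean within-group K2P distance
#'
#' Arithmetic mean of the K2P distance over all unordered pairs within a
#' group of sequences, each haplotype weighted equally. Undefined (saturated)
#' pairs are dropped with a warning.
#'
#' @param alignment A [hap_alignment()] or named sequence vector.
#' @param ids Ids of the group members (at least 2).
#' @return A tibble with `estimate` (substitutions/site) and `n_pairs`.
#' @export
mean_within <- function(alignment, ids) {
  d <- submatrix_k2p(alignment, ids)
  vals <- d[upper.tri(d)]
  summarise_pairs(vals)
}

#' Mean between-group K2P distance
#'
#' Mean K2P distance over all cross pairs between two disjoint groups.
#'
#' @inheritParams mean_within
#' @param ids_a,ids_b Ids of the two groups (non-empty, disjoint).
#' @return A tibble with `estimate` and `n_pairs`.
#' @export
mean_between <- function(alignment, ids_a, ids_b) {
  if (length(intersect(ids_a, ids_b))) stop("groups must be disjoint")
  d <- submatrix_k2p(alignment, c(ids_a, ids_b))
  vals <- as.vector(d[ids_a, ids_b, drop = FALSE])
  summarise_pairs(vals)
}

submatrix_k2p <- function(alignment, ids) {
  seqs <- align_sequences(alignment)
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) stop("ids not in alignment: ",
                            paste(missing, collapse = ", "))
  k2p_matrix(seqs[ids])
}

align_sequences <- function(alignment) {
  if (inherits(alignment, "hap_alignment")) {
    stats::setNames(alignment$sequence, alignment$id)
  } else if (inherits(alignment, "hap_table")) {
    hap_sequences(alignment)
  } else {
    stopifnot(!is.null(names(alignment)))
    alignment
  }
}

summarise_pairs <- function(vals) {
  if (length(vals) == 0L) stop("group too small: no pairs to average")
  dropped <- sum(is.na(vals))
  if (dropped > 0L) warning(dropped, " undefined pair(s) dropped from mean")
  tibble::tibble(estimate = mean(vals, na.rm = TRUE),
                 n_pairs = length(vals) - dropped)
}

#' Site-bootstrap standard errors for group mean distances
#'
#' Resamples alignment columns with replacement, recomputes every
#' within-group and between-group mean K2P distance on each pseudo-alignment,
#' and reports the standard deviation across replicates as the standard
#' error (the convention used for distance-table standard errors in
#' distance-based phylogenetic software).
#'
#' @param alignment A [hap_alignment()] or named sequence vector.
#' @param groups Named list of id vectors.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble `group1`, `group2`, `type` (within/between), `se`.
#' @export
bootstrap_se <- function(alignment, groups, replicates = 1000, seed = NULL) {
  stopifnot(replicates >= 1, length(groups) >= 1, !is.null(names(groups)))
  if (!is.null(seed)) set.seed(seed)
  seqs <- align_sequences(alignment)
  ids <- unique(unlist(groups))
  m <- seq_matrix(seqs[ids])
  L <- ncol(m)
  combos <- group_combos(names(groups))
  draws <- matrix(NA_real_, replicates, nrow(combos))
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- stats::setNames(apply(m[, cols, drop = FALSE], 1L,
                                  paste0, collapse = ""), ids)
    for (k in seq_len(nrow(combos))) {
      g1 <- groups[[combos$group1[k]]]
      g2 <- groups[[combos$group2[k]]]
      est <- if (combos$type[k] == "within") {
        if (length(g1) < 2L) NA_real_ else mean_within(boot, g1)$estimate
      } else {
        mean_between(boot, g1, g2)$estimate
      }
      draws[r, k] <- est
    }
  }
  combos$se <- apply(draws, 2L, stats::sd)
  combos$se[is.na(combos$se)] <- NA_real_
  tibble::as_tibble(combos)
}

group_combos <- function(nm) {
  within <- data.frame(group1 = nm, group2 = nm, type = "within")
  if (length(nm) >= 2L) {
    cross <- t(utils::combn(nm, 2L))
    between <- data.frame(group1 = cross[, 1L], group2 = cross[, 2L],
                          type = "between")
    rbind(within, between)
  } else {
    within
  }
}

#' Group mean distance summary with bootstrap standard errors
#'
#' Interspecies/interpopulation distance table: mean K2P within each group
#' and between each pair of groups, with site-bootstrap standard errors.
#' Groups default to the species label, one sequence per haplotype.
#'
#' @param alignment A [hap_alignment()] with group labels.
#' @param by Grouping column: `"species"` or `"population"`.
#' @param collapse If `TRUE` (default) collapse to haplotypes within each
#'   group first, so each distinct sequence counts once.
#' @param replicates Bootstrap replicates for standard errors (0 to skip).
#' @param seed Optional seed for the bootstrap.
#' @return A tibble `group1`, `group2`, `type`, `estimate`, `se`, `n_pairs`,
#'   distances in substitutions/site.
#' @export
group_distances <- function(alignment, by = c("species", "population"),
                            collapse = TRUE, replicates = 1000, seed = NULL) {
  by <- match.arg(by)
  labels <- alignment[[by]]
  if (all(is.na(labels))) stop("no ", by, " labels on alignment")
  keep <- !is.na(labels)
  x <- alignment[keep, ]
  labels <- labels[keep]
  seqs <- stats::setNames(x$sequence, x$id)
  groups <- split(x$id, labels)
  if (collapse) {
    groups <- lapply(groups, function(ids) ids[!duplicated(seqs[ids])])
  }
  combos <- group_combos(names(groups))
  est <- purrr::map_dfr(seq_len(nrow(combos)), function(k) {
    g1 <- groups[[combos$group1[k]]]
    g2 <- groups[[combos$group2[k]]]
    if (combos$type[k] == "within") {
      if (length(g1) < 2L) {
        tibble::tibble(estimate = NA_real_, n_pairs = 0L)
      } else {
        mean_within(seqs, g1)
      }
    } else {
      mean_between(seqs, g1, g2)
    }
  })
  out <- dplyr::bind_cols(tibble::as_tibble(combos), est)
  if (replicates > 0L) {
    se <- bootstrap_se(seqs, groups, replicates = replicates, seed = seed)
    out <- dplyr::left_join(out, se,
                            by = c("group1", "group2", "type"))
  } else {
    out$se <- NA_real_
  }
  dplyr::relocate(out, "estimate", "se", "n_pairs", .after = "type")
}

#' Write a labelled distance matrix
#'
#' @param d Symmetric labelled matrix.
#' @param path Output file path.
#' @param format `"tsv"` (square, with header) or `"phylip"` (lower
#'   triangle).
#' @param percent Write distances multiplied by 100.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip"),
                                  percent = FALSE) {
  format <- match.arg(format)
  if (percent) d <- d * 100
  if (format == "tsv") {
    utils::write.table(cbind(id = rownames(d), as.data.frame(d)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      vals <- if (i > 1L) paste(sprintf("%.6f", d[i, seq_len(i - 1L)]),
                                collapse = " ") else ""
      writeLines(trimws(sprintf("%-10s %s", rownames(d)[i], vals),
                        which = "right"), con)
    }
  }
  invisible(path)
}
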