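# Deterministic strict-clock dating: UPGMA ultrametric clustering of K2P
# distances, node ages across a grid of divergence rates, and rescaling by
# external calibration points (least squares over the calibrated nodes).

#' UPGMA clock tree from a distance matrix
#'
#' Average-linkage agglomeration; each internal node sits at half the join
#' distance, so the tree is ultrametric and node height is in
#' substitutions/site per lineage (pairwise divergence = 2 x height).
#'
#' @param d Symmetric labelled distance matrix (substitutions/site), e.g.
#'   from [k2p_matrix()].
#' @return An object of class `clock_tree`: list with `phylo` (ape tree),
#'   `heights` (tibble `node`, `height`, `tips` — a compact label for the
#'   clade) and `n_tips`.
#' @examples
#' d <- matrix(c(0, .02, .1, .02, 0, .1, .1, .1, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_tree(d)$heights
#' @export
upgma_tree <- function(d) {
  stopifnot(nrow(d) >= 2L, isTRUE(all.equal(d, t(d))))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phylo <- ape::as.phylo(hc)   # node height = join distance / 2
  heights_vec <- heights_from_phylo(phylo)
  structure(list(phylo = phylo, heights = heights_vec,
                 n_tips = length(phylo$tip.label)),
            class = "clock_tree")
}

heights_from_phylo <- function(phylo) {
  n_tip <- length(phylo$tip.label)
  depth <- ape::node.depth.edgelength(phylo)
  height <- max(depth) - depth
  inner <- (n_tip + 1L):(n_tip + phylo$Nnode)
  clade <- vapply(inner, function(nd) {
    tips <- sort(ape::extract.clade(phylo, nd)$tip.label)
    paste(tips[1L], tips[length(tips)], sep = "|")  # an MRCA-defining pair
  }, "")
  tibble::tibble(node = inner, height = height[inner], clade = clade)
}

#' @export
print.clock_tree <- function(x, ...) {
  cat(sprintf("<clock_tree> %d tips, root height %.4g subst/site\n",
              x$n_tips, max(x$heights$height)))
  invisible(x)
}

#' Node ages across a grid of divergence rates
#'
#' Converts ultrametric node heights to absolute ages for each rate in the
#' grid. A rate is expressed as pairwise sequence divergence per million
#' years (e.g. `0.03` for 3%/Myr), so `age = 2*height / rate`; with
#' `per_lineage = TRUE` the rate applies to a single lineage and
#' `age = height / rate`.
#'
#' @param tree A `clock_tree`.
#' @param rates Strictly increasing positive rates (divergence/Myr);
#'   default the conventional small-mammal mtDNA grid 3, 5, 10, 20, 40%.
#' @param per_lineage Interpret the rate per lineage rather than pairwise.
#' @return A tibble `node`, `clade`, `height`, `rate`, `age_ma`.
#' @export
ages_from_rates <- function(tree, rates = c(0.03, 0.05, 0.10, 0.20, 0.40),
                            per_lineage = FALSE) {
  stopifnot(inherits(tree, "clock_tree"),
            all(rates > 0), !is.unsorted(rates, strictly = TRUE))
  div <- if (per_lineage) 1 else 2
  tidyr::expand_grid(tree$heights, rate = rates) |>
    dplyr::mutate(age_ma = div * .data$height / .data$rate)
}

#' Calibrate a clock tree against absolute node ages
#'
#' Each calibration assigns an age (Ma) to the most recent common ancestor
#' of a pair of tips. A single scale factor `s` minimising
#' `sum((s*height_i - age_i)^2)` over the calibrated nodes converts all node
#' heights to ages; with one calibration the fit is exact at that node.
#'
#' @param tree A `clock_tree`.
#' @param calibrations A data frame with columns `tip_a`, `tip_b`, `age_ma`.
#' @return The tree with added elements `ages` (tibble `node`, `clade`,
#'   `height`, `age_ma`), `scale` (Ma per unit height), `residual` (root
#'   mean squared calibration error, Ma) and `calibration_nodes`.
#' @export
calibrate <- function(tree, calibrations) {
  stopifnot(inherits(tree, "clock_tree"))
  calibrations <- tibble::as_tibble(calibrations)
  need <- c("tip_a", "tip_b", "age_ma")
  stopifnot(all(need %in% names(calibrations)), all(calibrations$age_ma > 0))
  tips <- tree$phylo$tip.label
  nodes <- purrr::pmap_int(calibrations, function(tip_a, tip_b, age_ma) {
    miss <- setdiff(c(tip_a, tip_b), tips)
    if (length(miss)) {
      stop("calibration tip(s) not in tree: ", paste(miss, collapse = ", "))
    }
    as.integer(ape::getMRCA(tree$phylo, c(tip_a, tip_b)))
  })
  h <- tree$heights$height[match(nodes, tree$heights$node)]
  if (any(h <= 0)) {
    bad <- which(h <= 0)[1L]
    stop(sprintf("calibration node for (%s, %s) has zero height",
                 calibrations$tip_a[bad], calibrations$tip_b[bad]))
  }
  s <- sum(h * calibrations$age_ma) / sum(h^2)
  resid <- sqrt(mean((s * h - calibrations$age_ma)^2))
  out <- tree
  out$ages <- dplyr::mutate(tree$heights, age_ma = s * .data$height)
  out$scale <- s
  out$residual <- resid
  out$calibration_nodes <- nodes
  out
}

#' Write a clock tree as Newick
#' @param tree A `clock_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clock_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Write the node-ages table (one column per rate)
#' @param ages Tibble from [ages_from_rates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ages <- function(ages, path) {
  wide <- ages |>
    dplyr::mutate(rate = sprintf("rate_%g%%", 100 * .data$rate),
                  age_ma = round(.data$age_ma, 4)) |>
    tidyr::pivot_wider(id_cols = c("node", "clade", "height"),
                       names_from = "rate", values_from = "age_ma")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
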