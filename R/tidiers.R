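# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a haplotype table
#'
#' @param x A `hap_table`.
#' @param ... Unused.
#' @return Long tibble: `haplotype_id`, `population`, `species`, `n`.
#' @export
tidy.hap_table <- function(x, ...) {
  x$counts
}

#' @rdname tidy.hap_table
#' @export
glance.hap_table <- function(x, ...) {
  tibble::tibble(n_haplotypes = nrow(x$haplotypes),
                 n_specimens = nrow(x$membership),
                 n_sites = x$n_sites)
}

#' Tidy an AMOVA result
#'
#' @param x A `hap_amova`.
#' @param ... Unused.
#' @return One row per variance component (`among`, `within`) with sums of
#'   squares, degrees of freedom and sigma-squared.
#' @export
tidy.hap_amova <- function(x, ...) {
  tibble::tibble(
    component = c("among", "within"),
    ssd = c(x$ssd_among, x$ssd_within),
    df = c(x$df_among, x$df_within),
    sigma2 = c(x$sigma2_among, x$sigma2_within)
  )
}

#' @rdname tidy.hap_amova
#' @export
glance.hap_amova <- function(x, ...) {
  tibble::tibble(phi = x$phi, metric = x$metric, n_prime = x$n_prime)
}

#' Tidy a pairwise differentiation result
#'
#' @param x A `hap_differentiation`.
#' @param ... Unused.
#' @return Long tibble: `pop1`, `pop2`, `statistic`, `p_value`.
#' @export
tidy.hap_differentiation <- function(x, ...) {
  pops <- x$populations
  pairs <- utils::combn(seq_along(pops), 2L)
  tibble::tibble(
    pop1 = pops[pairs[1L, ]],
    pop2 = pops[pairs[2L, ]],
    statistic = x$stat[cbind(pairs[2L, ], pairs[1L, ])],
    p_value = x$pvalue[cbind(pairs[1L, ], pairs[2L, ])]
  )
}

#' @rdname tidy.hap_differentiation
#' @export
glance.hap_differentiation <- function(x, ...) {
  td <- tidy.hap_differentiation(x)
  tibble::tibble(metric = x$metric,
                 n_populations = length(x$populations),
                 n_permutations = x$n_permutations,
                 max_statistic = max(td$statistic),
                 min_p = min(td$p_value))
}

#' Tidy a haplotype network
#'
#' @param x A `hap_network`.
#' @param ... Unused.
#' @return Edge list tibble: `from`, `to`, `mutations`.
#' @export
tidy.hap_network <- function(x, ...) {
  tibble::tibble(from = x$edges$from, to = x$edges$to,
                 mutations = x$edges$weight)
}

#' @rdname tidy.hap_network
#' @export
glance.hap_network <- function(x, ...) {
  tibble::tibble(n_observed = sum(x$nodes$type == "observed"),
                 n_median_vectors = sum(x$nodes$type == "median"),
                 n_edges = nrow(x$edges),
                 cost = network_cost(x),
                 epsilon = x$epsilon)
}

#' Tidy a clock tree
#'
#' @param x A `clock_tree`.
#' @param ... Unused.
#' @return The node-heights tibble (with ages when calibrated).
#' @export
tidy.clock_tree <- function(x, ...) {
  if (!is.null(x$ages)) x$ages else x$heights
}

#' @rdname tidy.clock_tree
#' @export
glance.clock_tree <- function(x, ...) {
  tibble::tibble(n_tips = x$n_tips,
                 root_height = max(x$heights$height),
                 calibrated = !is.null(x$scale),
                 scale_ma = if (is.null(x$scale)) NA_real_ else x$scale,
                 residual_ma = if (is.null(x$residual)) NA_real_
                               else x$residual)
}

#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout; observed haplotypes are sized by specimen
#' count, median vectors drawn as small open squares; edges are labelled
#' with the number of mutations when greater than 1.
#'
#' @param object A `hap_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hap_network <- function(object, ...) {
  g <- object$graph
  # deterministic layout without disturbing the caller's RNG stream
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng,
                                    envir = globalenv()))
  set.seed(42)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1L], y = xy[, 2L])
  edges <- object$edges |>
    dplyr::mutate(
      x = nodes$x[match(.data$from, nodes$name)],
      y = nodes$y[match(.data$from, nodes$name)],
      xend = nodes$x[match(.data$to, nodes$name)],
      yend = nodes$y[match(.data$to, nodes$name)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey50") +
    ggplot2::geom_text(
      data = dplyr::filter(edges, .data$weight > 1),
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$weight),
      size = 3, colour = "grey30") +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$type == "observed"),
      ggplot2::aes(.data$x, .data$y, size = .data$count),
      shape = 21, fill = "steelblue") +
    ggplot2::geom_point(
      data = dplyr::filter(nodes, .data$type == "median"),
      ggplot2::aes(.data$x, .data$y),
      shape = 22, size = 2, fill = "white") +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$name),
      vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "specimens")
}

#' Plot per-population diversity
#'
#' Bar panel of haplotype diversity and nucleotide diversity (percent) per
#' population stratum.
#'
#' @param report Tibble from [diversity_report()].
#' @return A ggplot object.
#' @export
plot_diversity <- function(report) {
  long <- report |>
    dplyr::mutate(stratum = paste(.data$species, .data$population)) |>
    tidyr::pivot_longer(c("H", "pi_percent"), names_to = "measure",
                        values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$stratum, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot node ages across the rate grid
#'
#' One line per node: age (Ma) against divergence rate, log-log axes; under
#' a strict clock every line has slope -1.
#'
#' @param ages Tibble from [ages_from_rates()].
#' @return A ggplot object.
#' @export
plot_ages <- function(ages) {
  ggplot2::ggplot(ages,
                  ggplot2::aes(.data$rate, .data$age_ma,
                               group = .data$node)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "divergence rate (/Myr)", y = "node age (Ma)")
}
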