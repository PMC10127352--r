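# Median-joining haplotype networks (Bandelt-style). The backbone is the
# minimum spanning network (union of all minimum spanning trees, relaxed by
# an integer tolerance epsilon); median vectors are consensus sequences of
# linked triples added greedily while they reduce the minimal spanning cost
# of the node set (Steiner criterion), then pruned to fixpoint.

# Minimax (bottleneck) distance between all pairs: the largest edge weight
# on the MST path. An edge (u,v) belongs to some MST iff d(u,v) equals the
# minimax distance (cycle property); epsilon relaxes this threshold.
minimax_matrix <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(matrix(0, 1, 1, dimnames = dimnames(d)))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  adj <- lapply(seq_len(n), function(i) integer(0))
  wts <- lapply(seq_len(n), function(i) numeric(0))
  el <- igraph::as_edgelist(tree, names = FALSE)
  ew <- igraph::E(tree)$weight
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1L]; b <- el[e, 2L]
    adj[[a]] <- c(adj[[a]], b); wts[[a]] <- c(wts[[a]], ew[e])
    adj[[b]] <- c(adj[[b]], a); wts[[b]] <- c(wts[[b]], ew[e])
  }
  mm <- matrix(0, n, n, dimnames = dimnames(d))
  for (root in seq_len(n)) {
    seen <- rep(FALSE, n); seen[root] <- TRUE
    stack <- root; best <- rep(0, n)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (k in seq_along(adj[[v]])) {
        u <- adj[[v]][k]
        if (!seen[u]) {
          seen[u] <- TRUE
          best[u] <- max(best[v], wts[[v]][k])
          stack <- c(stack, u)
        }
      }
    }
    mm[root, ] <- best
  }
  mm
}

# Sum of MST edge weights over a set of sequences (the network cost used by
# the Steiner criterion).
spanning_cost <- function(d) {
  if (nrow(d) <= 1L) return(0)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) {
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0)))
  }
  mm <- minimax_matrix(d)
  keep <- which(upper.tri(d) & d <= mm + epsilon, arr.ind = TRUE)
  data.frame(from = rownames(d)[keep[, 1L]],
             to = colnames(d)[keep[, 2L]],
             weight = d[keep])
}

#' Minimum spanning network over haplotypes
#'
#' Builds the union of all minimum spanning trees over an integer distance
#' matrix, relaxed by `epsilon`: an edge is admitted when its weight is at
#' most the bottleneck (minimax) distance between its endpoints plus
#' `epsilon`.
#'
#' @param d Symmetric labelled matrix of integer site differences (see
#'   [hamming_matrix()]).
#' @param epsilon Non-negative integer relaxation (0 = exact MST union).
#' @return A `hap_network` (see [median_joining()]) without median vectors.
#' @export
minimum_spanning_network <- function(d, epsilon = 0) {
  stopifnot(epsilon >= 0)
  nodes <- tibble::tibble(name = rownames(d), type = "observed",
                          sequence = NA_character_, count = NA_integer_)
  new_hap_network(nodes, msn_edges(d, epsilon), epsilon)
}

new_hap_network <- function(nodes, edges, epsilon) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::E(g)$mutations <- edges$weight
  structure(list(graph = g, nodes = nodes, edges = tibble::as_tibble(edges),
                 epsilon = epsilon),
            class = "hap_network")
}

# Majority-consensus median(s) of three variable-site strings. A position
# where all three characters differ is a tie: all three variants are
# generated, capped (deterministically, in lexicographic order) at
# `max_candidates` sequences.
median_candidates <- function(u, v, w, max_candidates = 32L) {
  cu <- strsplit(u, "")[[1L]]; cv <- strsplit(v, "")[[1L]]
  cw <- strsplit(w, "")[[1L]]
  cons <- character(length(cu))
  tie <- integer(0)
  for (i in seq_along(cu)) {
    trio <- c(cu[i], cv[i], cw[i])
    tab <- table(trio)
    if (max(tab) >= 2L) {
      cons[i] <- names(tab)[which.max(tab)]
    } else {
      cons[i] <- NA_character_
      tie <- c(tie, i)
    }
  }
  if (!length(tie)) return(paste0(cons, collapse = ""))
  grids <- lapply(tie, function(i) sort(c(cu[i], cv[i], cw[i])))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  out <- apply(combos, 1L, function(row) {
    s <- cons
    s[tie] <- unlist(row)
    paste0(s, collapse = "")
  })
  sort(unique(out))[seq_len(min(length(out), max_candidates))]
}

#' Median-joining haplotype network
#'
#' Iteratively builds the minimum spanning network over the current node
#' set, proposes majority-consensus medians of linked triples (a node and
#' two of its neighbours), adds the median that most reduces the minimal
#' spanning cost of the node set, and repeats until no median helps.
#' Redundant median vectors (low degree, or lying on no shortest path
#' between observed haplotypes, and removable without a cost increase) are
#' pruned to fixpoint; survivors are named `mv1`, `mv2`, ... in creation
#' order. Only variable sites enter the computation; full-length sequences
#' are reconstructed for the output.
#'
#' @param x A `hap_table` (from [collapse_haplotypes()]), a
#'   [hap_alignment()] (collapsed internally), or a named character vector
#'   of distinct aligned haplotype sequences.
#' @param epsilon Non-negative integer MSN relaxation (default 0).
#' @param max_candidates Cap on tie-expansion variants per triple.
#' @return An object of class `hap_network`: list with `graph` (igraph,
#'   vertex attributes `type`, `sequence`, `count`; edge attribute
#'   `mutations`), `nodes`, `edges`, `epsilon`.
#' @examples
#' seqs <- c(a = "AAA", b = "GGA", c = "AGG")
#' net <- median_joining(seqs)   # one inferred intermediate 'mv1'
#' @export
median_joining <- function(x, epsilon = 0, max_candidates = 32L) {
  if (inherits(x, "hap_alignment")) x <- collapse_haplotypes(x)
  if (inherits(x, "hap_table")) {
    seqs <- hap_sequences(x)
    counts <- stats::setNames(x$haplotypes$n_total, names(seqs))
  } else {
    stopifnot(!is.null(names(x)))
    seqs <- x
    counts <- stats::setNames(rep(1L, length(x)), names(x))
  }
  if (anyDuplicated(seqs)) stop("haplotype sequences must be distinct")
  full_len <- unique(nchar(seqs))
  stopifnot(length(full_len) == 1L)

  chars <- seq_matrix(seqs)
  variable <- which(apply(chars, 2L, function(col) length(unique(col)) > 1L))
  template <- chars[1L, ]   # invariant sites identical across haplotypes
  var_of <- function(s) paste0(strsplit(s, "")[[1L]][variable], collapse = "")
  obs <- stats::setNames(vapply(seqs, var_of, ""), names(seqs))

  node_seq <- obs           # variable-site strings, named
  n_medians <- 0L
  if (length(variable) > 0L && length(node_seq) >= 3L) {
    for (round in seq_len(50L)) {
      d <- hamming_matrix(node_seq)
      cost <- spanning_cost(d)
      edges <- msn_edges(d, epsilon)
      nbrs <- split(c(edges$to, edges$from), c(edges$from, edges$to))
      cands <- character(0)
      for (v in names(nbrs)) {
        nb <- unique(nbrs[[v]])
        if (length(nb) < 2L) next
        pairs <- utils::combn(nb, 2L)
        for (p in seq_len(ncol(pairs))) {
          cands <- c(cands, median_candidates(node_seq[[pairs[1L, p]]],
                                              node_seq[[v]],
                                              node_seq[[pairs[2L, p]]],
                                              max_candidates))
        }
      }
      cands <- sort(setdiff(unique(cands), node_seq))
      if (!length(cands)) break
      best <- NULL; best_cost <- cost
      for (cand in cands) {
        trial <- c(node_seq, stats::setNames(cand, "."))
        tc <- spanning_cost(hamming_matrix(trial))
        if (tc < best_cost - 1e-9) { best_cost <- tc; best <- cand }
      }
      if (is.null(best)) break
      n_medians <- n_medians + 1L
      node_seq <- c(node_seq,
                    stats::setNames(best, paste0("mv", n_medians)))
    }
    node_seq <- prune_medians(node_seq, names(obs), epsilon)
  }

  # rename surviving medians mv1..mvK in creation order
  med_names <- setdiff(names(node_seq), names(obs))
  if (length(med_names)) {
    ord <- med_names[order(as.integer(sub("^mv", "", med_names)))]
    new_names <- paste0("mv", seq_along(ord))
    names(node_seq)[match(ord, names(node_seq))] <- new_names
  }

  expand_seq <- function(vs) {
    s <- template
    s[variable] <- strsplit(vs, "")[[1L]]
    paste0(s, collapse = "")
  }
  full_seqs <- vapply(node_seq, expand_seq, "")
  is_obs <- names(node_seq) %in% names(obs)
  nodes <- tibble::tibble(
    name = names(node_seq),
    type = ifelse(is_obs, "observed", "median"),
    sequence = unname(full_seqs),
    count = ifelse(is_obs, as.integer(counts[names(node_seq)]), 0L)
  )
  d <- hamming_matrix(node_seq)
  new_hap_network(nodes, msn_edges(d, epsilon), epsilon)
}

# Remove median vectors that are not needed: degree <= 2 in the MSN, or on
# no shortest path between observed haplotypes, provided their removal does
# not increase the minimal spanning cost. Repeat to fixpoint.
prune_medians <- function(node_seq, obs_names, epsilon) {
  repeat {
    med <- setdiff(names(node_seq), obs_names)
    if (!length(med)) return(node_seq)
    d <- hamming_matrix(node_seq)
    cost <- spanning_cost(d)
    edges <- msn_edges(d, epsilon)
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = names(node_seq)))
    deg <- igraph::degree(g)
    on_path <- rep(FALSE, length(node_seq))
    names(on_path) <- names(node_seq)
    for (a in obs_names) {
      for (b in obs_names) {
        if (a >= b) next
        sp <- igraph::all_shortest_paths(g, from = a, to = b,
                                         weights = edges$weight)$vpaths
        for (pth in sp) on_path[names(pth)] <- TRUE
      }
    }
    removed <- FALSE
    for (m in med) {
      if (deg[[m]] <= 2L || !on_path[[m]]) {
        rest <- node_seq[names(node_seq) != m]
        if (spanning_cost(hamming_matrix(rest)) <= cost + 1e-9) {
          node_seq <- rest
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) return(node_seq)
  }
}

#' Total cost (sum of mutation steps) of a haplotype network
#'
#' The minimal spanning cost of the network's node set: the sum of edge
#' weights of a minimum spanning tree of the network graph.
#'
#' @param network A `hap_network`.
#' @return Numeric cost.
#' @export
network_cost <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0L) return(0)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$mutations))$mutations)
}

#' @export
print.hap_network <- function(x, ...) {
  nm <- sum(x$nodes$type == "median")
  cat(sprintf(
    "<hap_network> %d observed haplotypes, %d median vectors, %d edges (epsilon=%d)\n",
    sum(x$nodes$type == "observed"), nm, nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Write a haplotype network to GraphML or GML
#'
#' Node attributes: `type` (observed/median), `count`, `sequence`; edge
#' attribute `mutations`.
#'
#' @param network A `hap_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"gml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- network$graph
  igraph::V(g)$type <- network$nodes$type
  igraph::V(g)$count <- network$nodes$count
  igraph::V(g)$sequence <- network$nodes$sequence
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
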