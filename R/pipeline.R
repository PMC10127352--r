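# End-to-end driver: haplotypes -> distances -> diversity ->
# differentiation -> network -> dating, from one alignment + popmap, with a
# consolidated machine-readable summary. Any stage failure aborts with a
# stage-named error; outputs written before the failure are retained.

#' Run the full haplotype-analysis pipeline
#'
#' Executes every analysis stage on one aligned dataset and writes all
#' outputs to `out_dir`: haplotype table (TSV + FASTA), K2P distance matrix,
#' group-mean distances with bootstrap standard errors, per-population
#' diversity table, pairwise differentiation tables (both the
#' haplotype-frequency Fst and the distance-based Phi-st), the
#' median-joining network (GraphML), the UPGMA clock tree (Newick) with the
#' node-ages table over the rate grid, a JSON summary, and a run log. All
#' randomness (bootstrap, permutations) is driven by `seed`.
#'
#' @param alignment A [hap_alignment()], or a path to an aligned FASTA.
#' @param popmap Optional path to a popmap TSV (required when `alignment`
#'   is a path and carries no labels).
#' @param out_dir Output directory, created if needed.
#' @param window Optional `c(from, to)` site window (1-based inclusive).
#' @param n_perm Permutations per population pair.
#' @param bootstrap Site-bootstrap replicates for distance standard errors.
#' @param seed Integer seed for bootstrap and permutations.
#' @param rates Divergence-rate grid for dating (fraction/Myr).
#' @param calibrations Optional data frame `tip_a`, `tip_b`, `age_ma` for
#'   absolute calibration of the clock tree.
#' @param epsilon Median-joining network tolerance.
#' @return The summary list (also written as `summary.json`), invisibly.
#' @export
run_pipeline <- function(alignment, popmap = NULL, out_dir,
                         window = NULL, n_perm = 10000, bootstrap = 1000,
                         seed = 1, rates = c(0.03, 0.05, 0.10, 0.20, 0.40),
                         calibrations = NULL, epsilon = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cat(sprintf("hapnet %s | seed=%d | %s\n",
              as.character(utils::packageVersion("hapnet")), seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      file = log_path)
  manifest <- character(0)
  emit <- function(path) { manifest <<- c(manifest, basename(path)); path }

  aln <- stage("read", {
    a <- if (is.character(alignment)) read_alignment(alignment, window)
         else if (!is.null(window))
           window_alignment(alignment, window[1L], window[2L])
         else alignment
    if (!is.null(popmap)) a <- read_popmap(popmap, a)
    a
  })
  logf("alignment: %d sequences x %d sites", nrow(aln), n_sites(aln))

  haps <- stage("haplotypes", collapse_haplotypes(aln))
  write_haplotypes(haps, emit(file.path(out_dir, "haplotypes.tsv")),
                   fasta = emit(file.path(out_dir, "haplotypes.fasta")))
  logf("haplotypes: %d distinct over %d specimens",
       nrow(haps$haplotypes), nrow(haps$membership))

  comp <- stage("composition", base_composition(aln))

  dmat <- stage("distances", k2p_matrix(haps))
  write_distance_matrix(dmat, emit(file.path(out_dir, "k2p_matrix.tsv")),
                        percent = TRUE)
  groups_tbl <- NULL
  by <- if (!all(is.na(aln$species))) "species"
        else if (!all(is.na(aln$population))) "population" else NA
  if (!is.na(by)) {
    groups_tbl <- stage("group_distances",
                        group_distances(aln, by = by,
                                        replicates = bootstrap,
                                        seed = seed))
    utils::write.table(groups_tbl,
                       emit(file.path(out_dir, "group_distances.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  div <- NULL
  if (!all(is.na(aln$population))) {
    div <- stage("diversity", diversity_report(aln))
    write_diversity(div, emit(file.path(out_dir, "diversity.tsv")))
  }

  diff_fst <- NULL; diff_phist <- NULL
  pops <- unique(aln$population[!is.na(aln$population)])
  pop_sizes <- table(aln$population)
  if (length(pops) >= 2L && all(pop_sizes >= 2L)) {
    diff_fst <- stage("fst",
      pairwise_differentiation(aln, metric = "frequency",
                               n_perm = n_perm, seed = seed))
    write_differentiation(diff_fst, emit(file.path(out_dir, "fst.tsv")),
                          long = emit(file.path(out_dir, "fst_long.tsv")))
    diff_phist <- stage("phist",
      pairwise_differentiation(aln, metric = "differences",
                               n_perm = n_perm, seed = seed + 1L))
    write_differentiation(diff_phist,
                          emit(file.path(out_dir, "phist.tsv")),
                          long = emit(file.path(out_dir, "phist_long.tsv")))
    logf("differentiation: %d population pairs, %d permutations",
         choose(length(pops), 2), n_perm)
  }

  net <- stage("network", median_joining(haps, epsilon = epsilon))
  write_network(net, emit(file.path(out_dir, "network.graphml")))
  logf("network: %d median vectors, cost %g",
       sum(net$nodes$type == "median"), network_cost(net))

  tree <- NULL; ages <- NULL
  if (nrow(haps$haplotypes) >= 2L) {
    tree <- stage("dating", upgma_tree(dmat))
    write_clock_tree(tree, emit(file.path(out_dir, "tree.nwk")))
    ages <- ages_from_rates(tree, rates)
    write_ages(ages, emit(file.path(out_dir, "ages.tsv")))
    if (!is.null(calibrations)) {
      tree <- stage("calibration", calibrate(tree, calibrations))
      utils::write.table(tree$ages,
                         emit(file.path(out_dir, "ages_calibrated.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logf("calibration: scale %.4g Ma/height, residual %.4g Ma",
           tree$scale, tree$residual)
    }
  }

  summary <- list(
    seed = seed,
    n_sequences = nrow(aln),
    n_sites = n_sites(aln),
    n_haplotypes = nrow(haps$haplotypes),
    base_composition = stats::setNames(as.list(comp$freq), comp$base),
    mean_k2p = mean(dmat[upper.tri(dmat)], na.rm = TRUE),
    diversity = if (!is.null(div)) div else NULL,
    group_distances = if (!is.null(groups_tbl)) groups_tbl else NULL,
    fst = if (!is.null(diff_fst)) tidy(diff_fst) else NULL,
    phist = if (!is.null(diff_phist)) tidy(diff_phist) else NULL,
    network = as.list(glance(net)),
    root_height = if (!is.null(tree)) max(tree$heights$height) else NULL,
    root_age_ma = if (!is.null(tree) && !is.null(tree$ages))
      max(tree$ages$age_ma) else NULL,
    manifest = NULL
  )
  manifest <- c(manifest, "summary.json", "run.log")
  summary$manifest <- sort(unique(manifest))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       dataframe = "rows")
  logf("done: %d output files", length(summary$manifest))
  invisible(summary)
}
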