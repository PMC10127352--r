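# Haplotype collapsing and frequency summaries. Haplotype identity is exact
# string equality of the aligned sequences: an 'N' never wildcard-matches a
# base, so two sequences differing only at an ambiguous site are distinct
# haplotypes. Ids H1..Hk follow order of first appearance.

#' Collapse aligned sequences into haplotypes
#'
#' Groups specimens carrying identical aligned sequences into haplotypes,
#' assigning ids `H1..Hk` in order of first appearance, and tabulates
#' haplotype counts per population.
#'
#' @param alignment A [hap_alignment()].
#' @return An object of class `hap_table`: a list with
#'   \describe{
#'     \item{haplotypes}{tibble `haplotype_id`, `sequence`, `n_total`}
#'     \item{membership}{tibble `haplotype_id`, `id`, `population`, `species`}
#'     \item{counts}{tibble `haplotype_id`, `population`, `species`, `n`}
#'   }
#' @examples
#' aln <- hap_alignment(paste0("s", 1:4), c("AAA", "AAA", "AAT", "AAA"))
#' collapse_haplotypes(aln)
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(inherits(alignment, "hap_alignment"))
  first <- !duplicated(alignment$sequence)
  hap_seqs <- alignment$sequence[first]
  hap_ids <- paste0("H", seq_along(hap_seqs))
  idx <- match(alignment$sequence, hap_seqs)
  membership <- tibble::tibble(
    haplotype_id = hap_ids[idx],
    id = alignment$id,
    population = alignment$population,
    species = alignment$species
  )
  counts <- membership |>
    dplyr::count(.data$haplotype_id, .data$population, .data$species,
                 name = "n")
  haplotypes <- tibble::tibble(
    haplotype_id = hap_ids,
    sequence = hap_seqs,
    n_total = as.integer(tabulate(idx, nbins = length(hap_seqs)))
  )
  structure(list(haplotypes = haplotypes, membership = membership,
                 counts = counts, n_sites = n_sites(alignment)),
            class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("<hap_table> %d haplotypes over %d specimens (%d sites)\n",
              nrow(x$haplotypes), nrow(x$membership), x$n_sites))
  print(x$haplotypes, ...)
  invisible(x)
}

#' Haplotype frequency shares
#'
#' Fraction of specimens carrying each haplotype, optionally restricted to
#' one species (e.g. the share of the dominant haplotype in the total
#' sample).
#'
#' @param table A `hap_table` from [collapse_haplotypes()].
#' @param scope Optional species label restricting the denominator.
#' @return A tibble `haplotype_id`, `n`, `share`; shares sum to 1.
#' @export
haplotype_shares <- function(table, scope = NULL) {
  stopifnot(inherits(table, "hap_table"))
  mem <- table$membership
  if (!is.null(scope)) {
    mem <- dplyr::filter(mem, .data$species == scope)
    if (nrow(mem) == 0L) stop("no specimens with species label: ", scope)
  }
  mem |>
    dplyr::count(.data$haplotype_id, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::arrange(match(.data$haplotype_id, table$haplotypes$haplotype_id))
}

#' Species composition of a sampling locality
#'
#' Fraction of specimens belonging to each species, optionally within one
#' population; e.g. a locality where one species makes up 70% of the
#' specimens caught.
#'
#' @param alignment A [hap_alignment()] with species labels.
#' @param population Optional population label restricting the sample.
#' @return A tibble `species`, `n`, `share`.
#' @export
species_shares <- function(alignment, population = NULL) {
  stopifnot(inherits(alignment, "hap_alignment"))
  x <- alignment
  if (!is.null(population)) {
    x <- dplyr::filter(x, .data$population == !!population)
    if (nrow(x) == 0L) stop("no specimens in population: ", population)
  }
  x |>
    dplyr::count(.data$species, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n))
}

#' Expand a haplotype table back to one sequence per specimen
#'
#' Inverse of [collapse_haplotypes()]: reconstructs the specimen-level
#' multiset of sequences from the haplotype table.
#'
#' @param table A `hap_table`.
#' @return A [hap_alignment()] with one row per specimen.
#' @export
expand_haplotypes <- function(table) {
  stopifnot(inherits(table, "hap_table"))
  seqs <- table$haplotypes$sequence[
    match(table$membership$haplotype_id, table$haplotypes$haplotype_id)]
  hap_alignment(table$membership$id, seqs,
                population = table$membership$population,
                species = table$membership$species)
}

#' Write a haplotype table to TSV (and optionally FASTA)
#'
#' The TSV has one row per haplotype: id, total count, per-population counts
#' (wide) and the member specimen ids.
#'
#' @param table A `hap_table`.
#' @param path Output TSV path.
#' @param fasta Optional path for a haplotype FASTA (one record per
#'   haplotype).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(table, path, fasta = NULL) {
  stopifnot(inherits(table, "hap_table"))
  wide <- table$counts |>
    dplyr::mutate(population = dplyr::coalesce(.data$population, "unassigned")) |>
    dplyr::group_by(.data$haplotype_id, .data$population) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  members <- table$membership |>
    dplyr::group_by(.data$haplotype_id) |>
    dplyr::summarise(members = paste(.data$id, collapse = ","),
                     .groups = "drop")
  out <- table$haplotypes |>
    dplyr::select("haplotype_id", "n_total") |>
    dplyr::left_join(wide, by = "haplotype_id") |>
    dplyr::left_join(members, by = "haplotype_id")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    lines <- rbind(paste0(">", table$haplotypes$haplotype_id),
                   table$haplotypes$sequence)
    writeLines(as.vector(lines), fasta)
  }
  invisible(path)
}

# Named haplotype sequences (named character vector), internal convenience.
hap_sequences <- function(table) {
  stats::setNames(table$haplotypes$sequence, table$haplotypes$haplotype_id)
}
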