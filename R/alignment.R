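# Alignment container: a tibble with columns id, sequence, population, species
# and an `n_sites` attribute. Sequences are uppercase strings over the DNA
# alphabet plus gaps and IUPAC ambiguity codes; all rows have equal length.

ALPHABET <- c("A", "C", "G", "T", "N", "-",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
UNAMBIGUOUS <- c("A", "C", "G", "T")

#' Construct an alignment from sequence strings
#'
#' Builds the tabular alignment object used throughout the package: one row
#' per specimen, with the aligned sequence held as an uppercase string.
#' Lower-case input is uppercased and `U` is converted to `T` (with a
#' warning), so RNA-style input is tolerated.
#'
#' @param id Character vector of unique, non-empty specimen identifiers.
#' @param sequence Character vector of aligned sequences, all the same length.
#' @param population,species Optional label vectors (recycled if length 1).
#' @return A tibble of class `hap_alignment` with columns `id`, `sequence`,
#'   `population`, `species` and attribute `n_sites`.
#' @examples
#' aln <- hap_alignment(c("s1", "s2"), c("ACGT", "ACGA"))
#' n_sites(aln)
#' @export
hap_alignment <- function(id, sequence, population = NA_character_,
                          species = NA_character_) {
  if (length(id) == 0L) stop("alignment must contain at least one sequence")
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("duplicate sequence ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  sequence <- toupper(as.character(sequence))
  if (any(grepl("U", sequence, fixed = TRUE))) {
    warning("'U' characters found; converted to 'T'")
    sequence <- gsub("U", "T", sequence, fixed = TRUE)
  }
  lens <- nchar(sequence)
  if (any(lens == 0L)) stop("empty sequence for id: ",
                            paste(id[lens == 0L], collapse = ", "))
  if (length(unique(lens)) > 1L) {
    ref <- lens[1L]   # the first sequence sets the expected length
    bad <- id[lens != ref]
    stop("ragged alignment: sequences of differing length for id(s): ",
         paste(bad, collapse = ", "))
  }
  .check_alphabet(id, sequence)
  out <- tibble::tibble(
    id = id,
    sequence = sequence,
    population = rep_len(as.character(population), length(id)),
    species = rep_len(as.character(species), length(id))
  )
  attr(out, "n_sites") <- unname(lens[1L])
  class(out) <- c("hap_alignment", class(out))
  out
}

.check_alphabet <- function(id, sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(!chars[[i]] %in% ALPHABET)
    if (length(bad)) {
      stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                   chars[[i]][bad[1L]], id[i], bad[1L]))
    }
  }
  invisible(TRUE)
}

#' Number of aligned sites
#' @param alignment A `hap_alignment`.
#' @return Integer alignment length.
#' @export
n_sites <- function(alignment) {
  stopifnot(inherits(alignment, "hap_alignment"))
  attr(alignment, "n_sites")
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned FASTA into a [hap_alignment()], optionally restricted
#' to a 1-based inclusive window of sites (e.g. a gene fragment such as a
#' 549-bp cytochrome-b window). Input order is preserved; sequences are
#' uppercased on read.
#'
#' @param path Path to an aligned FASTA file.
#' @param window Optional integer vector `c(from, to)`, 1-based inclusive,
#'   within the alignment; the returned alignment holds only those columns.
#' @return A `hap_alignment`.
#' @export
read_alignment <- function(path, window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE),
    error = function(e) stop("cannot parse FASTA file ", path, ": ",
                             conditionMessage(e)))
  if (length(dna) == 0L) stop("no sequences in FASTA file: ", path)
  seqs <- vapply(dna, paste0, "", collapse = "")
  aln <- hap_alignment(names(dna), seqs)
  if (!is.null(window)) aln <- window_alignment(aln, window[1L], window[2L])
  aln
}

#' Restrict an alignment to a window of sites
#'
#' @param alignment A `hap_alignment`.
#' @param from,to 1-based inclusive bounds on the current alignment columns
#'   (not on any external, full-gene coordinate system).
#' @return A `hap_alignment` of length `to - from + 1`.
#' @export
window_alignment <- function(alignment, from, to) {
  L <- n_sites(alignment)
  if (from < 1L || to > L || from > to) {
    stop(sprintf("window [%d, %d] outside alignment sites [1, %d]",
                 from, to, L))
  }
  out <- alignment
  out$sequence <- substr(alignment$sequence, from, to)
  attr(out, "n_sites") <- as.integer(to - from + 1L)
  out
}

#' Attach population and species labels from a specimen table
#'
#' Reads a tab-separated specimen table with header columns `id`,
#' `population`, `species` and joins its labels onto the alignment. Specimens
#' missing from the table keep empty labels (with a warning); table rows whose
#' id is absent from the alignment are ignored with a warning; duplicate ids
#' in the table are an error.
#'
#' @param path Path to the popmap TSV.
#' @param alignment A `hap_alignment`.
#' @return The alignment with `population` and `species` columns filled in.
#' @export
read_popmap <- function(path, alignment) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("id", "population", "species")
  if (!all(need %in% names(map))) {
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$id)) {
    stop("duplicate ids in popmap: ",
         paste(unique(map$id[duplicated(map$id)]), collapse = ", "))
  }
  unknown <- setdiff(map$id, alignment$id)
  if (length(unknown)) {
    warning("popmap ids not present in alignment (ignored): ",
            paste(unknown, collapse = ", "))
  }
  hit <- match(alignment$id, map$id)
  unlabelled <- alignment$id[is.na(hit)]
  if (length(unlabelled)) {
    warning("alignment ids missing from popmap (labels left empty): ",
            paste(unlabelled, collapse = ", "))
  }
  out <- alignment
  out$population <- ifelse(is.na(hit), out$population, map$population[hit])
  out$species <- ifelse(is.na(hit), out$species, map$species[hit])
  out
}

# Row subset that keeps the hap_alignment class and n_sites attribute
# (plain tibble subsetting drops custom attributes).
subset_alignment <- function(alignment, rows) {
  out <- alignment[rows, ]
  attr(out, "n_sites") <- attr(alignment, "n_sites")
  class(out) <- c("hap_alignment", class(out)[class(out) != "hap_alignment"])
  out
}

# Character matrix view (specimens x sites); internal workhorse.
seq_matrix <- function(x) {
  seqs <- if (inherits(x, "hap_alignment")) x$sequence else as.character(x)
  ids <- if (inherits(x, "hap_alignment")) x$id else names(x)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  m
}

#' Pooled base composition of an alignment
#'
#' Fractions of A, C, G and T pooled over all sequences; gaps and ambiguity
#' codes are excluded from the denominator.
#'
#' @param alignment A `hap_alignment`.
#' @return A tibble with columns `base` and `freq` (the four fractions sum
#'   to 1).
#' @export
base_composition <- function(alignment) {
  stopifnot(inherits(alignment, "hap_alignment"))
  chars <- unlist(strsplit(alignment$sequence, "", fixed = TRUE))
  chars <- chars[chars %in% UNAMBIGUOUS]
  if (!length(chars)) stop("no unambiguous bases in alignment")
  tab <- table(factor(chars, levels = UNAMBIGUOUS))
  tibble::tibble(base = UNAMBIGUOUS, freq = as.numeric(tab) / sum(tab))
}

#' Write an alignment to FASTA
#' @param alignment A `hap_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  lines <- rbind(paste0(">", alignment$id), alignment$sequence)
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Write a popmap TSV for an alignment
#' @param alignment A `hap_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(alignment, path) {
  utils::write.table(
    data.frame(id = alignment$id,
               population = alignment$population,
               species = alignment$species),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences x %d sites\n",
              nrow(x), n_sites(x)))
  NextMethod()
}
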