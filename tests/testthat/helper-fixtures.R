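# In-code fixtures shared across test files.

toy_alignment <- function() {
  hap_alignment(
    id = paste0("s", 1:3),
    sequence = c("ACGTACGTAC", "ACGTACGTAC", "ACGAACGTAC")
  )
}

write_temp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

write_temp_popmap <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Row-subset that rebuilds a valid alignment object.
subset_spec <- function(aln, rows) {
  hap_alignment(aln$id[rows], aln$sequence[rows],
                population = aln$population[rows],
                species = aln$species[rows])
}

# Random ACGT alignment of n sequences, used by property-style tests.
random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

# Family of sequences derived from one ancestor with a bounded number of
# substitutions each (keeps K2P far from saturation, like real
# intrageneric mtDNA data).
mutated_family <- function(n, L, n_mut) {
  base <- strsplit(random_seqs(1, L), "")[[1]]
  other <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  vapply(seq_len(n), function(i) {
    s <- base
    sites <- sample.int(L, n_mut)
    for (p in sites) s[p] <- sample(other[[s[p]]], 1)
    paste0(s, collapse = "")
  }, "")
}

# Independent per-site classification of a pair (oracle for K2P inputs).
oracle_patterns <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[keep]; cb <- cb[keep]
  ts <- 0L; tv <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pur <- c("A", "G")
    if ((ca[i] %in% pur) == (cb[i] %in% pur)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(L = length(ca), ts = ts, tv = tv)
}
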