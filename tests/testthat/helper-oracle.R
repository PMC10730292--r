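# Independent brute-force oracle for fourfold third-position counting:
# an explicit per-codon loop that decides fourfold degeneracy from the
# vertebrate mitochondrial genetic code table itself (a codon family is
# fourfold iff all four third bases give the same, non-stop amino acid),
# with no reference to the package's family constant.
oracle_fourfold_counts <- function(cds) {
  code <- Biostrings::getGeneticCode("2")
  bases <- c("A", "C", "G", "T")
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  n <- 0L
  for (i in seq(1L, nchar(cds), by = 3L)) {
    codon <- substr(cds, i, i + 2L)
    chars <- strsplit(codon, "")[[1]]
    if (length(chars) < 3L || !all(chars %in% bases)) next
    family <- paste0(substr(codon, 1L, 2L), bases)
    aas <- code[family]
    if (length(unique(aas)) == 1L && !any(aas == "*")) {
      b3 <- chars[3L]
      counts[b3] <- counts[b3] + 1L
      n <- n + 1L
    }
  }
  list(counts = counts, n = n)
}

# random in-frame CDS over all 64 codons (stops and all)
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  paste(sample(bases, 3L * n_codons, replace = TRUE), collapse = "")
}
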