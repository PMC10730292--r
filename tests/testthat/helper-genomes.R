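# Small in-code fixtures shared across test files.

# fast, tiny simulator settings for tests where composition does not matter
tiny_spec <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, pcg_length = 12, trna_length = 12,
                   rrnS_length = 40, rrnL_length = 60, cr_length = 60)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_spec, args)
}

# a handcrafted two-gene GenBank record: one forward CDS, one minus-strand
# CDS at positions 1..9 (1-based), on a short linear-text circular record
write_two_gene_genbank <- function(path) {
  seqline <- "atggcataaa tggcataagg cagcggctcc ataaacgtaa"
  writeLines(c(
    "LOCUS       TESTREC01              40 bp    DNA     circular MIT 01-JAN-2024",
    "DEFINITION  handcrafted two-gene test record.",
    "ACCESSION   TESTREC01",
    "VERSION     TESTREC01.1",
    "SOURCE      mitochondrion Testus fabricatus",
    "  ORGANISM  Testus fabricatus",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             complement(1..9)",
    "                     /gene=\"ND1\"",
    "                     /codon_start=1",
    "     CDS             10..27",
    "                     /gene=\"COX1\"",
    "                     /codon_start=1",
    "ORIGIN",
    sprintf("%9d %s", 1, seqline),
    "//"
  ), path)
  path
}

# a circular record whose single CDS wraps the origin:
# join(91..120,1..30) on a 120 bp record -> 60 bp CDS
write_wrapping_genbank <- function(path) {
  set.seed(42)
  body <- paste(sample(c("a", "c", "g", "t"), 120, replace = TRUE),
                collapse = "")
  # make the wrapped CDS an open reading frame: ATG + 18 codons + TAA
  cds <- paste0("ATG", strrep("GCA", 18), "TAA")
  body <- paste0(substr(body, 1, 90), substr(cds, 1, 30))   # 91..120
  body <- paste0(tolower(substr(cds, 31, 60)), substr(body, 31, 120))
  lines <- c(
    "LOCUS       WRAPREC01             120 bp    DNA     circular MIT 01-JAN-2024",
    "DEFINITION  wrapping CDS test record.",
    "VERSION     WRAPREC01.1",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             join(91..120,1..30)",
    "                     /gene=\"ND2\"",
    "                     /codon_start=1",
    "ORIGIN"
  )
  starts <- seq(1, 120, by = 60)
  for (s in starts) {
    lines <- c(lines, sprintf("%9d %s", s, tolower(substr(body, s, s + 59))))
  }
  writeLines(c(lines, "//"), path)
  list(path = path, cds = toupper(cds))
}
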