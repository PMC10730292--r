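test_that("the packaged template has the standard vertebrate gene content", {
  t <- vertebrate_template()
  expect_equal(nrow(t), 38L)  # 37 genes + Control Region
  expect_equal(sum(t$ftype == "PCG"), 13L)
  expect_equal(sum(t$ftype == "tRNA"), 22L)
  expect_equal(sum(t$ftype == "rRNA"), 2L)
  expect_equal(sum(t$ftype == "CR"), 1L)
  expect_false(any(duplicated(t$label)))
})

test_that("gene and product name variants normalise to canonical labels", {
  expect_equal(canonical_label(c("ND2", "nadh1", "COI", "CO3", "CYTB",
                                 "ATPase6", "12S rRNA", "16S ribosomal RNA",
                                 "D-loop", "control region", "mystery orf")),
               c("nad2", "nad1", "cox1", "cox3", "cob", "atp6", "rrnS",
                 "rrnL", "CR", "CR", "OTHER"))
  expect_equal(canonical_label(c("tRNA-Phe", "trnV", "tRNA-Trp")),
               c("F", "V", "W"))
  # Leu/Ser isoacceptors by codon family, explicit index, or anticodon
  expect_equal(canonical_label("tRNA-Leu (UUR)"), "L1")
  expect_equal(canonical_label("trnL2"), "L2")
  expect_equal(canonical_label("tRNA-Ser", anticodon = "TGA"), "S1")
  expect_equal(canonical_label("tRNA-Ser", anticodon = "GCT"), "S2")
  expect_equal(canonical_label("tRNA-Leu"), "L?")  # provisional, resolved positionally
})

test_that("handcrafted GenBank coordinates follow the 0-based half-open convention", {
  path <- withr::local_tempfile(fileext = ".gb")
  write_two_gene_genbank(path)
  g <- read_genbank(path)
  expect_s3_class(g, "mito_genome")
  expect_true(g$circular)
  expect_equal(genome_length(g), 40L)
  nd1 <- g$features[g$features$label == "nad1", ]
  expect_equal(nd1$strand, "-")
  expect_equal(nd1$start, 0L)
  expect_equal(nd1$end, 9L)
  cox1 <- g$features[g$features$label == "cox1", ]
  expect_equal(cox1$ftype, "PCG")
  expect_equal(c(cox1$start, cox1$end), c(9L, 27L))
  # minus-strand extraction reverse-complements: stored "atggcataa" -> RC
  expect_equal(extract_cds(g, nd1), revcomp("ATGGCATAA"))
})

test_that("an origin-spanning join becomes one wrapping feature with the full CDS", {
  path <- withr::local_tempfile(fileext = ".gb")
  fix <- write_wrapping_genbank(path)
  g <- read_genbank(path)
  ft <- g$features[g$features$label == "nad2", ]
  expect_true(ft$wraps_origin)
  expect_equal(ft$start, 90L)
  expect_equal(ft$end, 30L)
  expect_equal(nchar(extract_cds(g, ft)), 60L)
  expect_equal(extract_cds(g, ft), fix$cds)
})

test_that("extract_cds honours codon_start and drops incomplete terminal codons", {
  g <- mito_genome("ATGGCATCC",
                   tibble::tibble(label = "nad1", ftype = "PCG", start = 0,
                                  end = 7, strand = "+"))
  expect_equal(extract_cds(g, g$features[1, ]), "ATGGCA")
  g2 <- mito_genome("ATGGCATCC",
                    tibble::tibble(label = "nad1", ftype = "PCG", start = 0,
                                   end = 9, strand = "+", codon_start = 2))
  expect_equal(extract_cds(g2, g2$features[1, ]), "TGGCAT")
  g3 <- mito_genome("TGCCATAAA",
                    tibble::tibble(label = "nad1", ftype = "PCG", start = 0,
                                   end = 6, strand = "-"))
  expect_equal(extract_cds(g3, g3$features[1, ]), "ATGGCA")
  g4 <- mito_genome("ATGC",
                    tibble::tibble(label = "nad1", ftype = "PCG", start = 0,
                                   end = 2, strand = "+"))
  expect_error(extract_cds(g4, g4$features[1, ]), class = "mitoasym_cds_too_short")
})

test_that("GenBank writing then reading is the identity on annotations", {
  sim <- simulate_genome(tiny_spec(seed = 3))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  back <- read_genbank(path)
  expect_equal(back$sequence, sim$genome$sequence)
  expect_equal(back$circular, sim$genome$circular)
  cols <- c("label", "ftype", "start", "end", "strand", "codon_start",
            "wraps_origin", "copy_index")
  expect_equal(as.data.frame(back$features[, cols]),
               as.data.frame(sim$genome$features[, cols]))
})

test_that("a genome with a wrapping feature round-trips through GenBank", {
  sim <- simulate_genome(tiny_spec(seed = 4))
  rot <- rotate_genome(sim$genome, genome_length(sim$genome) - 20L)
  expect_true(any(rot$features$wraps_origin))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rot, path)
  back <- read_genbank(path)
  cols <- c("label", "start", "end", "strand", "wraps_origin")
  expect_equal(as.data.frame(back$features[, cols]),
               as.data.frame(rot$features[, cols]))
  expect_equal(back$sequence, rot$sequence)
})

test_that("FASTA + GFF3 writing then reading is the identity, with phase mapped to codon_start", {
  sim <- simulate_genome(tiny_spec(seed = 5))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fasta_gff(sim$genome, fa, gff)
  back <- read_fasta_gff(fa, gff)
  cols <- c("label", "ftype", "start", "end", "strand", "codon_start",
            "wraps_origin")
  expect_equal(as.data.frame(back$features[, cols]),
               as.data.frame(sim$genome$features[, cols]))
  expect_equal(back$sequence, sim$genome$sequence)
  # GFF3 phase p means p bases are skipped to reach the first codon: phase 1
  # is codon_start 2
  lines <- readLines(gff)
  cds <- grep("\tCDS\t", lines, value = TRUE)
  expect_true(all(vapply(strsplit(cds, "\t"), `[`, character(1), 8) == "0"))
  tweaked <- sub("(\tCDS\t[0-9]+\t[0-9]+\t\\.\t[+-]\t)0", "\\11", lines[grep("\tCDS\t", lines)[1]])
  lines[grep("\tCDS\t", lines)[1]] <- tweaked
  writeLines(lines, gff)
  back2 <- read_fasta_gff(fa, gff)
  expect_equal(back2$features$codon_start[back2$features$ftype == "PCG"][1], 2L)
})

test_that("an empty GFF yields a featureless genome with a warning", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">rec1", "ACGTACGTACGT"), fa)
  writeLines("##gff-version 3", gff)
  expect_warning(g <- read_fasta_gff(fa, gff), "no features")
  expect_equal(nrow(g$features), 0L)
  writeLines(c("##gff-version 3",
               paste("other_rec", "x", "CDS", 1, 6, ".", "+", "0",
                     "ID=z", sep = "\t")), gff)
  expect_error(read_fasta_gff(fa, gff), class = "mitoasym_seqid_mismatch")
})

test_that("feature extraction length equals end - start (+ wrap), independent of strand", {
  sim <- simulate_genome(tiny_spec(seed = 6))
  g <- rotate_genome(sim$genome, 33L)
  len <- genome_length(g)
  f <- g$features
  for (i in seq_len(nrow(f))) {
    expected <- ifelse(f$wraps_origin[i], len - f$start[i] + f$end[i],
                       f$end[i] - f$start[i])
    expect_equal(nchar(feature_seq(g, f[i, ])), expected)
  }
})

test_that("unmappable feature names are kept as 'other' with a warning", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       ODDREC                 30 bp    DNA     circular MIT 01-JAN-2024",
    "VERSION     ODDREC.1",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    1..12",
    "                     /gene=\"strange element\"",
    "ORIGIN",
    sprintf("%9d %s", 1, "atggcataag gcagcggctc cataaacgta"),
    "//"), path)
  expect_warning(g <- read_genbank(path), "unmappable")
  expect_equal(g$features$ftype, "other")
  expect_equal(g$features$raw_label, "strange element")
})
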