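test_that("fourfold third-position counting follows the eight codon families", {
  # ATG GCA GCG GCT CCA TAA: retained GCA, GCG, GCT, CCA
  r <- fourfold_third_counts("ATGGCAGCGGCTCCATAA")
  expect_equal(r$n_fourfold, 4L)
  expect_equal(c(r$A, r$C, r$G, r$T), c(2L, 0L, 1L, 1L))
  # no family prefix present
  expect_equal(fourfold_third_counts("ATGTGATAA")$n_fourfold, 0L)
  # ambiguous third base excludes the codon entirely
  expect_equal(fourfold_third_counts("GCN")$n_fourfold, 0L)
  # ambiguity in the family prefix also excludes
  expect_equal(fourfold_third_counts("GNAACA")$n_fourfold, 1L)
  expect_error(fourfold_third_counts("ATGG"), class = "mitoasym_frame_error")
})

test_that("no stop codon of the vertebrate mitochondrial code is in a fourfold family", {
  code <- Biostrings::getGeneticCode("2")
  stops <- names(code)[code == "*"]
  expect_setequal(stops, c("TAA", "TAG", "AGA", "AGG"))
  expect_false(any(substr(stops, 1, 2) %in% FOURFOLD_FAMILIES))
})

test_that("the eight families are exactly the fourfold-degenerate ones under table 2", {
  code <- Biostrings::getGeneticCode("2")
  bases <- c("A", "C", "G", "T")
  prefixes <- as.vector(outer(bases, bases, paste0))
  fourfold <- prefixes[vapply(prefixes, function(p) {
    aas <- code[paste0(p, bases)]
    length(unique(aas)) == 1L && !any(aas == "*")
  }, logical(1))]
  expect_setequal(fourfold, FOURFOLD_FAMILIES)
})

test_that("skew formulas and undefined-denominator handling are correct", {
  s <- compute_skews(c(A = 2, T = 1, G = 1, C = 0))
  expect_equal(s$at_skew, 1 / 3)
  expect_equal(s$gc_skew, 1)
  expect_true(s$defined_at && s$defined_gc)
  s2 <- compute_skews(c(A = 5, T = 5, G = 7, C = 7))
  expect_equal(c(s2$at_skew, s2$gc_skew), c(0, 0))
  s3 <- compute_skews(c(A = 0, T = 0, G = 5, C = 5))
  expect_true(is.na(s3$at_skew))
  expect_false(s3$defined_at)
  expect_equal(s3$gc_skew, 0)
})

test_that("counts are conserved and unaffected by non-fourfold codons", {
  withr::local_seed(101)
  for (i in 1:25) {
    cds <- random_cds(60)
    r <- fourfold_third_counts(cds)
    expect_equal(r$A + r$C + r$G + r$T, r$n_fourfold)
    # removing non-fourfold codons leaves the counts unchanged
    starts <- seq(1, nchar(cds), by = 3)
    codons <- substring(cds, starts, starts + 2)
    kept <- codons[substr(codons, 1, 2) %in% FOURFOLD_FAMILIES]
    r2 <- fourfold_third_counts(paste(kept, collapse = ""))
    expect_equal(r2[, c("A", "C", "G", "T", "n_fourfold")],
                 r[, c("A", "C", "G", "T", "n_fourfold")])
  }
})

test_that("production counter agrees exactly with the brute-force codon-table oracle", {
  withr::local_seed(202)
  for (i in 1:300) {
    cds <- random_cds(sample(20:80, 1))
    r <- fourfold_third_counts(cds)
    o <- oracle_fourfold_counts(cds)
    expect_equal(c(A = r$A, C = r$C, G = r$G, T = r$T), o$counts)
    expect_equal(r$n_fourfold, o$n)
  }
})

test_that("viewing the same fourfold sites from the complementary strand negates both skews", {
  withr::local_seed(303)
  for (i in 1:40) {
    cds <- random_cds(70)
    counts <- fourfold_third_counts(cds)
    sf <- compute_skews(counts)
    # the complementary strand pairs A<->T and G<->C at every site
    sc <- compute_skews(c(A = counts$T, T = counts$A,
                          G = counts$C, C = counts$G))
    if (isTRUE(sf$defined_at)) expect_equal(sc$at_skew, -sf$at_skew)
    if (isTRUE(sf$defined_gc)) expect_equal(sc$gc_skew, -sf$gc_skew)
  }
})

test_that("genes simulated with negated targets show negated skews within error", {
  std <- simulate_genome(synthetic_spec(seed = 42))
  neg <- simulate_genome(synthetic_spec(seed = 43, target_at_skew = 0.3,
                                        target_gc_skew = -0.4))
  a <- gene_skew_table(std$genome)
  b <- gene_skew_table(neg$genome)
  # signs must flip wherever the estimate is clearly away from zero
  clear <- function(x) abs(x) >= 0.05
  plus <- a$strand == "+"
  at_ok <- plus & clear(a$at_skew) & clear(b$at_skew)
  gc_ok <- plus & clear(a$gc_skew) & clear(b$gc_skew)
  expect_gt(sum(at_ok), 8)
  expect_true(all(sign(b$at_skew[at_ok]) == -sign(a$at_skew[at_ok])))
  expect_true(all(sign(b$gc_skew[gc_ok]) == -sign(a$gc_skew[gc_ok])))
})

test_that("frame inference recovers constructed frames and flags random sequence", {
  sim <- simulate_genome(synthetic_spec(seed = 9, pcg_length = 100))
  f <- sim$genome$features
  cds <- extract_cds(sim$genome, f[f$label == "cox1", ])
  fr <- infer_frame(cds)
  expect_equal(fr$frame, 0L)
  expect_false(fr$low_confidence)
  expect_equal(infer_frame(paste0("G", cds))$frame, 1L)
  expect_equal(infer_frame(paste0("GG", cds))$frame, 2L)
  withr::local_seed(7)
  rnd <- random_cds(100)
  fr2 <- infer_frame(rnd)
  expect_true(fr2$frame %in% 0:2)
  expect_true(fr2$low_confidence)
  expect_error(infer_frame("ATGGCA"), class = "mitoasym_too_short")
})

test_that("single-gene screening reproduces annotated-mode skews and records the frame", {
  s <- single_gene_skew("ATGGCAGCGGCTCCATAA", assume_frame = 0)
  expect_equal(s$at_skew, 1 / 3)
  expect_equal(s$gc_skew, 1)
  expect_equal(s$frame, 0L)
  # the complementary-strand view of the same sites negates the skews
  s2 <- compute_skews(c(A = s$T, T = s$A, G = s$C, C = s$G))
  expect_equal(s2$at_skew, -1 / 3)
  expect_equal(s2$gc_skew, -1)
  # AAN is not a fourfold family
  s3 <- single_gene_skew(strrep("AAA", 30), assume_frame = 0)
  expect_equal(s3$n_fourfold, 0L)
  expect_true(is.na(s3$at_skew) && is.na(s3$gc_skew))
})

test_that("gene_skew_table yields one row per PCG copy in template order", {
  sim <- simulate_genome(synthetic_spec(seed = 10, pcg_length = 60))
  tab <- gene_skew_table(sim$genome)
  expect_equal(nrow(tab), 13L)
  expect_equal(tab$gene, c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6",
                           "cox3", "nad3", "nad4l", "nad4", "nad5", "nad6",
                           "cob"))
  dup <- apply_rearrangement(sim$genome,
                             list(etype = "duplication", genes = "nad3"))
  tab2 <- gene_skew_table(dup)
  expect_equal(nrow(tab2), 14L)
  expect_equal(tab2$copy[tab2$gene == "nad3"], c(1L, 2L))
  g0 <- mito_genome("ACGTACGTAC",
                    tibble::tibble(label = "F", ftype = "tRNA", start = 0,
                                   end = 10, strand = "+"))
  expect_warning(empty <- gene_skew_table(g0), "no protein-coding")
  expect_equal(nrow(empty), 0L)
})

test_that("simulated genes recover their target skews within binomial error", {
  sim <- simulate_genome(synthetic_spec(seed = 123))  # default 200-codon genes
  tab <- gene_skew_table(sim$genome)
  truth <- sim$truth$per_gene
  m <- dplyr::inner_join(tab, truth, by = "gene")
  expect_equal(nrow(m), 13L)
  # 26 estimates (13 genes x 2 axes): with a 3-SE band (~99.7% each) at most
  # one exceedance is statistically comfortable; 4 SE must never be exceeded
  z <- function(est, target, n) abs(est - target) /
    (2 * sqrt((1 + target) / 2 * (1 - target) / 2 / n))
  zs <- c(z(m$at_skew, m$a, m$A + m$T), z(m$gc_skew, m$g, m$G + m$C))
  expect_lte(sum(zs > 3), 1L)
  expect_true(all(zs < 4))
})
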