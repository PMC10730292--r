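test_that("the expected signature follows gene polarity relative to the CR", {
  expect_equal(expected_signature("+", "+"), list(at_sign = -1, gc_sign = 1))
  expect_equal(expected_signature("-", "+"), list(at_sign = 1, gc_sign = -1))
  expect_equal(expected_signature("-", "-"), list(at_sign = -1, gc_sign = 1))
  expect_equal(expected_signature("+", "-"), list(at_sign = 1, gc_sign = -1))
  expect_error(expected_signature("+", "undetermined"),
               class = "mitoasym_cr_undetermined")
})

test_that("per-gene classification distinguishes concordant, reversed and ambiguous", {
  exp_std <- expected_signature("+", "+")
  p <- classifier_params()
  expect_equal(classify_gene(-0.3, 0.4, 50, exp_std, p), "concordant")
  expect_equal(classify_gene(0.3, -0.4, 50, exp_std, p), "reversed")
  expect_equal(classify_gene(-0.01, 0.02, 50, exp_std, p), "ambiguous")
  expect_equal(classify_gene(-0.3, 0.4, 5, exp_std, p), "ambiguous")   # too few sites
  expect_equal(classify_gene(NA, 0.4, 50, exp_std, p), "ambiguous")    # undefined
  expect_equal(classify_gene(-0.3, -0.4, 50, exp_std, p), "ambiguous") # axes disagree
  # one strong axis is enough when both signs agree with the expectation
  expect_equal(classify_gene(-0.02, 0.4, 50, exp_std, p), "concordant")
})

test_that("raising tau only ever moves genes towards ambiguity", {
  withr::local_seed(55)
  exp_std <- expected_signature("+", "+")
  for (i in 1:200) {
    at <- stats::runif(1, -0.5, 0.5)
    gc <- stats::runif(1, -0.5, 0.5)
    lo <- classify_gene(at, gc, 50, exp_std, classifier_params(tau = 0.02))
    hi <- classify_gene(at, gc, 50, exp_std, classifier_params(tau = 0.2))
    if (lo != hi) expect_equal(hi, "ambiguous")
    if (hi != "ambiguous") expect_equal(lo, hi)
  }
})

test_that("a standard-architecture genome classifies standard with all genes concordant", {
  sim <- simulate_genome(synthetic_spec(seed = 61))
  call <- classify_genome(sim$genome)
  expect_equal(call$genome_state, "standard")
  expect_equal(call$cr_orientation, "co-oriented")
  # sampling noise may leave the odd gene ambiguous, never counter-classified
  expect_gte(sum(call$per_gene$gene_state == "concordant"), 12L)
  expect_false(any(call$per_gene$gene_state == "reversed"))
  expect_equal(nrow(call$per_gene), 13L)  # every PCG exactly once
  expect_equal(sim$truth$label, "standard")
})

test_that("a CR-inverted, re-equilibrated genome classifies reversed", {
  sim <- simulate_genome(synthetic_spec(seed = 62, cr_strand = "-"))
  call <- classify_genome(sim$genome)
  expect_equal(call$genome_state, "reversed")
  expect_equal(call$cr_strand, "-")
  expect_equal(call$cr_orientation, "counter-oriented")
  expect_gte(sum(call$per_gene$gene_state == "concordant"), 12L)
  expect_false(any(call$per_gene$gene_state == "reversed"))
  expect_equal(sim$truth$label, "reversed")
})

test_that("a CR inversion without compositional re-equilibration classifies disrupted", {
  # CR flipped but every gene still carries the standard composition: the
  # transitory state
  sim <- simulate_genome(synthetic_spec(seed = 63, cr_strand = "-",
                                        target_at_skew = 0.3,
                                        target_gc_skew = -0.4))
  call <- classify_genome(sim$genome)
  expect_equal(call$genome_state, "disrupted")
  expect_equal(sim$truth$label, "disrupted")
  expect_true(all(call$per_gene$gene_state %in% c("reversed", "ambiguous")))
})

test_that("a block inversion carrying the CR leaves only the co-moved PCG concordant", {
  sim <- simulate_genome(synthetic_spec(
    seed = 64,
    edits = list(list(etype = "inversion",
                      genes = c("CR", "F", "rrnS", "V", "rrnL", "L1", "nad1")))))
  call <- classify_genome(sim$genome)
  expect_equal(call$genome_state, "disrupted")
  pg <- call$per_gene
  expect_equal(pg$gene_state[pg$gene == "nad1"], "concordant")
  others <- pg$gene_state[pg$gene != "nad1"]
  expect_true(all(others %in% c("reversed", "ambiguous")))
  expect_gt(mean(others == "reversed"), 0.8)
})

test_that("an undetectable CSB-II yields an undetermined call with signs still reported", {
  sim <- simulate_genome(synthetic_spec(seed = 65))
  g <- sim$genome
  # erase the motif from the CR
  cr <- g$features[g$features$ftype == "CR", ]
  crseq <- substr(g$sequence, cr$start + 1, cr$end)
  crseq <- gsub("C{5,}TAC{4,}", strrep("A", 13), crseq)
  g$sequence <- paste0(substr(g$sequence, 1, cr$start), crseq,
                       substr(g$sequence, cr$end + 1, nchar(g$sequence)))
  call <- classify_genome(g)
  expect_equal(call$genome_state, "undetermined")
  expect_equal(call$cr_strand, "undetermined")
  expect_equal(nrow(call$per_gene), 13L)
  expect_true(all(is.finite(call$per_gene$at_skew)))
  expect_true(all(is.na(call$per_gene$gene_state)))
})

test_that("the genome call is invariant under reverse complement of the stored genome", {
  for (seed in 66:68) {
    cs <- if (seed %% 2) "+" else "-"
    sim <- simulate_genome(synthetic_spec(seed = seed, cr_strand = cs))
    a <- classify_genome(sim$genome)
    b <- classify_genome(reverse_complement_genome(sim$genome))
    expect_equal(b$genome_state, a$genome_state)
    expect_equal(b$cr_orientation, a$cr_orientation)
  }
})

test_that("duplicated PCGs contribute only their longest copy", {
  sim <- simulate_genome(synthetic_spec(seed = 69))
  dup <- apply_rearrangement(sim$genome,
                             list(etype = "duplication", genes = "nad3"))
  # truncate the second copy to a pseudogene-like stub
  f <- dup$features
  i <- which(f$label == "nad3" & f$copy_index == 2L)
  dup$features$end[i] <- dup$features$start[i] + 30L
  call <- classify_genome(dup)
  expect_equal(sum(call$per_gene$gene == "nad3"), 1L)
  expect_equal(call$per_gene$copy[call$per_gene$gene == "nad3"], 1L)
  expect_equal(call$genome_state, "standard")
})

test_that("tidy, glance and the cohort report aggregate calls faithfully", {
  sims <- list(
    standard = simulate_genome(synthetic_spec(seed = 71, id = "G1")),
    reversed = simulate_genome(synthetic_spec(seed = 72, cr_strand = "-",
                                              id = "G2")),
    disrupted = simulate_genome(synthetic_spec(seed = 73, cr_strand = "-",
                                               target_at_skew = 0.3,
                                               target_gc_skew = -0.4,
                                               id = "G3")))
  calls <- lapply(sims, function(s) classify_genome(s$genome))
  td <- tidy(calls$standard)
  expect_equal(nrow(td), 13L)
  expect_true(all(c("genome", "gene", "at_skew", "gc_skew", "gene_state",
                    "genome_state") %in% names(td)))
  gl <- glance(calls$reversed)
  expect_equal(nrow(gl), 1L)
  expect_gte(gl$n_concordant, 12L)
  rep <- cohort_report(calls)
  expect_equal(nrow(rep$per_gene), 39L)
  expect_equal(sort(rep$summary$genome_state),
               c("disrupted", "reversed", "standard"))
  expect_equal(rep$summary$n_genomes, c(1L, 1L, 1L))
  p <- autoplot(calls$standard)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(rep)
  expect_s3_class(p2, "ggplot")
})
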