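#' Specification for a synthetic annotated mitogenome
#'
#' Defines the study conditions a simulated genome emulates: the standard
#' 37-gene vertebrate architecture, a strand-specific compositional bias at
#' fourfold third-codon positions with parametrised target skews, a Control
#' Region carrying the CSB-II motif in a chosen orientation, and an optional
#' list of architecture edits.
#'
#' The compositional model draws each protein-coding codon independently:
#' with probability `fourfold_prop` a fourfold-family codon whose third base
#' has distribution `A: f(1+a)/2`, `T: f(1-a)/2`, `G: (1-f)(1+g)/2`,
#' `C: (1-f)(1-g)/2`, where `f = at_content` and `(a, g)` are the target
#' skews for genes coded on the CR strand and `(-a, -g)` for genes on the
#' opposite strand; otherwise a non-fourfold codon with an unbiased third
#' position, so only fourfold sites carry signal. Because a sequence-level
#' inversion preserves a gene's coding-strand composition, an edited gene is
#' *not* re-equilibrated to its new polarity unless `equilibrate = TRUE`,
#' which pre-negates the targets of genes the edits will strand-flip.
#'
#' @param pcg_length Codons per PCG including start and stop (default 200).
#' @param trna_length tRNA length in bases (default 70).
#' @param rrnS_length,rrnL_length rRNA lengths in bases.
#' @param cr_length Control-Region length in bases (default 900).
#' @param target_at_skew,target_gc_skew Target skews in (-1, 1) at fourfold
#'   third positions of CR-strand genes. Defaults -0.3 and +0.4: the
#'   standard vertebrate sign regime (AT < 0, GC > 0) at magnitudes typical
#'   of fish mitogenomes.
#' @param at_content Fraction of A+T at fourfold third positions (default 0.6).
#' @param fourfold_prop Proportion of internal codons drawn from fourfold
#'   families (default 0.5).
#' @param cr_strand Orientation of the CSB-II motif, hence of the CR
#'   (`"+"` or `"-"`). With unchanged targets, `"-"` yields the fully
#'   re-equilibrated (reversed-asymmetry) genome.
#' @param edits List of edits applied in order by [apply_rearrangement()];
#'   each is a list with `etype` (`"inversion"`, `"translocation"`,
#'   `"shuffle"`, `"duplication"`), `genes` (character vector of canonical
#'   labels) and, for translocations, `after` (label to insert behind).
#' @param equilibrate Re-equilibrate the composition of genes the edits
#'   strand-flip (default `FALSE`: edits leave composition behind, the
#'   transitory state).
#' @param seed Integer seed; the simulation is deterministic given the spec.
#' @param id,species Identifier and organism label of the emitted genome.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(pcg_length = 200, trna_length = 70,
                           rrnS_length = 950, rrnL_length = 1600,
                           cr_length = 900,
                           target_at_skew = -0.3, target_gc_skew = 0.4,
                           at_content = 0.6, fourfold_prop = 0.5,
                           cr_strand = "+", edits = list(),
                           equilibrate = FALSE, seed = 1L,
                           id = NULL, species = "Synthetica simulata") {
  stopifnot(abs(target_at_skew) < 1, abs(target_gc_skew) < 1,
            at_content > 0, at_content < 1,
            fourfold_prop >= 0, fourfold_prop <= 1,
            pcg_length >= 3, trna_length > 0, cr_length > nchar(CSB2_REFERENCE),
            cr_strand %in% c("+", "-"))
  structure(list(pcg_length = as.integer(pcg_length),
                 trna_length = as.integer(trna_length),
                 rrnS_length = as.integer(rrnS_length),
                 rrnL_length = as.integer(rrnL_length),
                 cr_length = as.integer(cr_length),
                 target_at_skew = target_at_skew,
                 target_gc_skew = target_gc_skew,
                 at_content = at_content, fourfold_prop = fourfold_prop,
                 cr_strand = cr_strand, edits = edits,
                 equilibrate = isTRUE(equilibrate),
                 seed = as.integer(seed),
                 id = id %||% sprintf("SYN%06d", as.integer(seed) %% 1000000L),
                 species = species),
            class = "synthetic_spec")
}

# non-fourfold codon prefixes that are coding for every third base under the
# vertebrate mitochondrial code (no stops: TAN and AGN are excluded)
NONFOURFOLD_PREFIXES <- c("AT", "AA", "TG", "CA", "GA", "TT")

#' Simulate an annotated mitogenome with known ground truth
#'
#' Builds the standard vertebrate architecture gene by gene under the
#' compositional model of [synthetic_spec()], embeds the CSB-II reference
#' motif mid-CR on the chosen strand, applies the requested edits via
#' [apply_rearrangement()], and returns both the genome and the ground
#' truth needed to score downstream analyses. Deterministic given the spec
#' (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `genome` (a [mito_genome()]) and `truth`
#'   (list: `order` signature tibble, `cr_strand`, `per_gene` tibble of
#'   final strands, realised targets and fourfold site counts, `edits`,
#'   and `label`, the expected genome-level asymmetry state).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  template <- vertebrate_template()
  flip_set <- edit_flip_set(spec$edits, template)
  pieces <- character(nrow(template))
  feats <- vector("list", nrow(template))
  truth_rows <- vector("list", nrow(template))
  pos <- 0L
  for (i in seq_len(nrow(template))) {
    row <- template[i, ]
    if (row$ftype == "PCG") {
      a <- if (row$strand == spec$cr_strand) spec$target_at_skew else -spec$target_at_skew
      g <- if (row$strand == spec$cr_strand) spec$target_gc_skew else -spec$target_gc_skew
      if (spec$equilibrate && row$label %in% flip_set) { a <- -a; g <- -g }
      sim <- simulate_pcg(spec$pcg_length, a, g, spec$at_content,
                          spec$fourfold_prop)
      coding <- sim$cds
      truth_rows[[i]] <- tibble(gene = row$label, a = a, g = g,
                                n_fourfold = sim$n_fourfold)
      piece <- if (row$strand == "-") revcomp(coding) else coding
    } else if (row$ftype == "CR") {
      piece <- simulate_cr(spec$cr_length, spec$cr_strand)
    } else {
      n <- switch(row$label, rrnS = spec$rrnS_length,
                  rrnL = spec$rrnL_length, spec$trna_length)
      piece <- random_dna(n)
    }
    pieces[i] <- piece
    feats[[i]] <- tibble(label = row$label, ftype = row$ftype,
                         start = pos, end = pos + nchar(piece),
                         strand = if (row$ftype == "CR") "+" else row$strand,
                         codon_start = if (row$ftype == "PCG") 1L else NA_integer_,
                         wraps_origin = FALSE)
    pos <- pos + nchar(piece)
  }
  genome <- mito_genome(paste(pieces, collapse = ""), dplyr::bind_rows(feats),
                        id = spec$id, species = spec$species, circular = TRUE)
  for (ed in spec$edits) genome <- apply_rearrangement(genome, ed)
  truth <- build_truth(spec, genome, dplyr::bind_rows(truth_rows))
  list(genome = genome, truth = truth)
}

edit_flip_set <- function(edits, template) {
  flips <- character()
  n <- nrow(template)
  for (ed in edits) {
    if (identical(ed$etype, "inversion")) {
      idx <- sort(match(ed$genes, template$label))
      if ((max(idx) - min(idx) + 1L) == length(idx)) {
        flips <- c(flips, template$label[seq(min(idx), max(idx))])
      } else {
        # run wraps the circular template boundary: the listed genes are it
        flips <- c(flips, template$label[idx])
      }
    }
  }
  unique(flips)
}

simulate_pcg <- function(n_codons, a, g, f, fourfold_prop) {
  n_internal <- n_codons - 2L
  is_ff <- stats::runif(n_internal) < fourfold_prop
  n_ff <- sum(is_ff)
  codons <- character(n_internal)
  if (n_ff) {
    fam <- sample(FOURFOLD_FAMILIES, n_ff, replace = TRUE)
    third <- sample(ACGT, n_ff, replace = TRUE,
                    prob = c(f * (1 + a) / 2, (1 - f) * (1 - g) / 2,
                             (1 - f) * (1 + g) / 2, f * (1 - a) / 2))
    codons[is_ff] <- paste0(fam, third)
  }
  if (n_internal - n_ff) {
    pre <- sample(NONFOURFOLD_PREFIXES, n_internal - n_ff, replace = TRUE)
    codons[!is_ff] <- paste0(pre, sample(ACGT, n_internal - n_ff, replace = TRUE))
  }
  list(cds = paste0("ATG", paste(codons, collapse = ""), "TAA"),
       n_fourfold = n_ff)
}

simulate_cr <- function(cr_length, cr_strand) {
  motif <- if (cr_strand == "-") revcomp(CSB2_REFERENCE) else CSB2_REFERENCE
  flank <- cr_length - nchar(motif)
  left <- flank %/% 2L
  paste0(random_dna(left), motif, random_dna(flank - left))
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(ACGT, n, replace = TRUE), collapse = "")
}

build_truth <- function(spec, genome, per_gene) {
  f <- genome$features
  strands <- stats::setNames(f$strand[f$ftype == "PCG" & f$copy_index == 1L],
                             f$label[f$ftype == "PCG" & f$copy_index == 1L])
  per_gene$strand <- unname(strands[per_gene$gene])
  cr_strand <- f$strand[f$ftype == "CR"][1]
  # the CR was built on spec$cr_strand relative to its annotated "+"
  # orientation; an inversion edit flips the annotated strand
  cr_final <- if (identical(cr_strand, "-")) {
    if (spec$cr_strand == "+") "-" else "+"
  } else spec$cr_strand
  majority <- names(sort(table(per_gene$strand), decreasing = TRUE))[1]
  co <- per_gene$strand == cr_final
  concordant <- (co & per_gene$a < 0 & per_gene$g > 0) |
                (!co & per_gene$a > 0 & per_gene$g < 0)
  reversed_rel <- (co & per_gene$a > 0 & per_gene$g < 0) |
                  (!co & per_gene$a < 0 & per_gene$g > 0)
  informative <- concordant | reversed_rel
  label <- if (!any(informative)) {
    "undetermined"
  } else if (all(concordant[informative])) {
    if (identical(cr_final, majority)) "standard" else "reversed"
  } else {
    "disrupted"
  }
  list(order = as_tibble(order_signature(genome)),
       cr_strand = cr_final,
       per_gene = per_gene[, c("gene", "strand", "a", "g", "n_fourfold")],
       edits = spec$edits,
       label = label)
}

#' Apply one architecture edit to a genome
#'
#' Edits operate at the sequence level and remap all downstream feature
#' coordinates:
#' \describe{
#'   \item{inversion}{reverse-complements the minimal contiguous segment
#'     covering the listed genes and flips their strands (an involution);}
#'   \item{translocation}{excises the contiguous segment of the listed genes
#'     and reinserts it immediately after the feature named by `after`,
#'     strands kept;}
#'   \item{shuffle}{exchanges two adjacent features;}
#'   \item{duplication}{tandem-copies the segment of the listed genes,
#'     incrementing copy indices.}
#' }
#' Sequence length is conserved except under duplication. A segment whose
#' minimal cover wraps the stored origin is handled by rotating the origin
#' first (the circular molecule is unchanged).
#'
#' @param genome A [mito_genome()].
#' @param event List with `etype`, `genes` and (for translocation) `after`.
#' @return The edited [mito_genome()].
#' @export
apply_rearrangement <- function(genome, event) {
  genes <- event$genes
  f <- genome$features
  if (!all(genes %in% f$label)) {
    abort(sprintf("edit names absent gene(s): %s",
                  paste(setdiff(genes, f$label), collapse = ", ")),
          class = "mitoasym_bad_edit")
  }
  copies <- event$copies
  switch(event$etype,
         inversion = edit_inversion(genome, genes, copies),
         translocation = edit_translocation(genome, genes, event$after, copies),
         shuffle = edit_shuffle(genome, genes),
         duplication = edit_duplication(genome, genes, copies),
         abort(sprintf("unknown edit type '%s'", event$etype),
               class = "mitoasym_bad_edit"))
}

# indices (in start order) of the minimal contiguous feature segment
# covering the listed genes (intervening features are part of the segment);
# a cover wrapping the origin is linearised by rotating the genome (the
# circular molecule is unchanged)
segment_indices <- function(genome, genes, copies = NULL) {
  f <- genome$features
  n <- nrow(f)
  idx <- if (is.null(copies)) {
    sort(which(f$label %in% genes))
  } else {
    sort(which(paste(f$label, f$copy_index) %in% paste(genes, copies)))
  }
  if (!length(idx)) abort("edit genes not found.", class = "mitoasym_bad_edit")
  if (length(idx) == 1L) {
    return(list(genome = genome, from = idx, to = idx))
  }
  # minimal circular cover = complement of the largest gap between matches
  gaps <- diff(c(idx, idx[1] + n))
  gi <- which.max(gaps)
  from <- if (gi == length(idx)) idx[1] else idx[gi + 1L]
  to <- if (gi == length(idx)) idx[length(idx)] else idx[gi]
  if (from > to) {
    genome <- rotate_genome(genome, f$start[from])
    return(segment_indices(genome, genes, copies))
  }
  list(genome = genome, from = from, to = to)
}

edit_inversion <- function(genome, genes, copies = NULL) {
  seg <- segment_indices(genome, genes, copies)
  genome <- seg$genome
  f <- genome$features
  s <- f$start[seg$from]
  e <- max(f$end[seg$from:seg$to])
  inside <- f$start >= s & f$end <= e
  if (any(!inside & ((f$start < e & f$end > s & !f$wraps_origin)))) {
    abort("inversion segment boundary overlaps a feature.",
          class = "mitoasym_bad_edit")
  }
  seq0 <- genome$sequence
  newseq <- paste0(substr(seq0, 1, s),
                   revcomp(substr(seq0, s + 1, e)),
                   substr(seq0, e + 1, nchar(seq0)))
  f2 <- f
  f2$start[inside] <- s + (e - f$end[inside])
  f2$end[inside] <- s + (e - f$start[inside])
  f2$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
  mito_genome(newseq, f2, id = genome$id, species = genome$species,
              circular = genome$circular)
}

edit_translocation <- function(genome, genes, after, copies = NULL) {
  if (is.null(after)) abort("translocation needs an `after` anchor.",
                            class = "mitoasym_bad_edit")
  seg <- segment_indices(genome, genes, copies)
  genome <- seg$genome
  f <- genome$features
  s <- f$start[seg$from]
  e <- max(f$end[seg$from:seg$to])
  block <- f[seg$from:seg$to, ]
  if (after %in% block$label) abort("translocation anchor inside the moved block.",
                                    class = "mitoasym_bad_edit")
  seq0 <- genome$sequence
  blockseq <- substr(seq0, s + 1, e)
  rest <- f[-(seg$from:seg$to), ]
  restseq <- paste0(substr(seq0, 1, s), substr(seq0, e + 1, nchar(seq0)))
  shift <- e - s
  rest$start <- ifelse(rest$start >= e, rest$start - shift, rest$start)
  rest$end <- ifelse(rest$end > s, rest$end - shift, rest$end)
  anchor <- which(rest$label == after)[1]
  ins <- rest$end[anchor]
  block$start <- block$start - s + ins
  block$end <- block$end - s + ins
  rest$start <- ifelse(rest$start >= ins, rest$start + shift, rest$start)
  rest$end <- ifelse(rest$end > ins, rest$end + shift, rest$end)
  newseq <- paste0(substr(restseq, 1, ins), blockseq,
                   substr(restseq, ins + 1, nchar(restseq)))
  mito_genome(newseq, dplyr::bind_rows(rest, block), id = genome$id,
              species = genome$species, circular = genome$circular)
}

edit_shuffle <- function(genome, genes) {
  if (length(genes) != 2L) abort("shuffle exchanges exactly two features.",
                                 class = "mitoasym_bad_edit")
  f <- genome$features
  i <- which(f$label == genes[1])[1]
  j <- which(f$label == genes[2])[1]
  if (abs(i - j) != 1L) abort("shuffle requires adjacent features.",
                              class = "mitoasym_bad_edit")
  first <- min(i, j); second <- max(i, j)
  s1 <- f$start[first]; e1 <- f$end[first]
  s2 <- f$start[second]; e2 <- f$end[second]
  seq0 <- genome$sequence
  gap <- substr(seq0, e1 + 1, s2)  # any bases between the two features
  newseq <- paste0(substr(seq0, 1, s1),
                   substr(seq0, s2 + 1, e2), gap, substr(seq0, s1 + 1, e1),
                   substr(seq0, e2 + 1, nchar(seq0)))
  f2 <- f
  len2 <- e2 - s2
  len1 <- e1 - s1
  f2$start[second] <- s1
  f2$end[second] <- s1 + len2
  f2$start[first] <- s1 + len2 + (s2 - e1)
  f2$end[first] <- f2$start[first] + len1
  mito_genome(newseq, f2, id = genome$id, species = genome$species,
              circular = genome$circular)
}

edit_duplication <- function(genome, genes, copies = NULL) {
  seg <- segment_indices(genome, genes, copies)
  genome <- seg$genome
  f <- genome$features
  s <- f$start[seg$from]
  e <- max(f$end[seg$from:seg$to])
  seq0 <- genome$sequence
  blockseq <- substr(seq0, s + 1, e)
  newseq <- paste0(substr(seq0, 1, e), blockseq,
                   substr(seq0, e + 1, nchar(seq0)))
  shift <- e - s
  copy <- f[seg$from:seg$to, ]
  copy$start <- copy$start + shift
  copy$end <- copy$end + shift
  f2 <- f
  f2$start <- ifelse(f$start >= e, f$start + shift, f$start)
  f2$end <- ifelse(f$end > e, f$end + shift, f$end)
  mito_genome(newseq, dplyr::bind_rows(f2, copy), id = genome$id,
              species = genome$species, circular = genome$circular)
}

#' Write the standard validation fixture set
#'
#' Emits four named synthetic mitogenomes as GenBank + GFF3 + a flat
#' key-value ground-truth sidecar:
#' \describe{
#'   \item{standard}{default architecture and composition;}
#'   \item{sternoptyx_like}{CR inverted with fully re-equilibrated
#'     composition — classifies reversed;}
#'   \item{argyropelecus_like}{nine-gene block (F..nad2) inverted with
#'     matched composition — classifies standard;}
#'   \item{trematominae_like}{CR plus a gene block inverted with the
#'     composition not yet re-equilibrated — classifies disrupted.}
#' }
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base seed; each fixture derives its own.
#' @param pcg_length Codons per PCG (default 200).
#' @return Tibble manifest: `fixture`, `label`, `genbank`, `gff`, `fasta`,
#'   `truth`.
#' @export
write_fixture_set <- function(outdir, seed = 20230181L, pcg_length = 200) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  specs <- fixture_specs(seed, pcg_length)
  manifest <- purrr::imap_dfr(specs, function(spec, name) {
    sim <- simulate_genome(spec)
    gb <- file.path(outdir, paste0(name, ".gb"))
    fa <- file.path(outdir, paste0(name, ".fasta"))
    gff <- file.path(outdir, paste0(name, ".gff3"))
    tr <- file.path(outdir, paste0(name, ".truth.txt"))
    write_genbank(sim$genome, gb)
    write_fasta_gff(sim$genome, fa, gff)
    writeLines(c(
      paste0("fixture=", name),
      paste0("id=", sim$genome$id),
      paste0("label=", sim$truth$label),
      paste0("cr_strand=", sim$truth$cr_strand),
      paste0("order=", render_linear(order_signature(sim$genome))),
      paste0("seed=", spec$seed)
    ), tr)
    tibble(fixture = name, label = sim$truth$label, genbank = gb,
           gff = gff, fasta = fa, truth = tr)
  })
  manifest
}

fixture_specs <- function(seed = 20230181L, pcg_length = 200) {
  arg_block <- c("F", "rrnS", "V", "rrnL", "L1", "nad1", "I", "Q", "M", "nad2")
  list(
    standard = synthetic_spec(seed = seed, id = "SYN_STANDARD",
                              pcg_length = pcg_length),
    sternoptyx_like = synthetic_spec(seed = seed + 1L, cr_strand = "-",
                                     id = "SYN_STERNOPTYX",
                                     pcg_length = pcg_length),
    argyropelecus_like = synthetic_spec(
      seed = seed + 2L, id = "SYN_ARGYROPELECUS", pcg_length = pcg_length,
      edits = list(list(etype = "inversion", genes = arg_block)),
      equilibrate = TRUE),
    trematominae_like = synthetic_spec(
      seed = seed + 3L, id = "SYN_TREMATOMINAE", pcg_length = pcg_length,
      edits = list(list(etype = "inversion",
                        genes = c("CR", "F", "rrnS", "V", "rrnL", "L1", "nad1"))),
      equilibrate = FALSE)
  )
}
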