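#' Construct an annotated mitogenome object
#'
#' A `mito_genome` bundles a circular (or linear) nucleotide sequence with a
#' feature table in 0-based half-open coordinates on the stored forward
#' strand. Features that span the origin of a circular molecule are stored as
#' a single row with `wraps_origin = TRUE` and `end <= start`; such a feature
#' covers `[start, length)` followed by `[0, end)`.
#'
#' @param sequence Single nucleotide string over the IUPAC alphabet; stored
#'   uppercase.
#' @param features Data frame of features with columns `label`, `ftype`
#'   (one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"CR"`, `"other"`), `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`). Optional columns
#'   `codon_start` (1, 2 or 3; required for PCGs, defaulted to 1),
#'   `wraps_origin`, `copy_index` and `raw_label` are filled in when absent.
#' @param id Identifier (accession or label).
#' @param species Organism name, or `NA`.
#' @param circular Is the molecule circular? Default `TRUE`.
#'
#' @return An object of class `mito_genome`: a list with elements `id`,
#'   `species`, `sequence`, `circular` and `features` (a tibble).
#' @export
#' @examples
#' g <- mito_genome("ATGGCATTCTAAACCCGGG",
#'   tibble::tibble(label = "nad1", ftype = "PCG", start = 0, end = 12,
#'                  strand = "+"),
#'   id = "toy")
#' genome_length(g)
mito_genome <- function(sequence, features = NULL, id = "genome",
                        species = NA_character_, circular = TRUE) {
  if (length(sequence) != 1L || !is.character(sequence) || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty string.", class = "mitoasym_missing_sequence")
  }
  sequence <- str_to_upper(sequence)
  len <- nchar(sequence)
  features <- normalise_features(features, len)
  structure(
    list(id = id, species = species, sequence = sequence,
         circular = isTRUE(circular), features = features),
    class = "mito_genome"
  )
}

normalise_features <- function(features, len) {
  if (is.null(features) || nrow(as.data.frame(features)) == 0L) {
    return(empty_feature_table())
  }
  f <- as_tibble(features)
  required <- c("label", "ftype", "start", "end", "strand")
  missing <- setdiff(required, names(f))
  if (length(missing)) {
    abort(paste0("feature table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"codon_start" %in% names(f)) f$codon_start <- NA_integer_
  if (!"wraps_origin" %in% names(f)) f$wraps_origin <- FALSE
  if (!"copy_index" %in% names(f)) f$copy_index <- NA_integer_
  if (!"raw_label" %in% names(f)) f$raw_label <- f$label
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  f$codon_start <- as.integer(f$codon_start)
  f$wraps_origin <- as.logical(f$wraps_origin)
  f$codon_start[f$ftype == "PCG" & is.na(f$codon_start)] <- 1L
  if (any(f$start < 0L | f$start >= len | f$end < 0L | f$end > len)) {
    abort("feature coordinates outside [0, length).", class = "mitoasym_bad_coords")
  }
  lens <- feature_lengths(f, len)
  if (any(lens <= 0L)) abort("zero-length feature.", class = "mitoasym_bad_coords")
  f <- f[order(f$start), , drop = FALSE]
  f <- assign_copy_index(f)
  f[, c("label", "ftype", "start", "end", "strand", "codon_start",
        "wraps_origin", "copy_index", "raw_label")]
}

empty_feature_table <- function() {
  tibble(label = character(), ftype = character(), start = integer(),
         end = integer(), strand = character(), codon_start = integer(),
         wraps_origin = logical(), copy_index = integer(),
         raw_label = character())
}

assign_copy_index <- function(f) {
  f$copy_index <- stats::ave(seq_len(nrow(f)), f$label,
                             FUN = function(i) rank(i, ties.method = "first"))
  f$copy_index <- as.integer(f$copy_index)
  f
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %d bp, %s, %d features\n",
              x$id, ifelse(is.na(x$species), "unknown species", x$species),
              genome_length(x), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Genome length in bases
#' @param genome A `mito_genome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

feature_lengths <- function(features, len) {
  ifelse(features$wraps_origin,
         len - features$start + features$end,
         features$end - features$start)
}

#' Reverse-complement a nucleotide string
#'
#' IUPAC-aware, via [Biostrings::reverseComplement()].
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Forward-strand subsequence of one feature row (wrap-aware).
feature_forward_seq <- function(genome, start, end, wraps) {
  len <- genome_length(genome)
  if (isTRUE(wraps)) {
    paste0(substr(genome$sequence, start + 1L, len),
           substr(genome$sequence, 1L, end))
  } else {
    substr(genome$sequence, start + 1L, end)
  }
}

#' Extract the sequence of a feature on its coding strand
#'
#' @param genome A `mito_genome`.
#' @param feature A one-row feature data frame (a row of `genome$features`).
#' @return Nucleotide string on the feature's own strand.
#' @export
feature_seq <- function(genome, feature) {
  s <- feature_forward_seq(genome, feature$start, feature$end, feature$wraps_origin)
  if (identical(feature$strand, "-")) revcomp(s) else s
}

#' Extract an in-frame coding sequence for a protein-coding gene
#'
#' Returns the coding-strand sequence (reverse-complemented for minus-strand
#' features), trimmed at the 5' end by `codon_start - 1` bases and truncated
#' at the 3' end to a multiple of three (an incomplete terminal codon is
#' dropped).
#'
#' @inheritParams feature_seq
#' @return In-frame CDS string; length is a multiple of three and at least 3.
#' @export
extract_cds <- function(genome, feature) {
  if (!identical(feature$ftype, "PCG")) {
    abort("extract_cds() expects a PCG feature.", class = "mitoasym_not_pcg")
  }
  s <- feature_seq(genome, feature)
  cs <- feature$codon_start
  if (is.na(cs)) cs <- 1L
  s <- substr(s, cs, nchar(s))
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  if (nchar(s) < 3L) {
    abort(sprintf("CDS of %s too short after frame trimming.", feature$label),
          class = "mitoasym_cds_too_short")
  }
  s
}

#' Rotate the origin of a circular genome
#'
#' Shifts the stored origin by `offset` bases: position `offset` becomes
#' position 0. Feature annotations are remapped; the molecule it represents is
#' unchanged.
#'
#' @param genome A circular `mito_genome`.
#' @param offset Integer in `[0, length)`.
#' @return A `mito_genome`.
#' @export
rotate_genome <- function(genome, offset) {
  len <- genome_length(genome)
  offset <- as.integer(offset %% len)
  if (offset == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, len),
                 substr(genome$sequence, 1L, offset))
  f <- genome$features
  if (nrow(f)) {
    lens <- feature_lengths(f, len)
    new_start <- (f$start - offset) %% len
    raw_end <- new_start + lens
    f$start <- as.integer(new_start)
    f$wraps_origin <- raw_end > len
    f$end <- as.integer(ifelse(raw_end > len, raw_end - len, raw_end))
  }
  mito_genome(seq2, f, id = genome$id, species = genome$species,
              circular = genome$circular)
}

#' Reverse-complement an entire genome, remapping features
#'
#' The stored representation is flipped; the molecule (and every relative
#' relationship on it) is unchanged. Useful for representation-invariance
#' checks.
#'
#' @param genome A `mito_genome`.
#' @return A `mito_genome` on the opposite stored strand.
#' @export
reverse_complement_genome <- function(genome) {
  len <- genome_length(genome)
  f <- genome$features
  if (nrow(f)) {
    lens <- feature_lengths(f, len)
    # complement of [start, end) is [len - end, len - start); a wrapped
    # feature's image wraps as well, with the same length.
    new_start <- (len - f$end) %% len
    raw_end <- new_start + lens
    f$start <- as.integer(new_start %% len)
    f$wraps_origin <- raw_end > len
    f$end <- as.integer(ifelse(raw_end > len, raw_end - len, raw_end))
    f$strand <- ifelse(f$strand == "+", "-", "+")
  }
  mito_genome(revcomp(genome$sequence), f, id = genome$id,
              species = genome$species, circular = genome$circular)
}

#' The standard vertebrate mitochondrial gene-order template
#'
#' The canonical 37-gene vertebrate architecture (13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs) plus the Control Region, in circular order with the
#' conventional coding strands. Shipped as a versioned data file under
#' `inst/extdata/`.
#'
#' @return A tibble with columns `label`, `ftype`, `strand` (38 rows).
#' @export
#' @examples
#' vertebrate_template()
vertebrate_template <- function() {
  path <- system.file("extdata", "vertebrate_gene_order.tsv",
                      package = "mitoasym", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
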