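#' The eight fourfold-degenerate codon families
#'
#' Two-base codon prefixes whose amino acid is unchanged by any third-position
#' substitution under the vertebrate mitochondrial genetic code (translation
#' table 2): alanine (GCN), proline (CCN), serine (TCN), threonine (ACN),
#' arginine (CGN), glycine (GGN), leucine (CTN) and valine (GTN).
#'
#' @format Character vector of eight two-base prefixes.
#' @export
FOURFOLD_FAMILIES <- c("GC", "CC", "TC", "AC", "CG", "GG", "CT", "GT")

#' Count third-position bases at fourfold-degenerate sites
#'
#' Walks the codons of an in-frame coding sequence; a codon is retained iff
#' its first two bases exactly match one of the eight fourfold families and
#' its third base is unambiguous (`A`, `C`, `G` or `T`). Codons containing
#' any ambiguity code are excluded entirely, so family membership is certain.
#'
#' @param cds Coding-strand nucleotide string; length must be a multiple of
#'   three and the frame starts at the first base.
#' @return One-row tibble with columns `A`, `C`, `G`, `T` (third-base counts
#'   at retained codons) and `n_fourfold` (their sum).
#' @export
#' @examples
#' fourfold_third_counts("ATGGCAGCGGCTCCATAA")
fourfold_third_counts <- function(cds) {
  cds <- str_to_upper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    abort("CDS length is not a multiple of 3; supply an in-frame sequence.",
          class = "mitoasym_frame_error")
  }
  if (n == 0L) {
    return(tibble(A = 0L, C = 0L, G = 0L, T = 0L, n_fourfold = 0L))
  }
  starts <- seq(1L, n, by = 3L)
  prefix <- substring(cds, starts, starts + 1L)
  third <- substring(cds, starts + 2L, starts + 2L)
  keep <- prefix %in% FOURFOLD_FAMILIES & third %in% ACGT
  third <- third[keep]
  counts <- vapply(ACGT, function(b) sum(third == b), integer(1))
  tibble(A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
         T = counts[["T"]], n_fourfold = length(third))
}

#' Compute AT and GC skew from base counts
#'
#' Applies AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C). A skew
#' whose denominator is zero is undefined and reported as `NA` with its
#' `defined_*` flag set to `FALSE` — never coerced to 0, since 0 means
#' perfect balance.
#'
#' @param counts One-row data frame with columns `A`, `C`, `G`, `T` (e.g.
#'   from [fourfold_third_counts()]), or a named numeric vector.
#' @return One-row tibble: `at_skew`, `gc_skew`, `defined_at`, `defined_gc`.
#' @export
#' @examples
#' compute_skews(c(A = 2, T = 1, G = 1, C = 0))
compute_skews <- function(counts) {
  cv <- if (is.data.frame(counts)) {
    c(A = counts$A[1], C = counts$C[1], G = counts$G[1], T = counts$T[1])
  } else {
    counts[c("A", "C", "G", "T")]
  }
  if (any(cv < 0, na.rm = TRUE)) abort("counts must be nonnegative.")
  at_den <- cv[["A"]] + cv[["T"]]
  gc_den <- cv[["G"]] + cv[["C"]]
  tibble(
    at_skew = if (at_den > 0) (cv[["A"]] - cv[["T"]]) / at_den else NA_real_,
    gc_skew = if (gc_den > 0) (cv[["G"]] - cv[["C"]]) / gc_den else NA_real_,
    defined_at = at_den > 0,
    defined_gc = gc_den > 0
  )
}

#' Per-gene fourfold-site skew table for an annotated genome
#'
#' For every protein-coding feature: extracts the in-frame CDS
#' ([extract_cds()]), counts fourfold third-position bases
#' ([fourfold_third_counts()]) and computes both skews ([compute_skews()]).
#' Rows are ordered by position in the standard vertebrate template (then by
#' copy index); genes absent from the template come last.
#'
#' @param genome A [mito_genome()].
#' @return Tibble with one row per PCG copy: `genome`, `gene`, `copy`,
#'   `strand`, `n_fourfold`, `A`, `C`, `G`, `T`, `at_skew`, `gc_skew`,
#'   `defined_at`, `defined_gc`.
#' @export
gene_skew_table <- function(genome) {
  pcgs <- dplyr::filter(genome$features, .data$ftype == "PCG")
  if (!nrow(pcgs)) {
    warn(sprintf("genome %s has no protein-coding features.", genome$id))
    return(tibble(genome = character(), gene = character(), copy = integer(),
                  strand = character(), n_fourfold = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  at_skew = double(), gc_skew = double(),
                  defined_at = logical(), defined_gc = logical()))
  }
  rows <- purrr::map_dfr(seq_len(nrow(pcgs)), function(i) {
    row <- pcgs[i, ]
    cds <- extract_cds(genome, row)
    counts <- fourfold_third_counts(cds)
    dplyr::bind_cols(
      tibble(genome = genome$id, gene = row$label, copy = row$copy_index,
             strand = row$strand),
      counts[, c("n_fourfold", "A", "C", "G", "T")],
      compute_skews(counts)
    )
  })
  tmpl_pos <- stats::setNames(seq_len(nrow(vertebrate_template())),
                              vertebrate_template()$label)
  ord <- tmpl_pos[rows$gene]
  ord[is.na(ord)] <- length(tmpl_pos) + 1L
  rows[order(ord, rows$gene, rows$copy), , drop = FALSE]
}

# Stop codons of the vertebrate mitochondrial code (translation table 2).
MT_STOP_CODONS <- c("TAA", "TAG", "AGA", "AGG")

#' Infer the reading frame of an unannotated coding fragment
#'
#' Evaluates the three forward frames under the vertebrate mitochondrial
#' genetic code and returns the frame with the fewest internal stop codons
#' (the terminal codon is not counted). Ties are broken by the most fourfold
#' codons, then the lowest frame index. `confidence` is the internal-stop
#' difference between the runner-up and the best frame; the call is flagged
#' low-confidence when every frame has at least one internal stop per 100
#' codons.
#'
#' @param seq Nucleotide string, length >= 60.
#' @return List: `frame` (0, 1 or 2), `confidence`, `low_confidence`,
#'   `stops` (internal stops per frame).
#' @export
infer_frame <- function(seq) {
  seq <- str_to_upper(seq)
  if (nchar(seq) < 60L) {
    abort("frame inference needs at least 60 bases.", class = "mitoasym_too_short")
  }
  stats_by_frame <- purrr::map(0:2, function(f) {
    sub <- substr(seq, f + 1L, nchar(seq))
    sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    starts <- seq(1L, nchar(sub), by = 3L)
    codons <- substring(sub, starts, starts + 2L)
    internal <- codons[-length(codons)]
    list(stops = sum(internal %in% MT_STOP_CODONS),
         fourfold = sum(substr(codons, 1, 2) %in% FOURFOLD_FAMILIES),
         n_codons = length(codons))
  })
  stops <- map_int(stats_by_frame, "stops")
  fourfold <- map_int(stats_by_frame, "fourfold")
  ord <- order(stops, -fourfold, 0:2)
  best <- ord[1]
  sorted <- sort(stops)
  list(frame = best - 1L,
       confidence = sorted[2] - sorted[1],
       low_confidence = all(stops / map_int(stats_by_frame, "n_codons") >= 0.01),
       stops = stops)
}

#' Fourfold-site skews for a single unannotated gene sequence
#'
#' The screening mode for single-gene records (e.g. partial cox1 sequences
#' lacking deposited frame information): infers the reading frame unless one
#' is supplied, trims to a codon multiple, and computes fourfold-site counts
#' and skews.
#'
#' @param seq Nucleotide string over the IUPAC alphabet.
#' @param assume_frame Optional frame (0, 1 or 2) to use instead of
#'   [infer_frame()].
#' @param id Optional record identifier carried into the output.
#' @return One-row tibble: `id`, `frame`, `low_confidence`, `n_fourfold`,
#'   `A`, `C`, `G`, `T`, `at_skew`, `gc_skew`, `defined_at`, `defined_gc`.
#'   A low-confidence frame is flagged, never suppressed.
#' @export
single_gene_skew <- function(seq, assume_frame = NULL, id = NA_character_) {
  seq <- str_to_upper(seq)
  if (is.null(assume_frame)) {
    fr <- infer_frame(seq)
    frame <- fr$frame
    lowc <- fr$low_confidence
  } else {
    frame <- as.integer(assume_frame)
    stopifnot(frame %in% 0:2)
    lowc <- FALSE
  }
  sub <- substr(seq, frame + 1L, nchar(seq))
  sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
  counts <- fourfold_third_counts(sub)
  dplyr::bind_cols(
    tibble(id = id, frame = frame, low_confidence = lowc),
    counts[, c("n_fourfold", "A", "C", "G", "T")],
    compute_skews(counts)
  )
}
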