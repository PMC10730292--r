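#' Read an annotated mitogenome from FASTA + GFF3
#'
#' The FASTA must hold a single record; the GFF3 `seqid` must match its
#' name. GFF3 `phase` (0/1/2, CDS only) maps to `codon_start` (1/2/3).
#' Discontinuous features sharing an `ID` whose two parts abut the sequence
#' ends are merged into one origin-wrapping feature.
#'
#' @param fasta Path to a single-record FASTA file.
#' @param gff Path to a GFF3 file.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @return A [mito_genome()].
#' @export
read_fasta_gff <- function(fasta, gff, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) {
    abort("FASTA must contain exactly one record.", class = "mitoasym_bad_format")
  }
  seq_name <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  sequence <- as.character(seqs[[1]])
  len <- nchar(sequence)
  gr <- rtracklayer::import(gff, format = "gff3")
  if (!length(gr)) {
    warn(sprintf("GFF '%s' has no features.", gff))
    return(mito_genome(sequence, NULL, id = seq_name, circular = circular))
  }
  m <- as.data.frame(gr)
  seqids <- as.character(m$seqnames)
  if (!all(seqids == seq_name)) {
    abort(sprintf("GFF seqid(s) %s do not match FASTA record '%s'.",
                  paste(unique(setdiff(seqids, seq_name)), collapse = ","),
                  seq_name),
          class = "mitoasym_seqid_mismatch")
  }
  if (any(m$start < 1L | m$end > len)) {
    abort("GFF coordinates out of sequence range.", class = "mitoasym_bad_coords")
  }
  f <- tibble(
    label = as.character(m$Name %||% m$ID),
    ftype = gff_type_to_ftype(as.character(m$type)),
    start = as.integer(m$start) - 1L,
    end = as.integer(m$end),
    strand = ifelse(as.character(m$strand) == "-", "-", "+"),
    codon_start = ifelse(is.na(suppressWarnings(as.integer(as.character(m$phase)))),
                         NA_integer_,
                         suppressWarnings(as.integer(as.character(m$phase))) + 1L),
    id_attr = as.character(m$ID)
  )
  if (is.null(m$Name)) f$label <- f$id_attr
  f$label[is.na(f$label)] <- "OTHER"
  f <- merge_wrapped_parts(f, len)
  f$raw_label <- f$label
  known <- f$label %in% c(CANONICAL_PCGS, CANONICAL_TRNAS, CANONICAL_RRNAS, "CR")
  f$label[!known] <- canonical_label(f$label[!known])
  f$ftype <- ifelse(f$ftype == "guess", label_ftype(f$label), f$ftype)
  mito_genome(sequence, f[, c("label", "ftype", "start", "end", "strand",
                              "codon_start", "wraps_origin", "raw_label")],
              id = seq_name, circular = circular)
}

gff_type_to_ftype <- function(type) {
  dplyr::case_when(
    type == "CDS" ~ "PCG",
    type == "tRNA" ~ "tRNA",
    type == "rRNA" ~ "rRNA",
    type %in% c("D_loop", "D-loop", "control_region") ~ "CR",
    TRUE ~ "guess"
  )
}

# merge discontinuous GFF parts (same ID, parts abutting sequence ends)
merge_wrapped_parts <- function(f, len) {
  f$wraps_origin <- FALSE
  dup_ids <- unique(f$id_attr[duplicated(f$id_attr) & !is.na(f$id_attr)])
  for (id in dup_ids) {
    idx <- which(f$id_attr == id)
    if (length(idx) != 2L) next
    a <- f[idx[1], ]; b <- f[idx[2], ]
    hi <- if (a$end == len) a else if (b$end == len) b else NULL
    lo <- if (a$start == 0L) a else if (b$start == 0L) b else NULL
    if (is.null(hi) || is.null(lo)) next
    f$start[idx[1]] <- hi$start
    f$end[idx[1]] <- lo$end
    f$wraps_origin[idx[1]] <- TRUE
    f$codon_start[idx[1]] <- min(c(a$codon_start, b$codon_start), na.rm = TRUE)
    f <- f[-idx[2], , drop = FALSE]
  }
  f
}

#' Write a mitogenome as FASTA + GFF3
#'
#' Origin-wrapping features are written as two GFF3 lines sharing an `ID`
#' (a discontinuous feature); [read_fasta_gff()] re-merges them.
#'
#' @param genome A [mito_genome()].
#' @param fasta,gff Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_fasta_gff <- function(genome, fasta, gff) {
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$id
  Biostrings::writeXStringSet(seqs, fasta)
  f <- genome$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome_length(genome)))
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      row <- f[i, ]
      type <- switch(row$ftype, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                     CR = "D_loop", "region")
      fid <- sprintf("%s.%d", row$label, row$copy_index)
      phase <- if (row$ftype == "PCG") {
        as.character(ifelse(is.na(row$codon_start), 0L, row$codon_start - 1L))
      } else "."
      attrs <- sprintf("ID=%s;Name=%s", fid, row$label)
      if (isTRUE(row$wraps_origin)) {
        len <- genome_length(genome)
        lines <- c(lines,
          gff_line(genome$id, type, row$start + 1L, len, row$strand, phase, attrs),
          gff_line(genome$id, type, 1L, row$end, row$strand, phase, attrs))
      } else {
        lines <- c(lines,
          gff_line(genome$id, type, row$start + 1L, row$end, row$strand,
                   phase, attrs))
      }
    }
  }
  writeLines(lines, gff)
  invisible(list(fasta = fasta, gff = gff))
}

gff_line <- function(seqid, type, start, end, strand, phase, attrs) {
  paste(seqid, "mitoasym", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}
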