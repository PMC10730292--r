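#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses a single-record GenBank flat file: LOCUS length/topology,
#' DEFINITION/ACCESSION/ORGANISM, the FEATURES table (CDS, tRNA, rRNA,
#' D-loop, and any other keys) and the ORIGIN sequence. Coordinates are
#' converted from GenBank 1-based inclusive to 0-based half-open;
#' `join(a..L,1..b)` locations spanning the origin of a circular record
#' become a single feature with `wraps_origin = TRUE`. Gene/product names
#' are normalised with [canonical_label()]; unmappable names are kept with
#' `ftype = "other"` and a warning, never dropped.
#'
#' @param path Path to a GenBank flat file.
#' @return A [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    abort(sprintf("'%s' is not a parseable GenBank flat file.", path),
          class = "mitoasym_bad_format")
  }
  locus <- lines[startsWith(lines, "LOCUS")][1]
  circular <- grepl("circular", locus, ignore.case = TRUE)
  id <- parse_gb_id(lines, locus)
  species <- parse_gb_species(lines)
  sequence <- parse_gb_origin(lines)
  if (is.na(sequence) || !nzchar(sequence)) {
    abort(sprintf("GenBank record '%s' has no sequence.", path),
          class = "mitoasym_missing_sequence")
  }
  len <- nchar(sequence)
  raw_feats <- parse_gb_features(lines)
  features <- gb_features_to_table(raw_feats, len)
  mito_genome(sequence, features, id = id, species = species,
              circular = circular)
}

parse_gb_id <- function(lines, locus) {
  acc <- lines[startsWith(lines, "VERSION")]
  if (length(acc)) {
    v <- strsplit(trimws(sub("^VERSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(v) && nzchar(v)) return(v)
  }
  acc <- lines[startsWith(lines, "ACCESSION")]
  if (length(acc)) {
    v <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(v) && nzchar(v)) return(v)
  }
  strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
}

parse_gb_species <- function(lines) {
  org <- lines[grepl("^\\s{2}ORGANISM", lines)]
  if (length(org)) trimws(sub("^\\s+ORGANISM\\s*", "", org[1])) else NA_character_
}

parse_gb_origin <- function(lines) {
  i <- which(startsWith(lines, "ORIGIN"))
  if (!length(i)) return(NA_character_)
  j <- which(startsWith(lines, "//"))
  j <- j[j > i[1]]
  end <- if (length(j)) j[1] - 1L else length(lines)
  body <- lines[seq(i[1] + 1L, end)]
  str_to_upper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
}

# Split the FEATURES block into a list of (key, location, qualifiers).
parse_gb_features <- function(lines) {
  i <- which(startsWith(lines, "FEATURES"))
  if (!length(i)) return(list())
  j <- which(startsWith(lines, "ORIGIN") | startsWith(lines, "CONTIG") |
             startsWith(lines, "BASE COUNT"))
  j <- j[j > i[1]]
  end <- if (length(j)) j[1] - 1L else length(lines)
  block <- lines[seq(i[1] + 1L, end)]
  block <- block[nzchar(trimws(block))]
  feats <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("^\\s{1,10}\\S", ln) && !grepl("^\\s*/", ln)) {
      # new feature key line (key starts before column 21)
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = parts[1],
                  location = paste(parts[-1], collapse = ""),
                  quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (!length(cur$quals)) {
        cur$location <- paste0(cur$location, txt)  # continued location
      } else {
        n <- length(cur$quals)
        cur$quals[n] <- paste(cur$quals[n], txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

gb_qualifier <- function(quals, name) {
  pat <- paste0("^/", name, "=?")
  hit <- quals[grepl(pat, quals)]
  if (!length(hit)) return(NA_character_)
  v <- sub(pat, "", hit[1])
  gsub("^\"|\"$", "", v)
}

# Parse a GenBank location string into start/end/strand/wraps (0-based
# half-open). join(a..L,1..b) on a circular molecule wraps the origin;
# other multi-segment joins are collapsed to their span with a warning.
parse_gb_location <- function(loc, len) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\(", "", sub("\\)$", "", loc))
    segs <- strsplit(inner, ",")[[1]]
    rng <- lapply(segs, parse_gb_span)
    first <- rng[[1]]; last <- rng[[length(rng)]]
    if (length(rng) == 2L && first[2] == len && last[1] == 1L) {
      return(list(start = first[1] - 1L, end = last[2], strand = strand,
                  wraps = TRUE))
    }
    warn(sprintf("join location '%s' collapsed to its span.", loc))
    lo <- min(vapply(rng, `[`, numeric(1), 1))
    hi <- max(vapply(rng, `[`, numeric(1), 2))
    return(list(start = lo - 1L, end = hi, strand = strand, wraps = FALSE))
  }
  rng <- parse_gb_span(loc)
  list(start = rng[1] - 1L, end = rng[2], strand = strand, wraps = wraps)
}

parse_gb_span <- function(span) {
  span <- gsub("[<>]", "", span)
  if (grepl("\\.\\.", span)) {
    as.integer(strsplit(span, "\\.\\.")[[1]][c(1, 2)])
  } else {
    p <- as.integer(span)
    c(p, p)
  }
}

GB_TYPED_KEYS <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", `D-loop` = "CR")

gb_features_to_table <- function(raw_feats, len) {
  keep <- purrr::keep(raw_feats, ~ .x$key != "source")
  if (!length(keep)) return(empty_feature_table())
  rows <- purrr::map_dfr(keep, function(ft) {
    loc <- parse_gb_location(ft$location, len)
    gene <- gb_qualifier(ft$quals, "gene")
    product <- gb_qualifier(ft$quals, "product")
    anticodon <- gb_anticodon(ft$quals)
    raw_name <- if (!is.na(gene)) gene else if (!is.na(product)) product else ft$key
    label <- canonical_label(raw_name, anticodon)
    if (label == "OTHER" && !is.na(product)) {
      label <- canonical_label(product, anticodon)
      if (label != "OTHER") raw_name <- product
    }
    if (label == "OTHER" && ft$key == "D-loop") label <- "CR"
    cs <- suppressWarnings(as.integer(gb_qualifier(ft$quals, "codon_start")))
    tibble(key = ft$key, label = label, raw_label = raw_name,
           start = loc$start, end = loc$end, strand = loc$strand,
           wraps_origin = loc$wraps,
           codon_start = cs)
  })
  rows$ftype <- ifelse(rows$key %in% names(GB_TYPED_KEYS),
                       GB_TYPED_KEYS[rows$key],
                       label_ftype(rows$label))
  # 'gene' keys duplicate typed features in deposited records: keep a gene
  # row only when no typed feature shares its label.
  is_gene_key <- rows$key == "gene"
  typed_labels <- rows$label[!is_gene_key]
  rows <- rows[!(is_gene_key & rows$label %in% typed_labels), , drop = FALSE]
  rows$ftype[rows$ftype == "CR"] <- "CR"
  rows <- rows[order(rows$start), , drop = FALSE]
  rows <- resolve_ls_paralogs(rows)
  rows$ftype <- ifelse(rows$key %in% names(GB_TYPED_KEYS),
                       GB_TYPED_KEYS[rows$key], label_ftype(rows$label))
  if (any(rows$label == "OTHER")) {
    warn(sprintf("%d feature(s) with unmappable names kept as ftype 'other': %s",
                 sum(rows$label == "OTHER"),
                 paste(unique(rows$raw_label[rows$label == "OTHER"]), collapse = ", ")))
  }
  rows[, c("label", "ftype", "start", "end", "strand", "codon_start",
           "wraps_origin", "raw_label")]
}

gb_anticodon <- function(quals) {
  v <- gb_qualifier(quals, "anticodon")
  if (is.na(v)) return(NA_character_)
  m <- regmatches(v, regexpr("seq:([acgtuACGTU]{3})", v))
  if (length(m)) return(str_to_upper(sub("seq:", "", m)))
  NA_character_
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a flat file that [read_genbank()] parses back to an equivalent
#' genome (labels, feature types, strands, coordinates, codon_start and the
#' circular flag are preserved). Origin-wrapping features are written as
#' `join(a..L,1..b)` locations.
#'
#' @param genome A [mito_genome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genbank <- function(genome, path) {
  len <- genome_length(genome)
  topo <- if (genome$circular) "circular" else "linear"
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    abort(sprintf("cannot write '%s'.", path), class = "mitoasym_io_error")
  }
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  locus_name <- gsub("[^A-Za-z0-9_.-]", "_", genome$id)
  wl("LOCUS       %-16s %d bp    DNA     %s MIT %s",
     locus_name, len, topo, format(Sys.Date(), "%d-%b-%Y"))
  wl("DEFINITION  %s mitochondrion.",
     ifelse(is.na(genome$species), genome$id, genome$species))
  wl("ACCESSION   %s", sub("\\.\\d+$", "", genome$id))
  wl("VERSION     %s", genome$id)
  if (!is.na(genome$species)) {
    wl("SOURCE      mitochondrion %s", genome$species)
    wl("  ORGANISM  %s", genome$species)
  }
  wl("FEATURES             Location/Qualifiers")
  wl("     source          1..%d", len)
  wl("                     /organelle=\"mitochondrion\"")
  f <- genome$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      row <- f[i, ]
      key <- switch(row$ftype, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    CR = "D-loop", "misc_feature")
      loc <- gb_location_string(row, len)
      wl("     %-15s %s", key, loc)
      wl("                     /gene=\"%s\"", gb_gene_name(row$label, row$raw_label))
      if (row$ftype == "PCG") {
        wl("                     /codon_start=%d",
           ifelse(is.na(row$codon_start), 1L, row$codon_start))
        wl("                     /transl_table=2")
      }
      if (row$label %in% c("L1", "L2", "S1", "S2")) {
        ac <- names(LS_ANTICODONS)[LS_ANTICODONS == row$label]
        wl("                     /product=\"tRNA-%s\"",
           names(AA3_TO_1)[AA3_TO_1 == substr(row$label, 1, 1)][1])
        wl("                     /anticodon=\"(pos:complement(0..0),aa:Xxx,seq:%s)\"",
           tolower(ac))
      }
    }
  }
  wl("ORIGIN")
  writeLines(format_gb_origin(genome$sequence), con)
  wl("//")
  invisible(path)
}

gb_gene_name <- function(label, raw_label) {
  if (label == "OTHER" && !is.na(raw_label)) return(raw_label)
  if (label %in% c(CANONICAL_TRNAS)) {
    aa <- substr(label, 1, 1)
    return(paste0("trn", label))
  }
  label
}

gb_location_string <- function(row, len) {
  if (isTRUE(row$wraps_origin)) {
    base <- sprintf("join(%d..%d,1..%d)", row$start + 1L, len, row$end)
  } else {
    base <- sprintf("%d..%d", row$start + 1L, row$end)
  }
  if (identical(row$strand, "-")) sprintf("complement(%s)", base) else base
}

format_gb_origin <- function(sequence) {
  len <- nchar(sequence)
  starts <- seq(1L, len, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(sequence, s, min(s + 59L, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1))
}
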