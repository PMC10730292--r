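#' Reference CSB-II motif
#'
#' The conserved sequence block II consensus used to locate and orient the
#' Control Region: a run of six or more cytosines, then TA, then a run of
#' five or more cytosines.
#' @format A string.
#' @export
CSB2_REFERENCE <- "CCCCCCTACCCCC"

#' Find non-coding regions of an annotated genome
#'
#' Complements the union of all gene features (PCG, tRNA, rRNA) on the
#' circle. Annotated Control-Region features are non-genic and therefore
#' appear within the returned intervals. On a circular molecule, a gap
#' spanning the origin is returned as a single wrapped interval.
#'
#' @param genome A [mito_genome()].
#' @param min_len Minimum interval length to report (default 200 bases, to
#'   avoid spurious intergenic spacers).
#' @return Tibble with columns `start`, `end` (0-based half-open),
#'   `wraps_origin`, `length`.
#' @export
noncoding_regions <- function(genome, min_len = 200) {
  len <- genome_length(genome)
  covered <- logical(len)
  genes <- dplyr::filter(genome$features, .data$ftype %in% c("PCG", "tRNA", "rRNA"))
  if (nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      covered[feature_positions(genes$start[i], genes$end[i],
                                genes$wraps_origin[i], len) + 1L] <- TRUE
    }
  }
  if (all(covered)) {
    return(tibble(start = integer(), end = integer(),
                  wraps_origin = logical(), length = integer()))
  }
  r <- rle(covered)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  gaps <- tibble(start = run_start[!r$values] - 1L,
                 end = run_end[!r$values],
                 wraps_origin = FALSE)
  # merge a terminal and an initial gap across the origin of a circle
  if (genome$circular && nrow(gaps) > 1L &&
      gaps$start[1] == 0L && gaps$end[nrow(gaps)] == len) {
    first <- gaps[1, ]; last <- gaps[nrow(gaps), ]
    merged <- tibble(start = last$start, end = first$end, wraps_origin = TRUE)
    gaps <- dplyr::bind_rows(gaps[-c(1, nrow(gaps)), ], merged)
  }
  gaps$length <- as.integer(ifelse(gaps$wraps_origin,
                                   len - gaps$start + gaps$end,
                                   gaps$end - gaps$start))
  gaps <- gaps[gaps$length >= min_len, , drop = FALSE]
  gaps[order(gaps$start), , drop = FALSE]
}

# 0-based positions covered by an interval, wrap-aware.
feature_positions <- function(start, end, wraps, len) {
  if (isTRUE(wraps)) c(seq.int(start, len - 1L), seq.int(0L, end - 1L))
  else seq.int(start, end - 1L)
}

#' Scan a sequence for CSB-II motif matches on both strands
#'
#' Finds all maximal, non-overlapping matches of the pattern
#' `C{min_c5,}TAC{min_c3,}` on the given sequence and its reverse
#' complement (minus-strand coordinates are mapped back to the forward
#' sequence). The defaults allow one cytosine of slack on each flank
#' relative to the typical 6C-TA-5C reference, accommodating natural
#' variation in poly-C run length.
#'
#' @param seq Nucleotide string.
#' @param min_c5 Minimum length of the 5' poly-C run (default 5).
#' @param min_c3 Minimum length of the 3' poly-C run (default 4).
#' @return Tibble of hits sorted by score (match length) then position:
#'   `motif`, `start`, `end` (0-based half-open on `seq`), `strand`,
#'   `matched` (the motif text as read on its own strand), `score`.
#' @export
#' @examples
#' scan_csb2(paste0("AATT", CSB2_REFERENCE, "GGA"))
scan_csb2 <- function(seq, min_c5 = 5, min_c3 = 4) {
  seq <- str_to_upper(seq)
  pat <- sprintf("C{%d,}TAC{%d,}", min_c5, min_c3)
  fwd <- regex_hits(seq, pat)
  fwd$strand <- rep("+", nrow(fwd))
  rc <- regex_hits(revcomp(seq), pat)
  n <- nchar(seq)
  rev_hits <- tibble(start = n - rc$end, end = n - rc$start,
                     matched = rc$matched, strand = rep("-", nrow(rc)))
  hits <- dplyr::bind_rows(fwd[, c("start", "end", "matched", "strand")],
                           rev_hits)
  hits$motif <- rep("CSB-II", nrow(hits))
  hits$score <- nchar(hits$matched)
  hits <- hits[order(-hits$score, hits$start), , drop = FALSE]
  hits[, c("motif", "start", "end", "strand", "matched", "score")]
}

regex_hits <- function(seq, pat) {
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(), end = integer(), matched = character()))
  }
  st <- as.integer(m) - 1L
  lenm <- attr(m, "match.length")
  tibble(start = st, end = st + lenm,
         matched = substring(seq, st + 1L, st + lenm))
}

#' Locate the Control Region and its polarity via CSB-II
#'
#' Scans non-coding regions of an annotated genome for CSB-II on both
#' strands. If an annotated CR/D-loop feature exists the scan is restricted
#' to it first, falling back to all non-coding regions when it yields no
#' hit. The best hit is the longest match; ties are resolved in favour of
#' the hit inside the longest non-coding region, then the smallest start.
#' The CR strand is the best hit's strand; with no hit at all the call is
#' `"undetermined"`.
#'
#' @param genome A [mito_genome()].
#' @param min_c5,min_c3 Poly-C run minima passed to [scan_csb2()].
#' @param min_len Minimum non-coding region length scanned (default 200).
#' @return An object of class `control_region_call`: list with
#'   `cr_interval` (one-row tibble or NULL), `cr_strand`
#'   (`"+"`, `"-"` or `"undetermined"`) and `hits` (tibble of supporting
#'   CSB-II hits in genome coordinates, with `in_noncoding = TRUE`).
#' @export
locate_control_region <- function(genome, min_c5 = 5, min_c3 = 4,
                                  min_len = 200) {
  len <- genome_length(genome)
  cr_feats <- dplyr::filter(genome$features, .data$ftype == "CR")
  regions <- if (nrow(cr_feats)) {
    tibble(start = cr_feats$start, end = cr_feats$end,
           wraps_origin = cr_feats$wraps_origin,
           length = feature_lengths(cr_feats, len))
  } else {
    noncoding_regions(genome, min_len = min_len)
  }
  hits <- scan_regions(genome, regions, min_c5, min_c3)
  if (!nrow(hits) && nrow(cr_feats)) {
    regions <- noncoding_regions(genome, min_len = min_len)
    hits <- scan_regions(genome, regions, min_c5, min_c3)
  }
  if (!nrow(hits)) {
    best_region <- if (nrow(regions)) {
      regions[which.max(regions$length), , drop = FALSE]
    } else NULL
    return(structure(list(cr_interval = best_region,
                          cr_strand = "undetermined",
                          hits = hits),
                     class = "control_region_call"))
  }
  hits <- hits[order(-hits$score, -hits$region_length, hits$start), ,
               drop = FALSE]
  best <- hits[1, ]
  interval <- tibble(start = best$region_start, end = best$region_end,
                     wraps_origin = best$region_wraps)
  structure(list(cr_interval = interval, cr_strand = best$strand,
                 hits = hits),
            class = "control_region_call")
}

scan_regions <- function(genome, regions, min_c5, min_c3) {
  len <- genome_length(genome)
  empty <- tibble(motif = character(), start = integer(), end = integer(),
                  strand = character(), matched = character(),
                  score = integer(), in_noncoding = logical(),
                  region_start = integer(), region_end = integer(),
                  region_wraps = logical(), region_length = integer())
  if (is.null(regions) || !nrow(regions)) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    s <- feature_forward_seq(genome, r$start, r$end, r$wraps_origin)
    h <- scan_csb2(s, min_c5 = min_c5, min_c3 = min_c3)
    if (!nrow(h)) return(NULL)
    h$start <- as.integer((r$start + h$start) %% len)
    h$end <- as.integer(((r$start + h$end - 1L) %% len) + 1L)
    h$in_noncoding <- TRUE
    h$region_start <- r$start
    h$region_end <- r$end
    h$region_wraps <- r$wraps_origin
    h$region_length <- r$length
    h
  })
  if (is.null(out) || !nrow(out)) empty else out
}

#' @export
print.control_region_call <- function(x, ...) {
  cat(sprintf("<control_region_call> strand %s, %d CSB-II hit(s)\n",
              x$cr_strand, nrow(x$hits)))
  invisible(x)
}
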