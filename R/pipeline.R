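#' Run the full strand-asymmetry analysis over a set of genomes
#'
#' For each input genome: per-gene fourfold-site skews, CSB-II hits and
#' Control-Region polarity, gene-order events against the standard
#' vertebrate template, and the genome-level asymmetry call. Writes tab
#' separated tables (`skew.tsv`, `csb.tsv`, `events.tsv`, `asymmetry.tsv`,
#' `cohort_summary.tsv`), a machine-readable JSON mirror (`results.json`)
#' and a run log recording the effective parameters. A genome that fails to
#' parse or analyse is reported and skipped; the run only errors when every
#' input fails.
#'
#' @param inputs Character vector of GenBank file paths, and/or a list of
#'   [mito_genome()] objects (mixing is allowed).
#' @param output_dir Directory for outputs (created if needed).
#' @param params [classifier_params()].
#' @param min_c5,min_c3,min_noncoding CSB-II scan parameters (see
#'   [scan_csb2()] and [noncoding_regions()]).
#' @param template Gene-order template signature.
#' @return Invisibly, a list: `calls` (asymmetry calls), `tables` (the five
#'   output tibbles), `status` (per-input status tibble).
#' @export
run_pipeline <- function(inputs, output_dir,
                         params = classifier_params(),
                         min_c5 = 5, min_c3 = 4, min_noncoding = 200,
                         template = template_signature()) {
  if (!length(inputs)) {
    abort("no input genomes given.", class = "mitoasym_usage_error")
  }
  if (!is.list(inputs)) inputs <- as.list(inputs)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  calls <- list()
  skew_rows <- list(); csb_rows <- list(); event_rows <- list()
  status <- list()
  for (i in seq_along(inputs)) {
    input <- inputs[[i]]
    name <- if (inherits(input, "mito_genome")) input$id else as.character(input)
    res <- tryCatch({
      genome <- if (inherits(input, "mito_genome")) input else read_genbank(input)
      skews <- gene_skew_table(genome)
      cr <- locate_control_region(genome, min_c5 = min_c5, min_c3 = min_c3,
                                  min_len = min_noncoding)
      events <- classify_events(order_signature(genome), template)
      call <- classify_genome(genome, params = params, cr_call = cr)
      list(genome = genome, skews = skews, cr = cr, events = events,
           call = call)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[[i]] <- tibble(input = name, status = "failed",
                            message = conditionMessage(res))
      next
    }
    status[[i]] <- tibble(input = name, status = "ok", message = "")
    calls[[res$genome$id]] <- res$call
    skew_rows[[i]] <- res$skews
    if (nrow(res$cr$hits)) {
      h <- res$cr$hits[, c("motif", "start", "end", "strand", "matched",
                           "in_noncoding")]
      h$genome <- res$genome$id
      csb_rows[[i]] <- h[, c("genome", "motif", "start", "end", "strand",
                             "matched", "in_noncoding")]
    }
    if (nrow(res$events)) {
      ev <- res$events
      ev$genome <- res$genome$id
      event_rows[[i]] <- ev[, c("genome", "etype", "genes", "detail")]
    }
  }
  status <- dplyr::bind_rows(status)
  if (!length(calls)) {
    abort("all inputs failed to analyse.", class = "mitoasym_all_failed")
  }
  report <- cohort_report(calls)
  tables <- list(
    skew = dplyr::bind_rows(skew_rows),
    csb = if (length(csb_rows)) dplyr::bind_rows(csb_rows) else
      tibble(genome = character(), motif = character(), start = integer(),
             end = integer(), strand = character(), matched = character(),
             in_noncoding = logical()),
    events = if (length(event_rows)) dplyr::bind_rows(event_rows) else
      tibble(genome = character(), etype = character(), genes = character(),
             detail = character()),
    asymmetry = report$per_gene,
    cohort_summary = report$genomes
  )
  readr::write_tsv(tables$skew, file.path(output_dir, "skew.tsv"))
  readr::write_tsv(tables$csb, file.path(output_dir, "csb.tsv"))
  readr::write_tsv(tables$events, file.path(output_dir, "events.tsv"))
  readr::write_tsv(tables$asymmetry, file.path(output_dir, "asymmetry.tsv"))
  readr::write_tsv(tables$cohort_summary,
                   file.path(output_dir, "cohort_summary.tsv"))
  jsonlite::write_json(
    list(genomes = tables$cohort_summary, per_gene = tables$asymmetry,
         events = tables$events, status = status),
    file.path(output_dir, "results.json"), dataframe = "rows", na = "null")
  writeLines(c(
    sprintf("mitoasym %s", as.character(utils::packageVersion("mitoasym"))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("inputs: %d (ok: %d, failed: %d)", nrow(status),
            sum(status$status == "ok"), sum(status$status == "failed")),
    sprintf("params: tau=%g n_min=%d quorum=%g min_c5=%d min_c3=%d min_noncoding=%d",
            params$tau, params$n_min, params$quorum, min_c5, min_c3,
            min_noncoding)
  ), file.path(output_dir, "run_log.txt"))
  invisible(list(calls = calls, tables = tables, status = status))
}

#' Screen a FASTA of single-gene coding fragments for skew reversal
#'
#' The cox1-style screening mode: for every record, infers the reading
#' frame, computes fourfold-site skews, and flags the record as
#' `standard-like` (AT skew < 0 and GC skew > 0, the standard vertebrate
#' sign regime for a majority-strand gene), `reversed-like` (both signs
#' flipped) or `ambiguous` (undefined, sub-threshold or discordant signs).
#'
#' @param fasta Path to a (multi-)FASTA of CDS fragments.
#' @param params [classifier_params()]; `tau` is the magnitude threshold.
#' @param min_length Records shorter than this are skipped with a note
#'   (default 60, the minimum for frame inference).
#' @return Tibble: one row per retained record with skews, frame and
#'   `asymmetry_flag`; skipped records appear with `asymmetry_flag = "skipped"`.
#' @export
coi_screen <- function(fasta, params = classifier_params(), min_length = 60) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (!length(seqs)) {
    warn("empty FASTA; nothing to screen.")
    return(tibble(id = character(), frame = integer(),
                  low_confidence = logical(), n_fourfold = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  at_skew = double(), gc_skew = double(),
                  defined_at = logical(), defined_gc = logical(),
                  asymmetry_flag = character()))
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  purrr::map_dfr(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) < min_length) {
      return(tibble(id = ids[i], frame = NA_integer_, low_confidence = NA,
                    n_fourfold = NA_integer_, A = NA_integer_,
                    C = NA_integer_, G = NA_integer_, T = NA_integer_,
                    at_skew = NA_real_, gc_skew = NA_real_,
                    defined_at = NA, defined_gc = NA,
                    asymmetry_flag = "skipped"))
    }
    row <- single_gene_skew(s, id = ids[i])
    row$asymmetry_flag <- skew_sign_flag(row$at_skew, row$gc_skew,
                                         row$n_fourfold, params)
    row
  })
}

skew_sign_flag <- function(at, gc, n, params) {
  if (is.na(at) || is.na(gc) || n < params$n_min ||
      max(abs(at), abs(gc)) < params$tau) return("ambiguous")
  if (at < 0 && gc > 0) return("standard-like")
  if (at > 0 && gc < 0) return("reversed-like")
  "ambiguous"
}
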