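#' Classifier parameters for strand-asymmetry calls
#'
#' Numeric operationalisation of the qualitative sign reading of per-gene
#' skew signatures.
#'
#' @param tau Skew magnitude threshold (dimensionless, default 0.05): a gene
#'   needs `max(|at_skew|, |gc_skew|) >= tau` to count as signed.
#' @param n_min Minimum fourfold codons per gene (default 10).
#' @param quorum Fraction of informative PCGs required for a genome call
#'   (default 0.8).
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(tau = 0.05, n_min = 10, quorum = 0.8) {
  stopifnot(tau >= 0, n_min >= 1, quorum > 0, quorum <= 1)
  structure(list(tau = tau, n_min = as.integer(n_min), quorum = quorum),
            class = "classifier_params")
}

#' Expected skew signature of a gene given its polarity relative to the CR
#'
#' The strand-asymmetry model: a gene coded on the same strand as the
#' Control Region is expected to show the standard signature AT skew < 0 and
#' GC skew > 0 at fourfold sites; a gene on the opposite strand the negated
#' signature. No gene is special-cased — nad6's behaviour in standard
#' genomes follows from its strand alone.
#'
#' @param gene_strand `"+"` or `"-"`.
#' @param cr_strand `"+"` or `"-"`; passing `"undetermined"` is an error
#'   signalling an undetermined genome call.
#' @return List with `at_sign` and `gc_sign` (each -1 or +1).
#' @export
#' @examples
#' expected_signature("+", "+")  # standard: AT < 0, GC > 0
expected_signature <- function(gene_strand, cr_strand) {
  if (!cr_strand %in% c("+", "-")) {
    abort("Control-Region strand is undetermined; genome call is undetermined.",
          class = "mitoasym_cr_undetermined")
  }
  if (identical(gene_strand, cr_strand)) {
    list(at_sign = -1, gc_sign = +1)
  } else {
    list(at_sign = +1, gc_sign = -1)
  }
}

#' Classify one gene's observed skews against an expected signature
#'
#' A gene is `concordant` when both skew signs match the expectation and at
#' least one magnitude reaches `tau`; `reversed` when both match the negated
#' expectation likewise; and `ambiguous` when there are too few fourfold
#' codons, a skew is undefined, both magnitudes are sub-threshold, or the
#' two axes disagree.
#'
#' @param at_skew,gc_skew Observed skews (may be `NA` when undefined).
#' @param n_fourfold Number of fourfold codons behind the estimates.
#' @param expected Expected signature from [expected_signature()].
#' @param params [classifier_params()].
#' @return `"concordant"`, `"reversed"` or `"ambiguous"`.
#' @export
classify_gene <- function(at_skew, gc_skew, n_fourfold, expected,
                          params = classifier_params()) {
  if (is.na(at_skew) || is.na(gc_skew)) return("ambiguous")
  if (n_fourfold < params$n_min) return("ambiguous")
  if (max(abs(at_skew), abs(gc_skew)) < params$tau) return("ambiguous")
  s_at <- sign(at_skew); s_gc <- sign(gc_skew)
  if (s_at == expected$at_sign && s_gc == expected$gc_sign) return("concordant")
  if (s_at == -expected$at_sign && s_gc == -expected$gc_sign) return("reversed")
  "ambiguous"
}

#' Classify a genome's strand-asymmetry state relative to its Control Region
#'
#' Runs the full per-genome analysis: fourfold-site skews for every PCG
#' ([gene_skew_table()]), Control-Region location and polarity
#' ([locate_control_region()]), the CR-relative expected signature per gene
#' and a per-gene concordance state. The genome-level call is:
#' \describe{
#'   \item{standard}{every informative gene matches its CR-relative
#'     expectation and the CR is co-oriented with the majority PCG strand
#'     (the standard vertebrate configuration);}
#'   \item{reversed}{every informative gene matches its CR-relative
#'     expectation but the CR is counter-oriented — the fully
#'     re-equilibrated state seen after a CR inversion;}
#'   \item{disrupted}{adequate data whose signs are inconsistent with the
#'     CR-relative expectation for some or all genes — the transitory state
#'     in which architecture changed but composition has not re-equilibrated;}
#'   \item{undetermined}{CR polarity unknown, or fewer than `quorum`
#'     informative genes.}
#' }
#' The call depends only on relative polarity, so reverse-complementing the
#' whole stored genome leaves it unchanged. Duplicated PCG labels contribute
#' only their longest copy.
#'
#' @param genome A [mito_genome()].
#' @param params [classifier_params()].
#' @param cr_call Optional precomputed [locate_control_region()] result.
#' @return Object of class `asymmetry_call`: list with `genome`,
#'   `genome_state`, `cr_strand`, `cr_orientation` (`"co-oriented"`,
#'   `"counter-oriented"` or `NA`), `per_gene` (tibble) and `params`.
#' @export
classify_genome <- function(genome, params = classifier_params(),
                            cr_call = NULL) {
  skews <- gene_skew_table(genome)
  if (is.null(cr_call)) cr_call <- locate_control_region(genome)
  cr_strand <- cr_call$cr_strand
  # longest copy per duplicated PCG label
  if (nrow(skews)) {
    skews <- skews |>
      dplyr::group_by(.data$gene) |>
      dplyr::slice_max(.data$n_fourfold, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    tmpl_pos <- match(skews$gene, vertebrate_template()$label)
    skews <- skews[order(tmpl_pos, skews$gene), , drop = FALSE]
  }
  per_gene <- skews[, c("gene", "copy", "strand", "n_fourfold",
                        "at_skew", "gc_skew")]
  if (!cr_strand %in% c("+", "-")) {
    per_gene$expected_at <- NA_real_
    per_gene$expected_gc <- NA_real_
    per_gene$gene_state <- NA_character_
    return(new_asymmetry_call(genome$id, "undetermined", cr_strand,
                              NA_character_, per_gene, params))
  }
  expected <- purrr::map(per_gene$strand, expected_signature, cr_strand = cr_strand)
  per_gene$expected_at <- map_dbl(expected, "at_sign")
  per_gene$expected_gc <- map_dbl(expected, "gc_sign")
  per_gene$gene_state <- vapply(seq_len(nrow(per_gene)), function(i) {
    classify_gene(per_gene$at_skew[i], per_gene$gc_skew[i],
                  per_gene$n_fourfold[i], expected[[i]], params)
  }, character(1))

  strands <- per_gene$strand
  majority <- names(sort(table(strands), decreasing = TRUE))[1]
  orientation <- if (identical(cr_strand, majority)) "co-oriented" else "counter-oriented"

  informative <- per_gene$gene_state != "ambiguous"
  state <- if (nrow(per_gene) == 0L ||
               mean(informative) < params$quorum) {
    "undetermined"
  } else if (all(per_gene$gene_state[informative] == "concordant")) {
    if (orientation == "co-oriented") "standard" else "reversed"
  } else {
    "disrupted"
  }
  new_asymmetry_call(genome$id, state, cr_strand, orientation, per_gene, params)
}

new_asymmetry_call <- function(id, state, cr_strand, orientation, per_gene,
                               params) {
  structure(list(genome = id, genome_state = state, cr_strand = cr_strand,
                 cr_orientation = orientation, per_gene = per_gene,
                 params = params),
            class = "asymmetry_call")
}

#' @importFrom purrr map_dbl
#' @export
print.asymmetry_call <- function(x, ...) {
  cat(sprintf("<asymmetry_call> %s: %s (CR strand %s, %s)\n",
              x$genome, x$genome_state, x$cr_strand,
              x$cr_orientation %||% "orientation unknown"))
  states <- table(x$per_gene$gene_state, useNA = "ifany")
  cat("  per-gene:", paste(names(states), states, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a genome asymmetry call into a per-gene tibble
#' @param x An `asymmetry_call`.
#' @param ... Unused.
#' @return Tibble with one row per PCG.
#' @method tidy asymmetry_call
#' @export
tidy.asymmetry_call <- function(x, ...) {
  dplyr::bind_cols(tibble(genome = x$genome), x$per_gene,
                   tibble(genome_state = x$genome_state,
                          cr_strand = x$cr_strand))
}

#' One-row summary of a genome asymmetry call
#' @inheritParams tidy.asymmetry_call
#' @return One-row tibble.
#' @method glance asymmetry_call
#' @export
glance.asymmetry_call <- function(x, ...) {
  st <- x$per_gene$gene_state
  tibble(genome = x$genome, genome_state = x$genome_state,
         cr_strand = x$cr_strand, cr_orientation = x$cr_orientation,
         n_pcg = nrow(x$per_gene),
         n_concordant = sum(st == "concordant", na.rm = TRUE),
         n_reversed = sum(st == "reversed", na.rm = TRUE),
         n_ambiguous = sum(st == "ambiguous", na.rm = TRUE))
}

#' Combine asymmetry calls across genomes into a cohort report
#'
#' @param calls List of `asymmetry_call` objects.
#' @return Object of class `cohort_report`: list with `per_gene` (long
#'   tibble, genome x gene; genomes lacking a gene have no row) and
#'   `genomes` (one row per genome with state counts) plus `summary`
#'   (counts of genome states).
#' @export
cohort_report <- function(calls) {
  stopifnot(length(calls) >= 1L)
  per_gene <- purrr::map_dfr(calls, tidy)
  genomes <- purrr::map_dfr(calls, glance)
  summary <- genomes |> dplyr::count(.data$genome_state, name = "n_genomes")
  structure(list(per_gene = per_gene, genomes = genomes, summary = summary),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d genome(s)\n", nrow(x$genomes)))
  print(x$summary)
  invisible(x)
}

#' Plot per-gene fourfold-site skews for one genome call
#'
#' Dot plot of AT and GC skew per gene, coloured by the gene's concordance
#' state relative to the Control-Region expectation.
#'
#' @param object An `asymmetry_call`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot asymmetry_call
#' @export
autoplot.asymmetry_call <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"), names_to = "statistic",
                        values_to = "skew")
  d$gene <- factor(d$gene, levels = unique(d$gene))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$skew,
                                  shape = .data$statistic,
                                  colour = .data$gene_state)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(title = sprintf("%s: %s", object$genome, object$genome_state),
                  x = NULL, y = "skew at fourfold sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot a cohort of genome calls as a gene-by-genome skew matrix
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  d <- object$per_gene |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"), names_to = "statistic",
                        values_to = "skew")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$genome,
                                  fill = .data$skew)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "skew") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
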