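#' Signed circular gene-order signature of a genome
#'
#' Orders all gene-typed features (plus the Control Region, which
#' participates as a non-gene entry so CR inversions are reportable) by
#' genomic position and rotates the list into canonical form: cox1 on its
#' first copy leads when present, otherwise the lexicographically smallest
#' label. The canonical rotation makes the signature invariant to where the
#' stored origin happens to fall.
#'
#' @param genome A [mito_genome()], or a data frame with columns `label`,
#'   `strand` (and optionally `copy_index`) already in circular order.
#' @return Tibble of class `order_signature`: columns `label`, `strand`,
#'   `copy`.
#' @export
order_signature <- function(genome) {
  f <- if (inherits(genome, "mito_genome")) {
    g <- dplyr::filter(genome$features,
                       .data$ftype %in% c("PCG", "tRNA", "rRNA", "CR"))
    if (!nrow(g)) abort("genome has no gene features.",
                        class = "mitoasym_no_genes")
    g[order(g$start), c("label", "strand", "copy_index")]
  } else {
    g <- as_tibble(genome)
    if (!"copy_index" %in% names(g)) g$copy_index <- NA_integer_
    g[, c("label", "strand", "copy_index")]
  }
  names(f) <- c("label", "strand", "copy")
  if (any(is.na(f$copy))) {
    f$copy <- stats::ave(seq_len(nrow(f)), f$label,
                         FUN = function(i) rank(i, ties.method = "first"))
    f$copy <- as.integer(f$copy)
  }
  canonical_rotation(f)
}

canonical_rotation <- function(sig) {
  anchor <- which(sig$label == "cox1" & sig$copy == 1L)
  if (!length(anchor)) anchor <- which(sig$label == sort(sig$label)[1])[1]
  idx <- ((seq_len(nrow(sig)) + anchor[1] - 2L) %% nrow(sig)) + 1L
  out <- sig[idx, , drop = FALSE]
  class(out) <- c("order_signature", class(tibble()))
  out
}

#' The gene-order signature of the standard vertebrate template
#' @return An `order_signature` tibble.
#' @export
template_signature <- function() {
  t <- vertebrate_template()
  order_signature(tibble(label = t$label, strand = t$strand))
}

#' Render a gene order as a one-line text diagram
#'
#' Linearizes a signature with strand marks (`>` forward, `<` reverse) and
#' `.n` suffixes for extra copies, suitable for logs and documentation.
#'
#' @param observed An `order_signature` (or a compatible data frame).
#' @return A single string.
#' @export
#' @examples
#' cat(render_linear(template_signature()), "\n")
render_linear <- function(observed) {
  s <- as_tibble(observed)
  marks <- ifelse(s$strand == "+", ">", "<")
  copies <- ifelse(s$copy > 1L, paste0(".", s$copy), "")
  paste(paste0(marks, s$label, copies), collapse = " ")
}

#' Classify gene-order deviations from a template
#'
#' Greedy typed decomposition of the differences between an observed signed
#' circular gene order and a template order:
#' \enumerate{
#'   \item labels over-represented in the observed order are reported as
#'     duplications; under-represented labels as losses;
#'   \item strand-flipped genes, grouped into maximal runs contiguous in the
#'     observed order, yield one inversion event per run;
#'   \item strand-preserved genes out of place are explained as a single
#'     moved block where possible: a displacement of at most `k` template
#'     positions is a shuffle (a local exchange), anything farther is a
#'     translocation. Residual differences that no single block explains
#'     are reported as one best-effort `translocation` event with detail
#'     `"compound"`.
#' }
#' This is a typed description of observed patterns, not a minimal
#' rearrangement-distance solver.
#'
#' @param observed An `order_signature` (e.g. from [order_signature()]).
#' @param template Template signature; defaults to [template_signature()].
#' @param k Shuffle window: maximal displacement (in positions) still called
#'   a shuffle. Default 2.
#' @param max_block Maximal moved-block length tried (default 6).
#' @return Tibble with columns `etype` (`"duplication"`, `"loss"`,
#'   `"inversion"`, `"shuffle"`, `"translocation"`), `genes`
#'   (comma-separated labels) and `detail`. Empty when the orders agree.
#' @export
classify_events <- function(observed, template = template_signature(),
                            k = 2, max_block = 6) {
  obs <- as_tibble(order_signature(observed))
  tmp <- as_tibble(order_signature(template))
  events <- tibble(etype = character(), genes = character(),
                   detail = character())

  obs_n <- table(obs$label)
  tmp_n <- table(tmp$label)
  labels <- union(names(obs_n), names(tmp_n))
  for (lb in sort(labels)) {
    no <- if (lb %in% names(obs_n)) obs_n[[lb]] else 0L
    nt <- if (lb %in% names(tmp_n)) tmp_n[[lb]] else 0L
    if (no > nt) {
      events <- dplyr::bind_rows(events, tibble(
        etype = "duplication", genes = lb,
        detail = sprintf("%d copies observed, %d in template", no, nt)))
    } else if (no < nt) {
      events <- dplyr::bind_rows(events, tibble(
        etype = "loss", genes = lb,
        detail = sprintf("%d copies observed, %d in template", no, nt)))
    }
  }

  shared <- intersect(obs$label[obs$copy == 1L], tmp$label[tmp$copy == 1L])
  o1 <- obs[obs$copy == 1L & obs$label %in% shared, c("label", "strand")]
  t1 <- tmp[tmp$copy == 1L & tmp$label %in% shared, c("label", "strand")]
  t_strand <- stats::setNames(t1$strand, t1$label)
  flipped <- o1$label[o1$strand != t_strand[o1$label]]

  if (length(flipped)) {
    runs <- circular_runs(o1$label %in% flipped)
    for (r in runs) {
      events <- dplyr::bind_rows(events, tibble(
        etype = "inversion",
        genes = paste(o1$label[r], collapse = ","),
        detail = sprintf("%d gene(s) on the complementary strand", length(r))))
    }
  }

  o2 <- o1$label[!o1$label %in% flipped]
  t2 <- t1$label[!t1$label %in% flipped]
  if (!circular_equal(o2, t2)) {
    mv <- find_moved_block(o2, t2, max_block)
    if (!is.null(mv)) {
      if (mv$displacement <= k) {
        events <- dplyr::bind_rows(events, tibble(
          etype = "shuffle",
          genes = paste(unique(c(mv$block, mv$crossed)), collapse = ","),
          detail = sprintf("local exchange, displacement %d", mv$displacement)))
      } else {
        events <- dplyr::bind_rows(events, tibble(
          etype = "translocation",
          genes = paste(mv$block, collapse = ","),
          detail = sprintf("moved %d positions, now after %s",
                           mv$displacement, mv$new_pred)))
      }
    } else {
      displaced <- neighbour_changed(o2, t2)
      events <- dplyr::bind_rows(events, tibble(
        etype = "translocation",
        genes = paste(displaced, collapse = ","),
        detail = "compound"))
    }
  }
  events[order(events$etype, events$genes), , drop = FALSE]
}

# maximal circular runs of TRUE; returns list of index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (!any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  start <- which(!flag)[1]  # rotate so a FALSE leads
  idx <- ((seq_len(n) + start - 1L) %% n) + 1L
  f <- flag[idx]
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(q) idx[seq(starts[q], ends[q])])
}

circular_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  hit <- which(b == a[1])
  for (s in hit) {
    if (all(b[((seq_along(b) + s - 2L) %% length(b)) + 1L] == a)) return(TRUE)
  }
  FALSE
}

# Try to explain obs vs tmp (equal-content circular label vectors) as one
# contiguous moved block preserving internal order.
find_moved_block <- function(obs, tmp, max_block) {
  n <- length(obs)
  if (n < 2L) return(NULL)
  for (bl in seq_len(min(max_block, n - 1L))) {
    for (s in seq_len(n)) {
      idx <- ((seq_len(bl) + s - 2L) %% n) + 1L
      block <- obs[idx]
      rest_o <- obs[-idx]
      pos_t <- match(block[1], tmp)
      idx_t <- ((seq_len(bl) + pos_t - 2L) %% length(tmp)) + 1L
      if (!all(tmp[idx_t] == block)) next  # block not contiguous in template
      rest_t <- tmp[-idx_t]
      if (!circular_equal(rest_o, rest_t)) next
      pred_o <- obs[((s - 2L) %% n) + 1L]
      pred_t <- tmp[((pos_t - 2L) %% length(tmp)) + 1L]
      if (pred_o == pred_t) next  # block did not actually move
      io <- match(pred_o, rest_t)
      it <- match(pred_t, rest_t)
      m <- length(rest_t)
      d <- min((io - it) %% m, (it - io) %% m)
      crossed <- crossed_genes(rest_t, it, io)
      return(list(block = block, displacement = d, crossed = crossed,
                  new_pred = pred_o))
    }
  }
  NULL
}

crossed_genes <- function(rest, it, io, limit = 4L) {
  m <- length(rest)
  fwd <- (io - it) %% m
  bwd <- (it - io) %% m
  steps <- if (fwd <= bwd) {
    if (fwd == 0L) integer() else ((it + seq_len(fwd) - 1L) %% m) + 1L
  } else {
    if (bwd == 0L) integer() else ((io + seq_len(bwd) - 1L) %% m) + 1L
  }
  if (length(steps) > limit) steps <- steps[seq_len(limit)]
  rest[steps]
}

# genes whose circular neighbourhood changed between two equal-content orders
neighbour_changed <- function(obs, tmp) {
  nb <- function(x) {
    n <- length(x)
    stats::setNames(paste(x[((seq_len(n) - 2L) %% n) + 1L],
                          x[(seq_len(n) %% n) + 1L], sep = "|"), x)
  }
  no <- nb(obs); nt <- nb(tmp)
  common <- intersect(names(no), names(nt))
  sort(common[no[common] != nt[common]])
}
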