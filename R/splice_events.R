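# Splice-event classification: pair each isoform's exon chain against the
# reference (isoform-1) chain and name the differences with the field's
# deltaE-n (skip) / exN' (novel inclusion) nomenclature.

#' Pair exons of an isoform chain with the reference chain
#'
#' Order-preserving pairing; each exon pairs at most once. Under the
#' default strict mode an exon pairs only with a reference exon that has
#' identical genomic boundaries (annotated isoforms of one gene reuse exact
#' exon boundaries). The relaxed mode pairs on reciprocal overlap above
#' `min_overlap` (a fraction of the shorter exon; `0` = any overlap), for
#' noisy annotations.
#'
#' @param isoform_chain,reference_chain [exon_chain()]s from the same locus
#'   and strand.
#' @param mode `"strict"` (identical boundaries) or `"overlap"`.
#' @param min_overlap minimum reciprocal overlap fraction in overlap mode.
#' @return data frame with one row per pairing: `iso_idx`, `ref_idx`,
#'   `ref_label`. Attribute `partial_overlap_warnings` lists strict-mode
#'   exons that overlap a reference exon without sharing both boundaries
#'   (alternative 3'/5' splice-site candidates, reported but not
#'   classified).
#' @export
match_exons <- function(isoform_chain, reference_chain,
                        mode = c("strict", "overlap"), min_overlap = 0) {
  mode <- match.arg(mode)
  .check_same_locus(isoform_chain, reference_chain)
  # work in ascending genomic order; order preservation is equivalent on
  # either strand because both chains share the strand
  io <- order(isoform_chain$start); ro <- order(reference_chain$start)
  iso <- isoform_chain[io, , drop = FALSE]
  ref <- reference_chain[ro, , drop = FALSE]
  pairs <- list(); i <- 1L; j <- 1L
  while (i <= nrow(iso) && j <= nrow(ref)) {
    ov <- .ivl_overlap(iso$start[i], iso$end[i], ref$start[j], ref$end[j])
    matched <- if (mode == "strict") {
      iso$start[i] == ref$start[j] && iso$end[i] == ref$end[j]
    } else {
      shorter <- min(iso$end[i] - iso$start[i], ref$end[j] - ref$start[j])
      ov > 0 && ov / shorter >= min_overlap
    }
    if (matched) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        iso_idx = io[i], ref_idx = ro[j], ref_label = ref$label[j],
        stringsAsFactors = FALSE)
      i <- i + 1L; j <- j + 1L
    } else if (iso$end[i] <= ref$end[j]) i <- i + 1L else j <- j + 1L
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
         else data.frame(iso_idx = integer(), ref_idx = integer(),
                         ref_label = character(), stringsAsFactors = FALSE)
  warn <- character()
  if (mode == "strict") {
    unp <- setdiff(seq_len(nrow(isoform_chain)), out$iso_idx)
    for (u in unp) {
      ov <- .ivl_overlap(isoform_chain$start[u], isoform_chain$end[u],
                         reference_chain$start, reference_chain$end)
      if (any(ov > 0)) {
        warn <- c(warn, sprintf(
          "exon [%d, %d) overlaps reference exon '%s' without shared boundaries (possible alternative splice site)",
          isoform_chain$start[u], isoform_chain$end[u],
          reference_chain$label[which(ov > 0)[1]]))
      }
    }
  }
  attr(out, "partial_overlap_warnings") <- warn
  out
}

.check_same_locus <- function(a, b) {
  if (!identical(attr(a, "chromosome"), attr(b, "chromosome")) ||
      !identical(attr(a, "strand"), attr(b, "strand"))) {
    .stopf("exon chains come from different loci (chromosome/strand mismatch)")
  }
}

#' Name a novel exon after its upstream canonical neighbour
#'
#' Novel exons are labelled `"exN'"` where N is the canonical number of the
#' nearest reference exon upstream (5') in transcription order, preferring
#' a *paired* reference exon; when no reference exon lies upstream at all
#' the novel exon occupies the first-exon slot and is named `"ex1'"`. Two
#' novel exons falling between the same canonical pair get `a`, `b`, ...
#' suffixes in transcription order (handled by [classify_events()]).
#'
#' @param novel_start,novel_end genomic interval of the novel exon.
#' @param reference_chain the reference [exon_chain()].
#' @param paired_ref_idx indices of reference exons paired in the isoform
#'   under consideration (defaults to all of them).
#' @return character label.
#' @export
name_novel_exon <- function(novel_start, novel_end, reference_chain,
                            paired_ref_idx = seq_len(nrow(reference_chain))) {
  strand <- attr(reference_chain, "strand")
  upstream <- if (strand == "+") which(reference_chain$end <= novel_start)
              else which(reference_chain$start >= novel_end)
  if (length(upstream) == 0) return("ex1'")
  up_paired <- intersect(upstream, paired_ref_idx)
  pool <- if (length(up_paired) > 0) up_paired else upstream
  # nearest upstream = maximal transcription-order index (chains are stored
  # in transcription order)
  paste0("ex", .label_number(reference_chain$label[max(pool)]), "'")
}

#' Classify splicing events of an isoform against the reference
#'
#' Unpaired reference exons are skips (deltaE-n); unpaired isoform exons
#' are novel inclusions (exN'); additionally an alternative-first-exon
#' event is emitted when the isoform's 5'-most exon is novel. Identical
#' chains yield an empty event set.
#'
#' @inheritParams match_exons
#' @param isoform_id,reference_id ids recorded on the result.
#' @return object of class `splice_events`: a data frame with columns
#'   `kind` (`SKIP` / `NOVEL_INCLUSION` / `ALT_FIRST_EXON`), `exon_label`,
#'   `start`, `end`, and attributes `isoform_id`, `reference_id`,
#'   `shared_exon_count`.
#' @export
classify_events <- function(isoform_chain, reference_chain,
                            isoform_id = "isoform", reference_id = "reference",
                            mode = "strict", min_overlap = 0) {
  pairs <- match_exons(isoform_chain, reference_chain, mode = mode,
                       min_overlap = min_overlap)
  skip_idx <- setdiff(seq_len(nrow(reference_chain)), pairs$ref_idx)
  novel_idx <- setdiff(seq_len(nrow(isoform_chain)), pairs$iso_idx)

  ev <- list()
  for (j in sort(skip_idx)) {
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "SKIP", exon_label = reference_chain$label[j],
      start = reference_chain$start[j], end = reference_chain$end[j],
      stringsAsFactors = FALSE)
  }
  novel_idx <- sort(novel_idx)
  novel_labels <- vapply(novel_idx, function(u) {
    lab <- isoform_chain$label[u]
    if (!is.na(lab) && .is_novel_label(lab)) .normalize_exon_label(lab)
    else name_novel_exon(isoform_chain$start[u], isoform_chain$end[u],
                         reference_chain, paired_ref_idx = pairs$ref_idx)
  }, character(1))
  # tie-break duplicated novel names with a/b/... suffixes in genomic order
  if (anyDuplicated(novel_labels)) {
    for (lab in unique(novel_labels[duplicated(novel_labels)])) {
      k <- which(novel_labels == lab)
      k <- k[order(isoform_chain$start[novel_idx[k]])]
      novel_labels[k] <- paste0(lab, letters[seq_along(k)])
    }
  }
  for (m in seq_along(novel_idx)) {
    u <- novel_idx[m]
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "NOVEL_INCLUSION", exon_label = novel_labels[m],
      start = isoform_chain$start[u], end = isoform_chain$end[u],
      stringsAsFactors = FALSE)
  }
  if (nrow(isoform_chain) > 0 && 1L %in% novel_idx) {
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "ALT_FIRST_EXON",
      exon_label = novel_labels[match(1L, novel_idx)],
      start = isoform_chain$start[1], end = isoform_chain$end[1],
      stringsAsFactors = FALSE)
  }
  out <- if (length(ev)) do.call(rbind, ev)
         else data.frame(kind = character(), exon_label = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  structure(out, isoform_id = isoform_id, reference_id = reference_id,
            shared_exon_count = nrow(pairs),
            partial_overlap_warnings = attr(pairs, "partial_overlap_warnings"),
            class = c("splice_events", "data.frame"))
}

#' @export
print.splice_events <- function(x, ...) {
  cat(sprintf("splice events: %s vs %s (%d shared exon(s))\n",
              attr(x, "isoform_id"), attr(x, "reference_id"),
              attr(x, "shared_exon_count")))
  if (nrow(x) == 0) cat("  (identical chains)\n") else
    print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Compact event label, e.g. "dE1, dE3, +ex1'"
#' @param events a `splice_events` object.
#' @return character scalar.
#' @export
format_events <- function(events) {
  if (nrow(events) == 0) return("")
  parts <- character()
  sk <- events$exon_label[events$kind == "SKIP"]
  if (length(sk)) parts <- c(parts, paste0("dE", .label_number(sk)))
  nv <- events$exon_label[events$kind == "NOVEL_INCLUSION"]
  if (length(nv)) parts <- c(parts, paste0("+", nv))
  paste(parts, collapse = ", ")
}

#' Union of distinct exons across all isoforms of a locus
#'
#' @param locus a [gene_locus()].
#' @return an [exon_chain()] of the distinct exon intervals across every
#'   isoform chain, in transcription order; canonical exons keep their
#'   reference labels, novel exons their primed labels. The number of rows
#'   is the distinct exon count of the genomic region.
#' @export
exon_union <- function(locus) {
  ref <- reference_transcript(locus)$exons
  seen <- data.frame(start = ref$start, end = ref$end, label = ref$label,
                     is_novel = FALSE, stringsAsFactors = FALSE)
  for (tr in locus$isoforms) {
    ev <- classify_events(tr$exons, ref, isoform_id = tr$transcript_id,
                          reference_id = locus$reference_isoform_id)
    nov <- ev[ev$kind == "NOVEL_INCLUSION", , drop = FALSE]
    for (m in seq_len(nrow(nov))) {
      dup <- seen$start == nov$start[m] & seen$end == nov$end[m]
      if (!any(dup)) {
        seen <- rbind(seen, data.frame(start = nov$start[m], end = nov$end[m],
                                       label = nov$exon_label[m],
                                       is_novel = TRUE, stringsAsFactors = FALSE))
      }
    }
  }
  ord <- order(seen$start, decreasing = locus$strand == "-")
  seen <- seen[ord, , drop = FALSE]
  exon_chain(seen$start, seen$end, label = seen$label, is_novel = seen$is_novel,
             chromosome = locus$chromosome, strand = locus$strand)
}
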