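# Catalogue assembly: run event classification, translation, domain
# statistics and localization inference over a set of loci and emit one
# table row per isoform, mirroring the curated sirtuin catalogue layout.

#' Construct / validate a catalogue table
#'
#' Validates the per-isoform catalogue: one row per (gene, isoform) pair,
#' and -- wherever a domain is annotated -- the printed length and
#' percentage columns must agree with [domain_length()] and
#' [domain_fraction()] recomputed from the boundaries. Rows are ordered by
#' gene and isoform index.
#'
#' @param df data frame with columns `gene`, `chromosome`, `isoform`,
#'   `mrna_accession`, `exon_skipping`, `novel_exons`, `protein_accession`,
#'   `amino_acid`, `domain_from`, `domain_to`, `domain_length`,
#'   `pct_domain_total`, `nls_status`, `mts_status`, `localization`.
#' @return the validated data frame, classed `catalog_table`.
#' @export
catalog_table <- function(df) {
  key <- paste(df$gene, df$isoform)
  if (anyDuplicated(key)) .stopf("duplicate (gene, isoform) pair: %s", key[duplicated(key)][1])
  has_dom <- !is.na(df$domain_from)
  if (any(has_dom)) {
    len <- domain_length(df$domain_from[has_dom], df$domain_to[has_dom])
    if (!all(len == df$domain_length[has_dom])) {
      bad <- which(len != df$domain_length[has_dom])[1]
      .stopf("row %s: domain length %d inconsistent with boundaries %d-%d",
             key[has_dom][bad], df$domain_length[has_dom][bad],
             df$domain_from[has_dom][bad], df$domain_to[has_dom][bad])
    }
    pct <- domain_fraction(len, df$amino_acid[has_dom])
    if (!isTRUE(all.equal(pct, df$pct_domain_total[has_dom], tolerance = 1e-9))) {
      bad <- which(abs(pct - df$pct_domain_total[has_dom]) > 1e-9)[1]
      .stopf("row %s: domain percentage %.1f inconsistent (recomputed %.1f)",
             key[has_dom][bad], df$pct_domain_total[has_dom][bad], pct[bad])
    }
  }
  iso_num <- suppressWarnings(as.integer(sub("^[Vv]", "", df$isoform)))
  iso_num[is.na(iso_num)] <- seq_len(nrow(df))[is.na(iso_num)]
  df <- df[order(df$gene, iso_num), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("catalog_table", "data.frame"))
}

#' @export
print.catalog_table <- function(x, ...) {
  cat(sprintf("isoform catalogue: %d isoform(s) across %d gene(s)\n",
              nrow(x), length(unique(x$gene))))
  shown <- c("gene", "isoform", "mrna_accession", "exon_skipping",
             "amino_acid", "domain_length", "pct_domain_total", "localization")
  print.data.frame(as.data.frame(x)[, intersect(shown, names(x))], row.names = FALSE)
  invisible(x)
}

#' Build the isoform catalogue for a set of loci
#'
#' Runs the whole per-locus pipeline: translation of each coding isoform,
#' splice-event classification against the reference isoform, NLS
#' consensus scanning, the N-terminal mitochondrial-targeting heuristic,
#' attachment of user-supplied signal and domain annotations, and
#' localization inference. Signal presence/loss columns are reported
#' relative to the gene's reference isoform: when the reference itself
#' lacks a signal the column reads `"n/a"` ("lost" is only meaningful
#' against a reference that has it).
#'
#' @param loci a [gene_locus()] or list of them (as from [read_locus()]).
#' @param signals optional data frame from [read_signal_annotations()];
#'   `protein_id` entries are matched against transcript ids.
#' @param domains optional data frame from [read_domain_annotations()].
#' @param config settings from [isocat_config()].
#' @return a `catalog_table`; the per-isoform `splice_events` objects are
#'   attached as attribute `"events"`, the localization calls as
#'   `"localization_calls"`.
#' @export
build_catalog <- function(loci, signals = NULL, domains = NULL,
                          config = isocat_config()) {
  if (inherits(loci, "gene_locus")) loci <- list(loci)
  nls_pat <- compile_pattern(config$nls_pattern, name = "NLS consensus")
  rows <- list(); all_events <- list(); all_calls <- list()

  for (locus in loci) {
    ref_tr <- reference_transcript(locus)
    # analyse every isoform once
    analysed <- lapply(locus$isoforms, .analyse_isoform, locus = locus,
                       ref_tr = ref_tr, nls_pat = nls_pat, signals = signals,
                       domains = domains, config = config)
    ref_an <- analysed[[locus$reference_isoform_id]]
    ref_call <- infer_localization(ref_an$protein)
    ref_has <- function(kind) any(ref_an$protein$signals$kind == kind)

    for (tid in names(analysed)) {
      an <- analysed[[tid]]
      call <- if (tid == locus$reference_isoform_id) ref_call
              else infer_localization(an$protein, reference_call = ref_call)
      status <- function(kind) {
        if (!ref_has(kind)) "n/a"
        else if (any(an$protein$signals$kind == kind)) "present" else "lost"
      }
      dom <- an$protein$domains
      has_dom <- !is.null(dom) && nrow(dom) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = locus$gene_id, chromosome = locus$chromosome, isoform = tid,
        mrna_accession = an$tr$mrna_accession,
        exon_skipping = an$skipped, novel_exons = an$novel,
        protein_accession = an$protein$protein_accession,
        amino_acid = an$protein$length_aa,
        domain_from = if (has_dom) dom$from_aa[1] else NA_integer_,
        domain_to = if (has_dom) dom$to_aa[1] else NA_integer_,
        domain_length = if (has_dom) dom$length_aa[1] else NA_integer_,
        pct_domain_total = if (has_dom) dom$fraction_pct[1] else NA_real_,
        nls_status = status("NLS"), mts_status = status("MTS"),
        localization = call$compartment,
        stringsAsFactors = FALSE)
      all_events[[paste(locus$gene_id, tid)]] <- an$events
      all_calls[[paste(locus$gene_id, tid)]] <- call
    }
  }
  out <- catalog_table(do.call(rbind, rows))
  attr(out, "events") <- all_events
  attr(out, "localization_calls") <- all_calls
  out
}

# classify, translate and annotate one isoform
.analyse_isoform <- function(tr, locus, ref_tr, nls_pat, signals, domains, config) {
  ev <- classify_events(tr$exons, ref_tr$exons, isoform_id = tr$transcript_id,
                        reference_id = locus$reference_isoform_id,
                        mode = config$match_mode, min_overlap = config$min_overlap)
  skipped <- ev$exon_label[ev$kind == "SKIP"]
  novel <- ev$exon_label[ev$kind == "NOVEL_INCLUSION"]

  prot <- tr$protein
  if (is.null(prot)) {
    if (is.null(tr$cds) || is.null(locus$sequence)) {
      .stopf("isoform '%s': no protein and no translatable CDS", tr$transcript_id)
    }
    prot <- protein_isoform(paste0(tr$transcript_id, "-p"),
                            sequence = translate_cds(tr, locus$sequence))
  }
  sig_rows <- list()
  hits <- scan_motif(prot$sequence, nls_pat)
  for (i in seq_len(nrow(hits))) {
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      kind = "NLS", name = paste0("NLS", i),
      from_aa = hits$from_aa[i], to_aa = hits$to_aa[i],
      source = "pattern-scan", stringsAsFactors = FALSE)
  }
  mts <- scan_mts(prot$sequence, window = config$mts_window,
                  min_basic = config$mts_min_basic,
                  max_acidic = config$mts_max_acidic)
  if (mts$present) {
    sig_rows[[length(sig_rows) + 1L]] <- data.frame(
      kind = "MTS", name = "MTS", from_aa = 1L,
      to_aa = min(config$mts_window, prot$length_aa),
      source = "pattern-scan", stringsAsFactors = FALSE)
  }
  if (!is.null(signals)) {
    mine <- signals[signals$protein_id %in% c(tr$transcript_id, prot$protein_accession), ,
                    drop = FALSE]
    for (i in seq_len(nrow(mine))) {
      if (mine$to_aa[i] > prot$length_aa) {
        .stopf("signal %s outside protein '%s'", mine$name[i], tr$transcript_id)
      }
      sig_rows[[length(sig_rows) + 1L]] <-
        mine[i, c("kind", "name", "from_aa", "to_aa", "source")]
    }
  }
  sig <- if (length(sig_rows)) do.call(rbind, sig_rows)
         else data.frame(kind = character(), name = character(),
                         from_aa = integer(), to_aa = integer(),
                         source = character(), stringsAsFactors = FALSE)
  sig$exon_of_origin <- vapply(seq_len(nrow(sig)), function(i) {
    if (is.null(tr$cds)) return(NA_character_)
    paste(exons_of_interval(tr, sig$from_aa[i], sig$to_aa[i]), collapse = ",")
  }, character(1))

  dom <- NULL
  if (!is.null(domains)) {
    mine <- domains[domains$protein_id %in% c(tr$transcript_id, prot$protein_accession), ,
                    drop = FALSE]
    if (nrow(mine) > 0) {
      dom <- data.frame(name = mine$name, from_aa = mine$from_aa,
                        to_aa = mine$to_aa,
                        length_aa = domain_length(mine$from_aa, mine$to_aa),
                        stringsAsFactors = FALSE)
      dom$fraction_pct <- domain_fraction(dom$length_aa, prot$length_aa)
    }
  }
  prot <- protein_isoform(prot$protein_accession, sequence = prot$sequence,
                          domains = dom, signals = sig)
  list(tr = tr, protein = prot, events = ev,
       skipped = if (length(skipped) == 0) "" else
         paste(paste0("ex", .label_number(skipped)), collapse = ", "),
       novel = paste(novel, collapse = ", "))
}

#' Summary statistics of a catalogue
#'
#' Counts and extrema: number of isoforms and genes, genes with more than
#' one isoform, protein- and domain-length ranges (with the isoforms that
#' attain them), and per-gene isoform counts.
#'
#' @param object a `catalog_table`.
#' @param ... unused.
#' @return list of class `catalog_summary`.
#' @export
summary.catalog_table <- function(object, ...) {
  if (nrow(object) == 0) .stopf("empty catalogue")
  per_gene <- table(object$gene)
  id <- paste0(object$gene, "-", tolower(object$isoform))
  dl <- object$domain_length
  at <- function(x, idx) sort(id[which(x == x[idx])])
  pmin_i <- which.min(object$amino_acid); pmax_i <- which.max(object$amino_acid)
  has_dom <- any(!is.na(dl))
  dmin_i <- if (has_dom) which.min(dl) else NA_integer_
  dmax_i <- if (has_dom) which.max(dl) else NA_integer_
  structure(list(
    n_isoforms = nrow(object),
    n_genes = length(per_gene),
    genes_multi_isoform = sum(per_gene > 1),
    per_gene_counts = c(per_gene),
    protein_len_min = object$amino_acid[pmin_i],
    protein_len_min_ids = at(object$amino_acid, pmin_i),
    protein_len_max = object$amino_acid[pmax_i],
    protein_len_max_ids = at(object$amino_acid, pmax_i),
    domain_len_min = if (has_dom) dl[dmin_i] else NA_integer_,
    domain_len_min_ids = if (has_dom) at(dl, dmin_i) else character(),
    domain_len_max = if (has_dom) dl[dmax_i] else NA_integer_,
    domain_len_max_ids = if (has_dom) at(dl, dmax_i) else character()
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("%d isoform(s) from %d gene(s); %d gene(s) with >1 isoform\n",
              x$n_isoforms, x$n_genes, x$genes_multi_isoform))
  cat("per-gene counts: ",
      paste(sprintf("%s=%d", names(x$per_gene_counts), x$per_gene_counts),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("protein length range: %d (%s) to %d (%s)\n",
              x$protein_len_min, paste(x$protein_len_min_ids, collapse = ","),
              x$protein_len_max, paste(x$protein_len_max_ids, collapse = ",")))
  if (is.na(x$domain_len_min)) {
    cat("domain length range: no domain annotations\n")
  } else {
    cat(sprintf("domain length range: %d (%s) to %d (%s)\n",
                x$domain_len_min, paste(x$domain_len_min_ids, collapse = ","),
                x$domain_len_max, paste(x$domain_len_max_ids, collapse = ",")))
  }
  invisible(x)
}

#' @rdname summary.catalog_table
#' @param table a `catalog_table`.
#' @export
summarize_catalog <- function(table) summary(table)

#' Plot the isoform structure of a locus
#'
#' One horizontal track per isoform in transcription orientation
#' (5' left): exon boxes (novel exons hatched), connecting intron lines,
#' and localization-signal marks when a catalogue with signal calls is
#' supplied. Layout is deterministic.
#'
#' @param x a [gene_locus()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.gene_locus <- function(x, ...) {
  if (length(x$isoforms) == 0) .stopf("empty locus")
  n <- length(x$isoforms)
  rng <- x$span
  graphics::plot(NA, xlim = if (x$strand == "+") rng else rev(rng),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = sprintf("%s position (bp, 5'->3')", x$chromosome),
                 ylab = "", main = sprintf("%s isoforms", x$gene_id), ...)
  graphics::axis(2, at = seq_len(n), labels = rev(names(x$isoforms)), las = 1)
  for (k in seq_len(n)) {
    tr <- x$isoforms[[k]]
    y <- n - k + 1
    ch <- tr$exons
    graphics::segments(min(ch$start), y, max(ch$end), y, col = "grey60")
    graphics::rect(ch$start, y - 0.25, ch$end, y + 0.25,
                   col = ifelse(ch$is_novel, "orange", "steelblue"),
                   border = "black")
    graphics::text((ch$start + ch$end) / 2, y + 0.34, ch$label, cex = 0.6)
  }
  invisible(x)
}

#' Render the isoform diagram of a locus to a file
#'
#' @param locus a [gene_locus()].
#' @param path output path; `.pdf` and `.png` are supported.
#' @param width,height device size in inches.
#' @return invisibly, `path`.
#' @export
render_isoform_diagram <- function(locus, path, width = 8, height = 4) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") grDevices::pdf(path, width = width, height = height)
  else if (ext == "png") grDevices::png(path, width = width * 100, height = height * 100)
  else .stopf("unsupported figure format '%s'", ext)
  on.exit(grDevices::dev.off())
  plot(locus)
  invisible(path)
}
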