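# Readers/writers for the formats the pipeline touches: genomic FASTA +
# GFF3 annotation in, catalogue / events / signal TSVs out. All coordinate
# conversion between GFF3's 1-based inclusive convention and the package's
# 0-based half-open internal convention is isolated here.

#' Read gene loci from genomic FASTA + GFF3
#'
#' Expects the RefSeq-style feature hierarchy `gene -> mRNA -> exon/CDS`
#' linked through `Parent` attributes. Exon chains are returned in
#' transcription order; the contig sequence is attached to each locus.
#' Recognised optional attributes: `Name` (exon labels, isoform names),
#' `mrna_accession`, `protein_accession`, `reference` (marks the reference
#' isoform on its mRNA feature), `novel` (exon novelty flag).
#'
#' @param genomic_fasta path to the genomic FASTA.
#' @param annotation_gff3 path to the GFF3 annotation.
#' @return named list of [gene_locus()] objects, one per `gene` feature.
#' @export
read_locus <- function(genomic_fasta, annotation_gff3) {
  seqs <- Biostrings::readDNAStringSet(genomic_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(annotation_gff3, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  typ <- as.character(mc$type)
  ids <- as.character(mc$ID)
  parents <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  known <- ids[!is.na(ids)]
  orphan <- !is.na(parents) & !parents %in% known
  if (any(orphan)) {
    .stopf("orphan feature(s): Parent '%s' not defined", parents[orphan][1])
  }
  opt <- function(col, i) {
    if (col %in% names(mc)) as.character(mc[[col]])[i] else NA_character_
  }

  gene_rows <- which(typ == "gene")
  loci <- list()
  for (g in gene_rows) {
    gid <- if (!is.na(opt("Name", g))) opt("Name", g) else ids[g]
    chrom <- as.character(GenomicRanges::seqnames(gr))[g]
    if (!chrom %in% names(seqs)) .stopf("gene '%s': contig '%s' missing from FASTA", gid, chrom)
    strand <- as.character(GenomicRanges::strand(gr))[g]
    if (!strand %in% c("+", "-")) .stopf("gene '%s': unstranded gene feature", gid)
    span <- c(GenomicRanges::start(gr)[g] - 1L, GenomicRanges::end(gr)[g])

    mrna_rows <- which(typ %in% c("mRNA", "transcript") & parents == ids[g])
    isoforms <- list()
    ref_id <- NULL
    for (m in mrna_rows) {
      tid <- if (!is.na(opt("Name", m))) opt("Name", m) else ids[m]
      ex_rows <- which(typ == "exon" & parents == ids[m])
      cds_rows <- which(typ == "CDS" & parents == ids[m])
      if (length(ex_rows) == 0) .stopf("transcript '%s' has no exons", tid)
      es <- GenomicRanges::start(gr)[ex_rows] - 1L
      ee <- GenomicRanges::end(gr)[ex_rows]
      ord <- order(es, decreasing = strand == "-")
      labs <- opt("Name", ex_rows)[ord]
      novel <- tolower(opt("novel", ex_rows)[ord]) %in% "true"
      chain <- exon_chain(es[ord], ee[ord], label = labs, is_novel = novel,
                          chromosome = chrom, strand = strand)
      if (any(chain$start < span[1]) || any(chain$end > span[2])) {
        .stopf("transcript '%s': exon outside the gene span", tid)
      }
      cs <- ce <- NULL
      if (length(cds_rows) > 0) {
        cs <- GenomicRanges::start(gr)[cds_rows] - 1L
        ce <- GenomicRanges::end(gr)[cds_rows]
      }
      isoforms[[tid]] <- transcript(tid, chain, cds_start = cs, cds_end = ce,
                                    mrna_accession = opt("mrna_accession", m))
      if (tolower(opt("reference", m)) %in% "true") ref_id <- tid
    }
    loci[[gid]] <- gene_locus(gid, chrom, strand, span, isoforms,
                              reference_isoform_id = ref_id,
                              sequence = as.character(seqs[[chrom]]))
  }
  loci
}

#' Write a gene locus as FASTA + GFF3
#'
#' Deterministic minimal GFF3 emitter (fixed attribute order) so that the
#' same locus always serialises byte-identically; internal 0-based
#' half-open coordinates are converted to GFF3's 1-based inclusive ones.
#'
#' @param locus a [gene_locus()] (must carry its contig sequence).
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_locus <- function(locus, fasta_path, gff3_path) {
  stopifnot(!is.null(locus$sequence))
  seq <- Biostrings::DNAStringSet(locus$sequence)
  names(seq) <- locus$chromosome
  Biostrings::writeXStringSet(seq, fasta_path, width = 70L)

  g1 <- function(start0) start0 + 1L  # 0-based half-open -> 1-based inclusive
  lines <- c("##gff-version 3")
  gid <- paste0("gene-", locus$gene_id)
  row <- function(type, s0, e0, attrs) {
    sprintf("%s\tisocat\t%s\t%d\t%d\t.\t%s\t.\t%s",
            locus$chromosome, type, g1(s0), e0, locus$strand, attrs)
  }
  lines <- c(lines, row("gene", locus$span[1], locus$span[2],
                        sprintf("ID=%s;Name=%s", gid, locus$gene_id)))
  for (tr in locus$isoforms) {
    tid <- paste0("rna-", locus$gene_id, "-", tr$transcript_id)
    attrs <- sprintf("ID=%s;Parent=%s;Name=%s", tid, gid, tr$transcript_id)
    if (!is.na(tr$mrna_accession)) {
      attrs <- paste0(attrs, ";mrna_accession=", tr$mrna_accession)
    }
    if (identical(tr$transcript_id, locus$reference_isoform_id)) {
      attrs <- paste0(attrs, ";reference=true")
    }
    ch <- tr$exons
    lines <- c(lines, row("mRNA", min(ch$start), max(ch$end), attrs))
    for (i in seq_len(nrow(ch))) {
      lines <- c(lines, row("exon", ch$start[i], ch$end[i],
        sprintf("ID=%s-exon%d;Parent=%s;Name=%s;novel=%s", tid, i, tid,
                ch$label[i], if (ch$is_novel[i]) "true" else "false")))
    }
    if (!is.null(tr$cds)) {
      for (i in seq_len(nrow(tr$cds))) {
        lines <- c(lines, row("CDS", tr$cds$start[i], tr$cds$end[i],
          sprintf("ID=%s-cds%d;Parent=%s", tid, i, tid)))
      }
    }
  }
  writeLines(lines, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

# catalogue TSV ---------------------------------------------------------------

.CATALOG_COLS <- c("gene", "chromosome", "isoform", "mrna_accession",
                   "exon_skipping", "novel_exons", "protein_accession",
                   "amino_acid", "sirtuin_domain_from_to", "domain_length",
                   "pct_domain_total", "nls_status", "mts_status",
                   "localization")

#' Write a catalogue table as TSV
#'
#' One header line; the domain interval is rendered `"from-to"` (ASCII
#' hyphen; readers also accept the typographic en dash) and the percentage
#' column always carries exactly one decimal.
#'
#' @param table a `catalog_table` (see [build_catalog()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_catalog_tsv <- function(table, path) {
  df <- as.data.frame(table)
  out <- data.frame(
    gene = df$gene, chromosome = df$chromosome, isoform = df$isoform,
    mrna_accession = df$mrna_accession,
    exon_skipping = df$exon_skipping,
    novel_exons = df$novel_exons,
    protein_accession = df$protein_accession,
    amino_acid = df$amino_acid,
    sirtuin_domain_from_to = ifelse(is.na(df$domain_from), "",
                                    paste0(df$domain_from, "-", df$domain_to)),
    domain_length = df$domain_length,
    pct_domain_total = ifelse(is.na(df$pct_domain_total), "",
                              sprintf("%.1f", df$pct_domain_total)),
    nls_status = df$nls_status, mts_status = df$mts_status,
    localization = df$localization,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (j in seq_along(out)) out[[j]][is.na(out[[j]])] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalogue table from TSV
#'
#' Inverse of [write_catalog_tsv()]; also reads the packaged curated
#' catalogue. The skipped-exon column is normalised (whitespace, primes,
#' case) and the domain interval split back into numeric boundaries.
#'
#' @param path TSV path.
#' @return a `catalog_table`.
#' @export
read_catalog_tsv <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  need <- c("gene", "chromosome", "isoform", "mrna_accession",
            "exon_skipping", "protein_accession", "amino_acid",
            "sirtuin_domain_from_to", "domain_length", "pct_domain_total")
  miss <- setdiff(need, names(raw))
  if (length(miss)) .stopf("catalogue TSV lacks column(s): %s", paste(miss, collapse = ", "))
  ft <- .normalize_exon_label(raw$sirtuin_domain_from_to)
  ft <- gsub("–", "-", ft)  # en dash
  from <- suppressWarnings(as.integer(sub("-.*$", "", ft)))
  to <- suppressWarnings(as.integer(sub("^.*-", "", ft)))
  blank_na <- function(x) ifelse(trimws(x) == "", NA_character_, trimws(x))
  df <- data.frame(
    gene = raw$gene, chromosome = raw$chromosome, isoform = raw$isoform,
    mrna_accession = raw$mrna_accession,
    exon_skipping = trimws(raw$exon_skipping),
    novel_exons = if ("novel_exons" %in% names(raw)) trimws(raw$novel_exons) else "",
    protein_accession = raw$protein_accession,
    amino_acid = as.integer(raw$amino_acid),
    domain_from = from, domain_to = to,
    domain_length = suppressWarnings(as.integer(raw$domain_length)),
    pct_domain_total = suppressWarnings(as.numeric(raw$pct_domain_total)),
    nls_status = if ("nls_status" %in% names(raw)) blank_na(raw$nls_status) else NA_character_,
    mts_status = if ("mts_status" %in% names(raw)) blank_na(raw$mts_status) else NA_character_,
    localization = if ("localization" %in% names(raw)) blank_na(raw$localization) else NA_character_,
    stringsAsFactors = FALSE
  )
  catalog_table(df)
}

# signal / domain annotation TSVs ---------------------------------------------

#' Read localization-signal annotations from TSV
#'
#' Carries user-supplied NLS/NES/MTS intervals (export signals in
#' particular are accepted as input rather than predicted). Columns:
#' `protein_id`, `kind`, `name` (optional), `start`, `end` (1-based
#' inclusive residues).
#'
#' @param path TSV path.
#' @param proteins optional named list of [protein_isoform()]s used to
#'   range-check intervals.
#' @return data frame of validated annotations with `source = "user-supplied"`.
#' @export
read_signal_annotations <- function(path, proteins = NULL) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "kind", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss)) .stopf("signal TSV lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- !raw$kind %in% c("NLS", "NES", "MTS")
  if (any(bad)) .stopf("unknown signal kind '%s'", raw$kind[bad][1])
  if (any(raw$start < 1 | raw$end < raw$start)) .stopf("invalid signal interval")
  if (!is.null(proteins)) {
    for (i in seq_len(nrow(raw))) {
      p <- proteins[[raw$protein_id[i]]]
      if (!is.null(p) && raw$end[i] > p$length_aa) {
        .stopf("signal interval %d-%d outside protein '%s' (%d aa)",
               raw$start[i], raw$end[i], raw$protein_id[i], p$length_aa)
      }
    }
  }
  data.frame(
    protein_id = raw$protein_id, kind = raw$kind,
    name = if ("name" %in% names(raw)) raw$name else raw$kind,
    from_aa = as.integer(raw$start), to_aa = as.integer(raw$end),
    source = "user-supplied", stringsAsFactors = FALSE
  )
}

#' Read protein domain annotations from TSV
#'
#' Columns: `protein_id`, `name`, `from`, `to` (catalogue boundary
#' convention, see [domain_length()]).
#'
#' @param path TSV path.
#' @return data frame with `protein_id`, `name`, `from_aa`, `to_aa`.
#' @export
read_domain_annotations <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "name", "from", "to")
  miss <- setdiff(need, names(raw))
  if (length(miss)) .stopf("domain TSV lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(raw$from >= raw$to)) .stopf("domain boundaries must satisfy from < to")
  data.frame(protein_id = raw$protein_id, name = raw$name,
             from_aa = as.integer(raw$from), to_aa = as.integer(raw$to),
             stringsAsFactors = FALSE)
}

#' Write a splice-event table as TSV
#' @param events_list list of `splice_events` objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(events_list, path) {
  rows <- lapply(events_list, function(ev) {
    if (nrow(ev) == 0) return(NULL)
    data.frame(isoform_id = attr(ev, "isoform_id"),
               reference_id = attr(ev, "reference_id"),
               kind = ev$kind, exon_label = ev$exon_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(isoform_id = character(),
                                      reference_id = character(),
                                      kind = character(), exon_label = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults for the tunable analysis constants, optionally overridden from
#' a YAML file and/or `...` arguments.
#'
#' @param path optional YAML file with any of the keys below.
#' @param ... named overrides (`nls_pattern`, `mts_window`,
#'   `mts_min_basic`, `mts_max_acidic`, `match_mode`, `min_overlap`).
#' @return named list of settings.
#' @export
isocat_config <- function(path = NULL, ...) {
  cfg <- list(nls_pattern = "P.KX.KRK", mts_window = 30L, mts_min_basic = 4L,
              mts_max_acidic = 1L, match_mode = "strict", min_overlap = 0)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}
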