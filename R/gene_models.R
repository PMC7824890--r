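# Coordinate-aware data types: exon chains, transcripts, gene loci, protein
# isoforms, and the genome <-> CDS <-> protein projection that underlies
# "signal X is located in exon-N" statements.
#
# Conventions (fixed package-wide):
#   * genomic intervals 0-based half-open; protein residues 1-based;
#   * exon chains are stored in transcription order (for "-" strand genes
#     that means decreasing genomic coordinate);
#   * CDS features include the stop codon; translation drops it.

#' Construct an exon chain
#'
#' An exon chain is the ordered set of exon intervals of one transcript, in
#' transcription order. Labels follow the field convention: canonical exons
#' are `"e1".."eN"` (numbered along the reference chain), novel exons carry
#' a primed label such as `"ex1'"`.
#'
#' @param start,end integer vectors of 0-based half-open genomic intervals,
#'   given in transcription order.
#' @param label optional character labels; `NA` entries are filled with
#'   positional labels.
#' @param is_novel logical; `TRUE` for exons absent from the reference chain.
#' @param chromosome,strand sequence name and strand (`"+"` or `"-"`).
#' @return a data frame of class `exon_chain` with columns
#'   `label`, `start`, `end`, `is_novel` and attributes `chromosome`,
#'   `strand`.
#' @export
exon_chain <- function(start, end, label = NA_character_, is_novel = FALSE,
                       chromosome = "chr", strand = c("+", "-")) {
  strand <- match.arg(strand)
  n <- length(start)
  stopifnot(length(end) == n)
  df <- data.frame(
    label = rep_len(as.character(label), n),
    start = as.integer(start),
    end = as.integer(end),
    is_novel = rep_len(as.logical(is_novel), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    .check_intervals(df, "exon")
    # transcription order: monotone along the strand, non-overlapping
    ord_ok <- if (strand == "+") all(diff(df$start) > 0) && all(utils::head(df$end, -1) <= df$start[-1])
              else all(diff(df$start) < 0) && all(utils::head(df$start, -1) >= df$end[-1])
    if (!ord_ok) .stopf("exons must be non-overlapping and in transcription order on strand '%s'", strand)
    missing_lab <- is.na(df$label)
    df$label[missing_lab] <- .canonical_label(which(missing_lab))
  }
  structure(df, chromosome = chromosome, strand = strand,
            class = c("exon_chain", "data.frame"))
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("exon chain: %d exon(s) on %s(%s)\n",
              nrow(x), attr(x, "chromosome"), attr(x, "strand")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Construct a transcript
#'
#' @param transcript_id,mrna_accession identifiers (accession may be `NA`).
#' @param exons an [exon_chain()].
#' @param cds_start,cds_end 0-based half-open CDS intervals in transcription
#'   order; must be covered by the exon intervals. The stop codon is part of
#'   the CDS. `NULL` for non-coding transcripts.
#' @param protein optional [protein_isoform()].
#' @return list of class `transcript`.
#' @export
transcript <- function(transcript_id, exons, cds_start = NULL, cds_end = NULL,
                       mrna_accession = NA_character_, protein = NULL) {
  stopifnot(inherits(exons, "exon_chain"))
  cds <- NULL
  if (!is.null(cds_start)) {
    cds <- data.frame(start = as.integer(cds_start), end = as.integer(cds_end))
    .check_intervals(cds, "CDS")
    # order CDS in transcription order to match the chain
    cds <- cds[order(cds$start, decreasing = attr(exons, "strand") == "-"), ,
               drop = FALSE]
    rownames(cds) <- NULL
    for (i in seq_len(nrow(cds))) {
      covered <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
      if (!covered) {
        .stopf("transcript '%s': CDS interval [%d, %d) not covered by any exon",
               transcript_id, cds$start[i], cds$end[i])
      }
    }
    if (sum(cds$end - cds$start) %% 3L != 0L) {
      .stopf("transcript '%s': CDS length %d not divisible by 3",
             transcript_id, sum(cds$end - cds$start))
    }
  }
  structure(
    list(transcript_id = transcript_id,
         mrna_accession = mrna_accession,
         exons = exons, cds = cds, protein = protein),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s: %d exons%s%s\n", x$transcript_id, nrow(x$exons),
              if (is.null(x$cds)) ", non-coding"
              else sprintf(", CDS %d nt", sum(x$cds$end - x$cds$start)),
              if (is.null(x$protein)) "" else sprintf(", protein %d aa", x$protein$length_aa)))
  invisible(x)
}

#' Construct a gene locus
#'
#' A gene locus bundles a genomic region, its strand, and the transcript
#' isoforms annotated on it, one of which is the constitutively spliced
#' reference (isoform-1 in RefSeq nomenclature).
#'
#' @param gene_id gene symbol or identifier.
#' @param chromosome sequence name.
#' @param strand `"+"` or `"-"`.
#' @param span 0-based half-open genomic interval containing every exon.
#' @param isoforms list of [transcript()]s (named or not; names are taken
#'   from `transcript_id`).
#' @param reference_isoform_id id of the reference isoform. If `NULL`, the
#'   isoform with the longest CDS is used and a warning is issued.
#' @param sequence optional contig sequence (character); coordinates in
#'   `span` index into it.
#' @return list of class `gene_locus`.
#' @export
gene_locus <- function(gene_id, chromosome, strand, span, isoforms,
                       reference_isoform_id = NULL, sequence = NULL) {
  ids <- vapply(isoforms, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) .stopf("gene '%s': duplicate isoform ids", gene_id)
  names(isoforms) <- ids
  for (tr in isoforms) {
    if (nrow(tr$exons) == 0) next
    if (min(tr$exons$start) < span[1] || max(tr$exons$end) > span[2]) {
      .stopf("gene '%s': exon of '%s' outside the locus span",
             gene_id, tr$transcript_id)
    }
    if (!identical(attr(tr$exons, "strand"), strand)) {
      .stopf("gene '%s': isoform '%s' on the wrong strand", gene_id,
             tr$transcript_id)
    }
  }
  if (is.null(reference_isoform_id)) {
    cds_len <- vapply(isoforms, function(t)
      if (is.null(t$cds)) 0L else sum(t$cds$end - t$cds$start), integer(1))
    reference_isoform_id <- ids[which.max(cds_len)]
    warning(sprintf("gene '%s': no reference isoform marked; using '%s' (longest CDS)",
                    gene_id, reference_isoform_id), call. = FALSE)
  }
  if (!reference_isoform_id %in% ids) {
    .stopf("gene '%s': reference isoform '%s' is not a member isoform",
           gene_id, reference_isoform_id)
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         span = as.integer(span), isoforms = isoforms,
         reference_isoform_id = reference_isoform_id, sequence = sequence),
    class = "gene_locus"
  )
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("gene locus %s [%s:%d-%d (%s)], %d isoform(s), reference: %s\n",
              x$gene_id, x$chromosome, x$span[1], x$span[2], x$strand,
              length(x$isoforms), x$reference_isoform_id))
  for (tr in x$isoforms) print(tr)
  invisible(x)
}

#' Reference transcript of a locus
#' @param locus a [gene_locus()].
#' @return the reference [transcript()].
#' @export
reference_transcript <- function(locus) {
  locus$isoforms[[locus$reference_isoform_id]]
}

#' Construct a protein isoform
#'
#' @param protein_accession accession or id.
#' @param sequence amino-acid sequence (may be `NA` when only the length is
#'   known, as in a transcribed catalogue).
#' @param length_aa protein length; defaults to `nchar(sequence)`.
#' @param domains data frame with columns `name`, `from_aa`, `to_aa` (the
#'   catalogue boundary convention; see [domain_length()]).
#' @param signals data frame of localization signals with columns `kind`
#'   (`NLS`/`NES`/`MTS`), `name`, `from_aa`, `to_aa`, `source`.
#' @return list of class `protein_isoform`.
#' @export
protein_isoform <- function(protein_accession, sequence = NA_character_,
                            length_aa = NULL, domains = NULL, signals = NULL) {
  if (is.null(length_aa)) {
    if (is.na(sequence)) .stopf("protein '%s': need sequence or length_aa", protein_accession)
    length_aa <- nchar(sequence)
  }
  length_aa <- as.integer(length_aa)
  if (!is.na(sequence) && nchar(sequence) != length_aa) {
    .stopf("protein '%s': length_aa (%d) != sequence length (%d)",
           protein_accession, length_aa, nchar(sequence))
  }
  if (length_aa < 1L) .stopf("protein '%s': empty protein", protein_accession)
  if (is.null(signals)) {
    signals <- data.frame(kind = character(), name = character(),
                          from_aa = integer(), to_aa = integer(),
                          exon_of_origin = character(), source = character(),
                          stringsAsFactors = FALSE)
  }
  if (!is.null(domains) && nrow(domains) > 0) {
    bad <- domains$from_aa < 1 | domains$to_aa > length_aa | domains$from_aa >= domains$to_aa
    if (any(bad)) .stopf("protein '%s': domain interval outside protein", protein_accession)
  }
  structure(
    list(protein_accession = protein_accession, sequence = sequence,
         length_aa = length_aa, domains = domains, signals = signals),
    class = "protein_isoform"
  )
}

# genome <-> CDS <-> protein projection --------------------------------------

.cds_length <- function(tr) if (is.null(tr$cds)) 0L else sum(tr$cds$end - tr$cds$start)

# protein length implied by a transcript (stop codon excluded)
.protein_length <- function(tr) {
  if (!is.null(tr$protein)) return(tr$protein$length_aa)
  .cds_length(tr) %/% 3L - 1L
}

#' Project a protein residue onto the CDS
#'
#' Returns the 0-based half-open CDS nucleotide interval of the codon that
#' encodes residue `residue_index` (1-based): `[3(i-1), 3i)`.
#'
#' @param tr a coding [transcript()].
#' @param residue_index 1-based residue index.
#' @return integer vector `c(start, end)` in CDS coordinates.
#' @export
project_protein_to_cds <- function(tr, residue_index) {
  if (is.null(tr$cds)) .stopf("transcript '%s' has no CDS", tr$transcript_id)
  i <- as.integer(residue_index)
  L <- .protein_length(tr)
  if (is.na(i) || i < 1L || i > L) {
    .stopf("residue index %s out of range [1, %d] for transcript '%s'",
           as.character(residue_index), L, tr$transcript_id)
  }
  c(start = 3L * (i - 1L), end = 3L * i)
}

# map 0-based CDS coordinates to genomic coordinates (transcription order)
.cds_to_genomic <- function(tr, cds_pos) {
  strand <- attr(tr$exons, "strand")
  lens <- tr$cds$end - tr$cds$start
  cum <- cumsum(lens)
  offs <- c(0L, utils::head(cum, -1))
  vapply(cds_pos, function(t) {
    k <- which(t >= offs & t < cum)
    if (length(k) != 1L) .stopf("CDS position %d not covered", t)
    within <- t - offs[k]
    if (strand == "+") tr$cds$start[k] + within
    else tr$cds$end[k] - 1L - within
  }, integer(1))
}

#' Exon(s) of origin of a protein residue
#'
#' Projects a residue through its codon onto the genome and returns the
#' label of every exon the codon touches; a codon that straddles an
#' exon-exon junction is attributed to both exons, so statements like
#' "the NLS is located in exon-1" remain well defined.
#'
#' @inheritParams project_protein_to_cds
#' @return character vector of exon labels (transcription order).
#' @export
exon_of_residue <- function(tr, residue_index) {
  nt <- project_protein_to_cds(tr, residue_index)
  gpos <- .cds_to_genomic(tr, nt["start"]:(nt["end"] - 1L))
  hit <- vapply(seq_len(nrow(tr$exons)), function(j)
    any(gpos >= tr$exons$start[j] & gpos < tr$exons$end[j]), logical(1))
  labs <- tr$exons$label[hit]
  if (length(labs) == 0) .stopf("residue %d not covered by the exon chain", residue_index)
  unique(labs)
}

#' Exons of origin of a residue interval
#'
#' @inheritParams project_protein_to_cds
#' @param from_aa,to_aa 1-based inclusive residue interval.
#' @return character vector of exon labels touched by any codon in the
#'   interval, in transcription order.
#' @export
exons_of_interval <- function(tr, from_aa, to_aa) {
  stopifnot(from_aa <= to_aa)
  labs <- unlist(lapply(seq(from_aa, to_aa), function(i) exon_of_residue(tr, i)))
  unique(labs)
}

#' Spliced CDS sequence of a transcript
#'
#' @param tr a coding [transcript()].
#' @param genome contig sequence as a character scalar or
#'   [Biostrings::DNAString]; locus coordinates index into it (0-based).
#' @return character scalar, the CDS in transcription orientation.
#' @export
cds_sequence <- function(tr, genome) {
  if (is.null(tr$cds)) .stopf("transcript '%s' has no CDS", tr$transcript_id)
  genome <- Biostrings::DNAString(as.character(genome))
  strand <- attr(tr$exons, "strand")
  asc <- tr$cds[order(tr$cds$start), , drop = FALSE]
  parts <- lapply(seq_len(nrow(asc)), function(i)
    Biostrings::subseq(genome, asc$start[i] + 1L, asc$end[i]))
  spliced <- do.call(Biostrings::xscat, parts)
  if (strand == "-") spliced <- Biostrings::reverseComplement(spliced)
  as.character(spliced)
}

#' Translate a transcript's CDS
#'
#' Standard genetic code. The CDS is expected to carry the stop codon (the
#' RefSeq GFF3 dialect); a terminal stop is dropped from the returned
#' protein. An internal stop is an error naming the offending codon.
#'
#' @inheritParams cds_sequence
#' @return amino-acid sequence as a character scalar.
#' @export
translate_cds <- function(tr, genome) {
  cds <- if (is.character(tr) || inherits(tr, "DNAString")) as.character(tr)
         else cds_sequence(tr, genome)
  n <- nchar(cds)
  if (n %% 3L != 0L) .stopf("CDS length %d not divisible by 3", n)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "error"))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  n_codon <- n %/% 3L
  internal <- stops[stops < n_codon]
  if (length(internal) > 0) {
    .stopf("internal stop codon at codon %d", internal[1])
  }
  sub("\\*$", "", aa)
}
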