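# Domain-retention statistics (catalogue boundary convention), localization
# signal motifs (PROSITE-flavoured single-position patterns), an N-terminal
# mitochondrial-targeting heuristic, and the localization inference rules.

#' Catalytic-domain length under the catalogue convention
#'
#' The sirtuin catalogue reports a domain `from`-`to` boundary pair together
#' with a length equal to `to - from` (a half-open reading of the printed
#' boundaries). This convention reproduces every printed length in the
#' curated 23-isoform catalogue -- e.g. boundaries 244-498 give 254 -- and is
#' therefore adopted verbatim; the inclusive `to - from + 1` alternative is
#' rejected by those data.
#'
#' @param from_aa,to_aa 1-based domain boundaries, `from_aa < to_aa`.
#' @return integer domain length.
#' @examples
#' domain_length(244, 498)  # 254
#' @export
domain_length <- function(from_aa, to_aa) {
  from_aa <- as.integer(from_aa); to_aa <- as.integer(to_aa)
  if (any(from_aa >= to_aa)) .stopf("domain boundaries must satisfy from < to")
  to_aa - from_aa
}

#' Domain fraction of the protein, as a percentage
#'
#' `100 * domain_len / protein_len`, rounded half-up to one decimal (the
#' rounding that reproduces all printed catalogue percentages, e.g.
#' 241/400 -> 60.3).
#'
#' @param domain_len domain length in residues.
#' @param protein_len protein length in residues.
#' @return numeric percentage with one decimal.
#' @examples
#' domain_fraction(254, 747)  # 34.0
#' @export
domain_fraction <- function(domain_len, protein_len) {
  if (any(domain_len <= 0) || any(domain_len > protein_len)) {
    .stopf("need 0 < domain length <= protein length")
  }
  round_half_up(100 * domain_len / protein_len, 1)
}

#' Domain retention of an isoform relative to the reference
#'
#' @param isoform,reference [protein_isoform()]s with `domains` tables.
#' @param domain name of the domain to compare (default: the reference's
#'   first domain).
#' @return list with `retained_pct` (percentage of the reference domain
#'   length retained, one decimal; `0` when lost) and
#'   `status` (`"intact"`, `"truncated"` or `"lost"`).
#' @export
domain_truncation <- function(isoform, reference, domain = NULL) {
  refd <- reference$domains
  if (is.null(refd) || nrow(refd) == 0) .stopf("reference has no domain annotation")
  if (is.null(domain)) domain <- refd$name[1]
  r <- refd[refd$name == domain, , drop = FALSE]
  if (nrow(r) == 0) .stopf("domain '%s' absent from the reference", domain)
  ref_len <- domain_length(r$from_aa[1], r$to_aa[1])
  isod <- isoform$domains
  i <- if (is.null(isod)) isod else isod[isod$name == domain, , drop = FALSE]
  if (is.null(i) || nrow(i) == 0) {
    return(list(retained_pct = 0, status = "lost"))
  }
  iso_len <- domain_length(i$from_aa[1], i$to_aa[1])
  pct <- round_half_up(100 * iso_len / ref_len, 1)
  list(retained_pct = pct, status = if (pct < 100) "truncated" else "intact")
}

# motif patterns --------------------------------------------------------------

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Compile a single-position motif pattern
#'
#' Patterns use one-letter residue codes plus wildcards: `"."`, the middle
#' dot `"·"` and `"X"`/`"x"` all denote "any residue". The nuclear
#' localization consensus shared by the nuclear sirtuins is written
#' `"P·KX·KRK"` in this notation: an 8-position pattern with
#' literal P/K/K/R/K and four wildcard positions. Both the dot characters
#' and `X` compile to full wildcards (the most permissive single-position
#' reading; no residue alphabet is attached to them).
#'
#' @param spec pattern string.
#' @param name optional pattern name.
#' @return object of class `motif_pattern`: a list of allowed-residue sets,
#'   one per position.
#' @examples
#' compile_pattern("P.KX.KRK")
#' @export
compile_pattern <- function(spec, name = spec) {
  chars <- strsplit(.normalize_pattern(spec), "")[[1]]
  if (length(chars) == 0) .stopf("empty pattern")
  classes <- lapply(chars, function(ch) {
    if (ch == ".") .AA20
    else if (ch %in% .AA20) ch
    else .stopf("illegal pattern character '%s'", ch)
  })
  structure(list(name = name, classes = classes), class = "motif_pattern")
}

.normalize_pattern <- function(spec) {
  spec <- gsub("·", ".", spec)
  gsub("[Xx]", ".", spec)
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif pattern '%s' (%d positions): %s\n", x$name,
              length(x$classes),
              paste(vapply(x$classes, function(cl)
                if (length(cl) == length(.AA20)) "*" else paste(cl, collapse = "/"),
                character(1)), collapse = " ")))
  invisible(x)
}

#' Scan a protein sequence for a motif pattern
#'
#' Reports every (possibly overlapping) match, left to right.
#'
#' @param sequence amino-acid sequence.
#' @param pattern a [compile_pattern()] result (or a pattern string, which
#'   is compiled on the fly).
#' @return data frame with 1-based inclusive `from_aa`, `to_aa` and the
#'   matched subsequence `match`; zero rows when there is no match.
#' @export
scan_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  k <- length(pattern$classes)
  empty <- data.frame(from_aa = integer(), to_aa = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) < k) return(empty)
  rx <- paste0(vapply(pattern$classes, function(cl)
    if (length(cl) == length(.AA20)) "." else paste0("[", paste(cl, collapse = ""), "]"),
    character(1)), collapse = "")
  # lookahead makes overlapping matches visible
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  from <- as.integer(m)
  data.frame(from_aa = from, to_aa = from + k - 1L,
             match = substring(sequence, from, from + k - 1L),
             stringsAsFactors = FALSE)
}

#' Derive a consensus pattern from aligned signal sequences
#'
#' Column-wise consensus over pre-aligned, equal-length sequences: a column
#' with a single residue across all inputs becomes a literal; any
#' disagreement becomes a wildcard. Every input sequence matches the
#' derived pattern by construction.
#'
#' @param aligned character vector of >= 2 equal-length amino-acid
#'   sequences (no gaps).
#' @param name pattern name.
#' @return a `motif_pattern`.
#' @examples
#' derive_consensus(c("PAKSAKRK", "PGKTAKRK"))
#' @export
derive_consensus <- function(aligned, name = "consensus") {
  if (length(aligned) < 2) .stopf("need at least two aligned sequences")
  L <- unique(nchar(aligned))
  if (length(L) != 1) .stopf("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(aligned, ""))
  classes <- lapply(seq_len(L), function(j) {
    col <- unique(mat[, j])
    if (length(col) == 1) col else .AA20
  })
  structure(list(name = name, classes = classes), class = "motif_pattern")
}

#' As a pattern string
#' @param pattern a `motif_pattern`.
#' @return character; wildcards rendered as `"."`.
#' @export
pattern_string <- function(pattern) {
  paste(vapply(pattern$classes, function(cl)
    if (length(cl) == length(.AA20)) "." else cl[1], character(1)),
    collapse = "")
}

# mitochondrial targeting -----------------------------------------------------

#' N-terminal mitochondrial targeting heuristic
#'
#' Mitochondrial presequences are N-terminal, enriched in basic residues
#' (R/K) and depleted of acidic ones (D/E). This scanner implements that
#' composition rule directly: a targeting sequence is called present when,
#' within the first `window` residues, the basic count reaches `min_basic`
#' while the acidic count stays at or below `max_acidic`. It is a simple,
#' documented heuristic -- deliberately not a reimplementation of the
#' machine-learning presequence predictors used in annotation pipelines --
#' and its three constants are tunable.
#'
#' @param sequence amino-acid sequence; shorter sequences are evaluated on
#'   their full length.
#' @param window N-terminal window in residues (default 30).
#' @param min_basic minimum count of R/K in the window (default 4).
#' @param max_acidic maximum count of D/E tolerated (default 1).
#' @return list with `present` (logical), `score` (basic minus acidic
#'   count), `n_basic`, `n_acidic`.
#' @export
scan_mts <- function(sequence, window = 30L, min_basic = 4L, max_acidic = 1L) {
  stopifnot(window >= 1)
  nterm <- substr(sequence, 1L, min(window, nchar(sequence)))
  chars <- strsplit(nterm, "")[[1]]
  n_basic <- sum(chars %in% c("R", "K"))
  n_acidic <- sum(chars %in% c("D", "E"))
  list(present = n_basic >= min_basic && n_acidic <= max_acidic,
       score = n_basic - n_acidic, n_basic = n_basic, n_acidic = n_acidic)
}

# localization inference -------------------------------------------------------

#' Infer subcellular localization from signal annotations
#'
#' Rule order: any NLS present -> nucleus; else any MTS present ->
#' mitochondria; else cytoplasm. The rules are deterministic and total:
#' every protein receives exactly one compartment. NES annotations do not
#' enter the decision (export signals modulate shuttling, not the primary
#' compartment call) but are echoed in the basis.
#'
#' @param protein a [protein_isoform()] whose `signals` table is populated
#'   (by motif scans and/or user-supplied annotations).
#' @param reference_call optional `localization_call` of the gene's
#'   reference isoform, used to set `changed_vs_reference`.
#' @return list of class `localization_call` with fields `isoform_id`,
#'   `compartment`, `basis`, `changed_vs_reference`.
#' @export
infer_localization <- function(protein, reference_call = NULL) {
  sig <- protein$signals
  has <- function(kind) !is.null(sig) && any(sig$kind == kind)
  if (has("NLS")) {
    compartment <- "nucleus"
    basis <- paste("NLS present:", paste(sig$name[sig$kind == "NLS"], collapse = ", "))
  } else if (has("MTS")) {
    compartment <- "mitochondria"
    basis <- "MTS present, no NLS"
  } else {
    compartment <- "cytoplasm"
    basis <- "no NLS and no MTS detected"
  }
  if (has("NES")) basis <- c(basis, paste("NES:", paste(sig$name[sig$kind == "NES"], collapse = ", ")))
  structure(
    list(isoform_id = protein$protein_accession, compartment = compartment,
         basis = basis,
         changed_vs_reference = if (is.null(reference_call)) NA
                                else compartment != reference_call$compartment),
    class = "localization_call"
  )
}

#' @export
print.localization_call <- function(x, ...) {
  cat(sprintf("%s -> %s%s (%s)\n", x$isoform_id, x$compartment,
              if (isTRUE(x$changed_vs_reference)) " [changed vs reference]" else "",
              paste(x$basis, collapse = "; ")))
  invisible(x)
}

#' Protein molecular weight
#'
#' Average molecular weight of an amino-acid sequence in kilodaltons.
#'
#' @param sequence amino-acid sequence (character).
#' @return numeric, kDa.
#' @export
protein_mw <- function(sequence) {
  seqinr::pmw(strsplit(toupper(sequence), "")[[1]]) / 1000
}
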