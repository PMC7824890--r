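# Shared helpers: rounding, interval arithmetic, exon-label handling.
# Genomic intervals are 0-based half-open throughout the package; GFF3
# conversion happens only in io_formats.R.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.25 -> 0.3` at one decimal),
#' the convention used for all percentage columns of the catalogue.
#' Base R's `round()` rounds ties to even and cannot reproduce them.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(60.25, 1)  # 60.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# half-open interval overlap width; a, b are c(start, end)
.ivl_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start))
}

# exon labels ----------------------------------------------------------------

# Novel-exon labels are "exN'" (ASCII apostrophe); the Unicode prime is
# accepted on input. Canonical labels are "e1".."eN".
.normalize_exon_label <- function(x) {
  x <- gsub("′", "'", x)
  x <- gsub("ΔE", "e", x)  # "ΔE1" -> "e1" when met in user tables
  trimws(x)
}

.canonical_label <- function(i) {
  if (length(i) == 0) character(0) else paste0("e", i)
}

.is_novel_label <- function(x) grepl("'", .normalize_exon_label(x), fixed = TRUE)

# "e4" -> 4L, "ex4'" -> 4L, "ex4'b" -> 4L
.label_number <- function(x) {
  x <- .normalize_exon_label(x)
  as.integer(sub("^ex?([0-9]+).*$", "\\1", x))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# validate a two-column start/end data.frame of half-open intervals
.check_intervals <- function(df, what = "interval") {
  if (any(df$end <= df$start)) {
    .stopf("empty or reversed %s: [%d, %d)", what,
           df$start[which(df$end <= df$start)[1]],
           df$end[which(df$end <= df$start)[1]])
  }
  invisible(df)
}
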