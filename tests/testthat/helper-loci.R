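# In-code fixtures and independent oracles shared across test files.

# a hand-built plus-strand 3-exon locus with fully known coordinates:
# exon1 [100, 189) carries CDS nt [0, 89), exon2 [250, 341) nt [89, 180),
# exon3 [400, 421) nt [180, 201); total CDS 201 nt = 66 codons + stop
tiny_plus_locus <- function() {
  aa <- paste(rep(c("M", "A", "K", "L", "P", "G"), length.out = 66), collapse = "")
  codon <- c(M = "ATG", A = "GCT", K = "AAA", L = "CTG", P = "CCT", G = "GGT")
  cds <- paste0(paste(codon[strsplit(aa, "")[[1]]], collapse = ""), "TAA")
  stopifnot(nchar(cds) == 201)
  seq <- strrep("T", 500)
  put <- function(s, at0, frag) {  # write frag at 0-based position
    paste0(substr(s, 1, at0), frag, substr(s, at0 + nchar(frag) + 1, nchar(s)))
  }
  seq <- put(seq, 100, substr(cds, 1, 89))
  seq <- put(seq, 250, substr(cds, 90, 180))
  seq <- put(seq, 400, substr(cds, 181, 201))
  ch <- exon_chain(c(100, 250, 400), c(189, 341, 421),
                   chromosome = "tiny", strand = "+")
  tr <- transcript("t1", ch, cds_start = c(100, 250, 400),
                   cds_end = c(189, 341, 421))
  gene_locus("TINY", "tiny", "+", c(0, 500), list(tr),
             reference_isoform_id = "t1", sequence = seq)
}

# independent oracle: enumerate every CDS genomic position one by one (in
# transcription order) and look the codon's positions up in the exon table
brute_exon_of_residue <- function(tr, i) {
  gpos <- integer()
  for (k in seq_len(nrow(tr$cds))) {
    iv <- tr$cds$start[k]:(tr$cds$end[k] - 1L)
    if (attr(tr$exons, "strand") == "-") iv <- rev(iv)
    gpos <- c(gpos, iv)
  }
  codon <- gpos[(3L * (i - 1L) + 1L):(3L * i)]
  labs <- character()
  for (g in codon) {
    for (j in seq_len(nrow(tr$exons))) {
      if (g >= tr$exons$start[j] && g < tr$exons$end[j]) labs <- c(labs, tr$exons$label[j])
    }
  }
  unique(labs)
}

# independent oracle: position-by-position sliding-window motif scan
brute_scan <- function(sequence, pattern) {
  k <- length(pattern$classes)
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer()
  if (length(chars) >= k) {
    for (s in 1:(length(chars) - k + 1L)) {
      ok <- TRUE
      for (p in seq_len(k)) {
        if (!chars[s + p - 1L] %in% pattern$classes[[p]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# a random locus program with recoverable (unambiguous) event bookkeeping:
# at most one novel exon per intron, anchors never skipped by an isoform
# that includes them
random_program <- function(seed) {
  set.seed(seed)
  n <- sample(5:12, 1)
  n_novel <- sample(0:2, 1)
  anchors <- if (n_novel > 0) sort(sample(seq_len(n - 1), n_novel)) else integer()
  novel <- lapply(anchors, function(a) list(after = a, aa = sample(5:20, 1)))
  n_iso <- sample(1:3, 1)
  isoforms <- lapply(seq_len(n_iso), function(k) {
    skippable <- setdiff(seq_len(n - 1), anchors)  # keep the stop-carrying exon
    ns <- sample(0:min(2, length(skippable)), 1)
    skip <- if (ns > 0) sort(sample(skippable, ns)) else integer()
    inc <- if (n_novel > 0) sort(sample(seq_len(n_novel),
                                        sample(0:n_novel, 1))) else integer()
    list(name = paste0("v", k + 1), skip = skip, include = inc)
  })
  locus_program(gene_id = paste0("G", seed), chromosome = paste0("chr", seed),
                n_exons = n, exon_aa_range = c(8L, 30L),
                intron_length_range = c(20L, 80L),
                strand = sample(c("+", "-"), 1),
                novel_exons = novel, isoforms = isoforms, seed = seed)
}

expect_same_locus <- function(a, b) {
  expect_equal(a$gene_id, b$gene_id)
  expect_equal(a$strand, b$strand)
  expect_equal(a$span, b$span)
  expect_equal(a$sequence, b$sequence)
  expect_equal(names(a$isoforms), names(b$isoforms))
  expect_equal(a$reference_isoform_id, b$reference_isoform_id)
  for (id in names(a$isoforms)) {
    ta <- a$isoforms[[id]]; tb <- b$isoforms[[id]]
    expect_equal(as.data.frame(ta$exons), as.data.frame(tb$exons))
    expect_equal(ta$cds, tb$cds)
  }
}
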