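# Domain statistics, motif patterns, targeting heuristic, localization rules.

test_that("domain length follows the catalogue's half-open boundary convention", {
  expect_equal(domain_length(244, 498), 254)
  expect_equal(domain_length(65, 340), 275)
  expect_equal(domain_length(1, 2), 1)
  expect_error(domain_length(10, 10), "from < to")
})

test_that("domain fractions round half-up to one decimal", {
  expect_equal(domain_fraction(254, 747), 34.0)
  expect_equal(domain_fraction(202, 452), 44.7)
  expect_equal(domain_fraction(50, 50), 100.0)
  # an exact .x5 tie must go up, not to even
  expect_equal(domain_fraction(241, 400), 60.3)
  expect_equal(round_half_up(78.125, 1), 78.1)
  expect_error(domain_fraction(300, 250), "protein length")
})

test_that("domain truncation is reported relative to the reference domain", {
  mk <- function(from, to, len) protein_isoform("p", length_aa = len,
    domains = data.frame(name = "CORE", from_aa = from, to_aa = to))
  v1 <- mk(244, 498, 747)
  v2 <- mk(1, 203, 452)
  v3 <- mk(1, 195, 444)
  expect_equal(domain_truncation(v2, v1), list(retained_pct = 79.5, status = "truncated"))
  expect_equal(domain_truncation(v3, v1), list(retained_pct = 76.4, status = "truncated"))
  expect_equal(domain_truncation(v1, v1), list(retained_pct = 100, status = "intact"))
  bare <- protein_isoform("q", length_aa = 100)
  expect_equal(domain_truncation(bare, v1)$status, "lost")
  expect_error(domain_truncation(v2, v1, domain = "KINASE"), "absent from the reference")
})

test_that("pattern compilation reads dots and X as single-residue wildcards", {
  p <- compile_pattern("P·KX·KRK")  # the consensus, with middle dots
  expect_length(p$classes, 8)
  wild <- vapply(p$classes, length, integer(1)) == 20
  expect_equal(which(wild), c(2L, 4L, 5L))
  expect_equal(unlist(p$classes[c(1, 3, 6, 7, 8)]), c("P", "K", "K", "R", "K"))
  q <- compile_pattern("KRK")
  expect_true(all(vapply(q$classes, length, integer(1)) == 1))
  expect_error(compile_pattern("P?K"), "illegal pattern character")
  expect_error(compile_pattern(""), "empty")
})

test_that("motif scanning finds all matches, including overlapping ones", {
  pat <- compile_pattern("P.KX.KRK")
  hits <- scan_motif("AAPGKSAKRKLA", pat)
  expect_equal(hits$from_aa, 3L)
  expect_equal(hits$to_aa, 10L)
  expect_equal(nrow(scan_motif("", pat)), 0)
  expect_equal(scan_motif("PAKSAKRK", pat)$from_aa, 1L)
  expect_equal(scan_motif("KKKK", compile_pattern("KK"))$from_aa, 1:3)
})

test_that("motif scanning agrees with the sliding-window oracle on random cases", {
  set.seed(97)
  for (rep in 1:250) {
    k <- sample(2:8, 1)
    spec <- paste(sample(c(AA20, "."), k, replace = TRUE,
                         prob = c(rep(1, 20), 8)), collapse = "")
    pat <- compile_pattern(spec)
    seq <- rand_aa(sample(k:60, 1))
    expect_equal(scan_motif(seq, pat)$from_aa, brute_scan(seq, pat),
                 info = paste(spec, seq))
  }
})

test_that("derived consensus patterns wildcard exactly the disagreeing columns", {
  p <- derive_consensus(c("PAKSAKRK", "PGKTAKRK"))
  wild <- vapply(p$classes, length, integer(1)) == 20
  expect_equal(which(wild), c(2L, 4L))
  expect_equal(pattern_string(p), "P.K.AKRK")
  ident <- derive_consensus(c("KRKR", "KRKR"))
  expect_equal(pattern_string(ident), "KRKR")
  expect_equal(pattern_string(derive_consensus(c("KK", "KR"))), "K.")
  expect_error(derive_consensus(c("KK", "KKK")), "equal length")
  expect_error(derive_consensus("KK"), "at least two")
})

test_that("every input sequence matches the consensus derived from it", {
  set.seed(41)
  for (rep in 1:60) {
    L <- sample(4:12, 1)
    n <- sample(2:6, 1)
    base <- rand_aa(L)
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(base, "")[[1]]
      j <- sample(L, sample(0:L, 1))
      s[j] <- sample(AA20, length(j), replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    pat <- derive_consensus(seqs)
    for (s in seqs) expect_true(1L %in% scan_motif(s, pat)$from_aa, info = s)
  }
})

test_that("the targeting heuristic counts basic and acidic residues in the window", {
  # 4 basic (3 R + 1 K), 0 acidic in the first 30 residues
  mts <- scan_mts(paste0("MLRSRLLRSAK", strrep("A", 30)))
  expect_true(mts$present)
  expect_equal(mts$n_basic, 4)
  expect_equal(mts$score, 4)
  expect_false(scan_mts(strrep("E", 40))$present)
  # sequences shorter than the window are evaluated on their full length
  expect_true(scan_mts("RKRK")$present)
  expect_false(scan_mts("RKR")$present)
  # one acidic residue tolerated, two are not
  expect_true(scan_mts(paste0("RKRKD", strrep("G", 40)))$present)
  expect_false(scan_mts(paste0("RKRKDE", strrep("G", 40)))$present)
})

test_that("localization rules: NLS beats MTS beats cytoplasmic default", {
  sig <- function(...) {
    kinds <- c(...)
    data.frame(kind = kinds, name = kinds,
               from_aa = seq_along(kinds), to_aa = seq_along(kinds) + 7L,
               exon_of_origin = NA_character_, source = "user-supplied")
  }
  p_nls <- protein_isoform("a", length_aa = 100, signals = sig("NLS"))
  p_both <- protein_isoform("b", length_aa = 100, signals = sig("NLS", "MTS"))
  p_mts <- protein_isoform("c", length_aa = 100, signals = sig("MTS"))
  p_none <- protein_isoform("d", length_aa = 100)
  ref <- infer_localization(p_nls)
  expect_equal(ref$compartment, "nucleus")
  expect_equal(infer_localization(p_both)$compartment, "nucleus")
  expect_equal(infer_localization(p_mts)$compartment, "mitochondria")
  call <- infer_localization(p_none, reference_call = ref)
  expect_equal(call$compartment, "cytoplasm")
  expect_true(call$changed_vs_reference)
  expect_false(infer_localization(p_nls, reference_call = ref)$changed_vs_reference)
})

test_that("every protein receives exactly one compartment", {
  set.seed(13)
  for (rep in 1:40) {
    kinds <- sample(c("NLS", "NES", "MTS"), sample(0:3, 1))
    sigs <- if (length(kinds)) data.frame(kind = kinds, name = kinds,
                                          from_aa = 1L, to_aa = 8L,
                                          exon_of_origin = NA, source = "x")
            else NULL
    p <- protein_isoform("p", length_aa = 50, signals = sigs)
    call <- infer_localization(p)
    expect_true(call$compartment %in% c("nucleus", "cytoplasm", "mitochondria"))
    expect_length(call$compartment, 1)
  }
})

test_that("a lost targeting sequence moves the call from mitochondria to cytoplasm", {
  # mitochondrial-style gene: presequence on exon 1, isoform v2 skips it
  prog <- locus_program(gene_id = "MITO1", exon_aa = c(30L, 30L, 25L, 40L),
                        signals = list(list(kind = "MTS", at = 1L)),
                        isoforms = list(list(name = "v2", skip = 1L)),
                        seed = 77)
  loc <- generate_locus(prog)
  tab <- build_catalog(loc)
  expect_equal(tab$localization, c("mitochondria", "cytoplasm"))
  expect_equal(tab$mts_status, c("present", "lost"))
  calls <- attr(tab, "localization_calls")
  expect_true(calls[["MITO1 v2"]]$changed_vs_reference)
})

test_that("protein molecular weight matches an average-mass hand computation", {
  # average residue masses (Da) + one water
  res <- c(A = 71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
           G = 57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
           M = 131.1926, N = 114.1038, P = 97.1167, Q = 128.1307, R = 156.1875,
           S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
  water <- 18.0153
  for (s in c("G", "MK", "PAKSAKRK", rand_aa(50))) {
    expected <- (sum(res[strsplit(s, "")[[1]]]) + water) / 1000
    expect_equal(protein_mw(s), expected, tolerance = 2e-4, info = s)
  }
})
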