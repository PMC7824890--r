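# Catalogue assembly and summaries.

test_that("the SIRT1-like locus catalogue carries events, signals and localization", {
  fx <- load_sirtuin_fixture()
  tab <- build_catalog(fx$sirt1_locus, signals = fx$signals)
  expect_s3_class(tab, "catalog_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$isoform, c("v1", "v2", "v3"))
  expect_equal(tab$exon_skipping, c("", "ex1, ex3", "ex1, ex2, ex3"))
  expect_equal(tab$novel_exons, c("", "ex1'", "ex4'"))
  expect_equal(tab$nls_status, c("present", "lost", "lost"))
  expect_equal(tab$localization, c("nucleus", "cytoplasm", "cytoplasm"))
  calls <- attr(tab, "localization_calls")
  expect_false(isTRUE(calls[["SIRT1 v1"]]$changed_vs_reference))
  expect_true(calls[["SIRT1 v2"]]$changed_vs_reference)
  expect_true(calls[["SIRT1 v3"]]$changed_vs_reference)
})

test_that("user-supplied export signals get an exon of origin but no compartment vote", {
  fx <- load_sirtuin_fixture()
  tr <- fx$sirt1_locus$isoforms$v1
  expect_equal(exons_of_interval(tr, 30, 38), "e1")
  expect_equal(exons_of_interval(tr, 310, 318), "e7")
  # and the two NLS instances sit in exon-1 and exon-3
  aa <- translate_cds(tr, fx$sirt1_locus$sequence)
  hits <- scan_motif(aa, compile_pattern("P.KX.KRK"))
  expect_equal(nrow(hits), 2)
  expect_equal(exons_of_interval(tr, hits$from_aa[1], hits$to_aa[1]), "e1")
  expect_equal(exons_of_interval(tr, hits$from_aa[2], hits$to_aa[2]), "e3")
})

test_that("both mouse-style isoforms retain their signals and stay nuclear", {
  fx <- load_sirtuin_fixture()
  tab <- build_catalog(fx$mouse_sirt1_locus)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$exon_skipping, c("", "ex2"))
  expect_equal(tab$nls_status, c("present", "present"))
  expect_equal(tab$localization, c("nucleus", "nucleus"))
  expect_false(attr(tab, "localization_calls")[["mSirt1 v2"]]$changed_vs_reference)
})

test_that("a single-isoform locus yields one entry with no events", {
  loc <- generate_locus(locus_program(gene_id = "SOLO", n_exons = 5,
                                      exon_aa = rep(12L, 5), seed = 71))
  tab <- build_catalog(loc)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$exon_skipping, "")
  expect_equal(nrow(attr(tab, "events")[["SOLO v1"]]), 0)
})

test_that("multi-locus catalogues have one entry per programmed isoform", {
  loci <- lapply(c(201, 202, 203), function(s) generate_locus(random_program(s)))
  tab <- build_catalog(loci)
  expect_equal(nrow(tab), sum(vapply(loci, function(l) length(l$isoforms), 1L)))
})

test_that("programmed domains drive the length and fraction columns", {
  prog <- locus_program(gene_id = "DOMG", exon_aa = c(25L, 30L, 35L, 20L),
                        domain = c(20, 90), seed = 88)
  loc <- generate_locus(prog)
  tab <- build_catalog(loc, domains = attr(loc, "programmed_domain"))
  expect_equal(tab$domain_length, 70)
  expect_equal(tab$pct_domain_total, round_half_up(100 * 70 / 110, 1))
})

test_that("catalogue output is deterministic and byte-identical across runs", {
  fx <- load_sirtuin_fixture()
  t1 <- build_catalog(fx$sirt1_locus, signals = fx$signals)
  t2 <- build_catalog(fx$sirt1_locus, signals = fx$signals)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_catalog_tsv(t1, p1); write_catalog_tsv(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("catalogue validation rejects inconsistent domain statistics", {
  fx <- load_sirtuin_fixture()
  df <- as.data.frame(fx$catalogue)
  df$domain_length[1] <- df$domain_length[1] + 1L
  expect_error(catalog_table(df), "inconsistent with boundaries")
  df2 <- as.data.frame(fx$catalogue)
  df2$pct_domain_total[1] <- df2$pct_domain_total[1] + 0.1
  expect_error(catalog_table(df2), "percentage")
  df3 <- as.data.frame(fx$catalogue)
  df3$isoform[2] <- "V1"
  expect_error(catalog_table(df3), "duplicate")
})

test_that("summaries report counts and extrema with their isoforms", {
  fx <- load_sirtuin_fixture()
  s <- summary(fx$catalogue)
  expect_equal(s$n_isoforms, 23)
  expect_equal(s$n_genes, 7)
  expect_equal(s$genes_multi_isoform, 5)
  expect_equal(unname(s$per_gene_counts["SIRT6"]), 9)
  expect_equal(s$protein_len_min, 176)
  expect_equal(s$protein_len_min_ids, "SIRT6-v9")
  expect_equal(s$protein_len_max, 747)
  expect_equal(s$protein_len_max_ids, "SIRT1-v1")
  expect_equal(s$domain_len_min, 138)
  expect_equal(s$domain_len_min_ids, "SIRT6-v7")
  expect_equal(s$domain_len_max, 275)
  expect_true("SIRT2-v1" %in% s$domain_len_max_ids)
  expect_error(summary(fx$catalogue[0, , drop = FALSE]), "empty")
  expect_equal(summarize_catalog(fx$catalogue)$n_isoforms, 23)
})

test_that("isoform diagrams render one track per isoform", {
  fx <- load_sirtuin_fixture()
  path <- tempfile(fileext = ".pdf")
  render_isoform_diagram(fx$sirt1_locus, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  broken <- fx$sirt1_locus
  broken$isoforms <- list()
  expect_error(render_isoform_diagram(broken, tempfile(fileext = ".pdf")),
               "empty locus")
  expect_error(render_isoform_diagram(fx$sirt1_locus, tempfile(fileext = ".svg")),
               "unsupported figure format")
})
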