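# Exon pairing and event classification against the reference chain.

ref9 <- function() {
  fx <- load_sirtuin_fixture()
  fx$sirt1_locus
}

test_that("identical chains pair completely and yield an empty event set", {
  loc <- generate_locus(locus_program(n_exons = 6, exon_aa = rep(12L, 6), seed = 3))
  ch <- reference_transcript(loc)$exons
  pairs <- match_exons(ch, ch)
  expect_equal(nrow(pairs), 6)
  ev <- classify_events(ch, ch)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "shared_exon_count"), 6)
})

test_that("the SIRT1-like fixture reproduces the published event structure", {
  loc <- ref9()
  ref <- reference_transcript(loc)$exons
  expect_equal(nrow(ref), 9)

  v2 <- loc$isoforms$v2$exons
  expect_equal(nrow(v2), 8)
  pairs <- match_exons(v2, ref)
  expect_equal(nrow(pairs), 7)  # ex1' unpaired
  ev2 <- classify_events(v2, ref, isoform_id = "v2")
  expect_setequal(ev2$exon_label[ev2$kind == "SKIP"], c("e1", "e3"))
  expect_equal(ev2$exon_label[ev2$kind == "NOVEL_INCLUSION"], "ex1'")
  expect_equal(ev2$exon_label[ev2$kind == "ALT_FIRST_EXON"], "ex1'")

  v3 <- loc$isoforms$v3$exons
  expect_equal(nrow(v3), 7)
  ev3 <- classify_events(v3, ref, isoform_id = "v3")
  expect_setequal(ev3$exon_label[ev3$kind == "SKIP"], c("e1", "e2", "e3"))
  expect_equal(ev3$exon_label[ev3$kind == "NOVEL_INCLUSION"], "ex4'")
  expect_equal(sum(ev3$kind == "ALT_FIRST_EXON"), 0)

  # exon-count algebra |iso| = |ref| - skips + novels
  for (ev in list(ev2, ev3)) {
    iso <- if (identical(attr(ev, "isoform_id"), "v2")) v2 else v3
    expect_equal(nrow(iso),
                 nrow(ref) - sum(ev$kind == "SKIP") + sum(ev$kind == "NOVEL_INCLUSION"))
  }
})

test_that("novel exons are named after their nearest upstream canonical exon", {
  ref <- exon_chain(c(100, 300, 500), c(160, 360, 560),
                    chromosome = "c", strand = "+")
  expect_equal(name_novel_exon(400, 450, ref), "ex2'")  # between e2 and e3
  expect_equal(name_novel_exon(10, 50, ref), "ex1'")    # novel first exon
  # upstream exon skipped: falls back to the nearest upstream exon's slot
  expect_equal(name_novel_exon(200, 240, ref, paired_ref_idx = c(2L, 3L)), "ex1'")
  # minus strand: upstream means higher genomic coordinate
  refm <- exon_chain(c(500, 300, 100), c(560, 360, 160),
                     chromosome = "c", strand = "-")
  expect_equal(name_novel_exon(400, 450, refm), "ex1'")
})

test_that("two novel exons between the same canonical pair get a/b suffixes", {
  ref <- exon_chain(c(100, 500), c(160, 560), chromosome = "c", strand = "+")
  iso <- exon_chain(c(100, 200, 300, 500), c(160, 230, 330, 560),
                    chromosome = "c", strand = "+")
  ev <- classify_events(iso, ref)
  expect_equal(ev$exon_label[ev$kind == "NOVEL_INCLUSION"], c("ex1'a", "ex1'b"))
})

test_that("strict mode reports shifted boundaries as unpaired with a warning", {
  ref <- exon_chain(c(100, 300), c(160, 360), chromosome = "c", strand = "+")
  iso <- exon_chain(c(100, 290), c(160, 360), chromosome = "c", strand = "+")
  pairs <- match_exons(iso, ref)
  expect_equal(nrow(pairs), 1)
  expect_match(attr(pairs, "partial_overlap_warnings"),
               "alternative splice site")
  relaxed <- match_exons(iso, ref, mode = "overlap")
  expect_equal(nrow(relaxed), 2)
})

test_that("chains from different loci are rejected", {
  a <- exon_chain(100, 160, chromosome = "c1", strand = "+")
  b <- exon_chain(100, 160, chromosome = "c2", strand = "+")
  expect_error(match_exons(a, b), "different loci")
})

test_that("classification is anti-symmetric in skips and novel inclusions", {
  for (seed in 31:36) {
    loc <- generate_locus(random_program(seed))
    ref <- reference_transcript(loc)$exons
    for (tr in loc$isoforms) {
      fwd <- classify_events(tr$exons, ref)
      rev <- classify_events(ref, tr$exons)
      key <- function(ev, kind) {
        k <- ev[ev$kind == kind, , drop = FALSE]
        sort(paste(k$start, k$end))
      }
      expect_equal(key(fwd, "SKIP"), key(rev, "NOVEL_INCLUSION"))
      expect_equal(key(fwd, "NOVEL_INCLUSION"), key(rev, "SKIP"))
    }
  }
})

test_that("exon union counts distinct exons across isoforms", {
  loc <- ref9()
  u <- exon_union(loc)
  expect_equal(nrow(u), 11)
  expect_setequal(u$label[u$is_novel], c("ex1'", "ex4'"))
  # single-isoform locus: its own exon count
  solo <- generate_locus(locus_program(n_exons = 7, exon_aa = rep(10L, 7), seed = 5))
  expect_equal(nrow(exon_union(solo)), 7)
  # 3 isoforms, 2 programmed novel exons on a 6-exon reference -> 8
  prog <- locus_program(n_exons = 6, exon_aa = rep(10L, 6), seed = 6,
                        novel_exons = list(list(after = 2L, aa = 8L),
                                           list(after = 4L, aa = 9L)),
                        isoforms = list(list(name = "v2", skip = 3L, include = 1L),
                                        list(name = "v3", skip = 5L, include = 2L)))
  expect_equal(nrow(exon_union(generate_locus(prog))), 8)
})
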