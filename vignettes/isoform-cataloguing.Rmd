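---
title: "Cataloguing alternative-splicing isoforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloguing alternative-splicing isoforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocat)
```

## The problem

A multi-exon gene rarely produces a single transcript. Alternative
splicing includes or excludes exons and yields isoforms whose proteins
can lack part of a catalytic domain, a nuclear localization signal (NLS)
or a mitochondrial targeting sequence (MTS) — and with them, change
compartment and function. The sirtuin deacetylase family (SIRT1–SIRT7)
is the motivating example shipped with this package: 23 annotated human
isoforms across seven genes, most of them exon-skipping variants of the
constitutively spliced isoform-1, several with a truncated catalytic
core or a lost localization signal.

`isocat` turns that style of analysis into a reusable, testable
pipeline: given a locus (genomic FASTA + GFF3 with `gene → mRNA →
exon/CDS`), it classifies each isoform's splicing events against the
reference chain, projects protein residues back to their exons of
origin, computes domain-retention statistics, scans for signal motifs,
infers localization, and emits one catalogue row per isoform.

## Coordinate model

All genomic intervals are 0-based half-open internally; conversion to
and from GFF3's 1-based inclusive convention happens only in the I/O
layer, so interval arithmetic never carries ±1 corrections. Protein
residues are 1-based, matching how domain boundaries are printed in
catalogues. Exon chains are stored in transcription order — for a
minus-strand gene that is decreasing genomic coordinate — so all chain
logic is strand-agnostic.

The CDS is taken to include the stop codon (the RefSeq GFF3 dialect);
`translate_cds()` drops a terminal stop and treats an internal stop as
an error naming the codon. Residue *i* occupies CDS nucleotides
`[3(i−1), 3i)`; `exon_of_residue()` maps those through the exon chain
and attributes a junction-spanning codon to *every* exon it touches, so
statements like "the NLS is located in exon-1" stay well defined at
boundaries.

## Event classification

`match_exons()` pairs isoform exons with reference exons
order-preservingly, each exon at most once. The default is strict
boundary identity: annotated isoforms of one gene reuse exact splice
sites, and the sirtuin catalogue contains only whole-exon events. A
reciprocal-overlap mode (`mode = "overlap"`) exists for noisy
annotations. Partial overlaps found under strict mode are surfaced as
warnings (possible alternative 3′/5′ splice sites) but deliberately not
classified as events.

`classify_events()` then reads the pairing: unpaired reference exons are
skips (ΔEn), unpaired isoform exons are novel inclusions (exN′), and an
alternative-first-exon flag is added when the isoform's 5′-most exon is
novel. Novel exons are named after the nearest upstream *paired*
canonical exon; when every upstream exon is skipped the nearest upstream
exon's slot is used, which is what yields "ex1′" for a novel first exon
replacing a skipped exon-1. Two novel exons between the same canonical
pair get `a`, `b` suffixes in genomic order — the shipped data never
needs this, but labels must stay unique. The reference is the isoform
marked as such in the annotation (isoform-1 in RefSeq nomenclature);
without a mark the longest CDS is taken and a warning logged.

Labels use an ASCII apostrophe (`ex1'`) in files and code; readers also
accept the typographic prime, mirroring the hyphen/en-dash policy for
domain intervals.

## Domain statistics

Catalogue domain boundaries follow a half-open printed convention:
`domain_length(from, to) = to − from`. This is adopted because it
reproduces all 23 printed lengths of the shipped sirtuin catalogue
(e.g. 244–498 → 254); the inclusive `to − from + 1` alternative fails on
every row. Percentages are `100·length/protein_length` rounded **half
up** to one decimal — the only rounding rule consistent with ties in the
printed data (241/400 = 60.25 prints as 60.3, which banker's rounding
would turn into 60.2). `domain_truncation()` reports the isoform's
domain length as a percentage of the reference's, with an
intact/truncated/lost status.

## Signal motifs and localization

The nuclear sirtuins share an NLS consensus written `P·KX·KRK`. The
pattern compiler reads both the middle dot and `X` as single-residue
wildcards — the most permissive single-position reading, since no
residue alphabet accompanies the consensus — giving an 8-position
pattern with five literals. The pattern is a configuration value
(`isocat_config(nls_pattern = ...)`), not a constant.
`derive_consensus()` goes the other way: column-wise over pre-aligned
equal-length signals, literal where unanimous, wildcard otherwise, so
every input matches its own consensus by construction. No-gap alignment
is assumed.

MTS detection is a deliberately simple composition heuristic, not a
reimplementation of the machine-learning presequence predictors used in
annotation practice: within the first 30 residues, call present when
R/K ≥ 4 and D/E ≤ 1 (all three constants tunable; sequences shorter
than the window are evaluated whole). Nuclear export signals are *not*
predicted at all — they are accepted as user annotations and only their
exon of origin is computed.

Localization inference is a fixed rule order: NLS present → nucleus;
else MTS present → mitochondria; else cytoplasm. It is deterministic and
total. A consequence worth knowing: an N-terminal NLS is itself
basic-rich and can satisfy the MTS composition rule, so a nuclear
protein may carry `mts_status = "present"`; the rule order keeps the
compartment call correct, and the packaged mouse locus exhibits exactly
this behaviour. Presence/loss columns in the catalogue are relative to
the gene's reference isoform — when the reference lacks a signal the
column reads `n/a`, because "lost" is only meaningful against a
reference that has it.

## The synthetic-data generator

`generate_locus()` materialises a `locus_program()`: canonical exon
sizes in codons (so any skipped/included subset stays in frame), novel
exons parked inside introns, programmed per-isoform event lists, and
signal motifs spliced into the reference protein before back-translation
with one fixed codon per residue. Background sequence is uniform-random
over nucleotides and amino acids; determinism comes from the program
seed (same program, byte-identical FASTA/GFF3). A stop codon is appended
to the last canonical exon.

What the generator emulates: multi-exon loci (5–12 exons in the test
programs), whole-exon skip and novel-inclusion events, in-frame CDSs,
embedded NLS instances and MTS-like N-termini, both strands. What it
does not emulate: splice-site sequence context, codon usage,
intron-retention or partial-exon events, expression levels, sequencing
noise. Green round-trip tests therefore demonstrate that the
*coordinate and classification logic* is correct on cleanly annotated
loci, not that the pipeline is robust to messy real-world annotation —
that is what the relaxed matching mode and the partial-overlap warnings
are for.

The packaged fixture has two synthetic loci built with this generator at
fixed seeds: a human SIRT1-like locus (9-exon reference; v2 = ΔE1, ΔE3 +
ex1′ as first exon; v3 = ΔE1–ΔE3 + ex4′; 11 distinct exons in the
region; NLS instances in exon-1 and exon-3, NES annotations in exon-1
and exon-7) and a 2-isoform mouse-style locus (v2 = ΔE2, both isoforms
keeping their NLS and staying nuclear). Exon *coordinates* are
synthetic; only counts, chain memberships, event labels and
signal-to-exon assignments mirror the curated structure. The 23-row
catalogue itself is transcribed curated data; its one transcription
oddity (an `ex2, 3x3` skip cell, presumably `ex2, ex3`) is kept verbatim
in the file and normalised on load with a provenance note.

## Numerical and degenerate-input choices

* Rounding is half-up everywhere a percentage is printed (see above);
  no floating-point epsilon is added, as all catalogue values are exact
  at double precision.
* Empty event sets, empty catalogues (header-only TSV), proteins without
  sequence (length-only catalogue rows) and non-coding transcripts are
  all representable; `summary()` reports "no domain annotations" rather
  than inventing a range.
* Ties for extrema in summaries report *all* attaining isoforms (the
  shipped catalogue has two 275-residue domains).
* Exon-chain validation rejects overlapping or mis-ordered exons, CDS
  outside exons, and CDS lengths not divisible by 3, before any analysis
  runs.

## Problem sizes used in the test suite

Property suites run at fixed seeds: 200 random locus programs for event
round-trip recovery, 1,000 random (sequence, pattern) pairs against a
brute-force sliding-window oracle, 200 random alignments for the
consensus property, and full-protein projection round trips on loci from
both strands. These sizes give each property broad coverage while
keeping the suite fast on a single CPU.

## Known limitations

* Intron retention, mutually exclusive exons and partial-exon
  (alternative splice-site) events are reported as warnings, not
  classified.
* The MTS heuristic is a stand-in with stated constants; it trades
  sensitivity/specificity for transparency and offline reproducibility.
* NES biology is input-only; no export-signal prediction.
* Isoform naming (v1, v2, …) is annotation-driven; the package does not
  attempt to reproduce database naming from sequence alone.
* Cross-species orthology (the human/mouse comparison that motivates the
  second fixture locus) is out of scope: the mouse locus is analysed
  with the same machinery, not aligned to the human one.
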