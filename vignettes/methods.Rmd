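---
title: "Refining bacterial gene models from peptide evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining bacterial gene models from peptide evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ab initio bacterial gene prediction mis-places translational start sites
(TSSs), misses short genes, and cannot see frameshifts introduced by
sequencing errors. Peptides identified by tandem mass spectrometry are
direct evidence of translation: a peptide fixed on the genome pins down
the reading frame, and an N-terminal peptide pins down the initiation
codon. `proteorefine` turns a genome, a reference proteome and peptide
identification tables into validated, extended, shortened or newly called
gene models, plus candidate interrupted coding sequences (ICDSs).

## The six-frame database and its compaction rule

Each of the six reading frames of every contig is partitioned at stop
codons. Within a stop-free segment, the entry is translated from the
*most upstream* in-frame start codon (ATG, GTG or TTG — organisms such as
mycobacteria initiate at all three), the initiator is rendered as Met
regardless of the codon, the stop is excluded, and products shorter than
`min_len = 20` residues are dropped. `min_len` counts the initiator, so a
20-residue product passes. Terminal segments that run off a frame end are
translated up to the last whole codon and flagged `has_stop = FALSE`;
partial codons are never emitted. Identical products — typically
transposon-duplicated paralogs — merge into one entry carrying every
coordinate tuple, so a paralogous locus counts once everywhere downstream.

Entries are cross-mapped to the reference proteome by exact C-terminal
alignment: entry E maps to reference R when R equals E's suffix starting
d ≥ 0 residues in, with R's initiator Met matching whatever E holds at
that position (GTG/TTG initiation). Internal containment is deliberately
not a match — only N-terminal offsets are biologically meaningful here,
and d > 0 is exactly the signature of a possible TSS over-prediction by
the most-upstream-start convention. Entries matching several distinct
references (paralogs that the proteome lists twice) are flagged ambiguous
and excluded from TSS accounting.

Coordinates are 1-based inclusive forward-strand throughout, reverse
features keep `start < end` and translate end→start; this is the GFF3
convention and every emitted interval re-translates to its product (a
property the test suite checks literally).

## Peptide mapping

Peptide tables use a MaxQuant `peptides.txt`-like dialect (`Sequence`,
`PEP`, optional `Reverse`, `Modifications`, and `Experiment <id>`
evidence columns that define replicate membership). The replicate filter
(default ≥ 2) pools replicate membership per peptide *sequence* across
database searches — the unit being filtered is the peptide, not the table
row. Decoys pass through flagged, so decoy statistics can be computed on
either side of the filter.

The dynamic genome scan places a peptide wherever it equals the literal
frame translation, and additionally places Met-initial peptides where a
GTG/TTG start codon underlies the first residue. Each placement records
the literal translation of the preceding in-frame codon (`*` after a
stop, `^` at a frame edge) — the non-tryptic test for TSS evidence — and
its codon offset relative to the host entry's start codon. Ile and Leu
are treated as distinct (the search engine has already resolved
sequences). Placement classes: `unique` (one locus), `paralog_unique`
(several loci, all at the same residue offset of one merged entry, found
the same way), otherwise `ambiguous` and excluded from refinement.
Peptides absent from the reference proteome (substring test, tolerant of
the initiator-Met-removed reference form) are genome-search-specific
peptides (GSSPs).

## Gene model decisions

TSS evidence has two forms: an initiator-Met peptide whose first residue
sits on a start codon with a non-tryptic preceding residue (or N-terminal
acetylation, accepted as independent N-terminus evidence even after K/R,
since in-vivo Nt-acetylation destroys the tryptic context argument), and
an N-Met-cleaved peptide whose first residue sits immediately after a
start codon. The penultimate-residue set is *not* enforced at
classification time — rare Asn/Leu/Arg cleavages occur — the canonical
Met-AP set {A,C,G,P,S,T,V} is used only by the generator and as QC
annotation. A Met-at-start preceded by another start codon cannot be
distinguished from downstream initiation and is flagged indeterminate; a
cleaved Val-on-GTG at an annotated start is reported as N-Met cleavage
with an `adjacent_upstream_start` annotation rather than silently
rewriting the model.

Per reference-linked ORF, decisions are mutually exclusive and applied in
priority order:

1. **validated** — a TSS peptide places initiation exactly at the
   reference start.
2. **upstream_extension** — GSSPs (only GSSPs) map upstream of the
   reference start within the same stop-free segment. An upstream TSS
   peptide fixes the new start exactly; otherwise the *nearest* start
   codon at or upstream of the most upstream evidence residue is taken
   (minimal-extension rule — small median extensions argue against
   jumping to the segment-most-upstream start). With no reachable start
   codon the case is reported unresolvable rather than guessed.
3. **downstream_start** — a TSS peptide strictly downstream of the
   reference start, with no identified peptide mapping upstream of it
   inside the model. The no-conflict guard is essential: without it every
   internal TSS peptide of a multi-initiation gene would shorten its
   model. Predictions sharing the new TSS are recorded as corroboration.

Two or more distinct supported initiation coordinates additionally yield
a **multiple_initiation** report. Start-codon distributions are
summarized over non-paralogous decided ORFs.

## Novel ORFs and ICDSs

Unannotated peptide-supported ORFs are tiered: ≥ 2 GSSPs
(`multi_peptide`); 1 GSSP plus protein homology, transcript BLAST or
same-strand ≥ 1-nt transcript overlap (`single_supported`); 1 GSSP and
nothing else (`excluded`, retained with its reason — single unsupported
peptides are too likely erroneous). Ranking is lexicographic in GSSP
count, protein homology, transcript BLAST, transcript overlap, with
genomic coordinate as the deterministic tie-break. Homology tables
(12-column tabular alignments) are filtered at E ≤ 1e-4, best hit per
query.

ICDS candidates are same-strand, different-frame, non-paralogous,
peptide-supported ORF pairs without a reference link whose spans overlap
or lie within `max_gap_nt = 100` (the field gives no adjacency distance;
100 nt accommodates single-error frameshifts while excluding ordinary
neighbours). The junction window runs between the facing peptide-evidence
boundaries of the two ORFs — ORF bounds can mislead, because the
shifted-frame half's stop-free segment often begins upstream of the gene.
A shared homology subject with compatible ordered aligned spans upgrades
and up-ranks a call; without it, two genuinely separate adjacent genes
cannot be excluded, so such pairs rank lower. Reference proteins that map
to no single entry are split by seeding their first and last 7-mers on
the genome and extending: a prefix in frame A and a suffix in frame B ≠ A
within 1 kb, leaving at most two uncovered residues, define a junction
interval (an exact 1-nt deletion leaves one residue unexplained, so the
interval is typically two residues wide); identified peptides covering
the interval are flagged as frameshift-spanning evidence.

## PEP score statistics

Annotated, novel and reverse peptides are compared per database search at
each peptide's best (minimum) PEP. The Kruskal–Wallis statistic uses
midranks with tie correction C = 1 − Σ(t³−t)/(N³−N) and a χ² upper tail
with k−1 df; all-tied input is defined as H = 0, p = 1. Dunn's two-sided
z statistics use the tie-corrected variance N(N+1)/12 − Σ(t³−t)/(12(N−1))
and Bonferroni adjustment min(1, m·p), m = k(k−1)/2. PEPs are ranked on
the raw scale (ranks are invariant to monotone transforms). The pipeline
runs the analysis both before and after the replicate filter, since the
filter visibly reshapes the novel group. Both statistics are checked to
1e-10 against independently written rank implementations and against
`stats::kruskal.test`.

## The synthetic-data generator

The generator is first-class, tested code defining the study conditions:

- start-codon weights ATG/GTG/TTG = 0.6396/0.3490/0.0114 (observed
  mycobacterial usage), protein lengths uniform on 80–140 aa, random
  intergenic spacers, single linear contig (circularity out of scope);
- digestion: cleavage after K/R with up to 3 missed cleavages and a
  7-residue minimum, no maximum length (the combined LysC+trypsin digest
  makes K.P cleavable, so Arg-Pro suppression is off by default with a
  config switch); protein N-terminal peptides are emitted with and
  without initiator Met, the Met-removed form only when the penultimate
  residue is in the Met-AP set; a configurable fraction of N-terminal
  peptides is acetylated; each candidate is detected independently per
  replicate with probability 0.9 over 3 replicates;
- planted errors: reference proteins truncated by k residues (the (k+1)-th
  codon renders as an initiator Met if it happens to be a start codon),
  over-extended upstream to a planted in-frame earlier start codon,
  dropped entirely, duplicated byte-identically (paralogs), or split by a
  single 1-nt deletion;
- PEP scores are log-normal with group-calibrated medians (annotated
  1.32e-4, novel 1.04e-3, reverse 7.46e-2). The log-sd is per group —
  6 for targets, 1 for decoys — because target PEPs in real searches span
  many orders of magnitude while decoy PEPs concentrate near the FDR
  threshold; with unit dispersion the calibrated medians would make the
  annotated-novel comparison implausibly decisive, contradicting the
  rank-overlap structure the statistics module is meant to reproduce.

Three generator choices exist purely to keep the planted truth
recoverable and unambiguous, and are worth knowing when interpreting what
passing tests show: (i) every gene block is preceded by an in-frame stop,
so entries start exactly at planted gene starts and paralog copies are
byte-identical — real six-frame entries usually over-extend upstream,
which the planted truncations exercise instead; (ii) frameshift genes
carry a regular 15-residue K/R grid so both halves yield detectable fully
tryptic peptides; (iii) the broken codon is Trp (TGG) with a
non-T-ending codon before it and Val (GTG) as the first intact downstream
codon, making the deletion locally unambiguous (a chimeric codon cannot
re-encode the lost residue, which would slide the apparent junction) and
guaranteeing the downstream half an in-frame start codon. Consequently,
passing recovery tests demonstrate the pipeline's logic under clean
conditions; they do not quantify sensitivity on real spectra, real decoy
structure, or genes whose digest happens to leave a half unobservable.
The generator exposes a shuffled-peptide contaminant rate for
false-positive targets, defaulting to 0 since no rate is established.

## Numerical and scale choices

Default problem sizes keep every check fast on one CPU: unit fixtures use
genomes of 3–25 kb; the end-to-end recovery checks use 200 genes on
140 kb (the acceptance script) with 20 truncations (k = 1..40), 10
over-extensions, 10 frameshifts and 10 missing genes. All randomness is
seeded; generation and digestion restore the caller's RNG state, and
identical configurations are byte-identical. Determinism extends to
reports: ties in every ranking are broken by genomic coordinate.

Degenerate inputs are defined, not errored: empty genomes and empty
tables yield empty results; a genome too short for the requested genes
fails with a message naming the constraint; fully tied statistics return
their conventional values; out-of-bounds GFF features are dropped with a
warning while the remaining records are still written.

## Known limitations

Spectrum-level simulation (retention time, intensities, PTMs beyond
Nt-acetylation and Met excision), FDR recomputation, homology searching
itself, and distinguishing programmed frameshifts from sequencing errors
are out of scope; homology and transcript evidence are consumed as
precomputed tables. Reference matching requires exact C-terminal
agreement, so C-terminal mis-annotations are invisible. The
next-upstream-start rule recovers a start codon compatible with the
evidence, which need not be the historical truth when chance in-frame
start codons intervene — exactly as with real data.
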