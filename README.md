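# proteorefine

Proteogenomic refinement of bacterial genome annotation from shotgun
proteomics evidence.

Automated gene prediction in bacteria mis-assigns translational start
sites (TSSs) at reported rates of up to tens of percent, misses short
genes, and is confounded by sequencing errors that split one gene across
two reading frames. High-resolution LC-MS/MS peptide identifications give
direct evidence of translation and can validate, correct, or extend gene
models. `proteorefine` implements the computational side of such a study
for organisms (like mycobacteria) that initiate translation at ATG, GTG
and TTG:

- **Compacted six-frame database** — every stop-free segment of the six
  reading frames is translated from its most upstream start codon
  (initiator rendered as Met), products shorter than 20 residues are
  dropped, identical products (paralogs) are merged into one entry with
  multiple genomic coordinate tuples, and entries are cross-mapped to a
  reference proteome recording the N-terminal offset
  d = |six-frame product| − |reference protein|.
- **Peptide-to-genome mapping** — MaxQuant `peptides.txt`-style tables are
  parsed, filtered to peptides seen in ≥ 2 replicates, and located by a
  dynamic six-frame scan that also places Met-initial peptides on GTG/TTG
  start codons (literal translation Val/Leu). Placements are classified
  unique / paralog-unique / ambiguous, and peptides absent from the
  reference proteome become genome-search-specific peptides (GSSPs).
- **Gene model decisions** — TSS peptides (non-tryptic initiator-Met
  N-termini, N-Met-cleaved peptides immediately after a start codon, and
  N-terminally acetylated peptides) validate reference starts, drive
  upstream extensions (exact TSS, or the next upstream start codon when
  only tryptic GSSP evidence exists), downstream shortenings, and
  multiple-initiation reports.
- **Novel ORFs and interrupted coding sequences (ICDSs)** — unannotated
  peptide-supported ORFs are tiered by GSSP count and supporting homology
  or transcript evidence; same-strand, different-frame adjacent ORF pairs
  flag candidate frameshifts with a junction window, and reference
  proteins that fail single-ORF mapping are split across frames at the
  residue where their prefix and suffix placements meet.
- **PEP score statistics** — posterior error probability distributions of
  annotated, novel and reverse (decoy) peptides are compared with a
  tie-corrected Kruskal–Wallis test and Dunn's two-sided post-hoc z tests
  under Bonferroni correction:
  z = (R̄ᵢ − R̄ⱼ) / sqrt[(N(N+1)/12 − Σ(t³−t)/(12(N−1)))(1/nᵢ + 1/nⱼ)].
- **Synthetic studies** — a first-class generator plants genes with
  realistic start-codon usage, paralog duplications, TSS truncations and
  over-extensions, missing genes and 1-nt frameshifts, then produces
  corrupted reference proteomes and in-silico LysC+trypsin peptide tables
  with replicate structure, Met excision, acetylation, decoys and
  calibrated PEP scores — so the entire pipeline is testable against a
  known truth with no downloads.

## Worked example

```r
library(proteorefine)

cfg <- simulation_config(
  genome_length = 40000, n_genes = 40, n_paralog_pairs = 2,
  n_frameshift_genes = 3,
  ref_error_spec = list(missing_gene = 2, tss_upstream_k = c(5, 29, 12),
                        tss_downstream_k = c(8, 16)),
  seed = 7)
sim  <- generate_genome(cfg)
ann  <- corrupt_annotation(sim$truth, cfg)
peps <- digest_and_sample(sim$truth, cfg, reference = ann$proteome)

res <- run_pipeline(sim$genome, ann$proteome, list(sixframe = peps))
table(res$decisions$decision)
#>   downstream_start upstream_extension          validated
#>                  2                  3                 24
res$decisions[res$decisions$decision != "validated",
              c("ref_accession", "decision", "extension_aa", "evidence_kind")]
#>   ref_accession           decision extension_aa evidence_kind
#> 1        P_g008 upstream_extension            5     exact_tss
#> 2        P_g009 upstream_extension           29     exact_tss
#> 3        P_g010 upstream_extension           12     exact_tss
#> 4        P_g011   downstream_start           -8     exact_tss
#> 5        P_g012   downstream_start          -16     exact_tss
nrow(res$icds)   # 3 — one junction call per planted frameshift
```

The three planted truncations (5, 29 and 12 residues) and both planted
over-extensions (8 and 16 residues) are recovered exactly from N-terminal
peptide evidence; all other reference models are validated at their
annotated TSS. `write_run_report(res, "report/")` exports the summary
table, per-decision TSVs and a GFF3 of peptides, ORFs, modifications and
ICDS junctions for genome-browser inspection.

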