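Package: proteorefine
Title: Proteogenomic Refinement of Bacterial Genome Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for refining bacterial genome annotation with shotgun
    proteomics evidence. Builds a compacted six-frame translation database
    with coordinate-bearing headers and paralog merging, maps identified
    peptides back to the genome under bacterial start-codon rules
    (ATG/GTG/TTG read as initiator Met), classifies translational start
    site (TSS) evidence from non-tryptic N termini, N-terminal Met excision
    and N-terminal acetylation, validates or modifies gene models, calls
    novel ORFs with tiered supporting evidence, detects interrupted coding
    sequences (frameshifts) from cross-frame peptide support, and compares
    posterior error probability (PEP) distributions of annotated, novel and
    decoy peptides with a tie-corrected Kruskal-Wallis test and Dunn's
    post-hoc comparisons. Includes a synthetic-data generator that plants
    annotation errors (TSS truncations and over-extensions, missing genes,
    paralog duplications, single-nucleotide frameshifts) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
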