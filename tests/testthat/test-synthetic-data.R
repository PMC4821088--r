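# The generator's outputs must honour their own contracts: planted genes
# re-translate from the emitted genome, corruption is exactly as requested,
# and the digest equals a brute-force cleavage enumeration.

test_that("generation is deterministic and handles the empty case", {
  cfg0 <- simulation_config(genome_length = 5000L, n_genes = 0L, seed = 4L)
  sim0 <- generate_genome(cfg0)
  expect_equal(nrow(sim0$truth), 0L)
  expect_equal(nchar(sim0$genome[["chr1"]]), 5000L)

  cfg <- simulation_config(genome_length = 25000L, n_genes = 30L, seed = 1L)
  a <- generate_genome(cfg)
  b <- generate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  r1 <- digest_and_sample(a$truth, cfg)
  r2 <- digest_and_sample(b$truth, cfg)
  expect_identical(r1, r2)

  expect_error(generate_genome(simulation_config(genome_length = 1000L,
                                                 n_genes = 50L)),
               "genome_length")
})

test_that("every planted coding span re-translates to its protein", {
  for (sd in c(2L, 13L)) {
    cfg <- simulation_config(genome_length = 30000L, n_genes = 25L,
                             n_paralog_pairs = 3L, seed = sd)
    sim <- generate_genome(cfg)
    for (i in seq_len(nrow(sim$truth))) {
      tg <- sim$truth[i, ]
      span <- substr(sim$genome[[tg$contig]], tg$start, tg$end)
      if (tg$strand == "-") span <- rc_str(span)
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(span), no.init.codon = TRUE)), "")[[1L]]
      expect_identical(paste0("M", paste(aa[-1L], collapse = "")),
                       tg$protein_seq)
      expect_true((tg$end - tg$start + 1L) %% 3L == 0L)
      expect_false(grepl("*", tg$protein_seq, fixed = TRUE))
    }
    # exactly the requested paralog pairs, byte-identical proteins
    par <- sim$truth[!is.na(sim$truth$paralog_group), ]
    expect_equal(nrow(par), 6L)
    for (grp in unique(par$paralog_group)) {
      pp <- par[par$paralog_group == grp, ]
      expect_equal(nrow(pp), 2L)
      expect_identical(pp$protein_seq[1L], pp$protein_seq[2L])
    }
  }
})

test_that("frameshift genes carry exactly one 1-nt deletion at the stated boundary", {
  cfg <- simulation_config(genome_length = 30000L, n_genes = 15L,
                           n_frameshift_genes = 4L, seed = 8L)
  sim <- generate_genome(cfg)
  fs <- sim$truth[!is.na(sim$truth$frameshift_pos), ]
  expect_equal(nrow(fs), 4L)
  for (i in seq_len(nrow(fs))) {
    tg <- fs[i, ]
    L <- nchar(tg$protein_seq)
    expect_equal(tg$end - tg$start + 1L, 3L * L - 1L)  # one nt lost
    span <- substr(sim$genome[[tg$contig]], tg$start, tg$end)
    if (tg$strand == "-") span <- rc_str(span)
    r <- tg$frameshift_pos
    # residues 1..r read in the original frame
    aa_up <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(span, 1L, 3L * r)),
      no.init.codon = TRUE)), "")[[1L]]
    expect_identical(paste0("M", paste(aa_up[-1L], collapse = "")),
                     substr(tg$protein_seq, 1L, r))
    # residues r+2.. read in the shifted frame (codon r+1 lost one nt)
    down <- substr(span, 3L * r + 3L, nchar(span))
    aa_dn <- as.character(Biostrings::translate(Biostrings::DNAString(down),
                                                no.init.codon = TRUE))
    expect_identical(aa_dn, substr(tg$protein_seq, r + 2L, L))
  }
})

test_that("annotation corruption plants exactly the requested errors", {
  cfg0 <- simulation_config(genome_length = 15000L, n_genes = 10L, seed = 3L)
  sim0 <- generate_genome(cfg0)
  cor0 <- corrupt_annotation(sim0$truth, cfg0)
  expect_identical(unname(cor0$proteome),
                   sim0$truth$protein_seq)  # no errors: identity
  expect_equal(nrow(cor0$ledger), 0L)

  cfg <- simulation_config(
    genome_length = 20000L, n_genes = 10L,
    ref_error_spec = list(missing_gene = 1L, tss_upstream_k = 29L,
                          tss_downstream_k = 7L), seed = 3L)
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  expect_equal(length(cor$proteome), 9L)  # one gene missing
  led <- cor$ledger
  up <- led[led$err_type == "tss_upstream", ]
  expect_equal(up$k, 29L)
  tgid <- up$gene_id
  truth_prot <- sim$truth$protein_seq[sim$truth$gene_id == tgid]
  ref <- cor$proteome[[paste0("P_", tgid)]]
  expect_equal(nchar(truth_prot) - nchar(ref), 29L)
  expect_identical(substr(ref, 2L, nchar(ref)),
                   substr(truth_prot, 31L, nchar(truth_prot)))
  down <- led[led$err_type == "tss_downstream", ]
  ref_d <- cor$proteome[[down$accession]]
  truth_d <- sim$truth$protein_seq[sim$truth$gene_id == down$gene_id]
  expect_equal(nchar(ref_d) - nchar(truth_d), 7L)
  expect_identical(substr(ref_d, 9L, nchar(ref_d)),
                   substr(truth_d, 2L, nchar(truth_d)))
})

test_that("the digest equals an exhaustive brute-force enumeration", {
  cfg <- simulation_config(
    genome_length = 15000L, n_genes = 8L, seed = 21L, n_decoys = 0L,
    n_replicates = 1L,
    digestion = list(max_missed_cleavages = 3L, min_peptide_len = 7L,
                     max_peptide_len = Inf, detection_prob = 1))
  sim <- generate_genome(cfg)
  recs <- digest_and_sample(sim$truth, cfg)
  got <- sort(unique(recs$sequence))
  want <- sort(unique(unlist(lapply(sim$truth$protein_seq, naive_digest,
                                    max_missed = 3L, min_len = 7L,
                                    nmet_set = cfg$nmet_cleavage_residues))))
  expect_identical(got, want)
  # every emitted target peptide is a substring of some truth protein
  hay <- paste(sim$truth$protein_seq, collapse = "|")
  expect_true(all(vapply(got, grepl, NA, x = hay, fixed = TRUE)))
})

test_that("N-Met-removed forms follow the cleavage residue rule", {
  truth <- data.frame(gene_id = "g001", contig = "chr1", start = 1L,
                      end = 30L, strand = "+", start_codon = "ATG",
                      protein_seq = "MTAAAKAAAR", paralog_group = NA,
                      frameshift_pos = NA_integer_,
                      frameshift_genomic_pos = NA_integer_,
                      err_type = NA_character_, err_k = NA_integer_,
                      ext_ref_prefix = NA_character_,
                      cds = "x", frameshift_in_ref = FALSE,
                      stringsAsFactors = FALSE)
  cfg <- simulation_config(n_decoys = 0L, n_replicates = 1L, seed = 2L,
                           digestion = list(max_missed_cleavages = 3L,
                                            min_peptide_len = 5L,
                                            max_peptide_len = Inf,
                                            detection_prob = 1))
  recs <- digest_and_sample(truth, cfg)
  expect_true("TAAAK" %in% recs$sequence)       # Met removed: T licenses
  expect_true("MTAAAK" %in% recs$sequence)      # intact initiator form
  # with a non-licensing penultimate residue no Met-removed form appears
  truth$protein_seq <- "MWAAAKAAAR"
  recs2 <- digest_and_sample(truth, cfg)
  expect_false("WAAAK" %in% recs2$sequence)
})

test_that("detection probability zero leaves only decoys", {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 5L, seed = 5L,
                           n_decoys = 12L,
                           digestion = list(max_missed_cleavages = 3L,
                                            min_peptide_len = 7L,
                                            max_peptide_len = Inf,
                                            detection_prob = 0))
  sim <- generate_genome(cfg)
  recs <- digest_and_sample(sim$truth, cfg)
  expect_true(all(recs$is_decoy))
  expect_equal(nrow(recs), 12L)
})

test_that("PEP group medians are calibrated to the configured targets", {
  cfg <- simulation_config(
    genome_length = 180000L, n_genes = 290L, seed = 6L, n_decoys = 400L,
    ref_error_spec = list(missing_gene = 30L, tss_upstream_k = integer(0),
                          tss_downstream_k = integer(0)),
    digestion = list(max_missed_cleavages = 3L, min_peptide_len = 7L,
                     max_peptide_len = Inf, detection_prob = 1))
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  recs <- digest_and_sample(sim$truth, cfg, reference = cor$proteome)
  expect_gt(nrow(recs), 10000L)
  st <- classify_gssp(recs$sequence[!recs$is_decoy], cor$proteome)
  med <- c(annotated = median(recs$pep[!recs$is_decoy][st == "annotated"]),
           novel = median(recs$pep[!recs$is_decoy][st == "gssp"]),
           reverse = median(recs$pep[recs$is_decoy]))
  for (g in names(med)) {
    expect_gt(med[[g]], cfg$pep_medians[[g]] / 2)
    expect_lt(med[[g]], cfg$pep_medians[[g]] * 2)
  }
})

test_that("peptide tables round-trip through the MaxQuant-like dialect", {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 6L, seed = 9L,
                           n_decoys = 5L)
  sim <- generate_genome(cfg)
  recs <- digest_and_sample(sim$truth, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(recs, path)
  back <- parse_peptide_table(path, source_db = "sixframe")
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$modifications, recs$modifications)
  expect_identical(back$is_decoy, recs$is_decoy)
  expect_equal(back$pep, recs$pep)
  expect_identical(lapply(back$replicates, sort),
                   lapply(recs$replicates, sort))
})
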