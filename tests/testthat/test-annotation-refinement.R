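# TSS classification and gene-model verdicts on constructed and simulated
# evidence.

# Build a tiny study with one designated annotation error, returning all
# pipeline stage objects for inspection.
refine_fixture <- function(ref_error_spec, seed = 33L, detection = 1,
                           drop_nterm = FALSE, n_genes = 8L) {
  cfg <- simulation_config(
    genome_length = 20000L, n_genes = n_genes, seed = seed, n_decoys = 0L,
    ref_error_spec = ref_error_spec,
    digestion = list(max_missed_cleavages = 3L, min_peptide_len = 7L,
                     max_peptide_len = Inf, detection_prob = detection))
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  recs <- digest_and_sample(sim$truth, cfg, reference = cor$proteome)
  if (drop_nterm)
    recs <- recs[is.na(recs$start_residue) | recs$start_residue > 2L, ,
                 drop = FALSE]
  db <- map_reference(build_sixframe_db(sim$genome), cor$proteome)
  maps <- map_peptides(recs, db)
  agg <- aggregate_per_orf(recs, maps)
  dec <- refine_gene_models(db, agg, maps, recs)
  list(cfg = cfg, sim = sim, cor = cor, recs = recs, db = db, maps = maps,
       agg = agg, dec = dec)
}

test_that("TSS peptides are classified by start-codon context", {
  # gene: stop, then ATG gene with T as penultimate residue
  g <- c(chr1 = paste0("TAA", "ATG", "ACC", strrep("GAT", 10L), "AAA",
                       strrep("CAC", 8L), "TAG"))
  db <- build_sixframe_db(g, min_len = 10L)
  init <- locate_peptide(paste0("MT", strrep("D", 10L), "K"), db)
  tssi <- classify_tss_peptides(init, db)
  expect_identical(tssi$tss_kind, "initiator_met")
  expect_identical(tssi$penultimate, "T")
  expect_identical(tssi$tss_start_codon, "ATG")
  expect_equal(tssi$init_coord, 4L)

  cleaved <- locate_peptide(paste0("T", strrep("D", 10L), "K"), db)
  tssc <- classify_tss_peptides(cleaved, db)
  expect_identical(tssc$tss_kind, "nmet_cleaved")
  expect_identical(tssc$penultimate, "T")
  expect_equal(tssc$init_coord, 4L)

  interior <- locate_peptide(strrep("H", 8L), db)
  tssn <- classify_tss_peptides(interior, db)
  expect_true(all(is.na(tssn$tss_kind)))  # tryptic interior, no start context
})

test_that("N-Met-cleaved Val on a GTG start is classified with the adjacent-start flag", {
  g <- c(chr1 = paste0("TAA", "GTG", "GTG", strrep("GAT", 10L), "AAA", "TAG"))
  db <- build_sixframe_db(g, min_len = 10L)
  # peptide starts at codon 2 (GTG, literal V), preceded by the GTG start
  m <- locate_peptide(paste0("V", strrep("D", 10L), "K"), db)
  tss <- classify_tss_peptides(m, db)
  expect_identical(tss$tss_kind, "nmet_cleaved")
  expect_identical(tss$penultimate, "V")
  expect_identical(tss$tss_start_codon, "GTG")
  expect_true(tss$adjacent_upstream_start)
})

test_that("correct annotations are validated and never modified", {
  fx <- refine_fixture(list(missing_gene = 0L, tss_upstream_k = integer(0),
                            tss_downstream_k = integer(0)))
  expect_true(all(fx$dec$decision == "validated"))
  expect_equal(nrow(fx$dec), nrow(fx$sim$truth))
  expect_true(all(fx$dec$extension_aa == 0L))
  expect_identical(fx$dec$new_tss, fx$dec$old_tss)
  # validated old TSS equals the planted gene 5' end
  tr <- fx$sim$truth
  want <- ifelse(tr$strand == "+", tr$start, tr$end)
  names(want) <- paste0("P_", tr$gene_id)
  expect_equal(unname(want[fx$dec$ref_accession]), fx$dec$old_tss)
})

test_that("a planted truncation is recovered exactly via an upstream TSS peptide", {
  fx <- refine_fixture(list(missing_gene = 0L, tss_upstream_k = 29L,
                            tss_downstream_k = integer(0)))
  up <- fx$dec[fx$dec$decision == "upstream_extension", ]
  expect_equal(nrow(up), 1L)
  expect_equal(up$extension_aa, 29L)
  expect_identical(up$evidence_kind, "exact_tss")
  tg <- fx$sim$truth[fx$sim$truth$gene_id ==
                       sub("^P_", "", up$ref_accession), ]
  expect_equal(up$new_tss, ifelse(tg$strand == "+", tg$start, tg$end))
  # mutual exclusion: no other decision for that ORF
  expect_equal(sum(fx$dec$orf_id == up$orf_id &
                     fx$dec$decision != "multiple_initiation"), 1L)
})

test_that("without N-terminal peptides the next upstream start codon is taken", {
  fx <- refine_fixture(list(missing_gene = 0L, tss_upstream_k = 20L,
                            tss_downstream_k = integer(0)),
                       drop_nterm = TRUE)
  up <- fx$dec[fx$dec$decision == "upstream_extension", ]
  expect_equal(nrow(up), 1L)
  expect_identical(up$evidence_kind, "next_upstream_start")
  # minimal-extension rule: the new start is an actual start codon at or
  # downstream of the planted one, strictly upstream of the reference start
  tg <- fx$sim$truth[fx$sim$truth$gene_id ==
                       sub("^P_", "", up$ref_accession), ]
  true_tss <- ifelse(tg$strand == "+", tg$start, tg$end)
  expect_true(up$extension_aa > 0L && up$extension_aa <= 20L)
  if (tg$strand == "+") {
    expect_true(up$new_tss >= true_tss && up$new_tss < up$old_tss)
  } else {
    expect_true(up$new_tss <= true_tss && up$new_tss > up$old_tss)
  }
  expect_true(up$start_codon %in% c("ATG", "GTG", "TTG"))
})

test_that("downstream TSS evidence shortens an over-extended model", {
  fx <- refine_fixture(list(missing_gene = 0L, tss_upstream_k = integer(0),
                            tss_downstream_k = 16L))
  dn <- fx$dec[fx$dec$decision == "downstream_start", ]
  expect_equal(nrow(dn), 1L)
  expect_equal(dn$extension_aa, -16L)
  tg <- fx$sim$truth[fx$sim$truth$gene_id ==
                       sub("^P_", "", dn$ref_accession), ]
  expect_equal(dn$new_tss, ifelse(tg$strand == "+", tg$start, tg$end))
  # extension geometry: the retained model suffix equals the reference tail
  ref <- fx$cor$proteome[[dn$ref_accession]]
  expect_identical(substr(ref, 16L + 2L, nchar(ref)),
                   substr(tg$protein_seq, 2L, nchar(tg$protein_seq)))
})

test_that("two supported initiation sites yield a multiple-initiation report", {
  fx <- refine_fixture(list(missing_gene = 0L, tss_upstream_k = integer(0),
                            tss_downstream_k = integer(0)), seed = 44L)
  # fabricate a second initiation site: take one validated ORF and add a
  # TSS peptide at an internal ATG of that entry, if one exists
  db <- fx$db
  ent <- db$entries[match(fx$dec$orf_id[1L], db$entries$entry_id), ]
  cc <- ent$coords[[1L]][1L, ]
  internal <- NULL
  for (r in seq.int(10L, cc$codon_end - cc$codon_start - 12L)) {
    if (codon_at(db, cc$contig, cc$frame, cc$codon_start + r - 1L) == "ATG") {
      internal <- r
      break
    }
  }
  skip_if(is.null(internal), "no internal ATG in the sampled ORF")
  pep <- paste0("M", substr(ent$protein, internal + 1L, internal + 11L))
  m <- locate_peptide(pep, db)
  m <- m[m$host_entry == ent$entry_id, , drop = FALSE]
  tss <- classify_tss_peptides(m, db)
  ctx <- rbind(
    classify_tss_peptides(
      locate_peptide(paste0("M", substr(ent$protein, 2L, 12L)), db), db),
    tss)
  ctx$status <- "annotated"
  multi <- detect_multiple_initiation(ent, ctx)
  expect_false(is.null(multi))
  expect_identical(multi$decision, "multiple_initiation")
  expect_equal(multi$n_sites, 2L)
  # one site seen through both evidence forms is not multiple initiation
  one <- ctx[c(1L, 1L), ]
  expect_null(detect_multiple_initiation(ent, one))
})

test_that("start codon and penultimate summaries add up", {
  s <- summarize_start_codons(c("ATG", "ATG", "GTG"))
  expect_equal(s$percent[s$start_codon == "ATG"], 66.67)
  expect_equal(s$percent[s$start_codon == "GTG"], 33.33)
  expect_equal(sum(s$count), 3L)
  expect_equal(nrow(summarize_start_codons(character(0))), 0L)
  s2 <- summarize_start_codons(rep("ATG", 5L))
  expect_equal(s2$percent, 100)

  tss <- data.frame(tss_kind = c("nmet_cleaved", "nmet_cleaved",
                                 "nmet_cleaved", "initiator_met"),
                    penultimate = c("T", "T", "S", "A"),
                    stringsAsFactors = FALSE)
  p <- summarize_penultimate_residues(tss)
  expect_identical(p$residue, c("T", "S"))
  expect_identical(p$count, c(2L, 1L))
  expect_equal(nrow(summarize_penultimate_residues(tss[0L, ])), 0L)
})

test_that("observed start-codon usage tracks the planted weights", {
  cfg <- simulation_config(genome_length = 70000L, n_genes = 100L,
                           seed = 55L, n_decoys = 0L,
                           digestion = list(max_missed_cleavages = 3L,
                                            min_peptide_len = 7L,
                                            max_peptide_len = Inf,
                                            detection_prob = 1))
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  db <- map_reference(build_sixframe_db(sim$genome), cor$proteome)
  recs <- digest_and_sample(sim$truth, cfg, reference = cor$proteome)
  maps <- map_peptides(recs, db)
  agg <- aggregate_per_orf(recs, maps)
  dec <- refine_gene_models(db, agg, maps, recs)
  s <- summarize_start_codons(dec[dec$decision == "validated", ])
  n <- sum(s$count)
  p_atg <- s$count[s$start_codon == "ATG"] / n
  # within ~4 binomial standard errors of the planted weight
  expect_lt(abs(p_atg - 0.6396), 4 * sqrt(0.6396 * (1 - 0.6396) / n))
  # penultimate residues of cleaved TSS peptides come from the licensed set
  mm <- maps$matches[!duplicated(maps$matches$peptide), ]
  tss <- classify_tss_peptides(mm, db)
  pen <- summarize_penultimate_residues(tss)
  expect_true(all(pen$residue %in% cfg$nmet_cleavage_residues))
})
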