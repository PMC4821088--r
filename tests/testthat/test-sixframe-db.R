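# Database construction: compaction rule, paralog merging, reference
# cross-mapping, header round-trips.

test_that("a single forward ORF is extracted with exact fields", {
  g <- c(chr1 = paste0("ATG", strrep("GCT", 20L), "TAA"))
  e <- extract_sixframe_entries(g, min_len = 20L)
  expect_equal(nrow(e), 1L)
  expect_identical(e$protein, paste0("M", strrep("A", 20L)))
  expect_equal(nchar(e$protein), 21L)
  expect_identical(e$start_codon, "ATG")
  expect_true(e$has_stop)
  expect_equal(e$start, 1L)
  expect_equal(e$end, 63L)
  expect_identical(e$strand, "+")
  expect_equal(e$frame, 1L)
})

test_that("genomes without start codons yield no entries", {
  g <- c(chr1 = strrep("A", 300L))
  expect_equal(nrow(extract_sixframe_entries(g)), 0L)
  expect_equal(nrow(extract_sixframe_entries(c(chr1 = ""))), 0L)
})

test_that("the most upstream start codon wins within a segment", {
  # TTG ... ATG in the same stop-free frame: entry starts at the TTG
  g <- c(chr1 = paste0("TTG", "GCA", "ATG", strrep("GAA", 20L), "TAG"))
  e <- extract_sixframe_entries(g, min_len = 10L)
  e1 <- e[e$frame == 1L, ]
  expect_equal(nrow(e1), 1L)
  expect_identical(e1$start_codon, "TTG")
  expect_identical(substr(e1$protein, 1L, 3L), "MAM")
  expect_equal(e1$start, 1L)
})

test_that("terminal segments without a stop are retained and flagged", {
  g <- c(chr1 = paste0("ATG", strrep("GCT", 25L)))  # runs off the frame end
  e <- extract_sixframe_entries(g, min_len = 20L)
  e1 <- e[e$frame == 1L, ]
  expect_equal(nrow(e1), 1L)
  expect_false(e1$has_stop)
  expect_equal(e1$end, 78L)  # up till the last in-frame codon
})

test_that("extraction agrees exactly with the naive enumeration oracle", {
  for (sd in 1:20) {
    g <- random_genome(sample(500:4000, 1L), seed = sd)
    got <- extract_sixframe_entries(g, min_len = 10L)
    want <- naive_sixframe(g, min_len = 10L)
    got <- got[order(got$start, got$strand, got$protein), ]
    expect_equal(nrow(got), nrow(want))
    expect_identical(got$protein, want$protein)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$strand, want$strand)
    expect_identical(got$has_stop, want$has_stop)
  }
})

test_that("lowering min_len only adds entries and keeps the rest unchanged", {
  g <- random_genome(4000L, seed = 77L)
  hi <- extract_sixframe_entries(g, min_len = 25L)
  lo <- extract_sixframe_entries(g, min_len = 10L)
  expect_true(all(hi$protein %in% lo$protein))
  keep <- lo[match(hi$protein, lo$protein), c("protein", "start", "end",
                                              "strand", "frame")]
  rownames(keep) <- NULL
  expect_identical(keep, hi[, c("protein", "start", "end", "strand",
                                "frame")])
})

test_that("identical translated sequences merge into one multi-locus entry", {
  cfg <- simulation_config(genome_length = 25000L, n_genes = 16L,
                           n_paralog_pairs = 4L, seed = 31L)
  sim <- generate_genome(cfg)
  raw <- extract_sixframe_entries(sim$genome)
  merged <- deduplicate_entries(raw)
  # set-cardinality oracle
  expect_equal(nrow(merged), length(unique(raw$protein)))
  expect_false(any(duplicated(merged$protein)))
  expect_equal(nrow(merged) +
                 sum(vapply(merged$coords, nrow, 1L) - 1L), nrow(raw))
  par <- sim$truth[!is.na(sim$truth$paralog_group), ]
  for (grp in unique(par$paralog_group)) {
    prot <- par$protein_seq[par$paralog_group == grp][1L]
    hit <- merged[merged$protein == prot, ]
    expect_equal(nrow(hit), 1L)
    cc <- hit$coords[[1L]]
    expect_equal(nrow(cc), 2L)
    expect_true(all(diff(cc$start) > 0L))  # ascending starts
  }
  # all-distinct input: identity
  distinct <- raw[!duplicated(raw$protein) &
                    !raw$protein %in% raw$protein[duplicated(raw$protein)], ]
  rd <- deduplicate_entries(distinct)
  expect_identical(rd$protein, distinct$protein)
})

test_that("every coordinate tuple re-translates to the entry protein", {
  g <- random_genome(3000L, seed = 5L)
  db <- build_sixframe_db(g, min_len = 10L)
  for (i in seq_len(nrow(db$entries))) {
    cc <- db$entries$coords[[i]]
    for (j in seq_len(nrow(cc))) {
      span <- substr(g[[cc$contig[j]]], cc$start[j], cc$end[j])
      if (cc$strand[j] == "-") span <- rc_str(span)
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(span), no.init.codon = TRUE)), "")[[1L]]
      expect_identical(paste0("M", paste(aa[-1L], collapse = "")),
                       db$entries$protein[i])
    }
  }
})

test_that("reference mapping records N-terminal offsets and ambiguity", {
  g <- c(chr1 = paste0("TAA", "ATG", strrep("CAT", 30L), "TAA"))
  db <- build_sixframe_db(g, min_len = 10L)
  entry_prot <- db$entries$protein[db$entries$start_codon == "ATG"][1L]
  # identical reference
  db1 <- map_reference(db, c(REF1 = entry_prot))
  hit <- db1$entries[which(db1$entries$ref_accession == "REF1"), ]
  expect_true(hit$ref_identical)
  expect_equal(hit$ref_offset_aa, 0L)
  # reference shifted 10 residues downstream (initiator Met tolerant)
  trunc <- paste0("M", substr(entry_prot, 12L, nchar(entry_prot)))
  db2 <- map_reference(db, c(REF2 = trunc))
  hit2 <- db2$entries[which(db2$entries$ref_accession == "REF2"), ]
  expect_equal(hit2$ref_offset_aa, nchar(entry_prot) - nchar(trunc))
  expect_false(hit2$ref_identical)
  # two distinct references matching one entry: ambiguous, unlinked
  db3 <- map_reference(db, c(A = entry_prot, B = trunc))
  amb <- db3$entries[db3$entries$protein == entry_prot, ]
  expect_true(amb$ref_ambiguous)
  expect_true(is.na(amb$ref_accession))
})

test_that("a planted upstream truncation surfaces as exactly one k-offset entry", {
  cfg <- simulation_config(
    genome_length = 20000L, n_genes = 10L,
    ref_error_spec = list(missing_gene = 0L, tss_upstream_k = 29L,
                          tss_downstream_k = integer(0)), seed = 12L)
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  db <- map_reference(build_sixframe_db(sim$genome), cor$proteome)
  off <- db$entries$ref_offset_aa
  expect_equal(sum(off == 29L, na.rm = TRUE), 1L)
  acc29 <- db$entries$ref_accession[which(off == 29L)]
  expect_identical(acc29, cor$ledger$accession[cor$ledger$err_type ==
                                                 "tss_upstream"])
})

test_that("database FASTA headers round-trip bit-exactly", {
  cfg <- simulation_config(genome_length = 20000L, n_genes = 12L,
                           n_paralog_pairs = 2L, seed = 14L)
  sim <- generate_genome(cfg)
  cor <- corrupt_annotation(sim$truth, cfg)
  db <- map_reference(build_sixframe_db(sim$genome), cor$proteome)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_database_fasta(db, f1)
  parsed <- parse_database_fasta(f1)
  expect_identical(parsed$entry_id, db$entries$entry_id)
  expect_identical(parsed$protein, db$entries$protein)
  expect_identical(parsed$ref_accession, db$entries$ref_accession)
  expect_identical(parsed$ref_offset_aa, db$entries$ref_offset_aa)
  for (i in seq_len(nrow(parsed))) {
    cc <- db$entries$coords[[i]][order(db$entries$coords[[i]]$start),
                                 c("contig", "start", "end", "strand")]
    rownames(cc) <- NULL
    expect_identical(parsed$coords[[i]], cc)
  }
  # write -> parse -> write is byte-identical
  db2 <- db
  db2$entries <- parsed
  db2$entries$coords <- parsed$coords
  write_database_fasta(db2$entries, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("prediction ingestion verifies coordinates by re-translation", {
  cfg <- simulation_config(genome_length = 15000L, n_genes = 6L, seed = 15L)
  sim <- generate_genome(cfg)
  preds <- data.frame(pred_id = sim$truth$gene_id,
                      protein = sim$truth$protein_seq,
                      contig = sim$truth$contig, start = sim$truth$start,
                      end = sim$truth$end, strand = sim$truth$strand,
                      stringsAsFactors = FALSE)
  ok <- ingest_predictions(preds, sim$genome)
  expect_equal(nrow(ok), nrow(preds))
  expect_length(attr(ok, "mismatches"), 0L)
  # wrong strand: excluded and reported
  bad <- preds
  bad$strand[1L] <- ifelse(bad$strand[1L] == "+", "-", "+")
  res <- ingest_predictions(bad, sim$genome)
  expect_equal(nrow(res), nrow(preds) - 1L)
  expect_identical(attr(res, "mismatches"), bad$pred_id[1L])
  # empty input
  empty <- preds[0L, ]
  expect_equal(nrow(ingest_predictions(empty, sim$genome)), 0L)
})
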