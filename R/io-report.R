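# GFF3 export of peptides, ORFs, decisions and calls, plus the run report
# and the end-to-end pipeline driver.

GFF_ESCAPE <- c("%" = "%25", ";" = "%3B", "=" = "%3D", "&" = "%26",
                "," = "%2C", "\t" = "%09", "\n" = "%0A")

gff_escape <- function(x) {
  for (ch in names(GFF_ESCAPE)) x <- gsub(ch, GFF_ESCAPE[[ch]], x,
                                          fixed = TRUE)
  x
}

gff_unescape <- function(x) {
  for (ch in rev(names(GFF_ESCAPE))) x <- gsub(GFF_ESCAPE[[ch]], ch, x,
                                               fixed = TRUE)
  x
}

#' Export feature records as GFF3
#'
#' Features are sorted by contig then start; attribute values are
#' percent-escaped and round-trip through [parse_gff()]. Records outside
#' genome bounds (when a genome is supplied) are dropped with a warning
#' while the remaining records are still written; their ids are returned
#' in the `"errors"` attribute.
#'
#' @param features data.frame with `contig`, `source`, `feature_type`,
#'   `start`, `end`, `strand` and an `attributes` list-column of named
#'   character vectors
#' @param path output file
#' @param genome optional genome for bounds validation
#' @return the path, invisibly, with attribute `errors`
#' @export
export_gff <- function(features, path, genome = NULL) {
  errors <- character(0)
  if (!is.null(genome) && nrow(features) > 0L) {
    genome <- load_genome(genome)
    ok <- vapply(seq_len(nrow(features)), function(i) {
      ctg <- features$contig[i]
      ctg %in% names(genome) && features$start[i] >= 1L &&
        features$end[i] <= nchar(genome[[ctg]]) &&
        features$start[i] <= features$end[i]
    }, NA)
    if (any(!ok)) {
      errors <- vapply(which(!ok), function(i) {
        at <- features$attributes[[i]]
        if ("ID" %in% names(at)) at[["ID"]] else as.character(i)
      }, "")
      warning(length(errors), " feature(s) outside genome bounds dropped: ",
              paste(utils::head(errors, 5L), collapse = ", "))
      features <- features[ok, , drop = FALSE]
    }
  }
  if (nrow(features) > 0L)
    features <- features[order(features$contig, features$start), ,
                         drop = FALSE]
  lines <- "##gff-version 3"
  if (nrow(features) > 0L) {
    attrs <- vapply(features$attributes, function(at) {
      paste(paste0(gff_escape(names(at)), "=", gff_escape(unname(at))),
            collapse = ";")
    }, "")
    lines <- c(lines, paste(features$contig, features$source,
                            features$feature_type, features$start,
                            features$end, ".", features$strand, ".",
                            attrs, sep = "\t"))
  }
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "errors") <- errors
  out
}

#' Parse a GFF3 file written by [export_gff()]
#' @param path GFF3 file
#' @return features data.frame in [export_gff()] input shape
#' @export
parse_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(contig = character(0), source = character(0),
                      feature_type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    out$attributes <- list()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[`, "", 1L),
                    source = vapply(parts, `[`, "", 2L),
                    feature_type = vapply(parts, `[`, "", 3L),
                    start = as.integer(vapply(parts, `[`, "", 4L)),
                    end = as.integer(vapply(parts, `[`, "", 5L)),
                    strand = vapply(parts, `[`, "", 7L),
                    stringsAsFactors = FALSE)
  out$attributes <- lapply(parts, function(p) {
    kv <- strsplit(strsplit(p[9L], ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(gff_unescape(vapply(kv, `[`, "", 2L)),
                    gff_unescape(vapply(kv, `[`, "", 1L)))
  })
  out
}

# build GFF feature rows from pipeline results
features_from_results <- function(res) {
  rows <- list()
  add <- function(contig, type, start, end, strand, attrs) {
    r <- data.frame(contig = contig, source = "proteorefine",
                    feature_type = type, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
    r$attributes <- list(attrs)
    rows[[length(rows) + 1L]] <<- r
  }
  mm <- res$maps$matches
  keep <- mm$peptide %in% res$maps$peptides$sequence[
    res$maps$peptides$mapping_class %in% c("unique", "paralog_unique")]
  mm <- mm[keep, , drop = FALSE]
  for (i in seq_len(nrow(mm)))
    add(mm$contig[i], "peptide", mm$start[i], mm$end[i], mm$strand[i],
        c(ID = sprintf("pep%05d", i), sequence = mm$peptide[i],
          Parent = mm$host_entry[i]))
  ent <- res$db$entries
  ent <- ent[ent$entry_id %in% res$agg$entry_id, , drop = FALSE]
  for (i in seq_len(nrow(ent)))
    add(ent$contig[i], "orf", ent$start[i], ent$end[i], ent$strand[i],
        c(ID = ent$entry_id[i],
          ref = if (is.na(ent$ref_accession[i])) "novel"
                else ent$ref_accession[i]))
  dec <- res$decisions
  for (i in seq_len(nrow(dec))) {
    lo <- min(dec$old_tss[i], dec$new_tss[i], na.rm = TRUE)
    hi <- max(dec$old_tss[i], dec$new_tss[i], na.rm = TRUE)
    add(dec$contig[i], "gene_model_modification", lo, hi, dec$strand[i],
        c(ID = sprintf("dec%04d", i), Parent = dec$orf_id[i],
          decision = dec$decision[i],
          evidence = dec$evidence_kind[i]))
  }
  nov <- res$novel
  for (i in seq_len(nrow(nov)))
    add(nov$contig[i], "novel_orf", nov$start[i], nov$end[i], nov$strand[i],
        c(ID = sprintf("nov%04d", i), Parent = nov$entry_id[i],
          tier = nov$tier[i]))
  ic <- res$icds
  for (i in seq_len(nrow(ic)))
    add(ic$contig[i], "icds_junction", ic$junction_start[i],
        ic$junction_end[i], ic$strand[i],
        c(ID = sprintf("icds%03d", i),
          upstream = ic$upstream_orf[i], downstream = ic$downstream_orf[i],
          status = ic$status[i]))
  if (length(rows) == 0L) {
    out <- data.frame(contig = character(0), source = character(0),
                      feature_type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    out$attributes <- list()
    return(out)
  }
  do.call(rbind, rows)
}

#' Run the full proteogenomic refinement pipeline
#'
#' Builds the compacted six-frame database, maps the reference proteome,
#' parses and replicate-filters the peptide tables, maps peptides to the
#' genome, aggregates per ORF, refines gene models, calls novel ORFs and
#' ICDS candidates, splits unmapped reference proteins across frames, and
#' compares PEP-score distributions.
#'
#' @param genome genome (path/vector/DNAStringSet)
#' @param reference reference proteome (named vector or FASTA path)
#' @param tables named list of peptide tables (data.frames or TSV paths);
#'   names are the source database labels
#' @param predictions optional predictions (FASTA/data.frame)
#' @param homology optional protein homology table
#' @param cdna_blast optional transcript nucleotide homology table
#' @param transcripts optional transcript features
#' @param min_len six-frame minimum product length (residues)
#' @param min_replicates replicate-filter threshold
#' @param max_gap_nt ICDS adjacency distance
#' @return a list of all stage results plus a Table-style `summary`
#' @export
run_pipeline <- function(genome, reference, tables, predictions = NULL,
                         homology = NULL, cdna_blast = NULL,
                         transcripts = NULL, min_len = 20L,
                         min_replicates = 2L, max_gap_nt = 100L) {
  db <- build_sixframe_db(genome, min_len = min_len)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) reference <- read_proteome(reference)
  db <- map_reference(db, reference)
  if (!is.null(predictions) && !is.data.frame(predictions))
    predictions <- ingest_predictions(predictions, db$genome)
  if (is.null(names(tables)))
    names(tables) <- paste0("db", seq_along(tables))
  records <- do.call(rbind, lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    if (is.data.frame(t) && "sequence" %in% names(t)) {
      t$source_db <- nm
      t[, intersect(c("sequence", "modifications", "pep", "is_decoy",
                      "source_db", "replicates", "n_replicates"), names(t))]
    } else parse_peptide_table(t, source_db = nm)
  }))
  filtered <- filter_replicates(records, min_replicates)
  target <- filtered[filtered$replicate_pass, , drop = FALSE]
  maps <- map_peptides(target, db)
  agg <- aggregate_per_orf(target, maps)
  decisions <- refine_gene_models(db, agg, maps, target, predictions)
  novel <- call_novel_orfs(db, agg, maps, homology = homology,
                           cdna_blast = cdna_blast,
                           transcripts = transcripts)
  icds <- detect_icds_pairs(db, agg, maps, homology = homology,
                            max_gap_nt = max_gap_nt)
  ref_fs <- detect_reference_frameshift(db, records = target)
  pep <- pep_compare(records, reference, min_replicates)
  res <- list(db = db, records = records, filtered = target, maps = maps,
              agg = agg, decisions = decisions, novel = novel, icds = icds,
              ref_frameshifts = ref_fs, pep = pep,
              predictions = predictions)
  res$summary <- summarize_run(res)
  res
}

# Table-style per-database and combined tallies
summarize_run <- function(res) {
  dbs <- sort(unique(res$records$source_db))
  count_for <- function(sel_records) {
    seqs <- unique(sel_records$sequence[!sel_records$is_decoy])
    agg_sub <- res$agg
    agg_sub$peptides <- lapply(agg_sub$peptides, intersect, y = seqs)
    agg_sub$n_peptides <- lengths(agg_sub$peptides)
    agg_sub <- agg_sub[agg_sub$n_peptides > 0L, , drop = FALSE]
    dec <- refine_gene_models(res$db, agg_sub, res$maps, sel_records,
                              res$predictions)
    nov <- call_novel_orfs(res$db, agg_sub, res$maps)
    ref_linked <- res$db$entries$ref_accession[
      match(agg_sub$entry_id, res$db$entries$entry_id)]
    c(reference_orf_identifications = sum(!is.na(ref_linked)),
      reference_tss_validations = sum(dec$decision == "validated"),
      upstream_modifications = sum(dec$decision == "upstream_extension"),
      upstream_tss_identifications = sum(dec$decision == "upstream_extension" &
                                           dec$evidence_kind == "exact_tss"),
      downstream_tss_identifications = sum(dec$decision == "downstream_start"),
      novel_orf_identifications = sum(nov$tier != "excluded"))
  }
  cols <- lapply(dbs, function(d)
    count_for(res$filtered[res$filtered$source_db == d, , drop = FALSE]))
  names(cols) <- dbs
  cols$combined <- count_for(res$filtered)
  as.data.frame(cols, check.names = FALSE)
}

#' Write the run report bundle
#'
#' One summary TSV with per-database and combined tallies, one TSV per
#' decision/call type, and a GFF3 of peptides, ORFs, modifications, novel
#' ORFs and ICDS junctions. Deterministic for deterministic input.
#' @param res result of [run_pipeline()]
#' @param dir output directory (created if needed)
#' @return the summary data.frame, invisibly
#' @export
write_run_report <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    df <- df[, !vapply(df, is.list, NA), drop = FALSE]
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  summary_df <- cbind(metric = rownames(res$summary), res$summary)
  utils::write.table(summary_df, file.path(dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wt(res$decisions, "decisions.tsv")
  wt(res$novel, "novel_orfs.tsv")
  wt(res$icds, "icds.tsv")
  wt(res$ref_frameshifts, "reference_frameshifts.tsv")
  wt(res$pep$after$summary, "pep_summary.tsv")
  export_gff(features_from_results(res), file.path(dir, "features.gff3"),
             genome = res$db$genome)
  invisible(res$summary)
}
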