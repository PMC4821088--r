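# Peptide identification tables and the dynamic six-frame genome scan.
#
# Peptide tables follow a MaxQuant peptides.txt-like tab-separated dialect:
# required columns `Sequence` and `PEP`; optional `Reverse` ("+" marks
# decoys), `Modifications`, and `Experiment <id>` evidence-count columns
# that define replicate membership.

#' Parse a peptide identification table
#'
#' @param path TSV file (or a data.frame already in the dialect)
#' @param source_db label recorded on every record (`reference`,
#'   `sixframe` or `prediction`)
#' @return data.frame of peptide records: `sequence`, `modifications`,
#'   `pep`, `replicates` (list-column of replicate ids), `n_replicates`,
#'   `is_decoy`, `source_db`
#' @export
parse_peptide_table <- function(path, source_db = "sixframe") {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("Sequence", "PEP")) {
    if (!col %in% names(tab))
      stop("peptide table is missing required column: ", col)
  }
  pep <- suppressWarnings(as.numeric(tab$PEP))
  if (anyNA(pep) && nrow(tab) > 0L) {
    bad <- which(is.na(pep))
    stop("non-numeric PEP value at line ", bad[1L] + 1L)
  }
  expcols <- grep("^Experiment ", names(tab), value = TRUE)
  reps <- lapply(seq_len(nrow(tab)), function(i) {
    if (length(expcols) == 0L) return("R1")
    ev <- suppressWarnings(as.numeric(unlist(tab[i, expcols])))
    ev[is.na(ev)] <- 0
    sub("^Experiment ", "", expcols[ev > 0])
  })
  out <- data.frame(
    sequence = toupper(tab$Sequence),
    modifications = if ("Modifications" %in% names(tab))
      tab$Modifications else rep("Unmodified", nrow(tab)),
    pep = pep,
    is_decoy = if ("Reverse" %in% names(tab))
      !is.na(tab$Reverse) & tab$Reverse == "+" else rep(FALSE, nrow(tab)),
    source_db = rep(source_db, nrow(tab)),
    stringsAsFactors = FALSE)
  out$replicates <- reps
  out$n_replicates <- lengths(reps)
  out
}

#' Filter peptides by replicate support
#'
#' Replicate membership is pooled across database searches per peptide
#' sequence: a peptide seen in different replicates in two tables counts
#' the union. Decoy records are passed through regardless (flagged by
#' `replicate_pass`) so decoy statistics can still be computed upstream of
#' the filter.
#'
#' @param records peptide records (possibly from several tables)
#' @param min_replicates minimum distinct replicates per sequence
#' @return filtered records with a logical `replicate_pass` column
#' @export
filter_replicates <- function(records, min_replicates = 2L) {
  if (nrow(records) == 0L) {
    records$replicate_pass <- logical(0)
    return(records)
  }
  pooled <- tapply(records$replicates, records$sequence,
                   function(x) length(unique(unlist(x))))
  records$replicate_pass <- pooled[records$sequence] >= min_replicates
  out <- records[records$replicate_pass | records$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate a peptide on the genome (dynamic six-frame scan)
#'
#' Returns every placement where the peptide equals the literal frame
#' translation, plus placements where the peptide starts with Met sitting
#' on a start codon (GTG/TTG read as initiator Met at a putative
#' initiation point). Each match carries the literal translation of the
#' preceding in-frame codon (`"*"` after a stop, `"^"` at the frame edge)
#' and its codon position relative to the host entry's start codon
#' (`at_codon_index`, 1 = entry start codon).
#'
#' @param peptide amino-acid string (length >= 1)
#' @param db `sixframe_db` from [build_sixframe_db()]
#' @return data.frame of matches: `peptide`, `contig`, `start`, `end`,
#'   `strand`, `frame`, `codon_index`, `preceding_residue`,
#'   `at_codon_index`, `host_entry`, `via_initiator`
#' @export
locate_peptide <- function(peptide, db) {
  stopifnot(inherits(db, "sixframe_db"), nchar(peptide) >= 1L)
  peptide <- toupper(peptide)
  m <- nchar(peptide)
  out <- list()
  for (key in names(db$frames)) {
    fi <- db$frames[[key]]
    if (fi$ncod < m) next
    hits <- literal_hits(fi$aa, peptide)
    via_init <- rep(FALSE, length(hits))
    if (substr(peptide, 1L, 1L) == "M") {
      # initiator rule: first residue Met may sit on GTG/TTG whose literal
      # translation is V/L
      tail_pep <- substr(peptide, 2L, m)
      cand <- if (m == 1L) seq_len(fi$ncod) else literal_hits(fi$aa, tail_pep) - 1L
      cand <- cand[cand >= 1L]
      if (length(cand)) {
        lit1 <- substring(fi$aa, cand, cand)
        alt <- cand[lit1 %in% c("V", "L")]
        alt <- alt[vapply(alt, function(c0)
          codon_at(db, fi$contig, fi$frame, c0) %in% db$start_codons, NA)]
        alt <- setdiff(alt, hits)
        if (length(alt)) {
          hits <- c(hits, alt)
          via_init <- c(via_init, rep(TRUE, length(alt)))
        }
      }
    }
    if (length(hits) == 0L) next
    for (j in seq_along(hits)) {
      c0 <- hits[j]
      if (c0 + m - 1L > fi$ncod) next
      sp <- codon_span(fi$frame, c0, c0 + m - 1L, fi$L)
      prev <- if (c0 == 1L) "^" else substring(fi$aa, c0 - 1L, c0 - 1L)
      out[[length(out) + 1L]] <- data.frame(
        peptide = peptide, contig = fi$contig,
        start = unname(sp["start"]), end = unname(sp["end"]),
        strand = if (fi$frame > 0L) "+" else "-", frame = fi$frame,
        codon_index = c0, preceding_residue = prev,
        via_initiator = via_init[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_match_frame())
  res <- do.call(rbind, out)
  res <- host_matches(res, db)
  res <- res[order(res$contig, res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

literal_hits <- function(aa_string, pattern) {
  g <- gregexpr(pattern, aa_string, fixed = TRUE)[[1L]]
  if (g[1L] == -1L) return(integer(0))
  as.integer(g)
}

empty_match_frame <- function() {
  data.frame(peptide = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), codon_index = integer(0),
             preceding_residue = character(0), via_initiator = logical(0),
             host_entry = character(0), at_codon_index = integer(0),
             stringsAsFactors = FALSE)
}

# Attach host entry (the stop-free segment containing the match) and the
# codon index relative to the entry's compacted start codon. Matches inside
# a segment but upstream of the entry start get at_codon_index <= 0;
# matches in segments with no database entry host NA.
host_matches <- function(matches, db) {
  loci <- db$loci
  matches$host_entry <- NA_character_
  matches$at_codon_index <- NA_integer_
  if (nrow(matches) == 0L || nrow(loci) == 0L) return(matches)
  lkey <- paste(loci$contig, loci$frame)
  mkey <- paste(matches$contig, matches$frame)
  for (key in unique(mkey)) {
    li <- which(lkey == key)
    if (length(li) == 0L) next
    mi <- which(mkey == key)
    o <- li[order(loci$seg_begin[li])]  # segments are disjoint per frame
    pos <- findInterval(matches$codon_index[mi], loci$seg_begin[o])
    ok <- pos >= 1L
    ok[ok] <- matches$codon_index[mi][ok] <= loci$seg_end[o][pos[ok]]
    sel <- mi[ok]
    lsel <- o[pos[ok]]
    matches$host_entry[sel] <- loci$entry_id[lsel]
    matches$at_codon_index[sel] <-
      matches$codon_index[sel] - loci$codon_start[lsel] + 1L
  }
  matches
}

#' Classify mapping uniqueness of a peptide's genome matches
#'
#' `unique`: exactly one placement. `paralog_unique`: several placements
#' that all fall at the same residue offset inside one merged (paralogous)
#' entry. Anything else is `ambiguous` and is excluded from annotation
#' refinement. Peptides with no placement are `unmapped`.
#' @param matches output of [locate_peptide()]
#' @return one of `"unique"`, `"paralog_unique"`, `"ambiguous"`, `"unmapped"`
#' @export
classify_mapping <- function(matches) {
  n <- nrow(matches)
  if (n == 0L) return("unmapped")
  if (n == 1L) return("unique")
  hosts <- unique(matches$host_entry)
  offs <- unique(matches$at_codon_index)
  # all placements at one residue offset within one merged entry, reached
  # the same way (mixed literal/initiator placements stay ambiguous)
  if (length(hosts) == 1L && !anyNA(hosts) && length(offs) == 1L &&
      length(unique(matches$via_initiator)) == 1L)
    return("paralog_unique")
  "ambiguous"
}

#' Classify peptides as annotated or genome-search-specific (GSSP)
#'
#' A peptide is `annotated` iff its sequence is a substring of some
#' reference protein (the initiator-Met-removed form of a reference is a
#' substring of the full form, so it is covered); otherwise it is a
#' `gssp`. Decoy records are never classified.
#' @param sequences character vector of peptide sequences
#' @param reference named character vector of reference proteins
#' @return character vector `"annotated"`/`"gssp"`
#' @export
classify_gssp <- function(sequences, reference) {
  haystack <- paste(reference, collapse = "|")
  ifelse(vapply(sequences, function(s)
    grepl(s, haystack, fixed = TRUE), NA), "annotated", "gssp")
}

#' Map a set of peptide records onto the genome
#'
#' Runs [locate_peptide()] once per distinct non-decoy sequence, classifies
#' mapping uniqueness and (when a reference is attached to the database)
#' annotation status.
#' @param records peptide records
#' @param db `sixframe_db`
#' @return list with `matches` (all placements) and `peptides` (one row per
#'   distinct sequence: `sequence`, `mapping_class`, `host_entry`,
#'   `at_codon_index`, `status`)
#' @export
map_peptides <- function(records, db) {
  seqs <- unique(records$sequence[!records$is_decoy])
  all_matches <- lapply(seqs, locate_peptide, db = db)
  names(all_matches) <- seqs
  cls <- vapply(all_matches, classify_mapping, "")
  host <- vapply(all_matches, function(m) {
    h <- unique(m$host_entry)
    if (length(h) == 1L) h else NA_character_
  }, "")
  atc <- vapply(all_matches, function(m) {
    a <- unique(m$at_codon_index)
    if (length(a) == 1L) a else NA_integer_
  }, 1L)
  status <- if (!is.null(db$reference))
    classify_gssp(seqs, db$reference) else rep(NA_character_, length(seqs))
  matches <- if (length(all_matches)) do.call(rbind, all_matches) else
    empty_match_frame()
  rownames(matches) <- NULL
  list(matches = matches,
       peptides = data.frame(sequence = seqs, mapping_class = unname(cls),
                             host_entry = unname(host),
                             at_codon_index = unname(atc),
                             status = unname(status),
                             stringsAsFactors = FALSE))
}

#' Aggregate identified peptides per ORF across database searches
#'
#' ORF key is the host six-frame entry (merged paralogs count once). The
#' peptide set is the union of distinct unique/paralog-unique sequences
#' across all source databases, with per-database provenance; ORFs with no
#' unique-or-paralog-unique peptide are dropped.
#' @param records peptide records from one or more searches
#' @param maps output of [map_peptides()]
#' @return data.frame: `entry_id`, `n_peptides`, `peptides` (list-column),
#'   `source_dbs` (list-column), plus per-peptide provenance in the
#'   `"provenance"` attribute
#' @export
aggregate_per_orf <- function(records, maps) {
  pep <- maps$peptides
  usable <- pep[pep$mapping_class %in% c("unique", "paralog_unique") &
                  !is.na(pep$host_entry), , drop = FALSE]
  if (nrow(usable) == 0L) {
    out <- data.frame(entry_id = character(0), n_peptides = integer(0),
                      stringsAsFactors = FALSE)
    out$peptides <- list(); out$source_dbs <- list()
    return(out)
  }
  prov <- tapply(records$source_db, records$sequence,
                 function(x) sort(unique(x)))
  orf_ids <- sort(unique(usable$host_entry))
  out <- data.frame(entry_id = orf_ids, stringsAsFactors = FALSE)
  out$peptides <- lapply(orf_ids, function(id)
    sort(usable$sequence[usable$host_entry == id]))
  out$n_peptides <- lengths(out$peptides)
  out$source_dbs <- lapply(out$peptides, function(pp)
    sort(unique(unlist(prov[pp]))))
  attr(out, "provenance") <- prov
  out[, c("entry_id", "n_peptides", "peptides", "source_dbs")]
}
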