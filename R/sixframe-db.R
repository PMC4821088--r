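# Compacted six-frame translation database.
#
# Each of the six reading frames of every contig is partitioned at stop
# codons. Within a stop-free segment the most upstream in-frame start codon
# (ATG/GTG/TTG by default) defines the database entry, translated with the
# initiator rendered as Met and the stop excluded. Terminal segments that
# run off the end of a frame without a stop are retained and flagged.
# Entries with identical translated sequences (paralogs, e.g. transposon
# duplications) are merged into one record with multiple coordinate tuples.

#' Extract compacted six-frame entries from a genome
#'
#' @param genome anything accepted by [load_genome()]
#' @param min_len minimum translated product length in residues (the
#'   initiator Met counts); shorter entries are discarded
#' @param start_codons candidate initiator codons
#' @return a data.frame with one row per (pre-merge) entry: `entry_id`,
#'   `protein`, `start_codon`, `has_stop`, `contig`, `frame` (signed
#'   +1..+3/-1..-3), `strand`, `codon_start`/`codon_end` (frame codon
#'   indices of the product), `seg_begin`/`seg_end` (codon bounds of the
#'   host stop-free segment), `start`/`end` (forward genomic coordinates,
#'   stop codon excluded) and a `coords` list-column
#' @export
extract_sixframe_entries <- function(genome, min_len = 20L,
                                     start_codons = DEFAULT_START_CODONS) {
  genome <- load_genome(genome)
  stopifnot(min_len >= 1L)
  rows <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    L <- nchar(seq)
    rcseq <- revcomp(seq)
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      s <- if (fr > 0L) seq else rcseq
      codons <- frame_codons(s, abs(fr))
      ncod <- length(codons)
      if (ncod == 0L) next
      aa <- translate_codons(codons)
      stops <- which(aa == "*")
      seg_begin <- c(1L, stops + 1L)
      seg_end <- c(stops - 1L, ncod)
      keep <- seg_begin <= seg_end
      seg_begin <- seg_begin[keep]
      seg_end <- seg_end[keep]
      # the final segment lacks a stop iff the frame does not end in one
      terminal_open <- length(stops) == 0L || stops[length(stops)] != ncod
      for (k in seq_along(seg_begin)) {
        b0 <- seg_begin[k]; e0 <- seg_end[k]
        idx <- b0:e0
        is_start <- codons[idx] %in% start_codons
        if (!any(is_start)) next
        a <- idx[which(is_start)[1L]]
        len <- e0 - a + 1L
        if (len < min_len) next
        prot <- paste0("M", paste(aa[seq.int(a + 1L, length.out = len - 1L)],
                                  collapse = ""))
        sp <- codon_span(fr, a, e0, L)
        rows[[length(rows) + 1L]] <- list(
          protein = prot,
          start_codon = codons[a],
          has_stop = !(k == length(seg_begin) && terminal_open),
          contig = ctg, frame = fr,
          strand = if (fr > 0L) "+" else "-",
          codon_start = a, codon_end = e0,
          seg_begin = b0, seg_end = e0,
          start = unname(sp["start"]), end = unname(sp["end"]))
      }
    }
  }
  if (length(rows) == 0L) {
    return(empty_entry_frame())
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df <- df[order(df$contig, df$start, df$frame), , drop = FALSE]
  df$entry_id <- sprintf("sf%05d", seq_len(nrow(df)))
  df$coords <- lapply(seq_len(nrow(df)), function(i) {
    df[i, c("contig", "start", "end", "strand", "frame",
            "codon_start", "codon_end", "seg_begin", "seg_end")]
  })
  df$ref_accession <- NA_character_
  df$ref_offset_aa <- NA_integer_
  df$ref_identical <- NA
  df$ref_ambiguous <- FALSE
  rownames(df) <- NULL
  df[, entry_columns()]
}

entry_columns <- function() {
  c("entry_id", "protein", "start_codon", "has_stop", "contig", "frame",
    "strand", "codon_start", "codon_end", "seg_begin", "seg_end", "start",
    "end", "coords", "ref_accession", "ref_offset_aa", "ref_identical",
    "ref_ambiguous")
}

empty_entry_frame <- function() {
  df <- data.frame(entry_id = character(0), protein = character(0),
                   start_codon = character(0), has_stop = logical(0),
                   contig = character(0), frame = integer(0),
                   strand = character(0), codon_start = integer(0),
                   codon_end = integer(0), seg_begin = integer(0),
                   seg_end = integer(0), start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  df$coords <- list()
  df$ref_accession <- character(0)
  df$ref_offset_aa <- integer(0)
  df$ref_identical <- logical(0)
  df$ref_ambiguous <- logical(0)
  df
}

#' Merge entries with identical translated sequences
#'
#' Duplicated translated ORF products (paralogous loci) are combined into a
#' single entry whose `coords` list-column holds every source coordinate
#' tuple, ordered by ascending genomic start.
#' @param entries output of [extract_sixframe_entries()]
#' @return entries data.frame with pairwise-distinct `protein` sequences
#' @export
deduplicate_entries <- function(entries) {
  if (nrow(entries) == 0L) return(entries)
  grp <- match(entries$protein, unique(entries$protein))
  keep <- !duplicated(grp)
  out <- entries[keep, , drop = FALSE]
  out$coords <- lapply(unique(grp), function(g) {
    cc <- do.call(rbind, entries$coords[grp == g])
    cc[order(cc$start), , drop = FALSE]
  })
  out$entry_id <- sprintf("sf%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Build a six-frame database object
#'
#' Convenience constructor running extraction and paralog merging and
#' caching the per-frame translations used by the dynamic peptide scan.
#' @inheritParams extract_sixframe_entries
#' @return an object of class `sixframe_db` with components `entries`,
#'   `genome`, `frames` (per contig/frame literal translations) and `loci`
#'   (one row per coordinate tuple, linking back to merged entries)
#' @export
build_sixframe_db <- function(genome, min_len = 20L,
                              start_codons = DEFAULT_START_CODONS) {
  genome <- load_genome(genome)
  entries <- deduplicate_entries(
    extract_sixframe_entries(genome, min_len = min_len,
                             start_codons = start_codons))
  db <- structure(list(genome = genome, entries = entries,
                       min_len = min_len, start_codons = start_codons),
                  class = "sixframe_db")
  db$rc <- lapply(genome, revcomp)
  db$frames <- build_frame_index(genome)
  db$loci <- build_locus_table(entries)
  db
}

build_frame_index <- function(genome) {
  idx <- list()
  for (ctg in names(genome)) {
    seq <- genome[[ctg]]
    rcseq <- revcomp(seq)
    for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      s <- if (fr > 0L) seq else rcseq
      codons <- frame_codons(s, abs(fr))
      idx[[frame_key(ctg, fr)]] <- list(
        contig = ctg, frame = fr, L = nchar(seq),
        aa = paste(translate_codons(codons), collapse = ""),
        ncod = length(codons))
    }
  }
  idx
}

frame_key <- function(contig, frame) paste0(contig, "@", frame)

build_locus_table <- function(entries) {
  if (nrow(entries) == 0L) {
    return(data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), codon_start = integer(0),
                      codon_end = integer(0), seg_begin = integer(0),
                      seg_end = integer(0), start = integer(0),
                      end = integer(0), entry_id = character(0),
                      stringsAsFactors = FALSE))
  }
  loci <- do.call(rbind, lapply(seq_len(nrow(entries)), function(i) {
    cc <- entries$coords[[i]]
    cc$entry_id <- entries$entry_id[i]
    cc
  }))
  rownames(loci) <- NULL
  loci
}

# Codon (nucleotide triplet) at frame codon index i.
codon_at <- function(db, contig, frame, i) {
  seq <- if (frame < 0L) {
    if (!is.null(db$rc)) db$rc[[contig]] else revcomp(db$genome[[contig]])
  } else db$genome[[contig]]
  f <- abs(frame)
  substr(seq, f + 3L * (i - 1L), f + 3L * i - 1L)
}

#' Cross-map database entries to a reference proteome
#'
#' An entry maps to reference protein R when R equals the entry's suffix
#' starting `d >= 0` residues in; position 1 of R is Met-tolerant: an
#' initiator Met in R matches whatever the genome codon literally encodes
#' at that position (GTG/TTG initiation). `ref_offset_aa` records `d`, the
#' N-terminal overhang of the six-frame product relative to the annotated
#' protein. Entries matching more than one distinct reference are flagged
#' ambiguous and excluded from TSS accounting.
#'
#' @param db `sixframe_db` object (or deduplicated entries data.frame)
#' @param reference named character vector of reference proteins (or FASTA
#'   path, see [read_proteome()])
#' @return the input with reference fields populated
#' @export
map_reference <- function(db, reference) {
  is_db <- inherits(db, "sixframe_db")
  entries <- if (is_db) db$entries else db
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- read_proteome(reference)
  prot <- entries$protein
  plen <- nchar(prot)
  hits <- vector("list", nrow(entries))
  for (acc in names(reference)) {
    R <- reference[[acc]]
    rl <- nchar(R)
    if (rl < 1L) next
    cand <- which(plen >= rl)
    if (length(cand) == 0L) next
    tail_ok <- if (rl > 1L) {
      endsWith(prot[cand], substr(R, 2L, rl))
    } else rep(TRUE, length(cand))
    cand <- cand[tail_ok]
    if (length(cand) == 0L) next
    r1 <- substr(R, 1L, 1L)
    first_ok <- if (r1 == "M") rep(TRUE, length(cand)) else {
      substr(prot[cand], plen[cand] - rl + 1L, plen[cand] - rl + 1L) == r1
    }
    cand <- cand[first_ok]
    for (i in cand) hits[[i]] <- c(hits[[i]], acc)
  }
  nh <- lengths(hits)
  entries$ref_accession <- NA_character_
  entries$ref_offset_aa <- NA_integer_
  entries$ref_identical <- NA
  entries$ref_ambiguous <- nh > 1L
  one <- which(nh == 1L)
  if (length(one)) {
    accs <- vapply(hits[one], `[`, "", 1L)
    entries$ref_accession[one] <- accs
    d <- plen[one] - nchar(reference[accs])
    entries$ref_offset_aa[one] <- as.integer(d)
    entries$ref_identical[one] <- d == 0L
  }
  if (any(nh > 1L)) {
    attr(entries, "ambiguous_refs") <- lapply(which(nh > 1L), function(i)
      list(entry_id = entries$entry_id[i], accessions = hits[[i]]))
  }
  if (is_db) {
    db$entries <- entries
    db$reference <- reference
    db
  } else entries
}

#' Ingest ab initio gene predictions
#'
#' Reads predicted genes (FASTA with a `coords=contig:start-end(strand)`
#' header token, or a data.frame with columns `pred_id`, `protein`,
#' `contig`, `start`, `end`, `strand`) and verifies each by re-translating
#' its genomic span, initiator rendered as Met. Records that disagree with
#' the genome (wrong strand, shifted coordinates, sequence mismatch) are
#' excluded and reported via the `"mismatches"` attribute.
#'
#' @param predictions FASTA path or data.frame as above
#' @param genome anything accepted by [load_genome()]
#' @return data.frame of verified predictions with frame/codon columns
#' @export
ingest_predictions <- function(predictions, genome) {
  genome <- load_genome(genome)
  if (is.character(predictions) && length(predictions) == 1L) {
    ss <- Biostrings::readBStringSet(predictions)
    hdr <- names(ss)
    tok <- regmatches(hdr, regexpr("coords=[^| ]+", hdr))
    if (length(tok) != length(hdr))
      stop("prediction FASTA headers must carry a coords=contig:start-end(strand) token")
    m <- regmatches(tok, regexec("coords=([^:]+):(\\d+)-(\\d+)\\(([+-])\\)", tok))
    predictions <- data.frame(
      pred_id = sub("\\s.*$", "", hdr),
      protein = toupper(as.character(ss)),
      contig = vapply(m, `[`, "", 2L),
      start = as.integer(vapply(m, `[`, "", 3L)),
      end = as.integer(vapply(m, `[`, "", 4L)),
      strand = vapply(m, `[`, "", 5L),
      stringsAsFactors = FALSE)
  }
  if (nrow(predictions) == 0L) {
    predictions$frame <- integer(0)
    predictions$codon_start <- integer(0)
    attr(predictions, "mismatches") <- character(0)
    return(predictions)
  }
  bad <- character(0)
  keep <- logical(nrow(predictions))
  frames <- integer(nrow(predictions))
  cstarts <- integer(nrow(predictions))
  for (i in seq_len(nrow(predictions))) {
    p <- predictions[i, ]
    if (!p$contig %in% names(genome)) { bad <- c(bad, p$pred_id); next }
    L <- nchar(genome[[p$contig]])
    if (p$start < 1L || p$end > L || p$start >= p$end) { bad <- c(bad, p$pred_id); next }
    # coding span may or may not include the stop codon; accept either
    for (drop_stop in c(0L, 3L)) {
      end2 <- p$end; start2 <- p$start
      if (drop_stop == 3L) {
        if (p$strand == "+") end2 <- p$end - 3L else start2 <- p$start + 3L
      }
      sc <- span_to_codons(start2, end2, p$strand, L)
      if (is.null(sc)) next
      seqs <- genome[[p$contig]]
      s <- if (p$strand == "+") seqs else revcomp(seqs)
      codons <- frame_codons(s, abs(sc$frame))
      if (sc$b > length(codons)) next
      aa <- translate_codons(codons[sc$a:sc$b])
      if (any(aa == "*")) next
      got <- paste0("M", paste(aa[-1L], collapse = ""))
      if (identical(got, p$protein)) {
        keep[i] <- TRUE
        frames[i] <- sc$frame
        cstarts[i] <- sc$a
        break
      }
    }
    if (!keep[i]) bad <- c(bad, p$pred_id)
  }
  out <- predictions[keep, , drop = FALSE]
  out$frame <- frames[keep]
  out$codon_start <- cstarts[keep]
  rownames(out) <- NULL
  attr(out, "mismatches") <- bad
  out
}

#' Write the database as FASTA with coordinate-bearing headers
#'
#' Header grammar:
#' \verb{>sf|{entry_id}|coords={contig}:{start}-{end}({strand})[;...]|ref={acc}|offset={d}}
#' with absent reference fields omitted. Coordinate tokens of merged
#' entries are joined by `;` in ascending start order.
#' @param entries deduplicated entries (or a `sixframe_db`)
#' @param path output file
#' @export
write_database_fasta <- function(entries, path) {
  if (inherits(entries, "sixframe_db")) entries <- entries$entries
  headers <- vapply(seq_len(nrow(entries)), function(i) {
    cc <- entries$coords[[i]]
    cc <- cc[order(cc$start), , drop = FALSE]
    coords <- paste(sprintf("%s:%d-%d(%s)", cc$contig, cc$start, cc$end,
                            cc$strand), collapse = ";")
    h <- sprintf("sf|%s|coords=%s", entries$entry_id[i], coords)
    if (!is.na(entries$ref_accession[i]))
      h <- sprintf("%s|ref=%s|offset=%d", h, entries$ref_accession[i],
                   entries$ref_offset_aa[i])
    h
  }, "")
  seqs <- entries$protein
  names(seqs) <- headers
  write_fasta(seqs, path)
}

#' Parse a database FASTA written by [write_database_fasta()]
#' @param path FASTA file
#' @return data.frame with `entry_id`, `protein`, `coords` (list-column),
#'   `ref_accession`, `ref_offset_aa`
#' @export
parse_database_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- names(ss)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  entry_id <- vapply(parts, `[`, "", 2L)
  coords <- lapply(parts, function(p) {
    tok <- sub("^coords=", "", p[3L])
    m <- regmatches(strsplit(tok, ";", fixed = TRUE)[[1L]],
                    regexec("^([^:]+):(\\d+)-(\\d+)\\(([+-])\\)$",
                            strsplit(tok, ";", fixed = TRUE)[[1L]]))
    data.frame(contig = vapply(m, `[`, "", 2L),
               start = as.integer(vapply(m, `[`, "", 3L)),
               end = as.integer(vapply(m, `[`, "", 4L)),
               strand = vapply(m, `[`, "", 5L),
               stringsAsFactors = FALSE)
  })
  ref_acc <- rep(NA_character_, length(hdr))
  ref_off <- rep(NA_integer_, length(hdr))
  has_ref <- lengths(parts) >= 5L
  ref_acc[has_ref] <- sub("^ref=", "", vapply(parts[has_ref], `[`, "", 4L))
  ref_off[has_ref] <- as.integer(sub("^offset=", "",
                                     vapply(parts[has_ref], `[`, "", 5L)))
  out <- data.frame(entry_id = entry_id, protein = as.character(ss),
                    stringsAsFactors = FALSE)
  out$coords <- coords
  out$ref_accession <- ref_acc
  out$ref_offset_aa <- ref_off
  out
}
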