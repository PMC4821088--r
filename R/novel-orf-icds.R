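# Novel ORF calling with tiered evidence, and interrupted coding sequence
# (ICDS) detection from cross-frame ORF adjacency, shared homology and
# frameshift-spanning reference proteins.

#' Load and filter a protein/nucleotide homology table
#'
#' 12-column tabular alignment format (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Alignments above the E-value cutoff are dropped; when `best_per_query`
#' the highest-scoring alignment by E-value is kept per query.
#' @param x path to a tabular file or an equivalent data.frame
#' @param evalue_cutoff maximum E-value retained
#' @param best_per_query keep only the best alignment per query
#' @export
read_homology_table <- function(x, evalue_cutoff = 1e-4,
                                best_per_query = TRUE) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- if (is.data.frame(x)) x else
    utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE)
  if (!all(cols %in% names(tab))) names(tab)[seq_along(cols)] <- cols
  tab <- tab[tab$evalue <= evalue_cutoff, , drop = FALSE]
  if (best_per_query && nrow(tab) > 0L) {
    tab <- tab[order(tab$query, tab$evalue), , drop = FALSE]
    tab <- tab[!duplicated(tab$query), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Same-strand transcript overlap
#'
#' TRUE iff the ORF shares at least one nucleotide with a transcript
#' feature on the same contig and strand.
#' @param orf_coords one coordinate row (`contig`, `start`, `end`,
#'   `strand`)
#' @param transcripts data.frame of features with the same four columns
#' @export
overlap_cdna <- function(orf_coords, transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) return(FALSE)
  any(transcripts$contig == orf_coords$contig &
        transcripts$strand == orf_coords$strand &
        transcripts$start <= orf_coords$end &
        transcripts$end >= orf_coords$start)
}

#' Call novel ORFs with tiered supporting evidence
#'
#' Considers peptide-supported ORFs without a reference link; only GSSPs
#' count as support. Tiers: `multi_peptide` (>= 2 GSSPs),
#' `single_supported` (1 GSSP plus protein homology, transcript BLAST or
#' same-strand transcript overlap), `excluded` (1 GSSP, no support;
#' retained in the output with its reason). Calls are ranked by GSSP
#' count, protein homology, transcript BLAST and transcript overlap, ties
#' broken by genomic coordinate.
#'
#' @param db `sixframe_db` with reference mapped
#' @param agg per-ORF aggregation from [aggregate_per_orf()]
#' @param maps output of [map_peptides()]
#' @param homology optional protein homology table (see
#'   [read_homology_table()]; queries are entry ids)
#' @param cdna_blast optional nucleotide homology table against transcripts
#' @param transcripts optional transcript features (`contig`, `start`,
#'   `end`, `strand`)
#' @return data.frame of novel ORF calls, ranked
#' @export
call_novel_orfs <- function(db, agg, maps, homology = NULL,
                            cdna_blast = NULL, transcripts = NULL) {
  entries <- db$entries
  idx <- match(agg$entry_id, entries$entry_id)
  novel <- which(is.na(entries$ref_accession[idx]) &
                   !entries$ref_ambiguous[idx])
  out <- list()
  for (i in novel) {
    eid <- agg$entry_id[i]
    peps <- agg$peptides[[i]]
    st <- maps$peptides$status[match(peps, maps$peptides$sequence)]
    gssps <- peps[!is.na(st) & st == "gssp"]
    if (length(gssps) == 0L) next
    entry <- entries[match(eid, entries$entry_id), ]
    cc <- entry$coords[[1L]][1L, ]
    hom <- !is.null(homology) && eid %in% homology$query
    cbl <- !is.null(cdna_blast) && eid %in% cdna_blast$query
    cov <- overlap_cdna(cc, transcripts)
    tier <- if (length(gssps) >= 2L) "multi_peptide"
            else if (hom || cbl || cov) "single_supported"
            else "excluded"
    row <- data.frame(entry_id = eid, contig = cc$contig, start = cc$start,
                      end = cc$end, strand = cc$strand, frame = cc$frame,
                      n_peptides = length(gssps), tier = tier,
                      has_homology = hom, cdna_blast_hit = cbl,
                      cdna_overlap = cov,
                      homology_subject = if (hom)
                        homology$subject[match(eid, homology$query)]
                      else NA_character_,
                      reason = if (tier == "excluded")
                        "single peptide, no supporting evidence"
                      else NA_character_,
                      stringsAsFactors = FALSE)
    row$peptides <- list(gssps)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    res <- data.frame(entry_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      n_peptides = integer(0), tier = character(0),
                      has_homology = logical(0), cdna_blast_hit = logical(0),
                      cdna_overlap = logical(0),
                      homology_subject = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
    res$peptides <- list()
    res$rank <- integer(0)
    return(res)
  }
  res <- do.call(rbind, out)
  ord <- order(-res$n_peptides, -res$has_homology, -res$cdna_blast_hit,
               -res$cdna_overlap, res$contig, res$start)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# peptide-evidence genomic span per entry: min start / max end over
# supporting (unique/paralog-unique) matches hosted by the entry
peptide_spans <- function(agg, maps) {
  mm <- maps$matches
  spans <- lapply(seq_len(nrow(agg)), function(i) {
    sel <- mm$host_entry == agg$entry_id[i] & mm$peptide %in% agg$peptides[[i]]
    if (!any(sel)) return(c(NA_integer_, NA_integer_))
    c(min(mm$start[sel]), max(mm$end[sel]))
  })
  data.frame(entry_id = agg$entry_id,
             pep_min = vapply(spans, `[`, 1L, 1L),
             pep_max = vapply(spans, `[`, 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Detect candidate interrupted coding sequences (ICDSs)
#'
#' Candidate pairs are same-strand, different-frame, peptide-supported,
#' non-paralogous ORFs without a reference link whose spans overlap or lie
#' within `max_gap_nt`. The junction window runs between the facing
#' peptide-evidence boundaries of the two ORFs (the region a frameshift
#' must occupy). A shared homology subject with compatible (ordered,
#' essentially non-overlapping) aligned spans upgrades the call; pairs
#' without shared homology rank lower since adjacent separate genes cannot
#' be excluded.
#'
#' @param db `sixframe_db` with reference mapped
#' @param agg per-ORF aggregation
#' @param maps output of [map_peptides()]
#' @param homology optional homology table with per-ORF alignments
#'   (filtered, not necessarily best-per-query)
#' @param max_gap_nt maximum intervening genomic distance
#' @return data.frame of ICDS calls
#' @export
detect_icds_pairs <- function(db, agg, maps, homology = NULL,
                              max_gap_nt = 100L) {
  entries <- db$entries
  idx <- match(agg$entry_id, entries$entry_id)
  cand <- which(is.na(entries$ref_accession[idx]) &
                  !entries$ref_ambiguous[idx] &
                  vapply(entries$coords[idx], nrow, 1L) == 1L)
  if (length(cand) < 2L) return(empty_icds_frame())
  sp <- peptide_spans(agg, maps)
  info <- do.call(rbind, lapply(cand, function(i) {
    e <- entries[idx[i], ]
    cc <- e$coords[[1L]][1L, ]
    data.frame(entry_id = e$entry_id, contig = cc$contig, start = cc$start,
               end = cc$end, strand = cc$strand, frame = cc$frame,
               pep_min = sp$pep_min[i], pep_max = sp$pep_max[i],
               stringsAsFactors = FALSE)
  }))
  info <- info[order(info$contig, info$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(info) - 1L)) {
    for (j in seq.int(i + 1L, nrow(info))) {
      a <- info[i, ]; b <- info[j, ]
      if (a$contig != b$contig) break
      gap <- b$start - a$end - 1L
      if (gap > max_gap_nt) break
      if (a$strand != b$strand || a$frame == b$frame) next
      # order in translation direction by peptide evidence (ORF bounds can
      # mislead: the shifted-frame half's segment may begin upstream of
      # the gene)
      left <- if (a$pep_min <= b$pep_min) a else b
      right <- if (a$pep_min <= b$pep_min) b else a
      up <- if (a$strand == "+") left else right
      dn <- if (a$strand == "+") right else left
      # junction window: the region between the facing peptide-evidence
      # edges (the intersection-side interval when the spans overlap)
      inner <- sort(c(min(a$pep_max, b$pep_max), max(a$pep_min, b$pep_min)))
      shared <- NA_character_
      if (!is.null(homology)) {
        ha <- homology[homology$query == up$entry_id, , drop = FALSE]
        hb <- homology[homology$query == dn$entry_id, , drop = FALSE]
        common <- intersect(ha$subject, hb$subject)
        for (s in common) {
          sa <- ha[ha$subject == s, , drop = FALSE][1L, ]
          sb <- hb[hb$subject == s, , drop = FALSE][1L, ]
          # upstream ORF must align upstream on the subject, spans ordered
          if (min(sa$sstart, sa$send) <= min(sb$sstart, sb$send) &&
              max(sa$sstart, sa$send) <= max(sb$sstart, sb$send) + 10L) {
            shared <- s
            break
          }
        }
      }
      status <- if (!is.na(shared) && !is.null(db$reference) &&
                    shared %in% names(db$reference)) "known_validated"
                else "novel_candidate"
      out[[length(out) + 1L]] <- data.frame(
        upstream_orf = up$entry_id, downstream_orf = dn$entry_id,
        contig = a$contig, strand = a$strand,
        frames = paste(up$frame, dn$frame, sep = "/"),
        relationship = if (gap < 0L) "overlapping" else "adjacent",
        gap_or_overlap_nt = gap,
        junction_start = inner[1L], junction_end = inner[2L],
        shared_homology_subject = shared, status = status,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_icds_frame())
  res <- do.call(rbind, out)
  res <- res[order(is.na(res$shared_homology_subject), res$contig,
                   res$junction_start), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

empty_icds_frame <- function() {
  data.frame(upstream_orf = character(0), downstream_orf = character(0),
             contig = character(0), strand = character(0),
             frames = character(0), relationship = character(0),
             gap_or_overlap_nt = integer(0), junction_start = integer(0),
             junction_end = integer(0), shared_homology_subject = character(0),
             status = character(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

#' Detect reference proteins spanning a genomic frameshift
#'
#' For reference proteins that fail single-ORF mapping, searches for a
#' split into a prefix and suffix mapping to two different frames at
#' nearby loci. The junction is reported as the residue interval
#' compatible with both fragment placements (an exact split gives a
#' two-residue window around the lost codon); identified peptides whose
#' residue span covers the junction are flagged as frameshift-spanning
#' evidence.
#'
#' @param db `sixframe_db` with reference mapped
#' @param records optional peptide records; sequences that are substrings
#'   of the split protein and cover the junction provide peptide-level
#'   support
#' @param max_dist maximum genomic distance between fragment placements
#' @param min_frag minimum fragment length in residues
#' @return data.frame of split-mapping reports (one row per protein with a
#'   consistent split; inconsistent proteins reported with status
#'   `unmappable`)
#' @export
detect_reference_frameshift <- function(db, records = NULL, max_dist = 1000L,
                                        min_frag = 7L) {
  stopifnot(!is.null(db$reference))
  mapped <- db$entries$ref_accession
  amb <- attr(db$entries, "ambiguous_refs")
  mapped <- c(mapped, unlist(lapply(amb, `[[`, "accessions")))
  unmapped <- setdiff(names(db$reference), mapped[!is.na(mapped)])
  out <- list()
  for (acc in unmapped) {
    R <- db$reference[[acc]]
    L <- nchar(R)
    if (L < 2L * min_frag) next
    pre <- locate_peptide(substr(R, 1L, min_frag), db)
    suf <- locate_peptide(substr(R, L - min_frag + 1L, L), db)
    best <- NULL
    for (ip in seq_len(nrow(pre))) {
      pm <- pre[ip, ]
      fi <- db$frames[[frame_key(pm$contig, pm$frame)]]
      plen <- extend_match(fi$aa, pm$codon_index, R, from = 2L,
                           seed_len = min_frag)
      for (is_ in seq_len(nrow(suf))) {
        sm <- suf[is_, ]
        if (sm$contig != pm$contig || sm$strand != pm$strand ||
            sm$frame == pm$frame) next
        gfi <- db$frames[[frame_key(sm$contig, sm$frame)]]
        sstart_res <- L - min_frag + 1L
        slen <- extend_match_back(gfi$aa, sm$codon_index, R, sstart_res)
        b_start <- L - min_frag + 1L - slen  # first residue the suffix covers
        uncovered <- b_start - plen - 1L
        if (uncovered > 2L) next
        gdist <- abs(sm$start - pm$end)
        if (gdist > max_dist) next
        jmin <- min(plen, b_start - 1L)
        jmax <- max(plen, b_start - 1L)
        cand <- list(junction_min = jmin, junction_max = jmax,
                     gdist = gdist, pm = pm, sm = sm)
        if (is.null(best) || gdist < best$gdist) best <- cand
      }
    }
    if (is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        accession = acc, junction_min = NA_integer_,
        junction_max = NA_integer_, prefix_frame = NA_integer_,
        suffix_frame = NA_integer_, contig = NA_character_,
        strand = NA_character_, evidence = "unmappable",
        stringsAsFactors = FALSE)
      next
    }
    evid <- "mapping_only"
    span_peps <- character(0)
    if (!is.null(records)) {
      seqs <- unique(records$sequence[!records$is_decoy])
      for (s in seqs) {
        p0 <- regexpr(s, R, fixed = TRUE)
        if (p0 == -1L) next
        i0 <- as.integer(p0); i1 <- i0 + nchar(s) - 1L
        if (i0 <= best$junction_min && i1 >= best$junction_max + 1L)
          span_peps <- c(span_peps, s)
      }
      if (length(span_peps)) evid <- "peptide_spanning"
    }
    row <- data.frame(
      accession = acc, junction_min = best$junction_min,
      junction_max = best$junction_max, prefix_frame = best$pm$frame,
      suffix_frame = best$sm$frame, contig = best$pm$contig,
      strand = best$pm$strand, evidence = evid, stringsAsFactors = FALSE)
    row$spanning_peptides <- list(span_peps)
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0L) {
    res <- data.frame(accession = character(0), junction_min = integer(0),
                      junction_max = integer(0), prefix_frame = integer(0),
                      suffix_frame = integer(0), contig = character(0),
                      strand = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
    res$spanning_peptides <- list()
    return(res)
  }
  res <- do.call(rbind, lapply(out, function(r) {
    if (is.null(r$spanning_peptides)) r$spanning_peptides <- list(character(0))
    r
  }))
  rownames(res) <- NULL
  res
}

# residues of R matched forward from a seed placement: the seed covers
# R[1..seed_len] at frame codon c0; extend past the seed and return the
# total matched prefix length
extend_match <- function(aa, c0, R, from, seed_len) {
  L <- nchar(R)
  n <- nchar(aa)
  k <- seed_len
  while (k < L) {
    pos <- c0 + k
    if (pos > n) break
    if (substring(aa, pos, pos) != substring(R, k + 1L, k + 1L)) break
    k <- k + 1L
  }
  k
}

# residues matched backward from a seed placed at R[sstart_res..L]; returns
# how many extra residues before sstart_res match
extend_match_back <- function(aa, c0, R, sstart_res) {
  k <- 0L
  while (sstart_res - k - 1L >= 1L && c0 - k - 1L >= 1L) {
    if (substring(aa, c0 - k - 1L, c0 - k - 1L) !=
        substring(R, sstart_res - k - 1L, sstart_res - k - 1L)) break
    k <- k + 1L
  }
  k
}
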