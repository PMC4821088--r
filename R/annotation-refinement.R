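# TSS peptide classification and gene model verdicts.
#
# TSS evidence comes in two forms: peptides whose first residue is an
# initiator Met sitting on a start codon with a non-tryptic (or
# N-acetylated) N terminus, and N-Met-cleaved peptides whose first residue
# sits immediately after an in-frame start codon. Per reference-linked ORF
# the pipeline issues at most one of: TSS validation, upstream extension
# (exact TSS or next-upstream-start-codon), or downstream start; evidence
# for several distinct initiation points is reported separately as
# multiple initiation.

TRYPTIC_RESIDUES <- c("K", "R")

#' Classify TSS evidence for peptide-genome matches
#'
#' @param matches match rows from [locate_peptide()]/[map_peptides()]
#' @param db `sixframe_db`
#' @param acetylated logical vector (recycled) marking records carrying
#'   N-terminal acetylation
#' @return the matches with columns added: `tss_kind` (`initiator_met`,
#'   `nmet_cleaved` or NA), `penultimate` (first residue of an
#'   N-Met-cleaved peptide, second residue of an initiator peptide),
#'   `tss_start_codon`, `init_codon_index` (frame codon index of the
#'   initiation codon), `init_at_index` (relative to the host entry start
#'   codon), `init_coord` (genomic 5' coordinate of initiation),
#'   `tss_indeterminate` (Met-at-start where N-Met cleavage and downstream
#'   initiation cannot be discriminated) and `adjacent_upstream_start`
#'   (N-Met-cleaved peptide whose own first codon is a start codon)
#' @export
classify_tss_peptides <- function(matches, db, acetylated = FALSE) {
  n <- nrow(matches)
  acetylated <- rep_len(acetylated, n)
  kind <- rep(NA_character_, n)
  penu <- rep(NA_character_, n)
  scod <- rep(NA_character_, n)
  init_ci <- rep(NA_integer_, n)
  indet <- rep(FALSE, n)
  adj_up <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- matches[i, ]
    c0 <- m$codon_index
    this_codon <- codon_at(db, m$contig, m$frame, c0)
    prev_codon <- if (c0 > 1L) codon_at(db, m$contig, m$frame, c0 - 1L) else ""
    first_res <- substr(m$peptide, 1L, 1L)
    on_start <- this_codon %in% db$start_codons
    after_start <- prev_codon %in% db$start_codons
    is_init <- first_res == "M" && on_start &&
      (!(m$preceding_residue %in% TRYPTIC_RESIDUES) || acetylated[i])
    if (is_init) {
      kind[i] <- "initiator_met"
      penu[i] <- substr(m$peptide, 2L, 2L)
      scod[i] <- this_codon
      init_ci[i] <- c0
      indet[i] <- after_start  # Met on a start codon preceded by a start
    } else if (after_start) {
      kind[i] <- "nmet_cleaved"
      penu[i] <- first_res
      scod[i] <- prev_codon
      init_ci[i] <- c0 - 1L
      adj_up[i] <- on_start  # e.g. Val on GTG: possible adjacent upstream start
    }
  }
  matches$tss_kind <- kind
  matches$penultimate <- penu
  matches$tss_start_codon <- scod
  matches$init_codon_index <- init_ci
  matches$init_at_index <- init_ci - (matches$codon_index - matches$at_codon_index)
  matches$init_coord <- NA_integer_
  has <- !is.na(init_ci)
  if (any(has)) {
    matches$init_coord[has] <- vapply(which(has), function(i)
      tss_coord(matches$frame[i], matches$init_codon_index[i],
                nchar(db$genome[[matches$contig[i]]])), 1L)
  }
  matches$tss_indeterminate <- indet
  matches$adjacent_upstream_start <- adj_up
  matches
}

# Assemble the per-ORF evidence context used by the decision functions:
# one row per supporting peptide (deduplicated; for paralogous entries the
# first coordinate tuple is used), TSS columns attached.
orf_context <- function(entry, agg_row, maps, db, acetyl_by_seq) {
  peps <- agg_row$peptides[[1L]]
  mm <- maps$matches
  mm <- mm[mm$host_entry == entry$entry_id & mm$peptide %in% peps, ,
           drop = FALSE]
  mm <- mm[!duplicated(mm$peptide), , drop = FALSE]
  if (nrow(mm) == 0L) return(mm)
  ac <- unname(acetyl_by_seq[mm$peptide])
  ac[is.na(ac)] <- FALSE
  mm <- classify_tss_peptides(mm, db, acetylated = ac)
  st <- maps$peptides$status[match(mm$peptide, maps$peptides$sequence)]
  mm$status <- st
  mm
}

#' Validate a reference TSS from ORF evidence
#'
#' Validated when some TSS peptide places initiation exactly at the
#' reference start (initiator Met at reference codon 1, or N-Met-cleaved
#' peptide at codon 2).
#' @param entry one entry row (reference-linked)
#' @param ctx evidence context rows (see [refine_gene_models()])
#' @return decision row or NULL
#' @export
validate_reference_tss <- function(entry, ctx) {
  d <- entry$ref_offset_aa
  hit <- !is.na(ctx$tss_kind) & ctx$init_at_index == d + 1L
  if (!any(hit)) return(NULL)
  sup <- ctx[hit, , drop = FALSE]
  decision_row(entry, "validated", old_rel = d + 1L, new_rel = d + 1L,
               evidence_kind = "exact_tss", start_codon = sup$tss_start_codon[1L],
               peptides = sup$peptide)
}

#' Propose an upstream gene model extension
#'
#' Driven only by GSSPs mapping upstream of the reference start within the
#' same stop-free segment. An upstream TSS peptide fixes the new start
#' exactly; otherwise the nearest in-frame start codon at or upstream of
#' the most upstream evidence residue is taken. With no start codon
#' available the extension is reported unresolvable (no new TSS).
#' @inheritParams validate_reference_tss
#' @param db `sixframe_db`
#' @return decision row or NULL
#' @export
propose_upstream_extension <- function(entry, ctx, db) {
  d <- entry$ref_offset_aa
  ups <- ctx[!is.na(ctx$status) & ctx$status == "gssp" &
               ctx$at_codon_index < d + 1L, , drop = FALSE]
  if (nrow(ups) == 0L) return(NULL)
  exact <- ups[!is.na(ups$tss_kind) & ups$init_at_index < d + 1L, ,
               drop = FALSE]
  if (nrow(exact) > 0L) {
    new_rel <- min(exact$init_at_index)
    sup <- exact[exact$init_at_index == new_rel, , drop = FALSE]
    return(decision_row(entry, "upstream_extension", old_rel = d + 1L,
                        new_rel = new_rel, evidence_kind = "exact_tss",
                        start_codon = sup$tss_start_codon[1L],
                        peptides = ups$peptide))
  }
  u_rel <- min(ups$at_codon_index)
  s_rel <- next_upstream_start_rel(entry, u_rel, db)
  if (is.na(s_rel)) {
    return(decision_row(entry, "upstream_extension", old_rel = d + 1L,
                        new_rel = NA_integer_,
                        evidence_kind = "next_upstream_start",
                        start_codon = NA_character_, peptides = ups$peptide,
                        unresolvable = TRUE))
  }
  cc <- entry$coords[[1L]][1L, ]
  abs_ci <- cc$codon_start + s_rel - 1L
  decision_row(entry, "upstream_extension", old_rel = d + 1L, new_rel = s_rel,
               evidence_kind = "next_upstream_start",
               start_codon = codon_at(db, cc$contig, cc$frame, abs_ci),
               peptides = ups$peptide)
}

# nearest in-frame start codon at-or-upstream of relative codon index
# u_rel, limited to the host stop-free segment; NA when none exists
next_upstream_start_rel <- function(entry, u_rel, db) {
  cc <- entry$coords[[1L]][1L, ]
  lo_rel <- cc$seg_begin - cc$codon_start + 1L
  if (u_rel < lo_rel) return(NA_integer_)
  for (r in rev(seq.int(lo_rel, u_rel))) {
    if (codon_at(db, cc$contig, cc$frame, cc$codon_start + r - 1L) %in%
        db$start_codons)
      return(r)
  }
  NA_integer_
}

#' Propose a downstream TSS (gene model shortening)
#'
#' Requires a TSS peptide placing initiation strictly downstream of the
#' reference start and no identified peptide mapping strictly upstream of
#' that initiation point within the reference model. A supplied predicted
#' gene sharing the new TSS is recorded as corroboration.
#' @inheritParams propose_upstream_extension
#' @param predictions optional verified predictions from
#'   [ingest_predictions()]
#' @return decision row or NULL
#' @export
propose_downstream_start <- function(entry, ctx, db, predictions = NULL) {
  d <- entry$ref_offset_aa
  down <- ctx[!is.na(ctx$tss_kind) & ctx$init_at_index > d + 1L, ,
              drop = FALSE]
  if (nrow(down) == 0L) return(NULL)
  new_rel <- min(down$init_at_index)
  conflict <- ctx$at_codon_index >= d + 1L & ctx$at_codon_index < new_rel
  if (any(conflict)) {
    out <- NULL
    attr(out, "conflict") <- ctx$peptide[conflict]
    return(out)
  }
  sup <- down[down$init_at_index == new_rel, , drop = FALSE]
  row <- decision_row(entry, "downstream_start", old_rel = d + 1L,
                      new_rel = new_rel, evidence_kind = "exact_tss",
                      start_codon = sup$tss_start_codon[1L],
                      peptides = sup$peptide)
  if (!is.null(predictions) && nrow(predictions) > 0L) {
    hit <- predictions$contig == row$contig & predictions$strand == row$strand &
      !is.na(row$new_tss) &
      (ifelse(predictions$strand == "+", predictions$start,
              predictions$end) == row$new_tss)
    row$prediction_corroborated <- any(hit)
  } else row$prediction_corroborated <- FALSE
  row
}

#' Detect evidence for multiple initiation
#'
#' Reported when at least two distinct initiation coordinates in one ORF
#' each carry TSS peptide support. Indeterminate Met-at-start cases (where
#' N-Met cleavage and downstream initiation cannot be discriminated) do not
#' count towards distinct sites.
#' @inheritParams validate_reference_tss
#' @return decision row or NULL
#' @export
detect_multiple_initiation <- function(entry, ctx) {
  tss <- ctx[!is.na(ctx$tss_kind) & !ctx$tss_indeterminate, , drop = FALSE]
  sites <- unique(tss$init_at_index)
  if (length(sites) < 2L) return(NULL)
  row <- decision_row(entry, "multiple_initiation",
                      old_rel = entry$ref_offset_aa + 1L,
                      new_rel = NA_integer_, evidence_kind = "exact_tss",
                      start_codon = tss$tss_start_codon[1L],
                      peptides = tss$peptide)
  row$n_sites <- length(sites)
  row
}

decision_row <- function(entry, decision, old_rel, new_rel, evidence_kind,
                         start_codon, peptides, unresolvable = FALSE) {
  cc <- entry$coords[[1L]][1L, ]
  row <- data.frame(
    orf_id = entry$entry_id, ref_accession = entry$ref_accession,
    decision = decision, contig = cc$contig, strand = cc$strand,
    old_rel = old_rel, new_rel = new_rel,
    old_tss = NA_integer_, new_tss = NA_integer_,
    extension_aa = if (is.na(new_rel)) NA_integer_ else old_rel - new_rel,
    evidence_kind = evidence_kind, start_codon = start_codon,
    n_support = length(unique(peptides)), unresolvable = unresolvable,
    stringsAsFactors = FALSE)
  row$peptides <- list(sort(unique(peptides)))
  attr(row, "cc") <- cc
  row
}

# fill genomic TSS coordinates once contig lengths are known
finalize_decision_coords <- function(rows, db) {
  for (i in seq_len(nrow(rows))) {
    cc_frame <- rows$frame_internal[i]
    cs <- rows$codon_start_internal[i]
    L <- nchar(db$genome[[rows$contig[i]]])
    if (!is.na(rows$old_rel[i]))
      rows$old_tss[i] <- tss_coord(cc_frame, cs + rows$old_rel[i] - 1L, L)
    if (!is.na(rows$new_rel[i]))
      rows$new_tss[i] <- tss_coord(cc_frame, cs + rows$new_rel[i] - 1L, L)
  }
  rows
}

#' Refine gene models for every reference-linked ORF
#'
#' Applies, in priority order, TSS validation, upstream extension and
#' downstream start per ORF (mutually exclusive), plus a separate multiple
#' initiation report. Reference-ambiguous (paralogous) entries are excluded
#' from TSS accounting.
#'
#' @param db `sixframe_db` with reference mapped
#' @param agg per-ORF aggregation from [aggregate_per_orf()]
#' @param maps output of [map_peptides()]
#' @param records the peptide records behind `maps` (used for acetylation)
#' @param predictions optional verified predictions
#' @return data.frame of decisions (one or two rows per decided ORF):
#'   `orf_id`, `ref_accession`, `decision`, `old_tss`, `new_tss`,
#'   `extension_aa` (positive = extension, negative = shortening),
#'   `evidence_kind`, `start_codon`, `n_support`, `peptides`
#' @export
refine_gene_models <- function(db, agg, maps, records, predictions = NULL) {
  entries <- db$entries
  acetyl_by_seq <- tapply(grepl("Acetyl (Protein N-term)",
                                records$modifications, fixed = TRUE),
                          records$sequence, any)
  out <- list()
  for (i in seq_len(nrow(agg))) {
    eid <- agg$entry_id[i]
    k <- match(eid, entries$entry_id)
    if (is.na(k)) next
    entry <- entries[k, ]
    if (is.na(entry$ref_accession) || entry$ref_ambiguous) next
    ctx <- orf_context(entry, agg[i, ], maps, db, acetyl_by_seq)
    if (nrow(ctx) == 0L) next
    dec <- validate_reference_tss(entry, ctx)
    if (is.null(dec)) dec <- propose_upstream_extension(entry, ctx, db)
    if (is.null(dec)) dec <- propose_downstream_start(entry, ctx, db,
                                                      predictions)
    multi <- detect_multiple_initiation(entry, ctx)
    for (row in list(dec, multi)) {
      if (is.null(row)) next
      cc <- attr(row, "cc")
      row$frame_internal <- cc$frame
      row$codon_start_internal <- cc$codon_start
      row$n_sites <- if (is.null(row$n_sites)) NA_integer_ else row$n_sites
      row$prediction_corroborated <- if (is.null(row$prediction_corroborated))
        NA else row$prediction_corroborated
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) {
    return(data.frame(orf_id = character(0), ref_accession = character(0),
                      decision = character(0), contig = character(0),
                      strand = character(0), old_tss = integer(0),
                      new_tss = integer(0), extension_aa = integer(0),
                      evidence_kind = character(0), start_codon = character(0),
                      n_support = integer(0), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, out)
  rows <- finalize_decision_coords(rows, db)
  rows$frame_internal <- NULL
  rows$codon_start_internal <- NULL
  rownames(rows) <- NULL
  rows
}

#' Start codon distribution of TSS-decided ORFs
#' @param x character vector of start codons, or a decisions data.frame
#'   with a `start_codon` column
#' @return data.frame `start_codon`, `count`, `percent`
#' @export
summarize_start_codons <- function(x) {
  if (is.data.frame(x)) x <- x$start_codon
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(data.frame(start_codon = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  tab <- table(x)
  data.frame(start_codon = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Penultimate residue counts of N-Met-cleaved TSS peptides
#' @param tss classified matches from [classify_tss_peptides()] (or any
#'   data.frame with `tss_kind` and `penultimate`)
#' @return data.frame `residue`, `count`, descending
#' @export
summarize_penultimate_residues <- function(tss) {
  x <- tss$penultimate[!is.na(tss$tss_kind) & tss$tss_kind == "nmet_cleaved"]
  if (length(x) == 0L)
    return(data.frame(residue = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- sort(table(x), decreasing = TRUE)
  data.frame(residue = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
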