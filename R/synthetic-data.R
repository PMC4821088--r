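# Synthetic proteogenomics study generator.
#
# Emits a random genome with planted protein-coding genes (bacterial start
# codon usage), paralogous duplications, single-nucleotide deletions that
# split genes across reading frames, a deliberately corrupted "reference
# proteome" (TSS truncations, over-extensions, missing genes), and peptide
# identification tables from an in-silico LysC+trypsin digest with
# replicate structure, initiator-Met excision, N-terminal acetylation,
# decoy records and calibrated PEP scores. Every downstream pipeline stage
# is testable against the planted truth with no external data.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: start-codon
#' usage ATG/GTG/TTG of roughly 64/35/1 percent, a LysC+trypsin digest with
#' up to three missed cleavages and a seven-residue minimum length, three
#' replicates, and log-normal PEP scores whose group medians sit at the
#' annotated/novel/reverse levels seen in real searches.
#'
#' @param genome_length total contig length in nt
#' @param n_genes number of planted genes (paralog copies count)
#' @param start_codon_weights named probability triple over ATG/GTG/TTG
#' @param n_paralog_pairs pairs of byte-identical duplicated genes
#' @param n_frameshift_genes genes interrupted by a planted 1-nt deletion
#' @param n_frameshift_in_ref how many frameshift genes keep their
#'   corrected full-length protein in the reference proteome (the rest are
#'   absent, so their halves surface as novel ORFs)
#' @param ref_error_spec list with `missing_gene` (count), `tss_upstream_k`
#'   (integer vector; each entry plants one reference truncated by k
#'   residues) and `tss_downstream_k` (integer vector; each plants one
#'   reference over-extended upstream by k residues)
#' @param protein_len_range uniform range of planted protein lengths (aa)
#' @param digestion list: `max_missed_cleavages`, `min_peptide_len`,
#'   `max_peptide_len` (no cap by default), `detection_prob` (per peptide per replicate)
#' @param rp_suppression classic trypsin R/K.P suppression; off by default
#'   because combined LysC+trypsin cleaves K.P
#' @param nmet_cleavage_residues penultimate residues licensing initiator
#'   Met excision (canonical Met-AP specificity)
#' @param acetyl_prob probability an emitted N-terminal peptide carries
#'   N-terminal acetylation
#' @param pep_medians named group medians (annotated/novel/reverse) of the
#'   log-normal PEP score distributions
#' @param pep_sigma natural-log-scale spread of the PEP distributions,
#'   per group (a scalar is recycled). Target-peptide PEPs span many
#'   orders of magnitude while decoy PEPs concentrate near the FDR
#'   threshold, so targets default wide and decoys narrow; these values
#'   reproduce the degree of rank overlap between groups seen in real
#'   searches
#' @param n_replicates replicate count
#' @param n_decoys decoy (reverse-hit) records appended per table
#' @param contaminant_rate optional rate of shuffled false-positive target
#'   peptides (no default claimed; 0 disables)
#' @param seed integer seed; all generator randomness derives from it
#' @return a `simulation_config` list
#' @export
simulation_config <- function(genome_length = 30000L,
                              n_genes = 50L,
                              start_codon_weights = c(ATG = 0.6396, GTG = 0.3490, TTG = 0.0114),
                              n_paralog_pairs = 0L,
                              n_frameshift_genes = 0L,
                              n_frameshift_in_ref = 0L,
                              ref_error_spec = list(missing_gene = 0L,
                                                    tss_upstream_k = integer(0),
                                                    tss_downstream_k = integer(0)),
                              protein_len_range = c(80L, 140L),
                              digestion = list(max_missed_cleavages = 3L,
                                               min_peptide_len = 7L,
                                               max_peptide_len = Inf,
                                               detection_prob = 0.9),
                              rp_suppression = FALSE,
                              nmet_cleavage_residues = c("A","C","G","P","S","T","V"),
                              acetyl_prob = 0.2,
                              pep_medians = c(annotated = 1.32e-4,
                                              novel = 1.04e-3,
                                              reverse = 7.46e-2),
                              pep_sigma = c(annotated = 6, novel = 6,
                                            reverse = 1),
                              n_replicates = 3L,
                              n_decoys = 50L,
                              contaminant_rate = 0,
                              seed = 1L) {
  stopifnot(abs(sum(start_codon_weights) - 1) < 1e-8,
            n_genes >= 0L, n_paralog_pairs >= 0L, n_frameshift_genes >= 0L,
            digestion$detection_prob >= 0, digestion$detection_prob <= 1)
  cfg <- list(genome_length = as.integer(genome_length),
              n_genes = as.integer(n_genes),
              start_codon_weights = start_codon_weights,
              n_paralog_pairs = as.integer(n_paralog_pairs),
              n_frameshift_genes = as.integer(n_frameshift_genes),
              n_frameshift_in_ref = as.integer(n_frameshift_in_ref),
              ref_error_spec = ref_error_spec,
              protein_len_range = as.integer(protein_len_range),
              digestion = digestion,
              rp_suppression = isTRUE(rp_suppression),
              nmet_cleavage_residues = nmet_cleavage_residues,
              acetyl_prob = acetyl_prob,
              pep_medians = pep_medians,
              pep_sigma = pep_sigma,
              n_replicates = as.integer(n_replicates),
              n_decoys = as.integer(n_decoys),
              contaminant_rate = contaminant_rate,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# run expr under a derived seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.syn_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# sample one codon per residue of `residues`
sample_codons <- function(residues, syn) {
  vapply(residues, function(a) {
    cs <- syn[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "", USE.NAMES = FALSE)
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

#' Generate a genome with planted truth genes
#'
#' Each gene block is preceded by an in-frame stop codon so the gene's
#' stop-free segment begins at the gene itself, keeping truth recovery
#' unambiguous. Genes designated for a downstream reference over-extension
#' carry an in-frame upstream pad starting at a start codon (the region the
#' corrupted annotation will wrongly claim as coding). Frameshift genes
#' contain exactly one 1-nt deletion at the stated residue boundary; the
#' residue two positions past the junction is forced to Val(GTG) so the
#' downstream half has an in-frame start codon and is representable in the
#' six-frame database.
#'
#' @param config a [simulation_config()]
#' @return list with `genome` (named character vector, one contig),
#'   `truth` (data.frame of TruthGene rows, one per planted gene copy) and
#'   `config`
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$genome_length < 3L * config$n_genes * 60L)
    stop("genome_length must be at least 3 * n_genes * 60 nt to place ",
         config$n_genes, " genes without overlap")
  with_sim_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  syn <- .syn_codons()
  n <- config$n_genes
  es <- config$ref_error_spec
  n_par <- config$n_paralog_pairs
  n_fs <- config$n_frameshift_genes
  n_up <- length(es$tss_upstream_k)
  n_down <- length(es$tss_downstream_k)
  n_miss <- es$missing_gene
  if (2L * n_par + n_fs + n_up + n_down + n_miss > n)
    stop("requested paralog/frameshift/error gene counts exceed n_genes")

  # deterministic role assignment
  role <- rep("normal", n)
  if (n_par > 0L) role[seq_len(2L * n_par)] <- rep(c("paralog_a", "paralog_b"),
                                                   n_par)
  nxt <- 2L * n_par + 1L
  take <- function(k, what) {
    if (k == 0L) return(integer(0))
    ix <- seq.int(nxt, length.out = k)
    role[ix] <<- what
    nxt <<- nxt + k
    ix
  }
  ix_fs <- take(n_fs, "frameshift")
  ix_up <- take(n_up, "tss_upstream")
  ix_down <- take(n_down, "tss_downstream")
  ix_miss <- take(n_miss, "missing")

  err_k <- rep(NA_integer_, n)
  err_k[ix_up] <- as.integer(es$tss_upstream_k)
  err_k[ix_down] <- as.integer(es$tss_downstream_k)

  lo <- config$protein_len_range[1L]; hi <- config$protein_len_range[2L]
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    if (role[i] == "paralog_b") next  # copies its partner below
    if (role[i] == "tss_upstream") {
      Lp <- sample(seq.int(max(lo, err_k[i] + 30L), max(hi, err_k[i] + 40L)), 1L)
    } else if (role[i] == "frameshift") {
      Lp <- sample(seq.int(max(lo, 100L), max(hi, 140L)), 1L)
    } else {
      Lp <- sample(seq.int(lo, hi), 1L)
    }
    start_codon <- sample(names(config$start_codon_weights), 1L,
                          prob = config$start_codon_weights)
    residues <- c("M", sample(AA20, Lp - 1L, replace = TRUE))
    fs_pos <- NA_integer_
    if (role[i] == "frameshift") {
      fs_pos <- sample(seq.int(floor(Lp / 3), floor(2 * Lp / 3)), 1L)
      # frameshift genes get a regular tryptic grid (K/R every 15 residues,
      # no other K/R) so both halves of the split gene yield detectable
      # fully tryptic peptides
      residues <- c("M", sample(setdiff(AA20, c("K", "R")), Lp - 1L,
                                replace = TRUE))
      grid <- seq.int(15L, Lp - 5L, by = 15L)
      grid <- setdiff(grid, c(fs_pos + 1L, fs_pos + 2L))
      if (length(grid) < length(seq.int(15L, Lp - 5L, by = 15L)))
        grid <- sort(c(grid, fs_pos + 3L))
      residues[grid] <- sample(c("K", "R"), length(grid), replace = TRUE)
      # make the junction locally unambiguous and recoverable: the broken
      # codon is Trp (TGG, single codon), the codon before it must not end
      # in T (so the post-deletion chimeric codon cannot re-encode Trp),
      # and the first intact downstream codon is Val (GTG), giving the
      # downstream half an in-frame start codon
      residues[fs_pos + 1L] <- "W"
      residues[fs_pos + 2L] <- "V"
    }
    codons <- c(start_codon, sample_codons(residues[-1L], syn))
    if (!is.na(fs_pos)) {
      codons[fs_pos + 1L] <- "TGG"
      codons[fs_pos + 2L] <- "GTG"
      syn_r <- syn[[residues[fs_pos]]]
      no_t <- syn_r[substr(syn_r, 3L, 3L) != "T"]
      if (!substr(codons[fs_pos], 3L, 3L) %in% c("A", "C", "G"))
        codons[fs_pos] <- no_t[sample.int(length(no_t), 1L)]
    }
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    cds <- paste(c(codons, stop_codon), collapse = "")
    pad <- ""
    ext_prefix <- NA_character_
    if (role[i] == "tss_downstream") {
      k <- err_k[i]
      pad_start <- sample(names(config$start_codon_weights), 1L,
                          prob = config$start_codon_weights)
      pad_codons <- c(pad_start,
                      if (k > 1L) sample_codons(sample(AA20, k - 1L,
                                                       replace = TRUE), syn))
      pad <- paste(pad_codons, collapse = "")
      ext_prefix <- paste(c("M", translate_codons(pad_codons[-1L])),
                          collapse = "")
    }
    genes[[i]] <- list(role = role[i], protein = paste(residues, collapse = ""),
                       start_codon = start_codon, cds = cds, pad = pad,
                       ext_prefix = ext_prefix, fs_pos = fs_pos,
                       err_k = err_k[i])
  }
  for (i in seq_len(n)) {
    if (role[i] == "paralog_b") {
      g <- genes[[i - 1L]]
      g$role <- "paralog_b"
      genes[[i]] <- g
    }
  }

  # apply frameshift deletions: drop the first nt of codon fs_pos+1
  for (i in ix_fs) {
    g <- genes[[i]]
    del_at <- 3L * g$fs_pos + 1L
    g$cds <- paste0(substr(g$cds, 1L, del_at - 1L),
                    substr(g$cds, del_at + 1L, nchar(g$cds)))
    genes[[i]] <- g
  }

  strands <- sample(c("+", "-"), n, replace = TRUE)
  blocks <- vapply(seq_len(n), function(i)
    paste0("TAA", genes[[i]]$pad, genes[[i]]$cds), "")
  blens <- nchar(blocks)
  spare <- config$genome_length - sum(blens)
  if (spare < 10L * (n + 1L))
    stop("genome_length ", config$genome_length, " too short to place ",
         n, " gene blocks totalling ", sum(blens),
         " nt plus intergenic spacers without overlap")
  gaps <- if (n > 0L) {
    w <- stats::runif(n + 1L, 0.5, 1.5)
    g0 <- floor(spare * w / sum(w))
    g0[1L] <- g0[1L] + (spare - sum(g0))
    as.integer(g0)
  } else config$genome_length

  pieces <- character(0)
  truth_rows <- list()
  pos <- 1L
  for (i in seq_len(max(n, 0L))) {
    pieces <- c(pieces, random_dna(gaps[i]))
    pos <- pos + gaps[i]
    g <- genes[[i]]
    block <- blocks[i]
    placed <- if (strands[i] == "+") block else revcomp(block)
    pieces <- c(pieces, placed)
    blen <- nchar(block)
    padlen <- nchar(g$pad)
    prot_nt <- nchar(g$cds) - 3L  # coding span, stop excluded
    q1 <- 3L + padlen + 1L
    q2 <- q1 + prot_nt - 1L
    if (strands[i] == "+") {
      gstart <- pos + q1 - 1L
      gend <- pos + q2 - 1L
    } else {
      gstart <- pos + blen - q2
      gend <- pos + blen - q1
    }
    fs_genomic <- NA_integer_
    if (!is.na(g$fs_pos)) {
      # forward-coordinate position where the shifted reading begins
      fs_genomic <- if (strands[i] == "+") gstart + 3L * g$fs_pos
                    else gend - 3L * g$fs_pos
    }
    truth_rows[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i), contig = "chr1",
      start = gstart, end = gend, strand = strands[i],
      start_codon = g$start_codon, protein_seq = g$protein,
      paralog_group = if (startsWith(g$role, "paralog"))
        sprintf("par%02d", (i + 1L) %/% 2L) else NA_character_,
      frameshift_pos = g$fs_pos, frameshift_genomic_pos = fs_genomic,
      err_type = if (g$role %in% c("tss_upstream", "tss_downstream", "missing"))
        g$role else NA_character_,
      err_k = g$err_k, ext_ref_prefix = g$ext_prefix,
      cds = g$cds, stringsAsFactors = FALSE)
    pos <- pos + blen
  }
  pieces <- c(pieces, random_dna(gaps[length(gaps)]))
  genome <- c(chr1 = paste(pieces, collapse = ""))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               start_codon = character(0), protein_seq = character(0),
               paralog_group = character(0), frameshift_pos = integer(0),
               frameshift_genomic_pos = integer(0), err_type = character(0),
               err_k = integer(0), ext_ref_prefix = character(0),
               cds = character(0), stringsAsFactors = FALSE)
  # mark frameshift genes whose corrected protein stays in the reference
  truth$frameshift_in_ref <- logical(nrow(truth))
  if (length(ix_fs) && config$n_frameshift_in_ref > 0L) {
    keep <- ix_fs[seq_len(min(config$n_frameshift_in_ref, length(ix_fs)))]
    truth$frameshift_in_ref[keep] <- TRUE
  }
  list(genome = genome, truth = truth, config = config)
}

#' Corrupt the truth annotation into a reference proteome
#'
#' Plants the designated annotation errors: upstream truncations (first k
#' residues dropped; if the (k+1)-th codon happens to be a start codon its
#' residue is rendered as an initiator Met), downstream over-extensions
#' (reference extended upstream to the planted in-frame earlier start
#' codon), and missing genes. One reference entry is emitted per gene, so
#' paralogous identical proteins yield multiple accessions (and their
#' merged database entry is flagged reference-ambiguous, mirroring the
#' exclusion of paralogs from TSS accounting). Frameshift genes are absent
#' from the reference unless flagged `frameshift_in_ref`, in which case the
#' corrected full-length protein is included.
#'
#' @param truth truth data.frame from [generate_genome()]
#' @param config the same [simulation_config()]
#' @return list with `proteome` (named character vector, accession
#'   `P_<gene_id>`) and `ledger` (data.frame of every planted error)
#' @export
corrupt_annotation <- function(truth, config) {
  proteome <- character(0)
  ledger <- list()
  add_err <- function(gene_id, type, k, accession) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      gene_id = gene_id, err_type = type, k = k,
      accession = accession, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(truth))) {
    tg <- truth[i, ]
    acc <- paste0("P_", tg$gene_id)
    prot <- tg$protein_seq
    L <- nchar(prot)
    if (!is.na(tg$frameshift_pos)) {
      if (isTRUE(tg$frameshift_in_ref)) {
        proteome[acc] <- prot
        add_err(tg$gene_id, "frameshift_in_ref", tg$frameshift_pos, acc)
      } else {
        add_err(tg$gene_id, "frameshift_absent", tg$frameshift_pos,
                NA_character_)
      }
      next
    }
    et <- tg$err_type
    if (is.na(et)) {
      proteome[acc] <- prot
    } else if (et == "missing") {
      add_err(tg$gene_id, "missing_gene", NA_integer_, NA_character_)
    } else if (et == "tss_upstream") {
      k <- tg$err_k
      if (k >= L) stop("upstream truncation k=", k,
                       " leaves no residues for gene ", tg$gene_id)
      codon_k1 <- substr(tg$cds, 3L * k + 1L, 3L * k + 3L)
      trunc <- substr(prot, k + 1L, L)
      if (codon_k1 %in% names(config$start_codon_weights))
        trunc <- paste0("M", substr(trunc, 2L, nchar(trunc)))
      proteome[acc] <- trunc
      add_err(tg$gene_id, "tss_upstream", k, acc)
    } else if (et == "tss_downstream") {
      lit1 <- translate_codons(tg$start_codon)
      proteome[acc] <- paste0(tg$ext_ref_prefix, lit1, substr(prot, 2L, L))
      add_err(tg$gene_id, "tss_downstream", tg$err_k, acc)
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(gene_id = character(0), err_type = character(0),
               k = integer(0), accession = character(0),
               stringsAsFactors = FALSE)
  list(proteome = proteome, ledger = ledger)
}

# fully tryptic fragments (cleavage after K/R) with missed cleavages
tryptic_fragments <- function(protein, max_missed, rp_suppression = FALSE) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  L <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  if (rp_suppression)
    cut_after <- cut_after[!(cut_after < L & res[cut_after + 1L] == "P")]
  bounds <- c(0L, cut_after[cut_after < L], L)
  segs <- data.frame(from = bounds[-length(bounds)] + 1L, to = bounds[-1L])
  out <- list()
  for (i in seq_len(nrow(segs))) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nrow(segs)) break
      out[[length(out) + 1L]] <- c(segs$from[i], segs$to[j])
    }
  }
  do.call(rbind, out)
}

#' In-silico digest with replicate sampling, decoys and PEP scores
#'
#' Emits fully tryptic fragments of every truth protein plus the protein
#' N-terminal peptides with and without the initiator Met (the Met-removed
#' form only when the penultimate residue licenses Met-AP cleavage), each
#' detected independently per replicate. Peptides absent from `reference`
#' draw their PEP from the novel distribution; decoy records draw from the
#' reverse distribution.
#'
#' @param truth truth data.frame from [generate_genome()]
#' @param config the [simulation_config()]
#' @param reference optional corrupted reference proteome used to calibrate
#'   PEP group membership (annotated vs novel)
#' @param source_db label stamped on every record
#' @return peptide records data.frame in the shape of
#'   [parse_peptide_table()] output, with extra truth columns `gene_id` and
#'   `start_residue` (NA for decoys)
#' @export
digest_and_sample <- function(truth, config, reference = NULL,
                              source_db = "sixframe") {
  stopifnot(inherits(config, "simulation_config"))
  with_sim_seed(config$seed + 1000L,
                digest_and_sample_impl(truth, config, reference, source_db))
}

digest_and_sample_impl <- function(truth, config, reference, source_db) {
  dg <- config$digestion
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    prot <- truth$protein_seq[i]
    frags <- tryptic_fragments(prot, dg$max_missed_cleavages,
                               config$rp_suppression)
    if (is.null(frags)) next
    nterm <- frags[, 1L] == 1L
    # initiator-Met-removed N-terminal forms
    if (substr(prot, 2L, 2L) %in% config$nmet_cleavage_residues) {
      extra <- frags[nterm, , drop = FALSE]
      extra[, 1L] <- 2L
      frags <- rbind(frags, extra)
      nterm <- c(nterm, rep(TRUE, nrow(extra)))
    }
    len <- frags[, 2L] - frags[, 1L] + 1L
    keep <- len >= dg$min_peptide_len & len <= dg$max_peptide_len
    frags <- frags[keep, , drop = FALSE]
    nterm <- nterm[keep]
    if (nrow(frags) == 0L) next
    seqs <- substring(prot, frags[, 1L], frags[, 2L])
    acety <- nterm & stats::runif(length(seqs)) < config$acetyl_prob
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = seqs, gene_id = truth$gene_id[i],
      start_residue = frags[, 1L],
      modifications = ifelse(acety, "Acetyl (Protein N-term)", "Unmodified"),
      is_decoy = FALSE, stringsAsFactors = FALSE)
  }
  cand <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), gene_id = character(0),
               start_residue = integer(0), modifications = character(0),
               is_decoy = logical(0), stringsAsFactors = FALSE)
  # one candidate per (sequence, modification); paralogs collapse
  cand <- cand[!duplicated(cand[, c("sequence", "modifications")]), ,
               drop = FALSE]

  # optional shuffled-peptide contaminants
  if (config$contaminant_rate > 0 && nrow(cand) > 0L) {
    n_cont <- ceiling(config$contaminant_rate * nrow(cand))
    pick <- sample.int(nrow(cand), n_cont, replace = TRUE)
    shuf <- vapply(cand$sequence[pick], function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, "", USE.NAMES = FALSE)
    cand <- rbind(cand, data.frame(sequence = shuf, gene_id = NA_character_,
                                   start_residue = NA_integer_,
                                   modifications = "Unmodified",
                                   is_decoy = FALSE, stringsAsFactors = FALSE))
  }

  # replicate detection
  reps <- paste0("R", seq_len(config$n_replicates))
  det <- matrix(stats::runif(nrow(cand) * length(reps)) < dg$detection_prob,
                nrow = nrow(cand))
  seen <- rowSums(det) > 0L
  cand <- cand[seen, , drop = FALSE]
  det <- det[seen, , drop = FALSE]
  cand$replicates <- lapply(seq_len(nrow(cand)), function(i) reps[det[i, ]])

  # decoys
  if (config$n_decoys > 0L) {
    dseq <- vapply(seq_len(config$n_decoys), function(i)
      paste(c(sample(AA20, sample(7:19, 1L), replace = TRUE),
              sample(c("K", "R"), 1L)), collapse = ""), "")
    ddet <- matrix(stats::runif(config$n_decoys * length(reps)) < 0.4,
                   nrow = config$n_decoys)
    ddet[rowSums(ddet) == 0L, 1L] <- TRUE
    drows <- data.frame(sequence = dseq, gene_id = NA_character_,
                        start_residue = NA_integer_,
                        modifications = "Unmodified", is_decoy = TRUE,
                        stringsAsFactors = FALSE)
    drows$replicates <- lapply(seq_len(config$n_decoys), function(i)
      reps[ddet[i, ]])
    cand <- rbind(cand, drows)
  }

  # PEP scores: log-normal with group-calibrated medians
  grp <- rep("annotated", nrow(cand))
  grp[cand$is_decoy] <- "reverse"
  if (!is.null(reference) && any(!cand$is_decoy)) {
    tgt <- !cand$is_decoy
    st <- classify_gssp(cand$sequence[tgt], reference)
    grp[tgt][st == "gssp"] <- "novel"
  }
  med <- config$pep_medians[grp]
  sig <- if (length(config$pep_sigma) == 1L)
    rep(config$pep_sigma, nrow(cand)) else config$pep_sigma[grp]
  cand$pep <- pmin(1, exp(stats::rnorm(nrow(cand), mean = log(med),
                                       sd = sig)))
  cand$source_db <- source_db
  cand$n_replicates <- lengths(cand$replicates)
  rownames(cand) <- NULL
  cand[, c("sequence", "modifications", "pep", "is_decoy", "source_db",
           "replicates", "n_replicates", "gene_id", "start_residue")]
}

#' Write peptide records as a MaxQuant-style table
#'
#' Columns: Sequence, Modifications, PEP (full precision), Reverse and one
#' `Experiment <id>` evidence column per replicate. Round-trips through
#' [parse_peptide_table()].
#' @param records records from [digest_and_sample()]
#' @param path output TSV
#' @export
write_peptide_table <- function(records, path) {
  reps <- sort(unique(unlist(records$replicates)))
  if (length(reps) == 0L) reps <- "R1"
  tab <- data.frame(Sequence = records$sequence,
                    Modifications = records$modifications,
                    PEP = sprintf("%.17g", records$pep),
                    Reverse = ifelse(records$is_decoy, "+", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (r in reps) {
    tab[[paste0("Experiment ", r)]] <-
      vapply(records$replicates, function(x) as.integer(r %in% x), 1L)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth gene table as TSV
#' @param truth truth data.frame
#' @param path output file
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth[, setdiff(names(truth), "cds")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
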