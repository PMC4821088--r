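# Low-level sequence utilities shared by the database builder and the
# dynamic peptide-to-genome scan. Coordinates are 1-based inclusive on the
# forward strand throughout; reverse-strand features keep start < end and
# translate from end to start.

DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

#' Reverse-complement a nucleotide string
#' @param x single DNA string (ACGT alphabet; other letters complement to N)
#' @return reverse complement as a character scalar
#' @keywords internal
revcomp <- function(x) {
  stopifnot(length(x) == 1L)
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a vector of codons with the standard code
#'
#' Codons containing characters outside ACGT translate to \code{X}, which by
#' construction never matches a peptide residue. Stops are \code{*}.
#' @param codons character vector of 3-mers
#' @keywords internal
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Split a sequence into the codons of one frame
#' @param seq nucleotide string (already reverse-complemented for minus
#'   frames)
#' @param f frame offset 1..3
#' @keywords internal
frame_codons <- function(seq, f) {
  n <- nchar(seq)
  if (n < f + 2L) return(character(0))
  starts <- seq.int(f, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

# Genomic span of codons a..b of signed frame `frame` on a contig of length
# L. Forward frames: codon i covers [f + 3(i-1), f + 3i - 1]. Minus frames
# are frames of the reverse complement mapped back to forward coordinates.
codon_span <- function(frame, a, b, L) {
  if (frame > 0L) {
    c(start = frame + 3L * (a - 1L), end = frame + 3L * b - 1L)
  } else {
    g <- -frame
    c(start = L - g - 3L * b + 2L, end = L - g - 3L * a + 4L)
  }
}

# 5' coordinate (in translation direction) of codon c in a signed frame.
tss_coord <- function(frame, c, L) {
  if (frame > 0L) frame + 3L * (c - 1L) else L + frame - 3L * c + 4L
}

# Frame and codon index of a genomic interval start..end on a given strand.
# Returns list(frame, a, b) with a..b codon indices, or NULL when the span
# is not a whole number of codons.
span_to_codons <- function(start, end, strand, L) {
  len <- end - start + 1L
  if (len %% 3L != 0L) return(NULL)
  ncod <- len %/% 3L
  if (strand == "+") {
    f <- ((start - 1L) %% 3L) + 1L
    a <- (start - f) %/% 3L + 1L
  } else {
    g <- ((L - end) %% 3L) + 1L
    a <- (L - end + 1L - g) %/% 3L + 1L
    f <- -g
  }
  list(frame = f, a = a, b = a + ncod - 1L)
}

#' Load a genome into a named character vector
#'
#' Accepts a FASTA path, a \code{Biostrings::DNAStringSet}, or an already
#' named character vector of contig sequences.
#' @param genome path, DNAStringSet or named character vector
#' @return named uppercase character vector, one element per contig
#' @export
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    ss <- Biostrings::readBStringSet(genome)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
    return(toupper(genome))
  }
  stop("cannot interpret `genome`: supply a FASTA path, DNAStringSet or named character vector")
}

#' Write sequences to a FASTA file
#' @param seqs named character vector (names become headers)
#' @param path output file
#' @param width line width for sequence wrapping
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#'
#' UniProt-style headers (\code{db|ACCESSION|name}) are reduced to the
#' accession (second pipe field); otherwise the first whitespace-delimited
#' token is used.
#' @param path FASTA file
#' @export
read_proteome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  pipey <- grepl("^[^|]+\\|[^|]+\\|", ids)
  ids[pipey] <- vapply(strsplit(ids[pipey], "|", fixed = TRUE), `[`, "", 2L)
  names(out) <- ids
  out
}
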