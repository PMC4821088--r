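# Independent brute-force oracles. These deliberately take different code
# paths from the package (Biostrings translation, naive per-position
# enumeration, textbook rank formulas) so agreement is informative.

rc_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

frame_aa_oracle <- function(ss, f) {
  L <- nchar(ss)
  n <- (L - f + 1L) %/% 3L
  if (n < 1L) return(list(aa = character(0), cods = character(0), n = 0L))
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(ss, f, f + 3L * n - 1L)),
    no.init.codon = TRUE)), "")[[1L]]
  cods <- substring(ss, f + 3L * (0:(n - 1L)), f + 3L * (0:(n - 1L)) + 2L)
  list(aa = aa, cods = cods, n = n)
}

# enumerate every (position, frame), check start codon, extend to stop,
# translate, keep the most upstream start per stop-free segment, filter by
# length
naive_sixframe <- function(genome, min_len = 20L,
                           start_codons = c("ATG", "GTG", "TTG")) {
  out <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else rc_str(s)
      for (f in 1:3) {
        fr <- frame_aa_oracle(ss, f)
        if (fr$n < 1L) next
        stops <- c(which(fr$aa == "*"), fr$n + 1L)  # sentinel = open end
        claimed <- rep(FALSE, length(stops))
        for (i in which(fr$cods %in% start_codons)) {
          k <- which(stops > i)[1L]
          if (claimed[k]) next
          claimed[k] <- TRUE
          e <- stops[k] - 1L
          len <- e - i + 1L
          if (len < min_len) next
          prot <- paste0("M", paste(fr$aa[seq.int(i + 1L, length.out = len - 1L)],
                                    collapse = ""))
          p1 <- f + 3L * (i - 1L)
          p2 <- f + 3L * e - 1L
          gs <- if (strand == "+") p1 else L - p2 + 1L
          ge <- if (strand == "+") p2 else L - p1 + 1L
          out[[length(out) + 1L]] <- data.frame(
            protein = prot, start = gs, end = ge, strand = strand,
            has_stop = stops[k] <= fr$n, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      has_stop = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand, res$protein), , drop = FALSE]
}

# per-position naive scan over all six frames, with the
# initiator-Met-at-start-codon rule
naive_locate <- function(pep, genome, start_codons = c("ATG", "GTG", "TTG")) {
  m <- nchar(pep)
  pc <- strsplit(pep, "", fixed = TRUE)[[1L]]
  out <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else rc_str(s)
      for (f in 1:3) {
        fr <- frame_aa_oracle(ss, f)
        if (fr$n < m) next
        cand <- which(fr$aa == pc[1L])
        if (pc[1L] == "M")
          cand <- sort(union(cand, which(fr$cods %in% start_codons)))
        for (i in cand[cand <= fr$n - m + 1L]) {
          ok1 <- fr$aa[i] == pc[1L] ||
            (pc[1L] == "M" && fr$cods[i] %in% start_codons)
          if (!ok1) next
          if (m > 1L && !all(fr$aa[(i + 1L):(i + m - 1L)] == pc[-1L])) next
          p1 <- f + 3L * (i - 1L)
          p2 <- f + 3L * (i + m - 1L) - 1L
          out[[length(out) + 1L]] <- data.frame(
            start = if (strand == "+") p1 else L - p2 + 1L,
            end = if (strand == "+") p2 else L - p1 + 1L,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  res[order(res$start, res$strand), , drop = FALSE]
}

# exhaustive cleavage enumeration: every (i, j) with tryptic boundaries,
# at most max_missed internal K/R, plus initiator-Met-removed N-terminal
# starts when licensed
naive_digest <- function(prot, max_missed = 3L, min_len = 7L,
                         nmet_set = c("A", "C", "G", "P", "S", "T", "V")) {
  res <- strsplit(prot, "", fixed = TRUE)[[1L]]
  L <- length(res)
  starts <- c(1L, which(res %in% c("K", "R")) + 1L)
  if (L >= 2L && res[2L] %in% nmet_set) starts <- c(starts, 2L)
  starts <- unique(starts[starts <= L])
  ends <- unique(c(which(res %in% c("K", "R")), L))
  out <- character(0)
  for (i in starts) for (j in ends[ends >= i]) {
    if (j - i + 1L < min_len) next
    internal <- if (j > i) sum(res[i:(j - 1L)] %in% c("K", "R")) else 0L
    if (internal > max_missed) next
    out <- c(out, paste(res[i:j], collapse = ""))
  }
  sort(unique(out))
}

# textbook rank statistics written independently: midranks by block
# scanning, tie terms via rle
naive_rank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  sx <- x[o]
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && sx[j + 1L] == sx[i]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

naive_kw <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- naive_rank(x)
  S <- sum(tapply(r, g, sum)^2 / tabulate(g, length(samples)))
  H0 <- 12 / (N * (N + 1)) * S - 3 * (N + 1)
  tt <- rle(sort(x))$lengths
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) return(list(H = 0, df = length(samples) - 1L, p = 1))
  H <- H0 / C
  list(H = H, df = length(samples) - 1L,
       p = pchisq(H, length(samples) - 1L, lower.tail = FALSE))
}

naive_dunn_z <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  N <- length(x)
  r <- naive_rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g, length(samples))
  tt <- rle(sort(x))$lengths
  v <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  pr <- combn(length(samples), 2L)
  vapply(seq_len(ncol(pr)), function(p) {
    i <- pr[1L, p]; j <- pr[2L, p]
    (rbar[i] - rbar[j]) / sqrt(v * (1 / n_i[i] + 1 / n_i[j]))
  }, 0)
}

random_genome <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
}
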