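# PEP-score group comparisons: annotated vs novel (GSSP) vs reverse
# (decoy) peptides per database search. Kruskal-Wallis with tie correction
# and Dunn's two-sided post-hoc z tests with Bonferroni adjustment,
# following Dunn (1964) with midrank ties.

#' Group peptide PEP scores by annotation status
#'
#' Per source database: `annotated` = non-decoy peptides found in the
#' reference, `novel` = non-decoy GSSPs, `reverse` = decoys. Each peptide
#' sequence is counted once per database at its best (minimum) PEP.
#'
#' @param records peptide records carrying `pep`, `is_decoy`, `source_db`
#' @param reference reference proteome used to classify annotated vs novel
#'   (ignored for rows that already carry a `status` column)
#' @return named list (per source_db) of lists with numeric vectors
#'   `annotated`, `novel`, `reverse`; class `pep_groups`
#' @export
group_peptides <- function(records, reference = NULL) {
  if (!"status" %in% names(records)) {
    records$status <- NA_character_
    tgt <- !records$is_decoy
    if (any(tgt)) {
      if (is.null(reference))
        stop("supply `reference` or records with a precomputed `status` column")
      st <- classify_gssp(unique(records$sequence[tgt]), reference)
      records$status[tgt] <- st[match(records$sequence[tgt],
                                      unique(records$sequence[tgt]))]
    }
  }
  out <- list()
  for (dbname in sort(unique(records$source_db))) {
    r <- records[records$source_db == dbname, , drop = FALSE]
    best <- function(sel) {
      rr <- r[sel, , drop = FALSE]
      if (nrow(rr) == 0L) return(numeric(0))
      as.numeric(tapply(rr$pep, rr$sequence, min))
    }
    grp <- list(annotated = best(!r$is_decoy & r$status %in% "annotated"),
                novel = best(!r$is_decoy & r$status %in% "gssp"),
                reverse = best(r$is_decoy))
    empty <- names(grp)[lengths(grp) == 0L]
    if (length(empty))
      warning("empty PEP group(s) in ", dbname, ": ",
              paste(empty, collapse = ", "))
    out[[dbname]] <- grp
  }
  class(out) <- "pep_groups"
  out
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H is computed on midranks and divided by the tie correction
#' C = 1 - sum(t^3 - t) / (N^3 - N); the p-value comes from the chi-square
#' upper tail with k - 1 degrees of freedom. Inputs in which every value is
#' identical give H = 0, p = 1 by convention.
#'
#' @param samples list of k >= 2 numeric vectors
#' @return list with `H`, `df`, `p`
#' @export
kruskal_wallis <- function(samples) {
  samples <- samples[lengths(samples) > 0L]
  k <- length(samples)
  if (k < 2L) stop("need at least two non-empty samples")
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), lengths(samples))
  N <- length(x)
  r <- rank(x)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(list(H = 0, df = k - 1L, p = 1))
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g, k)
  H <- (12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)) / C
  list(H = unname(H), df = k - 1L,
       p = stats::pchisq(H, df = k - 1L, lower.tail = FALSE))
}

#' Dunn's two-sided post-hoc comparisons
#'
#' For each pair (i, j):
#' z = (meanrank_i - meanrank_j) / sqrt[(N(N+1)/12 -
#' sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)], two-sided p from the standard
#' normal, adjusted p = min(1, m p) under Bonferroni with m = k(k-1)/2.
#' Fully tied input reports z = 0, p = 1 per pair.
#'
#' @param samples named list of k >= 2 numeric vectors
#' @param adjustment only `"bonferroni"` is implemented
#' @return data.frame: `pair`, `z`, `p_unadjusted`, `p_adjusted`
#' @export
dunn_posthoc <- function(samples, adjustment = "bonferroni") {
  adjustment <- match.arg(adjustment, "bonferroni")
  samples <- samples[lengths(samples) > 0L]
  k <- length(samples)
  if (k < 2L) stop("need at least two non-empty samples")
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_len(k))
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_len(k), lengths(samples))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- tabulate(g, k)
  tie <- table(x)
  v0 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se2 <- v0 * (1 / n_i[i] + 1 / n_i[j])
    z <- if (se2 <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(se2)
    pu <- if (se2 <= 0) 1 else 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(names(samples)[i], names(samples)[j], sep = "-"),
               z = unname(z), p_unadjusted = unname(pu),
               p_adjusted = min(1, m * pu), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary statistics of PEP groups
#'
#' Medians (midpoint convention for even n), quartiles, and 1.5 x IQR
#' whisker bounds per group per database, driving boxplot-style reporting.
#' @param groups a `pep_groups` object (or one database's list)
#' @return data.frame: `source_db`, `group`, `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`
#' @export
summarize_distributions <- function(groups) {
  if (!inherits(groups, "pep_groups")) groups <- structure(list(db = groups),
                                                           class = "pep_groups")
  rows <- list()
  for (dbname in names(groups)) {
    for (gname in names(groups[[dbname]])) {
      v <- groups[[dbname]][[gname]]
      if (length(v) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_db = dbname, group = gname, n = 0L, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, whisker_lo = NA_real_,
          whisker_hi = NA_real_, stringsAsFactors = FALSE)
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3L] - q[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        source_db = dbname, group = gname, n = length(v), median = q[2L],
        q1 = q[1L], q3 = q[3L], whisker_lo = q[1L] - 1.5 * iqr,
        whisker_hi = q[3L] + 1.5 * iqr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Full PEP-score comparison, before and after the replicate filter
#'
#' Mirrors the paired presentation of PEP distributions with and without
#' excluding peptides seen in only one replicate.
#' @param records peptide records (all databases)
#' @param reference reference proteome for annotated/GSSP classification
#' @param min_replicates replicate threshold for the filtered pass
#' @return list with `before` and `after`, each holding `groups`,
#'   `kruskal` (per database), `dunn` (per database) and `summary`
#' @export
pep_compare <- function(records, reference, min_replicates = 2L) {
  run <- function(recs) {
    groups <- suppressWarnings(group_peptides(recs, reference))
    kw <- lapply(groups, function(g) {
      g <- g[lengths(g) > 0L]
      if (length(g) < 2L) return(NULL)
      kruskal_wallis(g)
    })
    dn <- lapply(groups, function(g) {
      g <- g[lengths(g) > 0L]
      if (length(g) < 2L) return(NULL)
      dunn_posthoc(g)
    })
    list(groups = groups, kruskal = kw, dunn = dn,
         summary = summarize_distributions(groups))
  }
  filtered <- filter_replicates(records, min_replicates)
  filtered <- filtered[filtered$replicate_pass | filtered$is_decoy, ,
                       drop = FALSE]
  list(before = run(records), after = run(filtered))
}
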