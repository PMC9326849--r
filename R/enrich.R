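# Region-to-RE assignment and the binomial enrichment test against the
# annotated-RE background.

#' Read a BED3/BED5 file
#'
#' Tab-separated, 0-based half-open intervals; column 4 (name) and column 5
#' (score, conventionally a -log10 p-value) are kept when present.
#'
#' @param path BED file path.
#' @return data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df[seq_len(min(ncol(df), 5))]
}

#' Assign genomic regions to their nearest regulatory element
#'
#' Distance is 0 for overlapping (or book-ended) intervals and the gap
#' between the closest interval ends otherwise; regions on chromosomes with
#' no RE never match. A region is assigned to its nearest RE only when the
#' distance is strictly smaller than `max_dist`; ties among equally near
#' REs are broken by the lower RE start coordinate.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param loci RE loci data.frame with columns `re`, `chrom`, `start`, `end`.
#' @param max_dist assignment cutoff in bp (default 1000; strict `<`).
#' @return `regions` with columns `re` (`NA` when unassigned) and
#'   `distance` appended.
#' @export
nearest_re <- function(regions, loci, max_dist = 1000) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(c("re", "chrom", "start", "end") %in% names(loci)))
  if (nrow(regions) > 0 && any(regions$start >= regions$end)) {
    stop("region start must be < end (0-based half-open)")
  }
  re_idx <- rep(NA_integer_, nrow(regions))
  re_dist <- rep(NA_real_, nrow(regions))

  for (chr in unique(regions$chrom)) {
    li <- which(loci$chrom == chr)
    ri <- which(regions$chrom == chr)
    if (length(li) == 0 || length(ri) == 0) next
    ls <- loci$start[li]
    le <- loci$end[li]
    rs <- regions$start[ri]
    re_ <- regions$end[ri]

    # candidate to the left: RE with the largest end <= region start;
    # among equal ends, the one with the lowest start
    eo <- order(le, ls, li)
    ends_sorted <- le[eo]
    pos <- findInterval(rs, ends_sorted)
    # step back over runs of equal ends to their lowest-start representative
    run_first <- match(ends_sorted, ends_sorted)
    left_cand <- ifelse(pos >= 1L, eo[run_first[pmax(pos, 1L)]], NA_integer_)
    left_dist <- ifelse(pos >= 1L, rs - ends_sorted[pmax(pos, 1L)], Inf)

    # candidate to the right: RE with the smallest start >= region end
    so <- order(ls, le, li)
    starts_sorted <- ls[so]
    pos_r <- findInterval(re_ - 1L, starts_sorted) + 1L
    right_cand <- ifelse(pos_r <= length(so), so[pmin(pos_r, length(so))],
                         NA_integer_)
    right_dist <- ifelse(pos_r <= length(so),
                         starts_sorted[pmin(pos_r, length(so))] - re_, Inf)

    # overlapping (or book-ended inside the interval) REs: distance 0,
    # lowest start wins
    ov <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(chr, IRanges::IRanges(rs + 1L, re_)),
      GenomicRanges::GRanges(chr, IRanges::IRanges(ls + 1L, le))
    )
    ov_cand <- rep(NA_integer_, length(ri))
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      ord <- order(q, ls[s], le[s], s)
      q <- q[ord]; s <- s[ord]
      first <- !duplicated(q)
      ov_cand[q[first]] <- s[first]
    }

    for (k in seq_along(ri)) {
      cand <- c(ov_cand[k], left_cand[k], right_cand[k])
      dist <- c(0, left_dist[k], right_dist[k])
      ok <- !is.na(cand) & is.finite(dist)
      if (!any(ok)) next
      cand <- cand[ok]; dist <- dist[ok]
      best <- which(dist == min(dist))
      if (length(best) > 1) best <- best[which.min(ls[cand[best]])]
      re_idx[ri[k]] <- li[cand[[best]]]
      re_dist[ri[k]] <- dist[[best]]
    }
  }

  out <- regions
  assigned <- !is.na(re_dist) & re_dist < max_dist
  out$re <- ifelse(assigned, loci$re[re_idx], NA_character_)
  out$distance <- re_dist
  out
}

#' Upper-tail binomial probability
#'
#' `Pr(X >= k)` for `X ~ Binomial(N, p)`, evaluated through the stable
#' survival function. Vectorized over `k`, `N`, `p`.
#'
#' @param k observed count(s), `0 <= k <= N`.
#' @param N number of trials.
#' @param p success probability in `[0, 1]`.
#' @return upper-tail probability in `[0, 1]`.
#' @export
binom_tail <- function(k, N, p) {
  if (any(k < 0 | k > N)) stop("k must satisfy 0 <= k <= N")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  ifelse(k == 0, 1, stats::pbinom(k - 1, N, p, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' output order matches input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted values.
#' @export
bh_correct <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Genome-wide term background fractions
#'
#' For each term, the fraction of annotated REs (REs with at least one
#' final term) that carry the term — the binomial success probability of
#' the enrichment test.
#'
#' @param regoa a `re_annotation` (normally kind `"final"`).
#' @return named numeric vector of fractions in `(0, 1]`.
#' @export
term_background <- function(regoa) {
  stopifnot(inherits(regoa, "re_annotation"))
  ann <- regoa$annotations[lengths(regoa$annotations) > 0]
  if (length(ann) == 0) stop("no annotated RE in the resource")
  counts <- table(unlist(ann, use.names = FALSE))
  stats::setNames(as.numeric(counts) / length(ann), names(counts))
}

#' Binomial enrichment of GO terms in a genomic region set
#'
#' Regions are assigned to their nearest annotated RE within `max_dist`
#' (see [nearest_re()]); `N` is the number of assigned regions, and for each
#' term carried by at least one assigned RE, `k` counts the assigned
#' regions whose RE carries the term (a region counts once per term). The
#' p-value is the upper binomial tail `Pr(X >= k | N, p(t))` with the
#' genome-wide background fraction `p(t)` from [term_background()], and BH
#' correction is applied over the tested terms. Rows are sorted by
#' increasing FDR (smaller is more enriched).
#'
#' @param regions data.frame of regions (`chrom`, `start`, `end`).
#' @param regoa a `re_annotation` resource (kind `"final"` in production).
#' @param loci RE loci data.frame (`re`, `chrom`, `start`, `end`).
#' @param max_dist assignment cutoff in bp.
#' @param background optional named background fraction vector; defaults to
#'   [term_background()] of `regoa`.
#' @param term_names optional named character vector of term labels.
#' @return an `enrichment_table` data.frame with columns `term`, `name`,
#'   `k`, `N`, `p_t`, `pvalue`, `fdr`.
#' @export
enrich_regions <- function(regions, regoa, loci, max_dist = 1000,
                           background = NULL, term_names = NULL) {
  stopifnot(inherits(regoa, "re_annotation"))
  if (is.null(background)) background <- term_background(regoa)
  annotated_res <- names(regoa$annotations)[lengths(regoa$annotations) > 0]
  use_loci <- loci[loci$re %in% annotated_res, , drop = FALSE]
  empty <- data.frame(
    term = character(), name = character(), k = integer(), N = integer(),
    p_t = numeric(), pvalue = numeric(), fdr = numeric(),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("enrichment_table", "data.frame")
  if (nrow(use_loci) == 0 || nrow(regions) == 0) {
    warning("no annotated RE or no region; returning empty table")
    return(empty)
  }
  assigned <- nearest_re(regions, use_loci, max_dist = max_dist)
  assigned <- assigned[!is.na(assigned$re), , drop = FALSE]
  N <- nrow(assigned)
  if (N == 0) {
    warning("no region within ", max_dist, " bp of an annotated RE")
    return(empty)
  }
  k <- table(unlist(lapply(regoa$annotations[assigned$re], unique),
                    use.names = FALSE))
  terms <- names(k)
  p_t <- background[terms]
  if (anyNA(p_t)) {
    stop("term(s) missing from background: ",
         paste(terms[is.na(p_t)], collapse = ", "))
  }
  pvalue <- binom_tail(as.integer(k), N, p_t)
  out <- data.frame(
    term = terms,
    name = if (is.null(term_names)) NA_character_ else
      unname(term_names[terms]),
    k = as.integer(k), N = N, p_t = unname(p_t), pvalue = unname(pvalue),
    fdr = bh_correct(unname(pvalue)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$fdr, out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param table an `enrichment_table`.
#' @param path output path.
#' @export
write_enrichment <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
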