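# Application drivers: ChIP-seq TF annotation evaluation, differential
# ATAC-seq peaks, GWAS trait similarity.

#' Select the top-scoring peaks
#'
#' Peaks are ranked by decreasing score (conventionally -log10 p-value)
#' with a stable coordinate tie-break (chrom, start, end), and at most
#' `cap` are returned; fewer peaks than the cap are returned unchanged
#' apart from the ordering.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `score`.
#' @param cap maximum number of peaks to keep (default 15000).
#' @return the selected peaks, ranked.
#' @export
select_top_peaks <- function(peaks, cap = 15000) {
  stopifnot(is.data.frame(peaks))
  has_scores <- "score" %in% names(peaks) && !anyNA(peaks$score)
  if (!has_scores) {
    if (nrow(peaks) > cap) stop("peaks must carry scores to rank beyond cap")
    ord <- order(peaks$chrom, peaks$start, peaks$end)
  } else {
    ord <- order(-peaks$score, peaks$chrom, peaks$start, peaks$end)
  }
  out <- utils::head(peaks[ord, , drop = FALSE], cap)
  rownames(out) <- NULL
  out
}

#' Evaluate a TF's enrichment-based annotation against a gold standard
#'
#' The prediction for a TF is the set of terms whose enrichment FDR is
#' below `theta`, together with all their ancestors; the gold standard is
#' the TF's own (closed) GO annotation. Precision, recall and f1 are
#' computed on the two term sets (f1 reported as 0, flagged, when both
#' precision and recall are 0 or the prediction is empty). AvgMSS is the
#' mean over predicted terms of each term's maximum Wang-style semantic
#' similarity to any gold-standard term.
#'
#' @param enriched an `enrichment_table` for the TF's binding regions.
#' @param standard character vector of gold-standard term ids (non-empty).
#' @param dag a [go_dag].
#' @param theta FDR cut selecting enriched terms (default 5e-8).
#' @param decay decay factor for the semantic similarity.
#' @return list with `precision`, `recall`, `f1`, `avg_mss`, `theta`,
#'   `n_predicted`, and `empty_prediction` flag.
#' @export
tf_eval <- function(enriched, standard, dag, theta = 5e-8, decay = 0.8) {
  stopifnot(length(standard) > 0)
  hits <- enriched$term[enriched$fdr < theta]
  anc <- ancestors_table(dag)
  predict <- unique(c(hits, unlist(anc[hits], use.names = FALSE)))
  standard <- unique(standard)
  if (length(predict) == 0) {
    return(list(precision = 0, recall = 0, f1 = 0, avg_mss = NA_real_,
                theta = theta, n_predicted = 0L, empty_prediction = TRUE))
  }
  common <- length(intersect(predict, standard))
  pre <- common / length(predict)
  rec <- common / length(standard)
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  mss <- vapply(predict, function(ta) {
    max(vapply(standard, function(tb) term_similarity(dag, ta, tb, decay), 0))
  }, 0)
  list(precision = pre, recall = rec, f1 = f1, avg_mss = mean(mss),
       theta = theta, n_predicted = length(predict),
       empty_prediction = FALSE)
}

#' Read a peak openness matrix
#'
#' TSV with peak coordinates (`chrom`, `start`, `end`) followed by one
#' nonnegative openness column per condition.
#'
#' @param path input TSV with a header.
#' @return data.frame; condition columns are everything after the first
#'   three.
#' @export
read_openness_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("openness matrix needs coordinates plus >= 1 condition")
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Differentially accessible peaks between two conditions
#'
#' Keeps peaks whose openness fold change between the two conditions
#' exceeds `phi` in either direction and whose larger openness exceeds
#' `min_open`. A zero denominator with a positive numerator counts as an
#' infinite ratio; peaks closed in both conditions are dropped.
#'
#' @param m openness data.frame as from [read_openness_matrix()].
#' @param t1,t2 condition column names.
#' @param phi fold-change cut (> 1); default 2.
#' @param min_open minimum openness at one of the two conditions (strict
#'   `>`); default 2.
#' @return the selected peak rows.
#' @export
differential_peaks <- function(m, t1, t2, phi = 2, min_open = 2) {
  stopifnot(phi > 1)
  for (cond in c(t1, t2)) {
    if (!cond %in% names(m)) stop("unknown condition: ", cond)
  }
  o1 <- m[[t1]]
  o2 <- m[[t2]]
  if (any(o1 < 0 | o2 < 0)) stop("openness values must be nonnegative")
  ratio <- ifelse(
    o1 == 0 & o2 == 0, 0,
    pmax(ifelse(o2 == 0, Inf, o1 / o2), ifelse(o1 == 0, Inf, o2 / o1))
  )
  keep <- ratio > phi & pmax(o1, o2) > min_open
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GWAS significant-SNP table
#'
#' TSV with a header and columns `chrom`, `pos` (1-based position),
#' `pval`. SNPs are converted to 1-bp half-open regions.
#'
#' @param path input path.
#' @param sig_cut optional genome-wide significance filter on `pval`
#'   (e.g. 5e-8); `NULL` keeps all rows.
#' @return data.frame with `chrom`, `start`, `end`, `pval`.
#' @export
read_gwas_snps <- function(path, sig_cut = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("chrom", "pos") %in% names(df))) {
    stop("GWAS table must have columns chrom, pos")
  }
  if (is.null(df$pval)) df$pval <- NA_real_
  if (!is.null(sig_cut)) df <- df[!is.na(df$pval) & df$pval < sig_cut, ]
  data.frame(chrom = df$chrom, start = df$pos - 1L, end = df$pos,
             pval = df$pval, stringsAsFactors = FALSE)
}

#' Enriched-term profile of a trait's associated SNPs
#'
#' Runs the binomial enrichment of the SNP positions (as 1-bp regions)
#' against the RE annotation resource and keeps terms with FDR below
#' `fdr_cut`.
#'
#' @param snps data.frame of SNP regions (`chrom`, `start`, `end`).
#' @param regoa a `re_annotation` resource.
#' @param loci RE loci data.frame.
#' @param fdr_cut enrichment FDR cut (default 0.05).
#' @param max_dist nearest-RE assignment cutoff in bp.
#' @return a `trait_profile`: list with the enriched term set `terms` and
#'   the full `table`.
#' @export
trait_profile <- function(snps, regoa, loci, fdr_cut = 0.05, max_dist = 1000) {
  if (nrow(snps) == 0) {
    tab <- suppressWarnings(
      enrich_regions(snps, regoa, loci, max_dist = max_dist)
    )
  } else {
    tab <- enrich_regions(snps, regoa, loci, max_dist = max_dist)
  }
  structure(
    list(terms = tab$term[tab$fdr < fdr_cut], table = tab,
         fdr_cut = fdr_cut),
    class = "trait_profile"
  )
}

#' Jaccard similarity between two traits' enriched term sets
#'
#' `|S1 intersect S2| / |S1 union S2|`; two empty sets give 0 by
#' convention (with a warning).
#'
#' @param p1,p2 `trait_profile` objects (or plain character vectors of
#'   term ids).
#' @return similarity in `[0, 1]`.
#' @export
trait_similarity <- function(p1, p2) {
  s1 <- if (inherits(p1, "trait_profile")) p1$terms else unique(p1)
  s2 <- if (inherits(p2, "trait_profile")) p2$terms else unique(p2)
  u <- union(s1, s2)
  if (length(u) == 0) {
    warning("both term sets empty; similarity reported as 0")
    return(0)
  }
  length(intersect(s1, s2)) / length(u)
}
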