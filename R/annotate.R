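# Node-term similarity with descendant maximization, per-term threshold
# calibration by f1 on gene function prediction, embedding-derived RE
# annotation and held-out AUROC evaluation.

# Normalized-vector cosine matrix between two sets of embedded nodes.
.cosine_matrix <- function(emb, rows, cols) {
  m <- emb$vectors
  norm_rows <- function(x) x / sqrt(rowSums(x^2))
  a <- norm_rows(m[rows, , drop = FALSE])
  b <- norm_rows(m[cols, , drop = FALSE])
  tcrossprod(a, b)
}

# nodes x terms matrix of sim(node, T) = max cosine over embedded
# descendants of T (T included); NA where no candidate term is embedded.
.sim_term_matrix <- function(emb, dag, nodes, terms) {
  embedded <- rownames(emb$vectors)
  nodes_in <- intersect(nodes, embedded)
  terms_in <- intersect(dag$ids, embedded)
  out <- matrix(NA_real_, length(nodes), length(terms),
                dimnames = list(nodes, terms))
  if (length(nodes_in) == 0 || length(terms_in) == 0) return(out)
  cm <- .cosine_matrix(emb, nodes_in, terms_in)
  for (t in terms) {
    cand <- intersect(c(t, go_descendants(dag, t)), terms_in)
    if (length(cand) == 0) next
    cols <- unname(as.data.frame(cm[, cand, drop = FALSE]))
    out[nodes_in, t] <- do.call(pmax, c(cols, na.rm = TRUE))
  }
  out
}

#' Similarity between an embedded node and a GO term
#'
#' `sim(v, T)` is the maximum cosine similarity between the node's vector
#' and the vectors of T and its descendants (True-Path-Rule-aware scoring:
#' a node close to any specialization of T is close to T). Terms without an
#' embedded candidate yield `NA`.
#'
#' @param emb a `node_embedding`.
#' @param dag a [go_dag].
#' @param node an embedded node id (gene or RE); unknown nodes are an error.
#' @param term a term id in `dag`.
#' @return similarity in `[-1, 1]`, or `NA` if neither the term nor any of
#'   its descendants is embedded.
#' @export
sim_node_term <- function(emb, dag, node, term) {
  stopifnot(inherits(emb, "node_embedding"))
  .check_term(dag, term)
  if (!node %in% rownames(emb$vectors)) stop("node not embedded: ", node)
  cand <- intersect(c(term, go_descendants(dag, term)), rownames(emb$vectors))
  if (length(cand) == 0) return(NA_real_)
  v <- emb$vectors[node, ]
  max(vapply(cand, function(t) cosine(v, emb$vectors[t, ]), 0))
}

#' Split a gene annotation map into train and test pairs
#'
#' The deduplicated (gene, term) pairs are partitioned at random,
#' `train_frac` of them into the training map. The split is at pair level
#' and unstratified; the two maps are disjoint and their union is the
#' input. The returned maps are not flagged closed (a pair-level subset of
#' a closed map is generally not ancestor-closed).
#'
#' @param goa a [gene_annotation].
#' @param train_frac fraction of pairs in the training map, in (0, 1).
#' @param seed integer RNG seed.
#' @return a `split_goa`: list with [gene_annotation]s `train` and `test`
#'   plus the seed.
#' @export
split_goa <- function(goa, train_frac = 0.8, seed = 1) {
  stopifnot(inherits(goa, "gene_annotation"))
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("train_frac must be in (0, 1)")
  }
  gene <- rep(names(goa$annotations), lengths(goa$annotations))
  term <- unlist(goa$annotations, use.names = FALSE)
  ord <- order(gene, term, method = "radix")  # locale-independent pair order
  gene <- gene[ord]
  term <- term[ord]
  n <- length(gene)
  idx <- with_seed(seed, sample.int(n, size = round(train_frac * n)))
  in_train <- logical(n)
  in_train[idx] <- TRUE
  structure(
    list(
      train = gene_annotation(split(term[in_train], gene[in_train])),
      test = gene_annotation(split(term[!in_train], gene[!in_train])),
      seed = seed
    ),
    class = "split_goa"
  )
}

# f1 of predicting `positive` by `sims > t`, for every candidate t.
.f1_at <- function(sims, positive, t) {
  pred <- sims > t
  tp <- sum(pred & positive)
  if (tp == 0) return(0)
  pre <- tp / sum(pred)
  rec <- tp / sum(positive)
  2 * pre * rec / (pre + rec)
}

# Candidate thresholds: f1 only changes where sims cross a value, so the
# midpoints between consecutive sorted sims plus the endpoints -1 and 1
# cover every achievable confusion table.
.threshold_candidates <- function(sims) {
  s <- sort(unique(sims))
  mids <- if (length(s) > 1) (s[-length(s)] + s[-1]) / 2 else numeric()
  c(-1, mids, 1)
}

#' Calibrate the similarity threshold of one GO term
#'
#' The threshold of term T is the cosine-similarity cut that maximizes the
#' f1 of predicting T's annotated genes (the positives in `train`) by
#' `sim(G, T) > t` over the gene universe. Since f1 changes only at
#' observed similarity values, the argmax is searched over midpoints of
#' consecutive sorted similarities plus the endpoints -1 and 1; among
#' optimal candidates the largest (most stringent) is returned.
#'
#' @param emb a `node_embedding`.
#' @param dag a [go_dag].
#' @param train a [gene_annotation] providing the gold-standard positives.
#' @param term term id to calibrate.
#' @param genes gene universe; defaults to all embedded training genes.
#' @return list with `threshold` and `f1`; threshold is `NA` (uncalibrated)
#'   for terms with no annotated gene in `train` or no embedded candidate.
#' @export
calibrate_threshold <- function(emb, dag, train, term, genes = NULL) {
  genes <- .calibration_universe(emb, train, genes)
  sims <- .sim_term_matrix(emb, dag, genes, term)[, 1]
  positive <- vapply(
    genes, function(g) term %in% train$annotations[[g]], logical(1)
  )
  .calibrate_one(sims, positive)
}

.calibration_universe <- function(emb, train, genes) {
  if (is.null(genes)) {
    genes <- intersect(names(train$annotations), rownames(emb$vectors))
  }
  if (length(genes) == 0) stop("empty gene universe for calibration")
  genes
}

.calibrate_one <- function(sims, positive) {
  ok <- !is.na(sims)
  sims <- sims[ok]
  positive <- positive[ok]
  if (length(sims) == 0 || sum(positive) == 0) {
    return(list(threshold = NA_real_, f1 = NA_real_))
  }
  cand <- .threshold_candidates(sims)
  f1 <- vapply(cand, function(t) .f1_at(sims, positive, t), 0)
  best <- max(f1)
  list(threshold = max(cand[f1 == best]), f1 = best)
}

#' Calibrate thresholds for every annotated term
#'
#' Runs [calibrate_threshold()] for each term with at least one annotated
#' gene in `train`; terms that are never embedded (absent from every walk,
#' along with all their descendants) are skipped.
#'
#' @inheritParams calibrate_threshold
#' @param terms terms to consider; defaults to all DAG terms.
#' @return a `term_thresholds`: data.frame with columns `term`,
#'   `threshold`, `f1`.
#' @export
calibrate_thresholds <- function(emb, dag, train, genes = NULL, terms = NULL) {
  genes <- .calibration_universe(emb, train, genes)
  if (is.null(terms)) terms <- dag$ids
  annotated <- unique(unlist(train$annotations, use.names = FALSE))
  terms <- intersect(terms, annotated)
  sims <- .sim_term_matrix(emb, dag, genes, terms)
  res <- lapply(terms, function(t) {
    positive <- vapply(
      genes, function(g) t %in% train$annotations[[g]], logical(1)
    )
    .calibrate_one(sims[, t], positive)
  })
  out <- data.frame(
    term = terms,
    threshold = vapply(res, `[[`, 0, "threshold"),
    f1 = vapply(res, `[[`, 0, "f1"),
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_thresholds", "data.frame")
  out
}

#' Embedding-derived RE annotations
#'
#' An RE is annotated with every calibrated term whose similarity (with
#' descendant maximization) strictly exceeds the term's threshold, plus all
#' ancestors of such terms, so the result is ancestor-closed by
#' construction. REs without an embedding receive the empty set with a
#' warning.
#'
#' @param emb a `node_embedding`.
#' @param dag a [go_dag].
#' @param thresholds a `term_thresholds` from [calibrate_thresholds()].
#' @param res character vector of RE ids.
#' @return a `re_annotation` of kind `"embed"` over `res`.
#' @export
goa_embed <- function(emb, dag, thresholds, res) {
  stopifnot(inherits(thresholds, "term_thresholds"))
  unembedded <- setdiff(res, rownames(emb$vectors))
  if (length(unembedded) > 0) {
    warning(length(unembedded), " RE(s) without embedding receive no ",
            "embedding-derived terms")
  }
  anc <- ancestors_table(dag)
  sims <- .sim_term_matrix(emb, dag, res, thresholds$term)
  thr <- thresholds$threshold
  ann <- lapply(res, function(r) {
    s <- sims[r, ]
    hits <- thresholds$term[!is.na(s) & s > thr]
    unique(c(hits, unlist(anc[hits], use.names = FALSE)))
  })
  names(ann) <- res
  re_annotation(ann, kind = "embed")
}

#' Final RE annotation: intersection of embedding- and regulation-derived sets
#'
#' For each RE the final term set is the intersection of its
#' embedding-derived set with its regulation-derived set, so the final
#' resource only keeps embedding calls that are supported by the RE's
#' target-gene annotations. Intersections of ancestor-closed sets are
#' ancestor-closed.
#'
#' @param embed_map a `re_annotation` of kind `"embed"`.
#' @param raw_map a `re_annotation` of kind `"raw"` over the same REs.
#' @return a `re_annotation` of kind `"final"`.
#' @export
annotate_res <- function(embed_map, raw_map) {
  stopifnot(inherits(embed_map, "re_annotation"),
            inherits(raw_map, "re_annotation"))
  res <- names(raw_map$annotations)
  ann <- lapply(res, function(r) {
    intersect(embed_map$annotations[[r]], raw_map$annotations[[r]])
  })
  names(ann) <- res
  re_annotation(ann, kind = "final")
}

#' Held-out AUROC of gene function prediction
#'
#' Scores every held-out (gene, term) pair by `sim(G, T)` and compares the
#' scores against an equal number (`neg_ratio` per positive) of negative
#' pairs sampled uniformly from (gene, term) combinations absent from the
#' full closed annotation map. The AUROC is computed from the rank
#' statistic (ties shared).
#'
#' @param emb a `node_embedding`.
#' @param dag a [go_dag].
#' @param test a [gene_annotation] of held-out pairs.
#' @param full_goa the complete closed [gene_annotation] (train and test),
#'   defining the negative universe.
#' @param genes gene universe for negatives; defaults to embedded genes of
#'   `full_goa`.
#' @param neg_ratio negatives sampled per scored positive.
#' @param seed integer RNG seed for negative sampling.
#' @return list with `auroc`, `n_pos`, `n_neg`.
#' @export
evaluate_auroc <- function(emb, dag, test, full_goa, genes = NULL,
                           neg_ratio = 1, seed = 1) {
  stopifnot(inherits(test, "gene_annotation"),
            inherits(full_goa, "gene_annotation"))
  if (is.null(genes)) {
    genes <- intersect(names(full_goa$annotations), rownames(emb$vectors))
  }
  genes <- genes[order(genes, method = "radix")]
  pair_gene <- rep(names(test$annotations), lengths(test$annotations))
  pair_term <- unlist(test$annotations, use.names = FALSE)
  keep <- pair_gene %in% rownames(emb$vectors) & pair_term %in% dag$ids
  pair_gene <- pair_gene[keep]
  pair_term <- pair_term[keep]
  if (length(pair_gene) == 0) stop("no embedded held-out positives to score")

  sims <- .sim_term_matrix(emb, dag, unique(pair_gene), unique(pair_term))
  pos_scores <- sims[cbind(pair_gene, pair_term)]
  scored <- !is.na(pos_scores)
  pos_scores <- pos_scores[scored]
  if (length(pos_scores) == 0) stop("no scoreable held-out positives")

  known <- stats::setNames(full_goa$annotations[genes], genes)
  n_neg <- round(neg_ratio * length(pos_scores))
  neg <- with_seed(seed, {
    out_g <- character(n_neg)
    out_t <- character(n_neg)
    got <- 0L
    guard <- 0L
    while (got < n_neg) {
      guard <- guard + 1L
      if (guard > 1000L * n_neg) {
        stop("could not sample enough unannotated negative pairs")
      }
      g <- genes[[sample.int(length(genes), 1L)]]
      t <- dag$ids[[sample.int(length(dag$ids), 1L)]]
      if (t %in% known[[g]]) next
      got <- got + 1L
      out_g[[got]] <- g
      out_t[[got]] <- t
    }
    data.frame(gene = out_g, term = out_t, stringsAsFactors = FALSE)
  })
  neg_sims <- .sim_term_matrix(emb, dag, unique(neg$gene), unique(neg$term))
  neg_scores <- neg_sims[cbind(neg$gene, neg$term)]
  neg_scores <- neg_scores[!is.na(neg_scores)]
  if (length(neg_scores) == 0) stop("no scoreable negative pairs")

  scores <- c(pos_scores, neg_scores)
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(scores)
  auroc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  list(auroc = auroc, n_pos = np, n_neg = nn)
}

#' Write the RE annotation resource as TSV
#'
#' One row per annotated RE: id, locus (0-based half-open) and a
#' semicolon-joined term list.
#'
#' @param map a `re_annotation`.
#' @param loci data.frame with columns `re`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_re_annotation <- function(map, loci, path) {
  stopifnot(inherits(map, "re_annotation"))
  keep <- names(map$annotations)[lengths(map$annotations) > 0]
  i <- match(keep, loci$re)
  if (anyNA(i)) stop("RE(s) missing from loci: ",
                     paste(keep[is.na(i)], collapse = ", "))
  df <- data.frame(
    re = keep, chrom = loci$chrom[i], start = loci$start[i],
    end = loci$end[i],
    terms = vapply(map$annotations[keep], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RE annotation resource written by [write_re_annotation()]
#'
#' @param path resource TSV path.
#' @param kind the `re_annotation` kind to stamp on the result.
#' @return list with the `re_annotation` and the `loci` data.frame.
#' @export
read_re_annotation <- function(path, kind = "final") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  ann <- stats::setNames(strsplit(df$terms, ";", fixed = TRUE), df$re)
  list(
    annotation = re_annotation(ann, kind = kind),
    loci = df[c("re", "chrom", "start", "end")]
  )
}

#' Write calibrated thresholds as TSV
#'
#' @param thresholds a `term_thresholds`.
#' @param path output path; columns `term`, `threshold`, `f1_at_opt`.
#' @export
write_thresholds <- function(thresholds, path) {
  df <- data.frame(term = thresholds$term, threshold = thresholds$threshold,
                   f1_at_opt = thresholds$f1)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
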