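# Loading PPI/GRN inputs and assembling the heterogeneous network of
# {Term, Gene, RE, TF} nodes with its seven typed edge sets.

#' Load a STRING-style protein-protein interaction table
#'
#' Expects a TSV with columns `protein1`, `protein2`, `combined_score`
#' (whitespace-delimited STRING dumps are accepted too). Edges below
#' `min_score` and self-loops are dropped, pairs are stored canonically
#' (lexicographically smaller protein first) and duplicate pairs keep the
#' maximum score.
#'
#' @param path input file path.
#' @param min_score minimum `combined_score` to keep an edge.
#' @return a `ppi_network`: data.frame with columns `protein1`, `protein2`,
#'   `weight`.
#' @export
load_ppi <- function(path, min_score = 0) {
  df <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                          stringsAsFactors = FALSE)
  req <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("PPI table is missing column(s): ", paste(missing, collapse = ", "))
  }
  ppi_network(df$protein1, df$protein2, df$combined_score,
              min_score = min_score)
}

#' @rdname load_ppi
#' @param protein1,protein2 character vectors of interaction partners.
#' @param weight numeric interaction scores (input-scale units, > 0).
#' @export
ppi_network <- function(protein1, protein2, weight = 1, min_score = 0) {
  df <- data.frame(
    protein1 = as.character(protein1),
    protein2 = as.character(protein2),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  df <- df[df$weight >= min_score & df$protein1 != df$protein2, , drop = FALSE]
  if (nrow(df) > 0) {
    # canonical pair order and sorting in C collation, locale-independent
    n <- nrow(df)
    r <- integer(2L * n)
    r[order(c(df$protein1, df$protein2), method = "radix")] <- seq_len(2L * n)
    swap <- r[seq_len(n)] > r[n + seq_len(n)]
    tmp <- df$protein1[swap]
    df$protein1[swap] <- df$protein2[swap]
    df$protein2[swap] <- tmp
    df <- df[order(df$protein1, df$protein2, -df$weight, method = "radix"), ,
             drop = FALSE]
    df <- df[!duplicated(df[c("protein1", "protein2")]), , drop = FALSE]
  }
  if (any(df$weight <= 0)) stop("PPI weights must be > 0")
  rownames(df) <- NULL
  class(df) <- c("ppi_network", "data.frame")
  df
}

#' Load a gene regulatory network from its three component tables
#'
#' The canonical dialect is three headered TSVs: TF-to-RE binding edges
#' (`tf`, `re`, `weight`), RE-to-target-gene regulation edges (`re`, `gene`,
#' `weight`) and RE genomic loci (`re`, `chrom`, `start`, `end`; 0-based
#' half-open, BED convention). A `weight` column is optional (defaults to 1).
#' Binding rows carrying a `type` column equal to `CR` (chromatin-regulator
#' recruitment) are skipped with a message. Duplicate edges keep the maximum
#' weight. Every RE appearing in an edge must have a locus.
#'
#' @param binds_path,regulates_path,loci_path paths to the three TSVs.
#' @return a `regulatory_network`: list with data.frames `binds`
#'   (`tf`, `re`, `weight`), `regulates` (`re`, `gene`, `weight`) and `loci`
#'   (`re`, `chrom`, `start`, `end`).
#' @export
load_grn <- function(binds_path, regulates_path, loci_path) {
  read_tsv <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    df
  }
  binds <- read_tsv(binds_path)
  regulates <- read_tsv(regulates_path)
  loci <- read_tsv(loci_path)
  if (!all(c("tf", "re") %in% names(binds))) {
    stop("binds table must have columns tf, re")
  }
  if (!all(c("re", "gene") %in% names(regulates))) {
    stop("regulates table must have columns re, gene")
  }
  if (!all(c("re", "chrom", "start", "end") %in% names(loci))) {
    stop("loci table must have columns re, chrom, start, end")
  }
  if ("type" %in% names(binds)) {
    cr <- toupper(binds$type) == "CR"
    if (any(cr)) message("skipping ", sum(cr), " CR recruitment row(s)")
    binds <- binds[!cr, , drop = FALSE]
  }
  if (is.null(binds$weight)) binds$weight <- 1
  if (is.null(regulates$weight)) regulates$weight <- 1
  regulatory_network(
    binds = binds[c("tf", "re", "weight")],
    regulates = regulates[c("re", "gene", "weight")],
    loci = loci[c("re", "chrom", "start", "end")]
  )
}

#' @rdname load_grn
#' @param binds,regulates,loci data.frames as described above.
#' @export
regulatory_network <- function(binds, regulates, loci) {
  dedup_max <- function(df, keys) {
    df <- df[order(df[[keys[1]]], df[[keys[2]]], -df$weight,
                   method = "radix"), , drop = FALSE]
    df <- df[!duplicated(df[keys]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  binds <- dedup_max(as.data.frame(binds), c("tf", "re"))
  regulates <- dedup_max(as.data.frame(regulates), c("re", "gene"))
  loci <- as.data.frame(loci)
  rownames(loci) <- NULL
  if (anyDuplicated(loci$re)) {
    stop("duplicate RE id(s) in loci table: ",
         paste(unique(loci$re[duplicated(loci$re)]), collapse = ", "))
  }
  if (any(binds$weight <= 0) || any(regulates$weight <= 0)) {
    stop("GRN edge weights must be > 0")
  }
  unmapped <- setdiff(unique(c(binds$re, regulates$re)), loci$re)
  if (length(unmapped) > 0) {
    stop("RE(s) referenced without a locus: ", paste(unmapped, collapse = ", "))
  }
  structure(
    list(binds = binds, regulates = regulates, loci = loci),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(
    "regulatory_network: %d TF->RE binding edges, %d RE->gene regulation edges, %d RE loci\n",
    nrow(x$binds), nrow(x$regulates), nrow(x$loci)
  ))
  invisible(x)
}

#' Restrict regulation edges to proximal or distal RE-gene pairs
#'
#' Splits the `regulates` edge set by the genomic distance between the RE
#' interval and its target gene's transcription start site, for ablation
#' runs contrasting proximal (within `cutoff`, default 5 kb) against distal
#' regulation.
#'
#' @param grn a `regulatory_network`.
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (0-based TSS).
#' @param keep `"proximal"` or `"distal"`.
#' @param cutoff distance cut in bp; proximal means distance <= cutoff.
#' @return the `regulatory_network` with a filtered `regulates` table.
#' @export
filter_regulates_by_distance <- function(grn, tss, keep = c("proximal", "distal"),
                                         cutoff = 5000) {
  keep <- match.arg(keep)
  stopifnot(inherits(grn, "regulatory_network"))
  if (!all(c("gene", "chrom", "pos") %in% names(tss))) {
    stop("tss table must have columns gene, chrom, pos")
  }
  reg <- grn$regulates
  li <- match(reg$re, grn$loci$re)
  gi <- match(reg$gene, tss$gene)
  if (anyNA(gi)) {
    stop("gene(s) without a TSS entry: ",
         paste(unique(reg$gene[is.na(gi)]), collapse = ", "))
  }
  same_chr <- grn$loci$chrom[li] == tss$chrom[gi]
  pos <- tss$pos[gi]
  start <- grn$loci$start[li]
  end <- grn$loci$end[li]
  dist <- ifelse(pos < start, start - pos,
                 ifelse(pos >= end, pos - end + 1L, 0L))
  dist[!same_chr] <- Inf
  sel <- if (keep == "proximal") dist <= cutoff else dist > cutoff
  regulatory_network(grn$binds, reg[sel, , drop = FALSE], grn$loci)
}

#' Construct an RE annotation map
#'
#' @param annotations named list mapping RE ids to character vectors of GO
#'   term ids.
#' @param kind one of `"raw"` (regulation-derived), `"embed"`
#'   (embedding-derived) or `"final"` (their intersection).
#' @return an object of class `re_annotation`.
#' @export
re_annotation <- function(annotations, kind = c("raw", "embed", "final")) {
  kind <- match.arg(kind)
  stopifnot(is.list(annotations))
  if (length(annotations) > 0 && is.null(names(annotations))) {
    stop("'annotations' must be named by RE id")
  }
  structure(
    list(annotations = lapply(annotations, function(x) unique(as.character(x))),
         kind = kind),
    class = "re_annotation"
  )
}

#' @export
print.re_annotation <- function(x, ...) {
  n_ann <- sum(lengths(x$annotations) > 0)
  cat(sprintf(
    "re_annotation [%s]: %d REs, %d with >=1 term, %d (RE,term) pairs\n",
    x$kind, length(x$annotations), n_ann, sum(lengths(x$annotations))
  ))
  invisible(x)
}

#' Regulation-derived RE annotations
#'
#' An RE inherits the (closed) annotation set of every gene it regulates:
#' the raw term set of RE R is the union of the gene annotations over R's
#' target genes. REs with no annotated target map to the empty set. Since a
#' union of ancestor-closed sets is ancestor-closed, the result is closed.
#'
#' @param grn a `regulatory_network`.
#' @param goa a closed [gene_annotation]; passing an unclosed map is an error.
#' @return a `re_annotation` of kind `"raw"` over all REs with a locus.
#' @export
goa_raw <- function(grn, goa) {
  stopifnot(inherits(grn, "regulatory_network"), inherits(goa, "gene_annotation"))
  if (!goa$closed) {
    stop("goa_raw() requires an ancestor-closed annotation map; ",
         "call close_annotations() first")
  }
  res <- grn$loci$re
  targets <- split(grn$regulates$gene, factor(grn$regulates$re, levels = res))
  ann <- lapply(targets, function(genes) {
    unique(unlist(goa$annotations[intersect(genes, names(goa$annotations))],
                  use.names = FALSE))
  })
  ann <- lapply(ann, function(x) if (is.null(x)) character() else x)
  re_annotation(ann, kind = "raw")
}

HETNET_EDGE_TYPES <- c("isa", "annotated", "interacts", "binds",
                       "regulates", "indirect_annotated", "coregulates")

# Node-type pair (unordered, "A|B" with A <= B) -> edge type, used to
# translate meta-path steps into edge-type constraints.
EDGE_TYPE_BY_PAIR <- c(
  "T|T" = "isa",
  "G|T" = "annotated",
  "G|G" = "interacts",
  "F|R" = "binds",
  "G|R" = "regulates",
  "R|T" = "indirect_annotated",
  "R|R" = "coregulates"
)

#' Assemble the heterogeneous network
#'
#' Builds the typed multigraph over GO terms (T), genes (G), regulatory
#' elements (R) and transcription factors (F). Five edge sets are copied
#' from the inputs (`isa`, `annotated`, `interacts`, `binds`, `regulates`)
#' and two are inferred: `indirect_annotated(R, T)` holds when R regulates
#' some gene annotated by T, and `coregulates(R1, R2)` when R1 and R2 share
#' a target gene. Sources without weights contribute weight 1. By default a
#' TF symbol yields a TF node (id prefixed `TF:`) distinct from the same
#' symbol's gene node, so the two receive independent embeddings;
#' `split_tf_gene = FALSE` collapses them onto the gene node.
#'
#' @param dag a [go_dag].
#' @param goa a [gene_annotation]; normally closed. Evaluation splits may
#'   pass an unclosed training subset.
#' @param ppi a `ppi_network` or `NULL` to omit interaction edges.
#' @param grn a `regulatory_network` or `NULL` to omit the regulatory layer
#'   (no RE or TF nodes).
#' @param split_tf_gene logical; see above.
#' @return a `hetnet`: list with data.frames `nodes` (`id`, `type`) and
#'   `edges` (`from`, `to`, `type`, `weight`).
#' @export
assemble_hetnet <- function(dag, goa, ppi = NULL, grn = NULL,
                            split_tf_gene = TRUE) {
  stopifnot(inherits(dag, "go_dag"), inherits(goa, "gene_annotation"))
  edges <- list()
  edge_df <- function(from, to, type, weight = 1) {
    if (length(from) == 0) return(NULL)
    data.frame(from = from, to = to, type = type, weight = weight,
               stringsAsFactors = FALSE)
  }

  child <- rep(names(dag$parents), lengths(dag$parents))
  edges$isa <- edge_df(child, unlist(dag$parents, use.names = FALSE), "isa")

  ann_gene <- rep(names(goa$annotations), lengths(goa$annotations))
  edges$annotated <- edge_df(
    ann_gene, unlist(goa$annotations, use.names = FALSE), "annotated"
  )

  genes <- names(goa$annotations)
  if (!is.null(ppi)) {
    stopifnot(inherits(ppi, "ppi_network"))
    edges$interacts <- edge_df(ppi$protein1, ppi$protein2, "interacts",
                               ppi$weight)
    genes <- union(genes, c(ppi$protein1, ppi$protein2))
  }

  res <- character()
  tfs <- character()
  if (!is.null(grn)) {
    stopifnot(inherits(grn, "regulatory_network"))
    res <- grn$loci$re
    tf_id <- if (split_tf_gene) paste0("TF:", grn$binds$tf) else grn$binds$tf
    tfs <- unique(tf_id)
    edges$binds <- edge_df(tf_id, grn$binds$re, "binds", grn$binds$weight)
    edges$regulates <- edge_df(grn$regulates$re, grn$regulates$gene,
                               "regulates", grn$regulates$weight)
    genes <- union(genes, grn$regulates$gene)
    if (!split_tf_gene) genes <- union(genes, grn$binds$tf)

    # indirect annotation: R regulates G, G annotated by T => R -- T
    raw <- lapply(
      split(grn$regulates$gene, factor(grn$regulates$re, levels = res)),
      function(g) unique(unlist(goa$annotations[intersect(g, names(goa$annotations))],
                                use.names = FALSE))
    )
    edges$indirect_annotated <- edge_df(
      rep(names(raw), lengths(raw)), unlist(raw, use.names = FALSE),
      "indirect_annotated"
    )

    # coregulation: R1 and R2 share a target gene (canonical order, no loops)
    by_gene <- split(grn$regulates$re, grn$regulates$gene)
    pairs <- lapply(by_gene, function(r) {
      r <- sort(unique(r))
      if (length(r) < 2) return(NULL)
      idx <- utils::combn(length(r), 2)
      data.frame(from = r[idx[1, ]], to = r[idx[2, ]],
                 stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairs)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      pairs <- unique(pairs)
      edges$coregulates <- edge_df(pairs$from, pairs$to, "coregulates")
    }
  }

  edges <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
  # deterministic, locale-independent edge order (walk RNG depends on it)
  edges <- edges[order(edges$type, edges$from, edges$to,
                       method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  genes <- unique(genes)
  nodes <- rbind(
    data.frame(id = dag$ids, type = "T", stringsAsFactors = FALSE),
    data.frame(id = genes[order(genes, method = "radix")], type = "G",
               stringsAsFactors = FALSE),
    if (length(res) > 0) data.frame(id = res, type = "R", stringsAsFactors = FALSE),
    if (length(tfs) > 0 && split_tf_gene)
      data.frame(id = tfs, type = "F", stringsAsFactors = FALSE)
  )
  if (anyDuplicated(nodes$id)) {
    stop("node id collision across types: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) without a node: ", paste(missing, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  nt <- table(x$nodes$type)
  et <- table(x$edges$type)
  cat("hetnet:\n  nodes:",
      paste(sprintf("%s=%d", names(nt), nt), collapse = ", "),
      "\n  edges:",
      paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a heterogeneous network as a typed edge-list TSV
#'
#' @param net a `hetnet`.
#' @param path output path; columns `from`, `to`, `type`, `weight`.
#' @export
write_hetnet <- function(net, path) {
  stopifnot(inherits(net, "hetnet"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
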