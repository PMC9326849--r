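# GO DAG handling: OBO parsing, ancestor closure (True Path Rule) and a
# Wang-style semantic similarity used for evaluation.

NAMESPACE_MAP <- c(
  biological_process = "BP",
  molecular_function = "MF",
  cellular_component = "CC"
)

#' Construct a GO DAG object
#'
#' Low-level constructor for the directed acyclic graph of GO terms used
#' throughout the package. Terms belong to a single namespace (BP, MF or CC)
#' and are connected by `is_a` edges only. Most users will obtain a `go_dag`
#' from [parse_obo()] or [make_toy_ontology()] instead.
#'
#' @param parents named list mapping each term id to the character vector of
#'   its `is_a` parents (empty vector for roots). Every referenced parent must
#'   itself be a name of the list.
#' @param names optional named character vector of term labels.
#' @param namespace one of `"BP"`, `"MF"`, `"CC"`.
#' @param alt_ids optional named character vector mapping alternate ids to
#'   primary term ids.
#' @return an object of class `go_dag` with elements `ids`, `parents`,
#'   `children`, `roots`, `names`, `namespace`, `alt_ids`.
#' @export
go_dag <- function(parents, names = NULL, namespace = "BP", alt_ids = character()) {
  namespace <- match.arg(namespace, c("BP", "MF", "CC"))
  ids <- base::names(parents)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("'parents' must be a named list with unique term ids")
  }
  parents <- lapply(parents, function(p) unique(as.character(p)))
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown) > 0) {
    stop("parent term(s) not present in DAG: ", paste(unknown, collapse = ", "))
  }
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) children[[i]] <- character()
  for (t in ids) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  dag <- structure(
    list(
      ids = ids,
      parents = parents,
      children = children,
      roots = ids[vapply(parents, length, 1L) == 0L],
      names = names,
      namespace = namespace,
      alt_ids = alt_ids
    ),
    class = "go_dag"
  )
  .check_acyclic(dag)
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf(
    "go_dag [%s]: %d terms, %d is_a edges, root(s): %s\n",
    x$namespace, length(x$ids), sum(lengths(x$parents)),
    paste(x$roots, collapse = ", ")
  ))
  invisible(x)
}

# Kahn topological sort; errors naming one offending edge if a cycle exists.
.check_acyclic <- function(dag) {
  indeg <- lengths(dag$parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  indeg_env <- indeg
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (c in dag$children[[t]]) {
      indeg_env[[c]] <- indeg_env[[c]] - 1L
      if (indeg_env[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(dag$ids)) {
    leftover <- names(indeg_env)[indeg_env > 0L]
    bad <- leftover[[1]]
    bad_parent <- intersect(dag$parents[[bad]], leftover)[[1]]
    stop(sprintf(
      "cycle detected in is_a hierarchy, involving edge %s is_a %s",
      bad, bad_parent
    ))
  }
  invisible(TRUE)
}

#' Validate the structural invariants of a GO DAG
#'
#' Checks acyclicity, the existence of exactly one root and that every term
#' is reachable from the root by following `is_a` edges downwards.
#'
#' @param dag a [go_dag] object.
#' @return `TRUE` invisibly; errors describing the violation otherwise.
#' @export
validate_go_dag <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  .check_acyclic(dag)
  if (length(dag$roots) != 1L) {
    stop("expected exactly one root term, found ", length(dag$roots))
  }
  reach <- c(dag$roots, go_descendants(dag, dag$roots))
  missing <- setdiff(dag$ids, reach)
  if (length(missing) > 0) {
    stop("term(s) unreachable from root: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Parse an OBO ontology file into a single-namespace GO DAG
#'
#' Reads an OBO 1.2/1.4 flat file, keeps non-obsolete `[Term]` stanzas of the
#' requested namespace and the `is_a` edges among them. Edges pointing at
#' terms of other namespaces (or at dropped terms) are discarded; other
#' relationship types (`part_of`, `regulates`, ...) are ignored entirely.
#' `alt_id` aliases are recorded so annotation readers can resolve them to
#' primary ids.
#'
#' @param path path to the OBO file.
#' @param namespace `"BP"`, `"MF"` or `"CC"`.
#' @return a [go_dag].
#' @export
parse_obo <- function(path, namespace = "BP") {
  namespace <- match.arg(namespace, c("BP", "MF", "CC"))
  lines <- readLines(path, warn = FALSE)
  default_ns <- NA_character_
  in_term <- FALSE
  stanza_line <- NA_integer_
  terms <- list()
  cur <- NULL

  flush <- function(cur) {
    if (is.null(cur)) return()
    if (is.na(cur$id)) {
      stop(sprintf("malformed [Term] stanza at line %d: missing id", cur$line))
    }
    terms[[length(terms) + 1L]] <<- cur
  }
  new_term <- function(line) {
    list(
      id = NA_character_, name = NA_character_, namespace = NA_character_,
      is_a = character(), alt_id = character(), obsolete = FALSE, line = line
    )
  }

  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush(cur)
      cur <- NULL
      in_term <- line == "[Term]"
      if (in_term) cur <- new_term(i)
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z_-]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) {
      if (in_term) stop(sprintf("malformed line %d in OBO file: '%s'", i, line))
      next
    }
    key <- m[[2]]
    val <- m[[3]]
    if (!in_term) {
      if (key == "default-namespace") default_ns <- val
      next
    }
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, sub("\\s*!.*$", "", val))
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete" && grepl("^true", val)) cur$obsolete <- TRUE
  }
  flush(cur)

  ns_of <- function(t) {
    ns <- if (is.na(t$namespace)) default_ns else t$namespace
    unname(NAMESPACE_MAP[ns])
  }
  keep <- vapply(
    terms,
    function(t) !t$obsolete && identical(ns_of(t), namespace),
    logical(1)
  )
  terms <- terms[keep]
  if (length(terms) == 0) {
    stop("no non-obsolete terms of namespace ", namespace, " found in ", path)
  }
  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s) in OBO file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  alt <- character()
  for (t in terms) {
    if (length(t$alt_id) > 0) {
      alt[t$alt_id] <- t$id
    }
  }
  parents <- stats::setNames(
    lapply(terms, function(t) {
      p <- t$is_a
      p[p %in% names(alt)] <- alt[p[p %in% names(alt)]]
      intersect(unique(p), ids)
    }),
    ids
  )
  go_dag(
    parents,
    names = stats::setNames(vapply(terms, `[[`, "", "name"), ids),
    namespace = namespace,
    alt_ids = alt
  )
}

.check_term <- function(dag, term) {
  if (!term %in% dag$ids) stop("unknown term id: ", term)
}

.bfs_closure <- function(link, start) {
  out <- character()
  frontier <- link[[start]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
    frontier <- unique(unlist(link[frontier], use.names = FALSE))
  }
  out
}

#' Ancestors of a GO term
#'
#' All terms reachable from `term` by following `is_a` edges upwards,
#' excluding the term itself.
#'
#' @param dag a [go_dag].
#' @param term a term id present in `dag`.
#' @return character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag, term) {
  .check_term(dag, term)
  .bfs_closure(dag$parents, term)
}

#' Descendants of a GO term
#'
#' All terms reachable from `term` by following `is_a` edges downwards,
#' excluding the term itself. `t` is a descendant of `T` exactly when `T` is
#' an ancestor of `t`.
#'
#' @inheritParams go_ancestors
#' @return character vector of descendant term ids.
#' @export
go_descendants <- function(dag, term) {
  .check_term(dag, term)
  .bfs_closure(dag$children, term)
}

# Ancestor sets for every term, computed once in topological order.
ancestors_table <- function(dag) {
  anc <- stats::setNames(vector("list", length(dag$ids)), dag$ids)
  order <- .topo_order(dag)
  for (t in order) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

.topo_order <- function(dag) {
  indeg <- lengths(dag$parents)
  queue <- names(indeg)[indeg == 0L]
  out <- character(length(dag$ids))
  k <- 0L
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    k <- k + 1L
    out[[k]] <- t
    for (c in dag$children[[t]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  out
}

#' Construct a gene annotation map
#'
#' @param annotations named list mapping gene ids to character vectors of GO
#'   term ids.
#' @param closed logical; whether True-Path-Rule closure has been applied.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(annotations, closed = FALSE) {
  stopifnot(is.list(annotations))
  if (length(annotations) > 0 && is.null(names(annotations))) {
    stop("'annotations' must be named by gene id")
  }
  structure(
    list(annotations = lapply(annotations, function(x) unique(as.character(x))),
         closed = isTRUE(closed)),
    class = "gene_annotation"
  )
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf(
    "gene_annotation: %d genes, %d (gene,term) pairs, %s\n",
    length(x$annotations), sum(lengths(x$annotations)),
    if (x$closed) "ancestor-closed" else "raw"
  ))
  invisible(x)
}

#' Read gene-to-term annotations
#'
#' Two dialects are supported: a plain two-column TSV (`gene<TAB>GO:ID`,
#' no header) and GAF 2.x, from which the gene symbol (column 3) and GO id
#' (column 5) are taken; GAF rows whose qualifier contains `NOT` are dropped,
#' as are `!`-prefixed comment lines. No evidence-code filtering is applied.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"gaf"`.
#' @return a [gene_annotation] with `closed = FALSE`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0) return(gene_annotation(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(lengths(fields) < 2L)
    if (length(bad) > 0) {
      stop("annotation TSV row ", bad[[1]], " has fewer than 2 columns")
    }
    gene <- vapply(fields, `[[`, "", 1L)
    term <- vapply(fields, `[[`, "", 2L)
  } else {
    bad <- which(lengths(fields) < 5L)
    if (length(bad) > 0) {
      stop("GAF row ", bad[[1]], " has fewer than 5 columns")
    }
    qualifier <- vapply(fields, `[[`, "", 4L)
    keep <- !grepl("NOT", qualifier)
    gene <- vapply(fields, `[[`, "", 3L)[keep]
    term <- vapply(fields, `[[`, "", 5L)[keep]
  }
  gene_annotation(split(term, gene))
}

#' Apply the True Path Rule to a gene annotation map
#'
#' Every gene annotated by a term is also annotated by all of that term's
#' ancestors, so the closed map for gene G is the union of its raw terms and
#' their ancestor sets. Alternate ids are resolved to primary ids first;
#' terms absent from the DAG are dropped with a warning. Closing an already
#' closed map is a no-op.
#'
#' @param dag a [go_dag].
#' @param raw a [gene_annotation].
#' @return a [gene_annotation] with `closed = TRUE`.
#' @export
close_annotations <- function(dag, raw) {
  stopifnot(inherits(dag, "go_dag"), inherits(raw, "gene_annotation"))
  anc <- ancestors_table(dag)
  dropped <- 0L
  closed <- lapply(raw$annotations, function(terms) {
    alias <- terms %in% names(dag$alt_ids)
    terms[alias] <- dag$alt_ids[terms[alias]]
    known <- terms %in% dag$ids
    dropped <<- dropped + sum(!known)
    terms <- unique(terms[known])
    unique(c(terms, unlist(anc[terms], use.names = FALSE)))
  })
  if (dropped > 0) {
    warning(dropped, " annotation(s) referenced terms absent from the ",
            dag$namespace, " DAG and were dropped")
  }
  gene_annotation(closed, closed = TRUE)
}

#' Wang-style semantic similarity between two GO terms
#'
#' For a term A, every ancestor t contributes an S-value
#' `S_A(t) = decay * max over children c of t inside A's ancestor sub-DAG`
#' with `S_A(A) = 1`. The similarity of A and B is the sum of `S_A + S_B`
#' over their shared sub-DAG terms divided by the sum of all S-values of
#' both terms. The measure is symmetric, lies in `[0, 1]` and equals 1 for
#' identical terms.
#'
#' @param dag a [go_dag].
#' @param t1,t2 term ids.
#' @param decay per-edge contribution factor in (0, 1); default 0.8.
#' @return similarity score in `[0, 1]`.
#' @export
term_similarity <- function(dag, t1, t2, decay = 0.8) {
  .check_term(dag, t1)
  .check_term(dag, t2)
  stopifnot(decay > 0, decay < 1)
  if (t1 == t2) return(1)
  s1 <- .svalues(dag, t1, decay)
  s2 <- .svalues(dag, t2, decay)
  common <- intersect(names(s1), names(s2))
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

# S-values over the is_a-induced sub-DAG of term a (a plus its ancestors).
.svalues <- function(dag, a, decay) {
  sub <- c(a, go_ancestors(dag, a))
  memo <- new.env(parent = emptyenv())
  assign(a, 1, envir = memo)
  sv <- function(t) {
    if (exists(t, envir = memo, inherits = FALSE)) {
      return(get(t, envir = memo, inherits = FALSE))
    }
    kids <- intersect(dag$children[[t]], sub)
    v <- decay * max(vapply(kids, sv, 0))
    assign(t, v, envir = memo)
    v
  }
  stats::setNames(vapply(sub, sv, 0), sub)
}
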