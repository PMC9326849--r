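# Meta-path expansion, meta-path-guided random walks and skip-gram training.

#' Define a meta-path
#'
#' A meta-path is an ordered sequence of node-type symbols over
#' `{T, G, R, F}` that constrains which typed edges a random walk may
#' traverse. Repeatable meta-paths are extended to a requested walk length
#' by tiling a cycle after a fixed prefix, matching the printed repetition
#' pattern of each default path (e.g. FRF extends as F,R,F,R,F,... while
#' RGGR tiles verbatim as R,G,G,R,R,G,G,R,...).
#'
#' @param name short label.
#' @param unit character vector of node-type symbols, e.g. `c("F","R","F")`.
#' @param repeatable logical; if `FALSE` the expansion is always `unit`.
#' @param prefix,cycle expansion pattern for repeatable paths: the expansion
#'   is `prefix` followed by `cycle` repeated, truncated at the requested
#'   length. Defaults to `prefix = character()`, `cycle = unit`.
#' @return an object of class `metapath`.
#' @export
metapath <- function(name, unit, repeatable = TRUE,
                     prefix = character(), cycle = unit) {
  unit <- as.character(unit)
  stopifnot(all(unit %in% c("T", "G", "R", "F")), length(unit) >= 2)
  pairs <- paste(pmin(unit[-length(unit)], unit[-1]),
                 pmax(unit[-length(unit)], unit[-1]), sep = "|")
  bad <- setdiff(pairs, names(EDGE_TYPE_BY_PAIR))
  if (length(bad) > 0) {
    stop("meta-path ", name, " contains type pair(s) with no edge type: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(name = name, unit = unit, repeatable = isTRUE(repeatable),
         prefix = as.character(prefix), cycle = as.character(cycle)),
    class = "metapath"
  )
}

#' @export
print.metapath <- function(x, ...) {
  cat(sprintf("metapath %s: %s%s\n", x$name, paste(x$unit, collapse = ""),
              if (x$repeatable) " (repeatable)" else ""))
  invisible(x)
}

#' The eight default meta-paths
#'
#' RT (RE-term, via the inferred indirect annotation), FRF (TF binding),
#' RGGR and GRFRG (regulation composed with interaction/binding), GTT, GTG,
#' GTTG (gene-term and term-term), and GGG (interaction only). When `net`
#' is given, meta-paths requiring an edge type absent from the network are
#' dropped, which is how ablation networks (e.g. no PPI, no GRN) select
#' their walkable subset.
#'
#' @param net optional `hetnet` used to filter the list.
#' @return list of [metapath] objects.
#' @export
default_metapaths <- function(net = NULL) {
  mps <- list(
    metapath("RT", c("R", "T"), repeatable = FALSE),
    metapath("FRF", c("F", "R", "F"), prefix = "F", cycle = c("R", "F")),
    metapath("RGGR", c("R", "G", "G", "R")),
    metapath("GRFRG", c("G", "R", "F", "R", "G"),
             prefix = "G", cycle = c("R", "F", "R", "G")),
    metapath("GTT", c("G", "T", "T"), prefix = "G", cycle = "T"),
    metapath("GTG", c("G", "T", "G"), prefix = "G", cycle = c("T", "G")),
    metapath("GTTG", c("G", "T", "T", "G")),
    metapath("GGG", c("G", "G", "G"), cycle = "G")
  )
  names(mps) <- vapply(mps, `[[`, "", "name")
  if (!is.null(net)) {
    present <- unique(net$edges$type)
    ok <- vapply(mps, function(mp) {
      # expand beyond one unit so tiling-boundary edge types are included
      types <- expand_metapath(mp, 3L * length(mp$unit))
      all(metapath_edge_types(types) %in% present)
    }, logical(1))
    mps <- mps[ok]
  }
  mps
}

# Edge types required between consecutive symbols of a type sequence.
metapath_edge_types <- function(types) {
  n <- length(types)
  pairs <- paste(pmin(types[-n], types[-1]), pmax(types[-n], types[-1]),
                 sep = "|")
  unname(EDGE_TYPE_BY_PAIR[pairs])
}

#' Expand a meta-path to a node-type sequence of a given length
#'
#' Non-repeatable paths return their unit unchanged; repeatable paths tile
#' their cycle after the prefix and truncate at `length`.
#'
#' @param mp a [metapath].
#' @param length target number of nodes; must be at least the unit length.
#' @return character vector of node-type symbols.
#' @export
expand_metapath <- function(mp, length) {
  stopifnot(inherits(mp, "metapath"))
  if (length < base::length(mp$unit)) {
    stop("length must be >= the meta-path unit length (",
         base::length(mp$unit), ")")
  }
  if (!mp$repeatable) return(mp$unit)
  reps <- ceiling((length - base::length(mp$prefix)) / base::length(mp$cycle))
  out <- c(mp$prefix, rep(mp$cycle, reps))
  out[seq_len(length)]
}

# Per-edge-type adjacency with precomputed cumulative weights, hashed by
# node id for O(1) lookup during walks.
.hetnet_adjacency <- function(net, weighted = TRUE) {
  adj <- list()
  for (et in unique(net$edges$type)) {
    e <- net$edges[net$edges$type == et, , drop = FALSE]
    env <- new.env(hash = TRUE, parent = emptyenv())
    nbr <- split(c(e$to, e$from), c(e$from, e$to))
    wts <- split(c(e$weight, e$weight), c(e$from, e$to))
    for (v in names(nbr)) {
      w <- if (weighted) wts[[v]] else rep(1, length(nbr[[v]]))
      assign(v, list(ids = nbr[[v]], cum = cumsum(w)), envir = env)
    }
    adj[[et]] <- env
  }
  adj
}

#' Generate meta-path-guided random walks
#'
#' For every meta-path and every node of its starting type,
#' `walks_per_start` walks are generated. At each step the walker moves to a
#' neighbor connected by the edge type the meta-path requires between the
#' current and next node type, chosen with probability proportional to edge
#' weight (or uniformly when `weighted = FALSE`). A node with no neighbor of
#' the required type ends the walk early; walks shorter than `min_length`
#' nodes are dropped. Walks are reproducible for a fixed seed.
#'
#' @param net a `hetnet`.
#' @param metapaths list of [metapath] objects; defaults to the eight
#'   standard ones, restricted to those walkable on `net`.
#' @param walks_per_start walks started from each eligible node.
#' @param length walk length in nodes (not steps).
#' @param seed integer RNG seed.
#' @param min_length minimum number of nodes for a walk to be retained.
#' @param weighted logical; bias transitions by edge weight.
#' @return a `walk_corpus`: list with `walks` (list of node-id vectors) and
#'   `provenance` (data.frame with the meta-path and start of each walk).
#' @export
generate_walks <- function(net, metapaths = default_metapaths(net),
                           walks_per_start = 20, length = 5, seed = 1,
                           min_length = 2, weighted = TRUE) {
  stopifnot(inherits(net, "hetnet"))
  present <- unique(net$edges$type)
  for (mp in metapaths) {
    need <- metapath_edge_types(
      expand_metapath(mp, max(length, base::length(mp$unit)))
    )
    missing <- setdiff(need, present)
    if (base::length(missing) > 0) {
      stop("meta-path ", mp$name, " requires edge type(s) absent from the ",
           "network: ", paste(missing, collapse = ", "))
    }
  }
  adj <- .hetnet_adjacency(net, weighted = weighted)
  starts_of <- split(net$nodes$id, net$nodes$type)

  with_seed(seed, {
    walks <- list()
    prov_mp <- character()
    prov_start <- character()
    for (mp in metapaths) {
      types <- expand_metapath(mp, length)
      etypes <- metapath_edge_types(types)
      L <- base::length(types)
      starts <- starts_of[[types[[1]]]]
      if (is.null(starts)) next
      for (s in starts) {
        for (rep_i in seq_len(walks_per_start)) {
          walk <- character(L)
          walk[[1]] <- s
          v <- s
          k <- 1L
          while (k < L) {
            nb <- get0(v, envir = adj[[etypes[[k]]]], inherits = FALSE)
            if (is.null(nb)) break
            total <- nb$cum[[base::length(nb$cum)]]
            j <- findInterval(stats::runif(1) * total, nb$cum,
                              left.open = TRUE) + 1L
            v <- nb$ids[[j]]
            k <- k + 1L
            walk[[k]] <- v
          }
          if (k >= min_length) {
            walks[[base::length(walks) + 1L]] <- walk[seq_len(k)]
            prov_mp <- c(prov_mp, mp$name)
            prov_start <- c(prov_start, s)
          }
        }
      }
    }
    structure(
      list(
        walks = walks,
        provenance = data.frame(metapath = prov_mp, start = prov_start,
                                stringsAsFactors = FALSE),
        params = list(walks_per_start = walks_per_start, length = length,
                      seed = seed, weighted = weighted)
      ),
      class = "walk_corpus"
    )
  })
}

#' @export
print.walk_corpus <- function(x, ...) {
  cat(sprintf("walk_corpus: %d walks, %d tokens, %d meta-path(s)\n",
              length(x$walks), sum(lengths(x$walks)),
              length(unique(x$provenance$metapath))))
  invisible(x)
}

#' Write a walk corpus in word2vec text-corpus convention
#'
#' One whitespace-delimited line of node ids per walk.
#'
#' @param corpus a `walk_corpus`.
#' @param path output path.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus$walks, paste, "", collapse = " "), path)
  invisible(path)
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (the softmax context likelihood
#' approximated by sampling `negatives` noise nodes per positive pair from
#' the unigram distribution raised to 3/4), trained by SGD with a linearly
#' decaying learning rate and a per-position randomly reduced window, as in
#' standard word2vec practice. Training is single-threaded and fully
#' reproducible for a fixed seed.
#'
#' @param corpus a `walk_corpus`, or a plain list of character vectors.
#' @param dim embedding dimension.
#' @param window maximum one-sided context window (in nodes).
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param seed integer seed for initialization and sampling.
#' @param alpha initial learning rate.
#' @param sample frequent-token subsampling threshold: occurrences of a
#'   node with corpus frequency f are kept with probability
#'   `(sqrt(f/sample) + 1) * sample/f` (word2vec convention). Nodes rarer
#'   than `sample` are unaffected; `0` disables subsampling. Subsampling
#'   prevents the most frequent node types from dominating the
#'   co-occurrence statistics.
#' @param min_count nodes occurring fewer times are dropped from the vocab.
#' @param vectors which vectors to report: the skip-gram input vectors, or
#'   the average of each node's input and output vectors. The averaged
#'   form directly reflects the input-output dot products the objective
#'   optimizes and is the default.
#' @param typed_negatives optional named character vector mapping node ids
#'   to node-type labels (e.g. `setNames(net$nodes$type, net$nodes$id)`).
#'   When supplied, negative samples for a positive node are drawn only
#'   among nodes of the same type (heterogeneous skip-gram negative
#'   sampling); `NULL` (default) samples homogeneously over all nodes.
#' @return a `node_embedding`: list with `vectors` (nodes x dim matrix with
#'   node ids as rownames), `dim` and training `meta`data.
#' @export
train_embedding <- function(corpus, dim = 128, window = 5, negatives = 5,
                            epochs = 5, seed = 1, alpha = 0.025,
                            sample = 1e-3, min_count = 1,
                            vectors = c("average", "input"),
                            typed_negatives = NULL) {
  walks <- if (inherits(corpus, "walk_corpus")) corpus$walks else corpus
  if (length(walks) == 0) stop("empty walk corpus")
  tokens <- unlist(walks, use.names = FALSE)
  # vocabulary in first-appearance order (locale-independent)
  all_ids <- unique(tokens)
  counts <- tabulate(match(tokens, all_ids), nbins = length(all_ids))
  names(counts) <- all_ids
  vocab <- all_ids[counts >= min_count]
  if (length(vocab) == 0) stop("no node meets min_count = ", min_count)
  index <- stats::setNames(seq_along(vocab) - 1L, vocab)
  iwalks <- lapply(walks, function(w) {
    i <- index[w]
    as.integer(i[!is.na(i)])
  })
  iwalks <- iwalks[lengths(iwalks) >= 2L]
  if (length(iwalks) == 0) stop("no walk retains >= 2 in-vocabulary nodes")
  type_idx <- rep(0L, length(vocab))
  if (!is.null(typed_negatives)) {
    ty <- typed_negatives[vocab]
    if (anyNA(ty)) stop("typed_negatives must cover every corpus node")
    type_idx <- as.integer(factor(ty)) - 1L
  }
  fit <- sgns_train(
    iwalks, length(vocab), as.integer(dim), as.integer(window),
    as.integer(negatives), as.integer(epochs),
    as.numeric(alpha), as.numeric(counts[vocab]), as.integer(seed),
    as.numeric(sample), type_idx
  )
  vectors <- match.arg(vectors)
  mat <- switch(vectors,
    input = fit$input,
    average = (fit$input + fit$output) / 2
  )
  rownames(mat) <- vocab
  structure(
    list(vectors = mat, dim = as.integer(dim),
         meta = list(window = window, negatives = negatives,
                     epochs = epochs, seed = seed, sample = sample,
                     min_count = min_count)),
    class = "node_embedding"
  )
}

#' @export
print.node_embedding <- function(x, ...) {
  cat(sprintf("node_embedding: %d nodes x %d dimensions\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Look up the embedding vector of a node
#'
#' @param emb a `node_embedding`.
#' @param id node id.
#' @return numeric vector of length `emb$dim`, or an error if the node has
#'   no vector.
#' @export
embedding_vector <- function(emb, id) {
  stopifnot(inherits(emb, "node_embedding"))
  if (!id %in% rownames(emb$vectors)) stop("node not embedded: ", id)
  emb$vectors[id, ]
}

#' Write an embedding in word2vec text format
#'
#' First line `count dim`, then one `id v1 ... vd` line per node.
#'
#' @param emb a `node_embedding`.
#' @param path output path.
#' @export
write_embedding <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb$vectors), emb$dim), con)
  writeLines(
    paste(rownames(emb$vectors),
          apply(emb$vectors, 1, function(v) paste(format(v, digits = 8),
                                                  collapse = " "))),
    con
  )
  invisible(path)
}

#' Cosine similarity of two vectors
#'
#' @param u,v numeric vectors of equal length and nonzero norm.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for zero-norm vector")
  sum(u * v) / (nu * nv)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
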