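# Synthetic fixtures with planted functional communities: a toy ontology,
# gene annotations, PPI, GRN and genomic region sets with known ground
# truth, written in the same dialects the loaders read.

#' Generate a random toy GO DAG
#'
#' A single-root DAG in which each non-root term draws 1 to `max_parents`
#' parents among earlier terms, so acyclicity and root-reachability hold by
#' construction. Deterministic per seed.
#'
#' @param n_terms number of terms including the root.
#' @param max_parents maximum parents per non-root term.
#' @param seed integer RNG seed.
#' @return a [go_dag] in namespace BP.
#' @export
make_toy_ontology <- function(n_terms, max_parents = 2, seed = 1) {
  stopifnot(n_terms >= 1, max_parents >= 1)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  with_seed(seed, {
    parents <- stats::setNames(vector("list", n_terms), ids)
    parents[[1]] <- character()
    for (i in seq_len(n_terms)[-1]) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[i]] <- ids[sample.int(i - 1L, k)]
    }
    go_dag(parents,
           names = stats::setNames(sprintf("toy term %d", seq_len(n_terms)), ids),
           namespace = "BP")
  })
}

#' Generate a planted-community world
#'
#' Builds a self-consistent toy data set in which every input layer shares
#' one community structure: each community owns a subtree of the ontology,
#' its genes are annotated by the subtree's terms, PPI edges connect mostly
#' within-community genes, REs regulate 1-3 within-community genes and TFs
#' bind within-community REs. Each generated edge (annotation, interaction,
#' regulation, binding) is redirected across communities with probability
#' `cross_edge_rate`, so the rate is also the expected fraction of
#' cross-community edges. RE loci are non-overlapping 200 bp intervals
#' spaced 1 kb apart on the toy chromosome `chrT`; gene TSS positions are
#' emitted for the proximal/distal regulation split.
#'
#' @param n_communities number of planted communities.
#' @param genes_per,res_per,terms_per,tfs_per community sizes (the default
#'   world has 2 communities x 20 genes, 10 REs, 15 terms, 3 TFs).
#' @param cross_edge_rate probability in `[0, 1)` that an edge crosses
#'   communities.
#' @param max_parents maximum parents per term inside a community subtree.
#' @param ppi_degree within-community interaction partners drawn per gene.
#' @param seed integer RNG seed.
#' @return a `planted_world`: list with `dag`, `goa` (raw, unclosed),
#'   `ppi`, `grn`, `tss`, `truth` (named community label per node id,
#'   `NA` for the root term) and `params`.
#' @export
make_planted_world <- function(n_communities = 2, genes_per = 20,
                               res_per = 10, terms_per = 15, tfs_per = 3,
                               cross_edge_rate = 0.05, max_parents = 2,
                               ppi_degree = 3, seed = 1) {
  stopifnot(n_communities >= 1, genes_per >= 1, res_per >= 1,
            terms_per >= 2, tfs_per >= 1,
            cross_edge_rate >= 0, cross_edge_rate < 1)
  comm <- seq_len(n_communities)
  with_seed(seed, {
    # ontology: shared root, one subtree per community
    root <- "GO:0000001"
    term_ids <- list()
    parents <- list()
    parents[[root]] <- character()
    truth <- stats::setNames(NA_integer_, root)
    n <- 1L
    for (c in comm) {
      ids <- sprintf("GO:%07d", n + seq_len(terms_per))
      n <- n + terms_per
      parents[[ids[[1]]]] <- root
      for (i in seq_along(ids)[-1]) {
        k <- sample.int(min(max_parents, i - 1L), 1L)
        parents[[ids[[i]]]] <- ids[sample.int(i - 1L, k)]
      }
      term_ids[[c]] <- ids
      truth[ids] <- c
    }
    all_ids <- c(root, unlist(term_ids))
    dag <- go_dag(
      parents[all_ids],
      names = stats::setNames(paste("planted term", seq_along(all_ids)), all_ids),
      namespace = "BP"
    )

    other <- function(c) if (n_communities == 1) c else sample(setdiff(comm, c), 1L)
    pick_comm <- function(c) {
      if (stats::runif(1) < cross_edge_rate) other(c) else c
    }

    genes <- split(
      sprintf("g%03d", seq_len(n_communities * genes_per)),
      rep(comm, each = genes_per)
    )
    gene_comm <- stats::setNames(rep(comm, each = genes_per), unlist(genes))

    # raw annotations: 1-3 community-subtree terms per gene
    ann <- lapply(names(gene_comm), function(g) {
      c0 <- gene_comm[[g]]
      k <- sample.int(3L, 1L)
      vapply(seq_len(k), function(i) {
        cc <- pick_comm(c0)
        term_ids[[cc]][sample.int(terms_per, 1L)]
      }, "")
    })
    names(ann) <- names(gene_comm)
    goa <- gene_annotation(ann, closed = FALSE)

    # PPI: ppi_degree partners per gene, STRING-scale scores
    p1 <- character(); p2 <- character()
    for (g in names(gene_comm)) {
      for (i in seq_len(ppi_degree)) {
        cc <- pick_comm(gene_comm[[g]])
        partner <- sample(setdiff(genes[[cc]], g), 1L)
        p1 <- c(p1, g); p2 <- c(p2, partner)
      }
    }
    ppi <- ppi_network(p1, p2, weight = sample(400:999, length(p1), replace = TRUE))

    res <- split(
      sprintf("re%03d", seq_len(n_communities * res_per)),
      rep(comm, each = res_per)
    )
    re_comm <- stats::setNames(rep(comm, each = res_per), unlist(res))
    loci <- data.frame(
      re = unname(unlist(res)),
      chrom = "chrT",
      start = (seq_len(n_communities * res_per) - 1L) * 1200L,
      end = (seq_len(n_communities * res_per) - 1L) * 1200L + 200L,
      stringsAsFactors = FALSE
    )

    reg_re <- character(); reg_gene <- character()
    for (r in names(re_comm)) {
      k <- sample.int(3L, 1L)
      for (i in seq_len(k)) {
        cc <- pick_comm(re_comm[[r]])
        reg_re <- c(reg_re, r)
        reg_gene <- c(reg_gene, sample(genes[[cc]], 1L))
      }
    }
    regulates <- data.frame(
      re = reg_re, gene = reg_gene,
      weight = round(stats::runif(length(reg_re), 0.5, 1.5), 3),
      stringsAsFactors = FALSE
    )

    tfs <- split(
      sprintf("tf%02d", seq_len(n_communities * tfs_per)),
      rep(comm, each = tfs_per)
    )
    tf_comm <- stats::setNames(rep(comm, each = tfs_per), unlist(tfs))
    bind_tf <- character(); bind_re <- character()
    for (f in names(tf_comm)) {
      k <- sample(3:min(6L, res_per), 1L)
      targets <- character()
      for (i in seq_len(k)) {
        cc <- pick_comm(tf_comm[[f]])
        targets <- c(targets, sample(res[[cc]], 1L))
      }
      targets <- unique(targets)
      bind_tf <- c(bind_tf, rep(f, length(targets)))
      bind_re <- c(bind_re, targets)
    }
    binds <- data.frame(
      tf = bind_tf, re = bind_re,
      weight = round(stats::runif(length(bind_tf), 0.5, 1.5), 3),
      stringsAsFactors = FALSE
    )
    grn <- regulatory_network(binds, regulates, loci)

    # TSS: half the genes sit near a random RE (proximal candidates),
    # the rest far downstream of the RE span
    span_end <- max(loci$end)
    tss_pos <- vapply(names(gene_comm), function(g) {
      if (stats::runif(1) < 0.5) {
        loci$start[sample.int(nrow(loci), 1L)] + sample.int(2000L, 1L)
      } else {
        span_end + 50000L + sample.int(500000L, 1L)
      }
    }, 0L)
    tss <- data.frame(gene = names(gene_comm), chrom = "chrT",
                      pos = as.integer(tss_pos), stringsAsFactors = FALSE)

    truth <- c(truth, gene_comm, re_comm, tf_comm)
    structure(
      list(dag = dag, goa = goa, ppi = ppi, grn = grn, tss = tss,
           truth = truth,
           params = list(n_communities = n_communities,
                         genes_per = genes_per, res_per = res_per,
                         terms_per = terms_per, tfs_per = tfs_per,
                         cross_edge_rate = cross_edge_rate, seed = seed)),
      class = "planted_world"
    )
  })
}

#' @export
print.planted_world <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "planted_world: %d communities x (%d genes, %d REs, %d terms, %d TFs), cross rate %.2f, seed %d\n",
    p$n_communities, p$genes_per, p$res_per, p$terms_per, p$tfs_per,
    p$cross_edge_rate, p$seed
  ))
  invisible(x)
}

#' Generate a labelled region fixture over a planted world
#'
#' `n_on_re` regions are placed within `jitter` bp of randomly chosen REs
#' (same width as the RE, shifted by a uniform offset in `[-jitter,
#' jitter]`), and `n_off` decoy regions are placed at least 2 kb away from
#' every RE, so the on/off assignment outcome under the default 1 kb
#' nearest-RE rule is known by construction.
#'
#' @param world a `planted_world`.
#' @param n_on_re,n_off region counts.
#' @param jitter maximum absolute shift in bp (must be < 1000 for the
#'   planted assignment guarantee).
#' @param seed integer RNG seed.
#' @return list with `regions` (data.frame `chrom`, `start`, `end`) and
#'   `labels` (data.frame `on_re` flag, source `re` id or `NA`,
#'   `community`).
#' @export
make_region_fixture <- function(world, n_on_re = 30, n_off = 10,
                                jitter = 100, seed = 1) {
  stopifnot(inherits(world, "planted_world"), jitter >= 0)
  loci <- world$grn$loci
  with_seed(seed, {
    pick <- sample.int(nrow(loci), n_on_re, replace = TRUE)
    shift <- as.integer(round(stats::runif(n_on_re, -jitter, jitter)))
    on_start <- pmax(0L, loci$start[pick] + shift)
    width <- loci$end[pick] - loci$start[pick]
    far0 <- max(loci$end) + 5000L
    off_start <- far0 + (seq_len(n_off) - 1L) * 5000L
    regions <- data.frame(
      chrom = "chrT",
      start = c(on_start, off_start),
      end = c(on_start + width, off_start + 200L),
      stringsAsFactors = FALSE
    )
    labels <- data.frame(
      on_re = rep(c(TRUE, FALSE), c(n_on_re, n_off)),
      re = c(loci$re[pick], rep(NA_character_, n_off)),
      community = c(unname(world$truth[loci$re[pick]]), rep(NA_integer_, n_off)),
      stringsAsFactors = FALSE
    )
    list(regions = regions, labels = labels)
  })
}

#' Write a planted world to disk in the loaders' file dialects
#'
#' Emits `ontology.obo`, `annotations.tsv` (gene TAB term),
#' `ppi.tsv` (STRING-style), `grn_binds.tsv`, `grn_regulates.tsv`,
#' `grn_loci.tsv` and `tss.tsv` under `dir`.
#'
#' @param world a `planted_world`.
#' @param dir output directory (created if needed).
#' @return named list of the file paths, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "planted_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    obo = file.path(dir, "ontology.obo"),
    goa = file.path(dir, "annotations.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    binds = file.path(dir, "grn_binds.tsv"),
    regulates = file.path(dir, "grn_regulates.tsv"),
    loci = file.path(dir, "grn_loci.tsv"),
    tss = file.path(dir, "tss.tsv")
  )
  dag <- world$dag
  con <- file(paths$obo, "w")
  writeLines("format-version: 1.2", con)
  for (t in dag$ids) {
    writeLines(c(
      "", "[Term]", paste0("id: ", t),
      paste0("name: ", dag$names[[t]]),
      "namespace: biological_process",
      paste0("is_a: ", dag$parents[[t]])
    ), con)
  }
  close(con)

  gene <- rep(names(world$goa$annotations), lengths(world$goa$annotations))
  term <- unlist(world$goa$annotations, use.names = FALSE)
  utils::write.table(data.frame(gene, term), paths$goa, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ppi_out <- data.frame(protein1 = world$ppi$protein1,
                        protein2 = world$ppi$protein2,
                        combined_score = world$ppi$weight)
  utils::write.table(ppi_out, paths$ppi, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(world$grn$binds, paths$binds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(world$grn$regulates, paths$regulates, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$grn$loci, paths$loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(world$tss, paths$tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
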