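# Shared in-code fixtures for the test suite.

# chain C is_a B is_a A
chain_dag <- function() {
  go_dag(list(A = character(), B = "A", C = "B"), namespace = "BP")
}

# diamond: D is_a B, D is_a C, B is_a A, C is_a A
diamond_dag <- function() {
  go_dag(list(A = character(), B = "A", C = "A", D = c("B", "C")),
         namespace = "BP")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal OBO text for a set of (id, parents) pairs, all BP
obo_text <- function(terms, extra = character()) {
  out <- "format-version: 1.2"
  for (id in names(terms)) {
    out <- c(out, "", "[Term]", paste0("id: ", id),
             paste0("name: name of ", id),
             "namespace: biological_process",
             paste0("is_a: ", terms[[id]], " ! comment"))
  }
  c(out, extra)
}

# tiny deterministic hetnet inputs shared by hetnet/walk tests:
# 2 genes, 2 REs, 1 TF, chain ontology
tiny_world <- function() {
  dag <- chain_dag()
  goa <- close_annotations(dag, gene_annotation(list(g1 = "C", g2 = "B")))
  ppi <- ppi_network("g1", "g2", weight = 500)
  grn <- regulatory_network(
    binds = data.frame(tf = "f1", re = c("r1", "r2"), weight = 1),
    regulates = data.frame(re = c("r1", "r1", "r2"),
                           gene = c("g1", "g2", "g2"), weight = 1),
    loci = data.frame(re = c("r1", "r2"), chrom = "chrT",
                      start = c(0L, 1200L), end = c(200L, 1400L))
  )
  list(dag = dag, goa = goa, ppi = ppi, grn = grn)
}

# independent ancestor closure by repeated parent lookup (test oracle)
oracle_ancestors <- function(dag, term) {
  out <- character()
  frontier <- term
  repeat {
    ps <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    ps <- setdiff(ps, out)
    if (length(ps) == 0) break
    out <- c(out, ps)
    frontier <- ps
  }
  sort(out)
}

# embedding stub with prescribed vectors
stub_embedding <- function(vectors) {
  structure(
    list(vectors = vectors, dim = ncol(vectors), meta = list()),
    class = "node_embedding"
  )
}
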