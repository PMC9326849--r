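# deterministic random embedding over a DAG's terms plus extra node ids
random_embedding <- function(dag, nodes, dim = 6, seed = 1) {
  set.seed(seed)
  ids <- c(dag$ids, nodes)
  m <- matrix(rnorm(length(ids) * dim), nrow = length(ids),
              dimnames = list(ids, NULL))
  stub_embedding(m)
}

test_that("node-term similarity maximizes cosine over term and descendants", {
  dag <- chain_dag()  # C is_a B is_a A
  m <- rbind(
    n1 = c(1, 0),
    A = c(0, 1),   # orthogonal to node
    B = c(0.6, 0.8),
    C = c(1, 0)    # collinear with node
  )
  emb <- stub_embedding(m)
  # leaf: plain cosine
  expect_equal(sim_node_term(emb, dag, "n1", "C"), 1)
  # max picks the collinear descendant of the root
  expect_equal(sim_node_term(emb, dag, "n1", "A"), 1)
  expect_equal(sim_node_term(emb, dag, "n1", "B"),
               max(cosine(m["n1", ], m["B", ]), cosine(m["n1", ], m["C", ])))
  expect_error(sim_node_term(emb, dag, "missing", "A"), "not embedded")
})

test_that("similarity with descendant max equals the exhaustive oracle", {
  for (seed in 1:20) {
    dag <- make_toy_ontology(20, max_parents = 3, seed = seed)
    emb <- random_embedding(dag, c("x1", "x2"), seed = seed)
    for (node in c("x1", "x2")) {
      for (term in sample(dag$ids, 5)) {
        cand <- c(term, go_descendants(dag, term))
        want <- max(vapply(cand, function(t) {
          cosine(emb$vectors[node, ], emb$vectors[t, ])
        }, 0))
        expect_equal(sim_node_term(emb, dag, node, term), want,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the annotation split is an exact 80/20 pair partition", {
  set.seed(1)
  goa <- gene_annotation(split(
    sprintf("GO:%07d", sample.int(50, 100, replace = TRUE)),
    rep(paste0("g", 1:20), each = 5)
  ))
  # dedup may reduce below 100; rebuild exactly 100 unique pairs
  genes <- rep(paste0("g", 1:10), each = 10)
  terms <- paste0("t", rep(1:10, times = 10))
  goa <- gene_annotation(split(terms, genes))
  expect_equal(sum(lengths(goa$annotations)), 100L)

  sp <- split_goa(goa, train_frac = 0.8, seed = 3)
  n_train <- sum(lengths(sp$train$annotations))
  n_test <- sum(lengths(sp$test$annotations))
  expect_equal(n_train, 80L)
  expect_equal(n_test, 20L)

  pair_set <- function(m) {
    sort(paste(rep(names(m$annotations), lengths(m$annotations)),
               unlist(m$annotations, use.names = FALSE)))
  }
  expect_length(intersect(pair_set(sp$train), pair_set(sp$test)), 0)
  expect_identical(sort(c(pair_set(sp$train), pair_set(sp$test))),
                   pair_set(goa))
  expect_identical(split_goa(goa, 0.8, seed = 3)$train$annotations,
                   sp$train$annotations)
  expect_error(split_goa(goa, 1.2), "train_frac")
})

test_that("threshold calibration returns the documented optimum and tie-break", {
  # positives' sims {0.9, 0.8}, negative {0.1}: perfect separation, the
  # returned threshold is the largest candidate below 0.8 = midpoint 0.45
  dag <- go_dag(list(T1 = character()), namespace = "BP")
  m <- rbind(T1 = c(1, 0),
             gp1 = c(cos(acos(0.9)), sin(acos(0.9))),
             gp2 = c(cos(acos(0.8)), sin(acos(0.8))),
             gn = c(cos(acos(0.1)), sin(acos(0.1))))
  emb <- stub_embedding(m)
  train <- gene_annotation(list(gp1 = "T1", gp2 = "T1"))
  got <- calibrate_threshold(emb, dag, train, "T1",
                             genes = c("gp1", "gp2", "gn"))
  expect_equal(got$f1, 1)
  expect_equal(got$threshold, (0.1 + 0.8) / 2, tolerance = 1e-9)
})

test_that("all-positive terms get a permissive threshold with perfect f1", {
  dag <- go_dag(list(T1 = character()), namespace = "BP")
  m <- rbind(T1 = c(1, 0), g1 = c(0.9, 0.1), g2 = c(0.5, 0.5))
  emb <- stub_embedding(m)
  train <- gene_annotation(list(g1 = "T1", g2 = "T1"))
  got <- calibrate_threshold(emb, dag, train, "T1", genes = c("g1", "g2"))
  expect_equal(got$f1, 1)
  expect_lt(got$threshold, min(cosine(m["g1", ], m["T1", ]),
                               cosine(m["g2", ], m["T1", ])))
})

test_that("calibrated thresholds beat every dense-grid candidate", {
  grid <- seq(-1, 1, by = 0.001)
  for (seed in 1:25) {
    dag <- make_toy_ontology(8, seed = seed)
    genes <- paste0("g", 1:10)
    emb <- random_embedding(dag, genes, seed = seed)
    set.seed(seed + 500)
    train <- gene_annotation(stats::setNames(
      lapply(genes, function(g) sample(dag$ids, sample(1:3, 1))), genes
    ))
    thr <- calibrate_thresholds(emb, dag, train, genes = genes)
    sims <- regoa:::.sim_term_matrix(emb, dag, genes, thr$term)
    for (i in seq_len(nrow(thr))) {
      t0 <- thr$term[i]
      positive <- vapply(genes, function(g) t0 %in% train$annotations[[g]],
                         TRUE)
      f1_at <- function(t) {
        pred <- sims[, t0] > t
        tp <- sum(pred & positive)
        if (tp == 0) return(0)
        pre <- tp / sum(pred)
        rec <- tp / sum(positive)
        2 * pre * rec / (pre + rec)
      }
      expect_equal(f1_at(thr$threshold[i]), thr$f1[i], tolerance = 1e-12)
      grid_best <- max(vapply(grid, f1_at, 0))
      expect_gte(thr$f1[i] + 1e-12, grid_best)
    }
  }
})

test_that("terms without annotated training genes are uncalibrated", {
  dag <- chain_dag()
  emb <- random_embedding(dag, "g1", seed = 2)
  train <- gene_annotation(list(g1 = c("A", "B")))
  got <- calibrate_threshold(emb, dag, train, "C", genes = "g1")
  expect_true(is.na(got$threshold))
  thr <- calibrate_thresholds(emb, dag, train, genes = "g1")
  expect_setequal(thr$term, c("A", "B"))
})

test_that("embedding-derived RE annotations are threshold-gated and closed", {
  dag <- chain_dag()
  m <- rbind(A = c(0, 1), B = c(0.5, 0.5), C = c(1, 0),
             r1 = c(1, 0), g = c(1, 0))
  emb <- stub_embedding(m)
  thr <- data.frame(term = c("A", "B", "C"),
                    threshold = c(0.99, 0.99, 0.5), f1 = 1)
  class(thr) <- c("term_thresholds", "data.frame")
  got <- goa_embed(emb, dag, thr, "r1")
  # C passes (cos=1 > 0.5); ancestors B, A added by closure
  expect_setequal(got$annotations$r1, c("C", "B", "A"))
  expect_equal(got$kind, "embed")

  none <- data.frame(term = "A", threshold = 1, f1 = 1)
  class(none) <- c("term_thresholds", "data.frame")
  expect_length(goa_embed(emb, dag, none, "r1")$annotations$r1, 0)
  expect_warning(goa_embed(emb, dag, thr, c("r1", "r_missing")),
                 "without embedding")
})

test_that("raising one threshold never enlarges any RE's annotation call set", {
  for (seed in 1:10) {
    dag <- make_toy_ontology(10, seed = seed)
    res <- paste0("r", 1:5)
    emb <- random_embedding(dag, res, seed = seed)
    set.seed(seed)
    thr <- data.frame(term = dag$ids,
                      threshold = runif(length(dag$ids), -0.5, 0.5), f1 = 1)
    class(thr) <- c("term_thresholds", "data.frame")
    base <- goa_embed(emb, dag, thr, res)
    bump <- sample.int(nrow(thr), 1)
    thr2 <- thr
    thr2$threshold[bump] <- thr2$threshold[bump] + 0.3
    tighter <- goa_embed(emb, dag, thr2, res)
    for (r in res) {
      expect_true(all(tighter$annotations[[r]] %in% base$annotations[[r]]))
    }
  }
})

test_that("final annotations are the per-RE intersection of embed and raw", {
  embed <- re_annotation(list(r1 = c("T1", "T2"), r2 = character()),
                         kind = "embed")
  raw <- re_annotation(list(r1 = c("T2", "T3"), r2 = c("T1")), kind = "raw")
  fin <- annotate_res(embed, raw)
  expect_equal(fin$annotations$r1, "T2")
  expect_length(fin$annotations$r2, 0)
  expect_equal(fin$kind, "final")
  for (r in names(fin$annotations)) {
    expect_true(all(fin$annotations[[r]] %in% raw$annotations[[r]]))
    expect_true(all(fin$annotations[[r]] %in% embed$annotations[[r]]))
  }
})

test_that("emitted annotation sets stay ancestor-closed through the algebra", {
  for (seed in 1:10) {
    w <- make_planted_world(n_communities = 2, genes_per = 5, res_per = 4,
                            terms_per = 5, seed = seed)
    goa <- close_annotations(w$dag, w$goa)
    raw <- goa_raw(w$grn, goa)
    emb <- random_embedding(w$dag, w$grn$loci$re, seed = seed)
    thr <- data.frame(term = w$dag$ids, threshold = 0.2, f1 = 1)
    class(thr) <- c("term_thresholds", "data.frame")
    embed <- goa_embed(emb, w$dag, thr, w$grn$loci$re)
    fin <- annotate_res(embed, raw)
    closed <- function(terms) {
      all(unlist(lapply(terms, go_ancestors, dag = w$dag)) %in% terms)
    }
    for (r in w$grn$loci$re) {
      expect_true(closed(raw$annotations[[r]]))
      expect_true(closed(embed$annotations[[r]]))
      expect_true(closed(fin$annotations[[r]]))
    }
  }
})

test_that("AUROC is 1 for separating scores and ~0.5 for label-free scores", {
  # root A with leaves B and C; the held-out pair (g1, C) scores 1 while
  # the only possible negative (g1, B) scores negative cosine
  dag <- go_dag(list(A = character(), B = "A", C = "A"), namespace = "BP")
  m <- rbind(A = c(0, 1), B = c(-1, 0.2), C = c(1, 0), g1 = c(1, 0))
  emb <- stub_embedding(m)
  test_map <- gene_annotation(list(g1 = "C"))
  full <- gene_annotation(list(g1 = c("C", "A")), closed = TRUE)
  got <- evaluate_auroc(emb, dag, test_map, full, genes = "g1",
                        neg_ratio = 2, seed = 1)
  expect_equal(got$auroc, 1)

  # label-independent scores: AUROC concentrates near 1/2
  set.seed(7)
  n <- 40
  dag2 <- make_toy_ontology(30, seed = 7)
  genes <- paste0("g", 1:n)
  emb2 <- random_embedding(dag2, genes, seed = 7)
  ann <- gene_annotation(stats::setNames(
    lapply(seq_len(n), function(i) sample(dag2$ids, 8)), genes
  ), closed = TRUE)
  sp <- split_goa(ann, 0.8, seed = 7)
  got2 <- evaluate_auroc(emb2, dag2, sp$test, ann, genes = genes,
                         neg_ratio = 5, seed = 7)
  expect_gt(got2$auroc, 0.4)
  expect_lt(got2$auroc, 0.6)
})

test_that("rank-statistic AUROC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- runif(60)
  labels <- rep(c(1, 0), each = 30)
  np <- 30; nn <- 30
  r <- rank(c(scores[labels == 1], scores[labels == 0]))
  ours <- (sum(r[1:np]) - np * (np + 1) / 2) / (np * nn)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("resource and thresholds round-trip through their TSV formats", {
  loci <- data.frame(re = c("r1", "r2"), chrom = "chrT",
                     start = c(0L, 1200L), end = c(200L, 1400L))
  map <- re_annotation(list(r1 = c("GO:1", "GO:2"), r2 = character()),
                       kind = "final")
  f <- tempfile(fileext = ".tsv")
  write_re_annotation(map, loci, f)
  back <- read_re_annotation(f)
  expect_equal(names(back$annotation$annotations), "r1")
  expect_setequal(back$annotation$annotations$r1, c("GO:1", "GO:2"))
  expect_equal(back$loci$start, 0L)

  thr <- data.frame(term = "GO:1", threshold = 0.25, f1 = 0.9)
  class(thr) <- c("term_thresholds", "data.frame")
  f2 <- tempfile(fileext = ".tsv")
  write_thresholds(thr, f2)
  got <- utils::read.delim(f2)
  expect_equal(got$threshold, 0.25)
  expect_equal(got$f1_at_opt, 0.9)
})
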