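# quadratic all-pairs oracle for nearest-RE assignment
oracle_nearest <- function(regions, loci, max_dist) {
  t(vapply(seq_len(nrow(regions)), function(i) {
    best_re <- NA_character_
    best_d <- Inf
    best_start <- Inf
    for (j in seq_len(nrow(loci))) {
      if (regions$chrom[i] != loci$chrom[j]) next
      d <- max(0, max(loci$start[j] - regions$end[i],
                      regions$start[i] - loci$end[j]))
      if (d < best_d || (d == best_d && loci$start[j] < best_start)) {
        best_d <- d
        best_re <- loci$re[j]
        best_start <- loci$start[j]
      }
    }
    c(re = if (is.finite(best_d) && best_d < max_dist) best_re else NA_character_,
      d = as.character(best_d))
  }, c(re = "", d = "")))
}

test_that("nearest_re assigns overlaps at distance 0 and enforces the 1 kb rule", {
  loci <- data.frame(re = "r1", chrom = "chr1", start = 150L, end = 160L)
  got <- nearest_re(data.frame(chrom = "chr1", start = 100L, end = 200L), loci)
  expect_equal(got$re, "r1")
  expect_equal(got$distance, 0)

  far <- data.frame(re = "r1", chrom = "chr1", start = 1300L, end = 1400L)
  got2 <- nearest_re(data.frame(chrom = "chr1", start = 100L, end = 200L), far)
  expect_equal(got2$distance, 1100)
  expect_true(is.na(got2$re))  # 1100 >= 1000: unassigned

  # strictness at the boundary: distance exactly 1000 is not assigned
  edge <- data.frame(re = "r1", chrom = "chr1", start = 1200L, end = 1400L)
  got3 <- nearest_re(data.frame(chrom = "chr1", start = 100L, end = 200L), edge)
  expect_equal(got3$distance, 1000)
  expect_true(is.na(got3$re))
})

test_that("nearest_re matches the quadratic scan on random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    loci <- data.frame(
      re = paste0("r", 1:20),
      chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
      start = sample.int(50000L, 20)
    )
    loci$end <- loci$start + sample.int(500L, 20)
    regions <- data.frame(
      chrom = sample(c("chr1", "chr2", "chr3"), 50, replace = TRUE),
      start = sample.int(52000L, 50)
    )
    regions$end <- regions$start + sample.int(400L, 50)
    got <- nearest_re(regions, loci, max_dist = 1000)
    want <- oracle_nearest(regions, loci, 1000)
    expect_identical(got$re, unname(want[, "re"]))
  }
})

test_that("nearest_re assignments are invariant under a constant coordinate shift", {
  set.seed(42)
  loci <- data.frame(re = paste0("r", 1:10), chrom = "chr1",
                     start = sample.int(20000L, 10))
  loci$end <- loci$start + 200L
  regions <- data.frame(chrom = "chr1", start = sample.int(21000L, 30))
  regions$end <- regions$start + 150L
  base <- nearest_re(regions, loci)
  shift <- 12345L
  shifted <- nearest_re(
    transform(regions, start = start + shift, end = end + shift),
    transform(loci, start = start + shift, end = end + shift)
  )
  expect_identical(base$re, shifted$re)
  expect_identical(base$distance, shifted$distance)
})

# direct-summation oracle for the upper binomial tail
oracle_binom_tail <- function(k, N, p) {
  if (k == 0) return(1)
  sum(vapply(k:N, function(i) choose(N, i) * p^i * (1 - p)^(N - i), 0))
}

test_that("binom_tail handles edge cases and the direct-summation example", {
  expect_equal(binom_tail(0, 10, 0.3), 1)
  expect_equal(binom_tail(10, 10, 1), 1)
  expect_equal(binom_tail(3, 10, 0.1), oracle_binom_tail(3, 10, 0.1),
               tolerance = 1e-12)
  expect_equal(round(binom_tail(3, 10, 0.1), 4), 0.0702)
  expect_error(binom_tail(11, 10, 0.1), "k must")
  expect_error(binom_tail(1, 10, 1.5), "p must")
})

test_that("binom_tail equals the summation oracle and is monotone in k", {
  for (seed in 1:100) {
    set.seed(seed)
    N <- sample(1:50, 1)
    k <- sample(0:N, 1)
    p <- runif(1)
    expect_equal(binom_tail(k, N, p), oracle_binom_tail(k, N, p),
                 tolerance = 1e-12)
  }
  p <- 0.37; N <- 30
  tails <- binom_tail(0:N, N, p)
  expect_true(all(diff(tails) <= 1e-15))
})

# hand step-up BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

test_that("BH correction matches the hand step-up oracle", {
  expect_equal(bh_correct(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_correct(0.2), 0.2)
  expect_equal(bh_correct(rep(0.05, 4)), rep(0.05, 4))
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(sample(1:30, 1))
    expect_equal(bh_correct(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
})

test_that("BH output is invariant under input reordering and bounded by 1", {
  set.seed(9)
  p <- runif(25)
  perm <- sample(25)
  direct <- bh_correct(p)
  permuted <- bh_correct(p[perm])
  expect_equal(permuted[order(perm)], direct)
  expect_true(all(direct <= 1))
})

test_that("enrich_regions reproduces the 4-region toy by hand", {
  # 4 regions: 3 near REs, 1 far; term T on 2 of the 3 assigned REs; p(T)=0.5
  loci <- data.frame(re = c("r1", "r2", "r3", "r4"), chrom = "chrT",
                     start = c(0L, 5000L, 10000L, 15000L))
  loci$end <- loci$start + 200L
  regoa <- re_annotation(
    list(r1 = c("T", "root"), r2 = c("T", "root"), r3 = "root", r4 = "other"),
    kind = "final"
  )
  regions <- data.frame(
    chrom = "chrT",
    start = c(10L, 5010L, 10010L, 40000L),
    end = c(150L, 5150L, 10150L, 40100L)
  )
  tab <- enrich_regions(regions, regoa, loci)
  expect_equal(unique(tab$N), 3L)
  rowT <- tab[tab$term == "T", ]
  expect_equal(rowT$k, 2L)
  expect_equal(rowT$p_t, 0.5)
  expect_equal(rowT$pvalue, 0.5)  # binom_tail(2, 3, 0.5)
  expect_false("other" %in% tab$term)  # k=0 terms are not tested
})

test_that("enrichment is empty with a warning when nothing is assignable", {
  loci <- data.frame(re = "r1", chrom = "chrT", start = 0L, end = 200L)
  regoa <- re_annotation(list(r1 = "T"), kind = "final")
  far <- data.frame(chrom = "chrT", start = 90000L, end = 90100L)
  expect_warning(tab <- enrich_regions(far, regoa, loci), "no region")
  expect_equal(nrow(tab), 0L)
})

test_that("a term on every annotated RE has p-value 1 (background consistency)", {
  loci <- data.frame(re = c("r1", "r2"), chrom = "chrT",
                     start = c(0L, 5000L), end = c(200L, 5200L))
  regoa <- re_annotation(list(r1 = "T", r2 = "T"), kind = "final")
  regions <- data.frame(chrom = "chrT", start = c(10L, 5010L),
                        end = c(100L, 5100L))
  tab <- enrich_regions(regions, regoa, loci)
  expect_equal(tab$pvalue[tab$term == "T"], 1)
  expect_equal(tab$fdr[tab$term == "T"], 1)
})

test_that("the full enrichment table equals an independent recomputation", {
  for (seed in 1:20) {
    w <- make_planted_world(n_communities = 2, genes_per = 6, res_per = 5,
                            terms_per = 6, cross_edge_rate = 0.2, seed = seed)
    goa <- close_annotations(w$dag, w$goa)
    regoa <- goa_raw(w$grn, goa)
    fix <- make_region_fixture(w, n_on_re = 12, n_off = 5, jitter = 300,
                               seed = seed)
    tab <- enrich_regions(fix$regions, regoa, w$grn$loci)

    # from-scratch recomputation in test code
    loci <- w$grn$loci
    ann <- regoa$annotations
    annotated <- names(ann)[lengths(ann) > 0]
    asg <- oracle_nearest(fix$regions,
                          loci[loci$re %in% annotated, , drop = FALSE], 1000)
    hits <- asg[, "re"][!is.na(asg[, "re"])]
    N <- length(hits)
    counts <- table(unlist(lapply(ann[hits], unique)))
    n_annot <- length(annotated)
    bg <- vapply(names(counts), function(t) {
      sum(vapply(ann[annotated], function(s) t %in% s, TRUE)) / n_annot
    }, 0)
    pv <- vapply(names(counts),
                 function(t) oracle_binom_tail(counts[[t]], N, bg[[t]]), 0)
    fdr <- oracle_bh(pv)
    ord <- match(tab$term, names(counts))
    expect_equal(tab$N, rep(N, nrow(tab)))
    expect_equal(tab$k, as.integer(counts)[ord])
    expect_equal(tab$p_t, unname(bg[ord]), tolerance = 1e-12)
    expect_equal(tab$pvalue, unname(pv[ord]), tolerance = 1e-12)
    expect_equal(tab$fdr, unname(fdr[ord]), tolerance = 1e-12)
    expect_true(!is.unsorted(tab$fdr))
  }
})
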