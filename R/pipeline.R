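# Pipeline orchestration: configuration, resource building and the
# application entry points used by the command-line script.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: walk and
#' skip-gram hyperparameters, the fixed analysis thresholds (1 kb
#' nearest-RE cut, enrichment theta 5e-8 for ChIP evaluation, openness
#' fold cut phi = 2 with minimum openness 2, GWAS enrichment FDR 0.05,
#' 80/20 train split) and the RNG seed. Configurations round-trip
#' losslessly through YAML via [write_config()] / [read_config()].
#'
#' @param namespace GO namespace, one of `"BP"`, `"MF"`, `"CC"`.
#' @param min_ppi_score minimum PPI combined score.
#' @param walks_per_start,walk_length,dim,window,negatives,epochs,min_count
#'   walk and embedding hyperparameters.
#' @param weighted bias walk transitions by edge weight.
#' @param split_tf_gene embed a TF separately from its gene node.
#' @param max_dist nearest-RE assignment cut in bp.
#' @param theta enrichment FDR cut for ChIP-seq TF annotation.
#' @param phi openness fold-change cut.
#' @param min_open minimum openness at one condition.
#' @param fdr_cut GWAS/trait enrichment FDR cut.
#' @param train_frac training fraction of the annotation split.
#' @param seed integer RNG seed used for every stochastic stage.
#' @return a `regoa_config` list.
#' @export
regoa_config <- function(namespace = "BP", min_ppi_score = 0,
                         walks_per_start = 20, walk_length = 5,
                         dim = 128, window = 5, negatives = 5, epochs = 5,
                         min_count = 1, weighted = TRUE,
                         split_tf_gene = TRUE, max_dist = 1000,
                         theta = 5e-8, phi = 2, min_open = 2,
                         fdr_cut = 0.05, train_frac = 0.8, seed = 1) {
  cfg <- list(
    namespace = match.arg(namespace, c("BP", "MF", "CC")),
    min_ppi_score = min_ppi_score,
    walks_per_start = as.integer(walks_per_start),
    walk_length = as.integer(walk_length),
    dim = as.integer(dim), window = as.integer(window),
    negatives = as.integer(negatives), epochs = as.integer(epochs),
    min_count = as.integer(min_count),
    weighted = isTRUE(weighted), split_tf_gene = isTRUE(split_tf_gene),
    max_dist = max_dist, theta = theta, phi = phi, min_open = min_open,
    fdr_cut = fdr_cut, train_frac = train_frac, seed = as.integer(seed)
  )
  stopifnot(
    cfg$walks_per_start >= 1, cfg$walk_length >= 2, cfg$dim >= 1,
    cfg$window >= 1, cfg$negatives >= 0, cfg$epochs >= 1,
    cfg$max_dist > 0, cfg$theta > 0, cfg$theta < 1, cfg$phi > 1,
    cfg$min_open >= 0, cfg$fdr_cut > 0, cfg$fdr_cut < 1,
    cfg$train_frac > 0, cfg$train_frac < 1
  )
  class(cfg) <- "regoa_config"
  cfg
}

#' @rdname regoa_config
#' @param config a `regoa_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname regoa_config
#' @export
read_config <- function(path) {
  do.call(regoa_config, yaml::read_yaml(path))
}

.require_inputs <- function(paths) {
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (is.null(p) || !file.exists(p)) {
      stop("missing input '", nm, "': ", if (is.null(p)) "not set" else p)
    }
  }
}

#' Build the RE annotation resource from raw input files
#'
#' Runs the full pipeline for one GO namespace: parse the ontology, close
#' the gene annotations under the True Path Rule, load PPI and GRN,
#' assemble the heterogeneous network, generate meta-path walks, train the
#' skip-gram embedding, calibrate per-term thresholds on gene function
#' prediction, derive the embedding-based RE annotations and intersect
#' them with the regulation-based ones. Writes the resource TSV, the
#' thresholds TSV and a JSON run manifest (all parameters, the seed and
#' md5 of every input) to `out_dir`; all stages are deterministic given
#' the seed, so a rerun reproduces the resource byte for byte.
#'
#' @param obo,goa,ppi,binds,regulates,loci input file paths
#'   (`goa` is a gene TAB term TSV or GAF, see `goa_format`).
#' @param out_dir output directory.
#' @param config a [regoa_config()].
#' @param goa_format `"tsv"` or `"gaf"`.
#' @return invisibly, a list with the built objects (`dag`, `goa`, `net`,
#'   `embedding`, `thresholds`, `raw`, `embed`, `final`) and the output
#'   `paths`.
#' @export
build_regoa <- function(obo, goa, ppi, binds, regulates, loci,
                        out_dir, config = regoa_config(),
                        goa_format = "tsv") {
  stopifnot(inherits(config, "regoa_config"))
  inputs <- list(obo = obo, goa = goa, ppi = ppi, binds = binds,
                 regulates = regulates, loci = loci)
  .require_inputs(inputs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  dag <- stage("ontology", parse_obo(obo, namespace = config$namespace))
  goa_closed <- stage("annotations", {
    close_annotations(dag, read_annotations(goa, format = goa_format))
  })
  ppi_net <- stage("ppi", load_ppi(ppi, min_score = config$min_ppi_score))
  grn <- stage("grn", load_grn(binds, regulates, loci))
  net <- stage("assemble", assemble_hetnet(
    dag, goa_closed, ppi_net, grn, split_tf_gene = config$split_tf_gene
  ))
  corpus <- stage("walks", generate_walks(
    net, default_metapaths(net),
    walks_per_start = config$walks_per_start, length = config$walk_length,
    seed = config$seed, weighted = config$weighted
  ))
  emb <- stage("embedding", train_embedding(
    corpus, dim = config$dim, window = config$window,
    negatives = config$negatives, epochs = config$epochs,
    seed = config$seed, min_count = config$min_count
  ))
  thresholds <- stage("calibration",
                      calibrate_thresholds(emb, dag, goa_closed))
  embed_map <- stage("annotation", suppressWarnings(
    goa_embed(emb, dag, thresholds, grn$loci$re)
  ))
  raw_map <- stage("annotation", goa_raw(grn, goa_closed))
  final <- stage("annotation", annotate_res(embed_map, raw_map))

  ns <- config$namespace
  paths <- list(
    resource = file.path(out_dir, sprintf("regoa_%s.tsv", ns)),
    thresholds = file.path(out_dir, sprintf("thresholds_%s.tsv", ns)),
    manifest = file.path(out_dir, sprintf("manifest_%s.json", ns))
  )
  write_re_annotation(final, grn$loci, paths$resource)
  write_thresholds(thresholds, paths$thresholds)
  manifest <- list(
    params = unclass(config),
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf(
    "built %s resource: %d/%d REs annotated, %d calibrated terms",
    ns, sum(lengths(final$annotations) > 0), nrow(grn$loci),
    nrow(thresholds)
  ))
  invisible(list(
    dag = dag, goa = goa_closed, net = net, embedding = emb,
    thresholds = thresholds, raw = raw_map, embed = embed_map,
    final = final, loci = grn$loci, paths = paths
  ))
}

#' Enrichment of a region set against a built resource
#'
#' Thin delegation to [enrich_regions()] using the configuration's
#' nearest-RE cutoff; logs the assignment counts.
#'
#' @param resource list with elements `annotation` (a `re_annotation`) and
#'   `loci`, e.g. from [read_re_annotation()] or `final`/`loci` of
#'   [build_regoa()].
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param config a [regoa_config()].
#' @return an `enrichment_table`.
#' @export
run_enrich <- function(resource, regions, config = regoa_config()) {
  tab <- enrich_regions(regions, resource$annotation, resource$loci,
                        max_dist = config$max_dist)
  message(sprintf("enrichment: %d regions in, N = %d assigned, %d terms tested",
                  nrow(regions), if (nrow(tab) > 0) tab$N[[1]] else 0L,
                  nrow(tab)))
  tab
}

#' ChIP-seq TF annotation driver
#'
#' Selects the top-scoring peaks (cap 15000), runs the enrichment and
#' evaluates the predicted term set against the TF's gold-standard
#' annotation at FDR cut `config$theta`.
#'
#' @inheritParams run_enrich
#' @param peaks scored peak data.frame (`chrom`, `start`, `end`, `score`).
#' @param standard character vector of gold-standard term ids for the TF.
#' @param dag a [go_dag].
#' @param cap maximum number of peaks used.
#' @return list with `peaks_used`, `enrichment` and `eval` (see
#'   [tf_eval()]).
#' @export
run_chip <- function(resource, peaks, standard, dag,
                     config = regoa_config(), cap = 15000) {
  top <- select_top_peaks(peaks, cap = cap)
  message(sprintf("chip-eval: using %d of %d peaks", nrow(top), nrow(peaks)))
  tab <- run_enrich(resource, top, config)
  list(peaks_used = nrow(top), enrichment = tab,
       eval = tf_eval(tab, standard, dag, theta = config$theta))
}

#' Differential ATAC-seq peak driver
#'
#' Filters differential peaks between two conditions (fold cut
#' `config$phi`, minimum openness `config$min_open`) and runs the
#' enrichment on the survivors.
#'
#' @inheritParams run_enrich
#' @param m openness data.frame as from [read_openness_matrix()].
#' @param t1,t2 condition column names.
#' @return list with `peaks` (the differential peaks) and `enrichment`.
#' @export
run_atac <- function(resource, m, t1, t2, config = regoa_config()) {
  peaks <- differential_peaks(m, t1, t2, phi = config$phi,
                              min_open = config$min_open)
  message(sprintf("atac-diff: %d of %d peaks pass phi > %g, openness > %g",
                  nrow(peaks), nrow(m), config$phi, config$min_open))
  list(peaks = peaks, enrichment = run_enrich(resource, peaks, config))
}

#' GWAS trait-similarity driver
#'
#' Profiles each trait's SNP set by enrichment (FDR cut `config$fdr_cut`)
#' and returns the pairwise Jaccard similarity of the enriched term sets.
#'
#' @inheritParams run_enrich
#' @param snp_sets named list of SNP region data.frames (one per trait).
#' @return list with `profiles`, the square `similarity` matrix and a
#'   long-format `pairs` data.frame.
#' @export
run_gwas <- function(resource, snp_sets, config = regoa_config()) {
  stopifnot(is.list(snp_sets), !is.null(names(snp_sets)))
  profiles <- lapply(snp_sets, function(snps) {
    trait_profile(snps, resource$annotation, resource$loci,
                  fdr_cut = config$fdr_cut, max_dist = config$max_dist)
  })
  n <- length(profiles)
  sim <- matrix(1, n, n, dimnames = list(names(profiles), names(profiles)))
  pairs <- NULL
  if (n > 1) {
    idx <- utils::combn(n, 2)
    vals <- apply(idx, 2, function(ij) {
      suppressWarnings(trait_similarity(profiles[[ij[1]]], profiles[[ij[2]]]))
    })
    for (j in seq_len(ncol(idx))) {
      sim[idx[1, j], idx[2, j]] <- vals[[j]]
      sim[idx[2, j], idx[1, j]] <- vals[[j]]
    }
    pairs <- data.frame(
      trait1 = names(profiles)[idx[1, ]],
      trait2 = names(profiles)[idx[2, ]],
      similarity = vals, stringsAsFactors = FALSE
    )
  }
  list(profiles = profiles, similarity = sim, pairs = pairs)
}
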