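#' Pipeline run configuration
#'
#' Bundles the paths, thresholds and seeds of a full run. The configuration
#' is serialised into the run manifest, and a hash of it is written into
#' every output header so results are traceable to their settings.
#'
#' @param tree path to the rooted reference tree (Newick).
#' @param hits path to the homology hit table (NULL when `profiles` given).
#' @param genome_map optional subject-to-genome mapping TSV.
#' @param profiles path to a precomputed profile TSV (alternative to hits).
#' @param genomes character vector of genome ids (required with `hits`).
#' @param query_genome focal genome id (required with `hits`).
#' @param annotations optional gene-to-GO TSV.
#' @param obo optional GO ontology OBO file.
#' @param evalue_max profile e-value threshold.
#' @param rooting `"asis"`, `"midpoint"` or `"mad"`.
#' @param subsample optional number of genomes to retain (with the query
#'   genome always kept).
#' @param cut_heights dendrogram cut heights to evaluate.
#' @param min_freq minimal GO term frequency for the enrichment test.
#' @param n_resamples enrichment resamples.
#' @param seed master seed.
#' @param restarts optimiser restarts per fit.
#' @param checkpoint optional checkpoint TSV for the pairwise stage.
#' @param skip_go skip the GO evaluation stage?
#' @return a `run_config` list.
#' @export
run_config <- function(tree, hits = NULL, genome_map = NULL, profiles = NULL,
                       genomes = NULL, query_genome = NULL,
                       annotations = NULL, obo = NULL,
                       evalue_max = 1e-20, rooting = "asis",
                       subsample = NULL, cut_heights = c(60, 80, 100),
                       min_freq = 5, n_resamples = 1e5, seed = 1L,
                       restarts = 10L, checkpoint = NULL, skip_go = FALSE) {
  cfg <- list(tree = tree, hits = hits, genome_map = genome_map,
              profiles = profiles, genomes = genomes,
              query_genome = query_genome, annotations = annotations,
              obo = obo, evalue_max = evalue_max, rooting = rooting,
              subsample = subsample, cut_heights = cut_heights,
              min_freq = min_freq, n_resamples = n_resamples,
              seed = as.integer(seed), restarts = as.integer(restarts),
              checkpoint = checkpoint, skip_go = skip_go)
  class(cfg) <- "run_config"
  cfg
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  # small rolling hash; enough to fingerprint a config in output headers
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

.write_with_header <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coevo %s | config %s | seed %d",
                     as.character(utils::packageVersion("coevo")),
                     .config_hash(cfg), cfg$seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes profiles -> rooting -> pairwise LRT -> distance/UPGMA -> cuts ->
#' GO evaluation, writing every stage's output (with a provenance header)
#' into `out_dir` plus a `manifest.json` recording the configuration, its
#' hash and the package version. The pairwise stage is checkpointed when a
#' checkpoint path is configured, and the run resumes from it.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_newick(cfg$tree)

  # --- profiles ---
  if (!is.null(cfg$profiles)) {
    pm <- read_profiles(cfg$profiles)
  } else {
    if (is.null(cfg$hits) || is.null(cfg$genomes) || is.null(cfg$query_genome))
      stop("stage profiles failed: need hits + genomes + query_genome, or a profile TSV")
    hits <- read_hits(cfg$hits, cfg$genome_map)
    pm <- build_profiles(hits, cfg$genomes, cfg$query_genome,
                         evalue_max = cfg$evalue_max)
  }
  pm <- deduplicate_profiles(pm)
  if (!is.null(cfg$subsample)) {
    keep <- if (!is.null(cfg$query_genome)) cfg$query_genome else character()
    ss <- subsample_taxa(pm, tree, cfg$subsample, keep = keep, seed = cfg$seed)
    pm <- ss$profiles; tree <- ss$tree
  }
  write_profiles(pm, file.path(out_dir, "profiles.tsv"))

  # --- rooting ---
  tree <- switch(cfg$rooting,
                 asis = tree,
                 midpoint = midpoint_root(tree),
                 mad = mad_root(tree),
                 stop("unknown rooting method: ", cfg$rooting))
  write_newick(tree, file.path(out_dir, "rooted.nwk"))

  # --- pairwise LRT ---
  opts <- pagel_options(restarts = cfg$restarts, seed = cfg$seed)
  lr <- tryCatch(
    all_pairs_lrt(pm, tree, opts, checkpoint = cfg$checkpoint),
    error = function(e) stop("stage pagel failed: ", conditionMessage(e)))
  lr_df <- data.frame(profile = rownames(lr), lr, check.names = FALSE)
  .write_with_header(lr_df, file.path(out_dir, "lr.tsv"), cfg)

  # --- clustering ---
  d <- lr_to_distance(lr)
  dend <- profile_upgma(d)
  .write_with_header(merge_table(dend), file.path(out_dir, "merges.tsv"), cfg)
  cuts <- lapply(cfg$cut_heights, function(h) cut_clusters(dend, h))
  names(cuts) <- as.character(cfg$cut_heights)
  cut_df <- data.frame(profile = dend$ids,
                       do.call(cbind, lapply(cuts, function(cl) cl[dend$ids])),
                       check.names = FALSE)
  names(cut_df)[-1] <- paste0("h", names(cuts))
  .write_with_header(cut_df, file.path(out_dir, "clusters.tsv"), cfg)

  # --- GO evaluation ---
  go <- NULL
  if (!cfg$skip_go && !is.null(cfg$obo) && !is.null(cfg$annotations)) {
    dag <- parse_obo(cfg$obo)
    annot <- read_annotations(cfg$annotations, dag)
    go <- lapply(names(cuts), function(h) {
      cl <- cuts[[h]]
      score <- tryCatch(clustering_score(dag, annot, cl),
                        error = function(e) NULL)
      enr <- enrichment_test(cl, annot, n_resamples = cfg$n_resamples,
                             min_freq = cfg$min_freq, seed = cfg$seed)
      .write_with_header(enr, file.path(out_dir, paste0("enrichment_h", h, ".tsv")),
                         cfg)
      list(h = h, score = score, enrichment = enr)
    })
    names(go) <- names(cuts)
    sc <- data.frame(h = names(go),
                     overall_score = vapply(go, function(g)
                       if (is.null(g$score)) NA_real_ else g$score$overall,
                       numeric(1)))
    .write_with_header(sc, file.path(out_dir, "go_scores.tsv"), cfg)
  }

  manifest <- list(package = "coevo",
                   version = as.character(utils::packageVersion("coevo")),
                   config = unclass(cfg), config_hash = .config_hash(cfg),
                   n_profiles = ncol(pm$mat), n_genomes = nrow(pm$mat))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(profiles = pm, tree = tree, lr = lr, dendrogram = dend,
                 cuts = cuts, go = go))
}
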