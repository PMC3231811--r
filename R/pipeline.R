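#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Only the
#' algorithms named in `algorithms` are run; each entry's `rng_seed` is
#' derived from the global `rng_seed` unless set explicitly.
#'
#' @param expression Path to the expression TSV.
#' @param annotations Optional path to a gene-term annotation file.
#' @param gold Optional path to the gold-standard network; `gold_directed`
#'   says whether its records are directed (interaction databases are not).
#' @param out_dir Output directory (created if absent).
#' @param preprocess A [preprocess_config()].
#' @param algorithms Named list of parameter objects; names among
#'   `cc`, `isa`, `opsm`, `kmeans`, or paths to external bicluster files
#'   under arbitrary names (detected by a character value).
#' @param bde A [bde_config()].
#' @param search A [search_config()].
#' @param levels Significance levels for the enrichment comparison.
#' @param gold_directed Is the gold file a directed edge list?
#' @param rng_seed Global seed.
#' @export
pipeline_config <- function(expression, annotations = NULL, gold = NULL,
                            out_dir = "bicgrn_out",
                            preprocess = preprocess_config(),
                            algorithms = list(cc = cc_params(),
                                              isa = isa_params(),
                                              opsm = opsm_params(),
                                              kmeans = kmeans_params()),
                            bde = bde_config(levels = preprocess$discretization_levels),
                            search = search_config(),
                            levels = c(0.01, 0.05),
                            gold_directed = FALSE,
                            rng_seed = 1L) {
  if (!length(algorithms)) stopf("at least one algorithm must be enabled")
  if (is.null(names(algorithms)) || any(!nzchar(names(algorithms)))) {
    stopf("`algorithms` must be a named list")
  }
  structure(list(expression = expression, annotations = annotations,
                 gold = gold, out_dir = out_dir, preprocess = preprocess,
                 algorithms = algorithms, bde = bde, search = search,
                 levels = levels, gold_directed = gold_directed,
                 rng_seed = as.integer(rng_seed)),
            class = "PipelineConfig")
}

run_one_algorithm <- function(name, par, m, seed_offset, global_seed) {
  reseed <- function(p) {
    p$rng_seed <- as.integer(global_seed + seed_offset)
    p
  }
  if (is.character(par)) {
    return(import_external_biclusters(par, m))
  }
  switch(class(par)[[1L]],
         CCParams = cc_bicluster(m, reseed(par)),
         ISAParams = isa_bicluster(m, reseed(par)),
         OPSMParams = opsm_bicluster(m, par),
         KMeansParams = kmeans_as_biclusters(m, reseed(par)),
         stopf("algorithm %s: unsupported parameter class %s",
               name, class(par)[[1L]]))
}

#' Run the full network-construction pipeline
#'
#' Executes impute -> filter -> (per algorithm) bicluster ->
#' enrichment comparison -> subnetwork learning -> merge -> evaluation
#' against the gold standard (standard and indirect-edge-reclassified) ->
#' topology, writing per-algorithm networks, the union (`ALL`) network,
#' comparison and evaluation TSVs, and a JSON manifest. Reruns with the
#' same config and seed are bit-identical. On any stage error, files
#' created by this run are removed and the error names the stage.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(cfg$out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- "read_expression"
  manifest <- list(package_version = as.character(utils::packageVersion("bicgrn")),
                   rng_seed = cfg$rng_seed, stages = list())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  tryCatch({
    m <- read_expression_tsv(cfg$expression)
    log_stage(stage, "%d genes x %d conditions", nrow(m$values), ncol(m$values))

    stage <- "impute"
    m <- knn_impute(m, cfg$preprocess$knn_k)
    stage <- "filter"
    m <- filter_genes(m, cfg$preprocess)
    log_stage(stage, "%d genes retained", nrow(m$values))

    ann <- NULL
    if (!is.null(cfg$annotations)) {
      stage <- "annotations"
      ann <- read_annotations(cfg$annotations, gene_ids(m))
    }
    gold <- NULL
    if (!is.null(cfg$gold)) {
      stage <- "gold"
      gold <- read_network(cfg$gold, directed = cfg$gold_directed)
    }

    stage <- "bicluster"
    sets <- list()
    for (i in seq_along(cfg$algorithms)) {
      nm <- names(cfg$algorithms)[[i]]
      sets[[nm]] <- run_one_algorithm(nm, cfg$algorithms[[i]], m, i,
                                      cfg$rng_seed)
      st <- bicluster_stats(sets[[nm]])
      log_stage(stage, "%s: %d biclusters, gene coverage %.1f%%",
                nm, st$n_biclusters, st$gene_coverage)
      write_biclusters(sets[[nm]], emit(sprintf("%s_biclusters.txt", nm)),
                       source = nm)
    }

    if (!is.null(ann)) {
      stage <- "compare"
      comp <- rbind(
        suppressWarnings(percent_enriched(sets, ann, cfg$levels, filtered = FALSE)),
        suppressWarnings(percent_enriched(sets, ann, cfg$levels, filtered = TRUE)))
      write_comparison_tsv(comp, emit("comparison.tsv"))
      manifest$comparison <- "comparison.tsv"
    }

    stage <- "learn"
    networks <- list()
    for (nm in names(sets)) {
      dags <- suppressWarnings(
        learn_subnetworks(m, sets[[nm]], cfg$preprocess, cfg$bde, cfg$search))
      networks[[nm]] <- merge_subnetworks(dags)
      log_stage(stage, "%s: %d subnetworks, %d merged edges",
                nm, length(dags), nrow(networks[[nm]]$edges))
      write_network(networks[[nm]], emit(sprintf("%s_network.tsv", nm)))
    }
    stage <- "merge"
    all_edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
    all_genes <- unique(unlist(lapply(networks, `[[`, "genes")))
    networks[["ALL"]] <- gene_network(
      all_edges %||% matrix(character(0), 0, 2), all_genes)
    write_network(networks[["ALL"]], emit("ALL_network.tsv"))

    if (!is.null(gold)) {
      stage <- "evaluate"
      universe <- union(unique(unlist(lapply(networks, `[[`, "genes"))),
                        gold$genes)
      reports <- lapply(networks, modified_reclassify, gold = gold,
                        universe = universe)
      write_evaluation_tsv(reports, emit("evaluation.tsv"))
      manifest$evaluation <- "evaluation.tsv"

      stage <- "topology"
      topo <- list(gold = topology_stats(gold))
      if (nrow(networks[["ALL"]]$edges)) {
        topo$ALL <- topology_stats(networks[["ALL"]])
      }
      topo_df <- do.call(rbind, lapply(names(topo), function(nm) {
        t <- topo[[nm]]
        data.frame(Network = nm, Diameter = t$diameter,
                   Density = format_4dp(t$density),
                   AvgNeighbors = format_4dp(t$avg_neighbors))
      }))
      utils::write.table(topo_df, emit("topology.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest$topology <- "topology.tsv"
    }

    stage <- "manifest"
    manifest$networks <- stats::setNames(
      lapply(names(networks), function(nm) {
        list(file = sprintf("%s_network.tsv", nm),
             edges = nrow(networks[[nm]]$edges))
      }), names(networks))
    manifest$parameters <- list(
      preprocess = unclass(cfg$preprocess),
      bde = unclass(cfg$bde),
      search = unclass(cfg$search)[c("max_parents", "candidate_size")],
      significance_levels = cfg$levels)
    jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}
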