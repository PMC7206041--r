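# Orchestration: simulate -> single-subject analysis -> DEG selection ->
# network -> functional enrichment, driven by one YAML/list config and one
# seed, emitting per-stage TSV outputs and a digest manifest so a rerun can
# be checked for byte-identical results.

.default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      n_genes = 500, n_pathways = 20, pathway_size_range = c(10, 20),
      n_implanted_pathways = 3, within_implanted_dysreg_frac = 0.5,
      background_dysreg_frac = 0.05, effect_mean = 2.5, effect_sd = 0.4,
      nb_dispersion = 0.1, baseline_mean_log_range = c(log(20), log(2000)),
      library_size_ratio = 1.3, up_fraction = 0.5,
      interactome = list(n_nodes = 200, n_communities = 5,
                         community_size = 10, p_in = 0.9, p_out = 0.01,
                         score_in_range = c(701, 999),
                         score_out_range = c(150, 700))),
    inputs = list(counts = NULL, condition_map = NULL, gmt = NULL,
                  interactions = NULL, alias_map = NULL),
    ssa = list(normalization = "upper_quartile", pseudocount = 0.5,
               min_set_size = 5, alpha = 0.05),
    deg = list(lfc_threshold = 1, p_adj_threshold = 0.05),
    network = list(score_min = 700, expansion = "first_shell",
                   evidence_channels = NULL, hub_fraction = 0.10,
                   penalty = 2, min_size = 3, min_density = 0.5,
                   omega_threshold = 0.8, alpha = 0.05),
    enrich = list(alpha = 0.05, correction = "none"))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills unspecified values with the
#' package defaults, and validates the schema. Unknown top-level keys are a
#' schema violation.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return The completed configuration list.
#' @seealso [runPipeline()]
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  known <- c(names(.default_config()), "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .merge_config(.default_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  if (!isTRUE(cfg$simulate$enabled)) {
    need <- c("counts", "gmt", "interactions")
    miss <- need[vapply(cfg$inputs[need], is.null, logical(1))]
    if (length(miss))
      stop("simulate disabled but input(s) missing: ",
           paste(miss, collapse = ", "))
    for (f in c("counts", "gmt", "interactions"))
      if (!file.exists(cfg$inputs[[f]]))
        stop("input file does not exist: ", cfg$inputs[[f]])
  }
  cfg
}

.digest_files <- function(paths) {
  d <- tools::md5sum(paths)
  stats::setNames(unname(d), basename(paths))
}

.write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full single-subject network pipeline
#'
#' Executes, in order: (1) `simulate` — paired counts with implanted
#' pathways plus a planted-partition interactome laid over the gene
#' universe with dysregulated genes placed preferentially inside
#' communities (or, when disabled, reading of the configured input files);
#' (2) `ssa` — normalization, fold changes, mixture classification and
#' BY-adjusted bidirectional pathway enrichment; (3) `degs` — DEG
#' selection; (4) `network` — seeded network construction, hub calling,
#' overlapping clustering with significance; (5) `enrich` — functional
#' enrichment of the hub set and of each significant cluster. Every stage
#' writes TSV outputs under `out_dir` and the manifest records an MD5
#' digest per file. A failed stage aborts with an error naming the stage.
#'
#' Stage randomness derives from the single config seed by fixed offsets,
#' so a rerun with the same config reproduces identical outputs.
#'
#' @param config YAML path or config list (see [pipelineConfig()]).
#' @param out_dir output directory (created if needed; defaults to
#'   `config$out_dir`).
#' @return The run manifest (invisibly a list; also written to
#'   `manifest.json`): config snapshot, seed, package version, timestamp
#'   and per-stage output digests.
#' @seealso [manifestDigests()] to compare two runs.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  cfg <- pipelineConfig(config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("out_dir must be given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  stage <- function(name, expr) {
    files <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages[[name]] <<- list(name = name, outputs = .digest_files(files))
    .msg("stage '", name, "' done (", length(files), " output file(s))")
  }

  # -- stage 1: simulate (or load inputs) ------------------------------------
  sim_env <- new.env()
  stage("simulate", {
    if (isTRUE(cfg$simulate$enabled)) {
      sc <- cfg$simulate
      sim <- simulatePairedCounts(simulationConfig(
        n_genes = sc$n_genes, n_pathways = sc$n_pathways,
        pathway_size_range = sc$pathway_size_range,
        n_implanted_pathways = sc$n_implanted_pathways,
        within_implanted_dysreg_frac = sc$within_implanted_dysreg_frac,
        background_dysreg_frac = sc$background_dysreg_frac,
        effect_mean = sc$effect_mean, effect_sd = sc$effect_sd,
        nb_dispersion = sc$nb_dispersion,
        baseline_mean_log_range = sc$baseline_mean_log_range,
        library_size_ratio = sc$library_size_ratio,
        up_fraction = sc$up_fraction, seed = cfg$seed))
      ic <- sc$interactome
      genes <- names(sim$truth$true_class)
      dys <- genes[sim$truth$true_class != "unaltered"]
      node_ids <- utils::head(c(dys, setdiff(genes, dys)), ic$n_nodes)
      isim <- simulateInteractome(
        n_nodes = length(node_ids), n_communities = ic$n_communities,
        community_size = ic$community_size, p_in = ic$p_in,
        p_out = ic$p_out, score_in_range = ic$score_in_range,
        score_out_range = ic$score_out_range,
        seed = cfg$seed + 101L, node_ids = node_ids)
      sim_env$counts <- sim$counts
      sim_env$sets <- sim$sets
      sim_env$interactions <- isim$interactions
      sim_env$truth <- sim$truth
      sim_env$communities <- isim$truth$planted_communities
      c(writeCounts(sim$counts, file.path(out_dir, "counts.tsv")),
        writeGmt(sim$sets, file.path(out_dir, "pathways.gmt")),
        writeInteractions(isim$interactions,
                          file.path(out_dir, "interactions.tsv")),
        .write_tsv_out(data.frame(gene_id = names(sim$truth$true_class),
                                  true_class = sim$truth$true_class),
                       file.path(out_dir, "truth_genes.tsv")),
        .write_tsv_out(data.frame(
          community = rep(seq_along(sim_env$communities),
                          lengths(sim_env$communities)),
          node_id = unlist(sim_env$communities)),
          file.path(out_dir, "truth_communities.tsv")))
    } else {
      cm <- unlist(cfg$inputs$condition_map)
      sim_env$counts <- readCounts(cfg$inputs$counts, condition_map = cm)
      sim_env$sets <- readGmt(cfg$inputs$gmt)
      sim_env$interactions <- readInteractions(cfg$inputs$interactions)
      character()
    }
  })

  # -- stage 2: single-subject analysis --------------------------------------
  ssa_env <- new.env()
  stage("ssa", {
    pair <- normalizePair(sim_env$counts, method = cfg$ssa$normalization)
    fc <- computeFoldChanges(pair, pseudocount = cfg$ssa$pseudocount)
    fit <- fitDysregulationMixture(fc)
    classes <- classifyGenes(fit, fc)
    enr <- pathwayFet(classes, sim_env$sets,
                      min_set_size = cfg$ssa$min_set_size)
    enr <- enr[order(enr$p_adj, enr$p_raw, enr$set_id), ]
    ssa_env$classes <- classes
    ssa_env$enrichment <- enr
    c(.write_tsv_out(classes, file.path(out_dir, "gene_classes.tsv")),
      .write_tsv_out(enr, file.path(out_dir, "pathway_enrichment.tsv")))
  })

  # -- stage 3: DEG selection ------------------------------------------------
  deg_env <- new.env()
  stage("degs", {
    degs <- selectDegs(ssa_env$classes,
                       lfc_threshold = cfg$deg$lfc_threshold,
                       p_adj_threshold = cfg$deg$p_adj_threshold)
    if (!nrow(degs)) stop("no DEGs passed the thresholds")
    deg_env$degs <- degs
    writeDegTable(degs, file.path(out_dir, "degs.tsv"))
  })

  # -- stage 4: network ------------------------------------------------------
  net_env <- new.env()
  stage("network", {
    nc <- cfg$network
    alias <- if (!is.null(cfg$inputs$alias_map))
      readAliasMap(cfg$inputs$alias_map) else NULL
    net <- buildNetwork(deg_env$degs, sim_env$interactions,
                        score_min = nc$score_min, expansion = nc$expansion,
                        evidence_channels = nc$evidence_channels,
                        alias_map = alias)
    hubs <- findHubs(net, fraction = nc$hub_fraction)
    clusters <- growClusters(net, penalty = nc$penalty,
                             min_size = nc$min_size,
                             min_density = nc$min_density)
    clusters <- mergeOverlapping(clusters, net,
                                 omega_threshold = nc$omega_threshold,
                                 penalty = nc$penalty)
    clusters <- scoreClusters(clusters, net, alpha = nc$alpha)
    net_env$net <- net
    net_env$hubs <- hubs
    net_env$clusters <- clusters
    ctab <- clusters
    ctab$members <- vapply(ctab$members, paste, character(1), collapse = ",")
    c(writeNetworkGraphml(net, file.path(out_dir, "network.graphml")),
      writeEdgeList(net, file.path(out_dir, "network_edges.tsv")),
      .write_tsv_out(hubs, file.path(out_dir, "hubs.tsv")),
      .write_tsv_out(ctab, file.path(out_dir, "clusters.tsv")))
  })

  # -- stage 5: functional enrichment ----------------------------------------
  stage("enrich", {
    ec <- cfg$enrich
    enrich_one <- function(ids, label) {
      rep <- suppressWarnings(
        enrichGeneSet(ids, sim_env$sets, alpha = ec$alpha,
                      correction = ec$correction))
      cbind(query = label, rep)
    }
    hub_rep <- enrich_one(net_env$hubs$node_id, "hubs")
    sig <- net_env$clusters[net_env$clusters$significant, , drop = FALSE]
    cl_rep <- if (nrow(sig)) {
      do.call(rbind, lapply(seq_len(nrow(sig)), function(i)
        enrich_one(sig$members[[i]], sig$cluster_id[i])))
    } else {
      hub_rep[0, ]
    }
    c(.write_tsv_out(hub_rep, file.path(out_dir, "hub_enrichment.tsv")),
      .write_tsv_out(cl_rep, file.path(out_dir, "cluster_enrichment.tsv")))
  })

  manifest <- list(
    tool = "sololens",
    version = as.character(utils::packageVersion("sololens")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = cfg,
    stages = unname(stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Output digests of a pipeline manifest
#'
#' Flattens the per-stage MD5 digests of a [runPipeline()] manifest into one
#' named vector (`stage/file` -> digest), suitable for comparing two runs
#' for byte-identical outputs.
#'
#' @param manifest a manifest list as returned by [runPipeline()].
#' @return Named character vector of digests.
#' @export
manifestDigests <- function(manifest) {
  out <- character()
  for (st in manifest$stages) {
    d <- unlist(st$outputs)
    if (length(d))
      out[paste(st$name, names(d), sep = "/")] <- unname(d)
  }
  out
}

#' Path to the bundled demo configuration
#'
#' A small fully synthetic run (500 genes, 20 pathways, 3 implanted;
#' 200-node interactome with 5 planted communities) used by the examples
#' and the determinism checks.
#'
#' @return Path to the YAML file.
#' @export
demoConfig <- function() {
  system.file("extdata", "demo-config.yaml", package = "sololens",
              mustWork = TRUE)
}
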