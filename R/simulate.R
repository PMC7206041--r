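# Ground-truth generators: a paired negative-binomial transcriptome with
# pathway-implanted dysregulation, and a planted-partition interactome with
# STRING-style scores. Defaults reproduce the package's reference study
# conditions (5,000 genes, 100 pathways of 30-50 genes, 10 implanted at 50%
# member dysregulation over a 5% background, log2 effect |N(2.5, 0.4)|).

#' Simulation configuration for paired counts
#'
#' Collects and validates the knobs of [simulatePairedCounts()].
#'
#' @param n_genes number of genes in the universe.
#' @param n_pathways number of gene sets generated.
#' @param pathway_size_range integer `(min, max)` set size, drawn uniformly.
#' @param n_implanted_pathways number of pathways carrying implanted
#'   dysregulation.
#' @param within_implanted_dysreg_frac probability that a gene belonging to
#'   an implanted pathway is dysregulated.
#' @param background_dysreg_frac probability that any other gene is
#'   dysregulated (phenotype-unrelated background noise).
#' @param effect_mean,effect_sd log2-unit effect size: dysregulated genes get
#'   a fold-change exponent `delta = sign * |N(effect_mean, effect_sd)|`.
#' @param nb_dispersion negative-binomial dispersion shared by all genes
#'   (variance `mu + dispersion * mu^2`).
#' @param baseline_mean_log_range `(min, max)` of the natural-log baseline
#'   mean count, drawn log-uniformly per gene.
#' @param library_size_ratio global multiplier of treated means, exercising
#'   between-sample normalization (default 1.3).
#' @param up_fraction probability a dysregulated gene is upregulated.
#' @param seed integer random seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulationConfig <- function(n_genes = 5000, n_pathways = 100,
                             pathway_size_range = c(30L, 50L),
                             n_implanted_pathways = 10,
                             within_implanted_dysreg_frac = 0.5,
                             background_dysreg_frac = 0.05,
                             effect_mean = 2.5, effect_sd = 0.4,
                             nb_dispersion = 0.1,
                             baseline_mean_log_range = c(log(20), log(2000)),
                             library_size_ratio = 1.3,
                             up_fraction = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_implanted_pathways = as.integer(n_implanted_pathways),
              within_implanted_dysreg_frac = within_implanted_dysreg_frac,
              background_dysreg_frac = background_dysreg_frac,
              effect_mean = effect_mean, effect_sd = effect_sd,
              nb_dispersion = nb_dispersion,
              baseline_mean_log_range = baseline_mean_log_range,
              library_size_ratio = library_size_ratio,
              up_fraction = up_fraction, seed = as.integer(seed))
  fr <- c(cfg$within_implanted_dysreg_frac, cfg$background_dysreg_frac,
          cfg$up_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_implanted_pathways > cfg$n_pathways)
    stop("n_implanted_pathways exceeds n_pathways")
  if (length(cfg$pathway_size_range) != 2 ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2])
    stop("pathway_size_range must be (min, max)")
  if (cfg$pathway_size_range[2] > cfg$n_genes)
    stop("pathways cannot be larger than the gene universe")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$library_size_ratio <= 0) stop("library_size_ratio must be > 0")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a paired single-subject transcriptome with implanted pathways
#'
#' Emulates one subject's untreated/treated pair: per-gene baseline means are
#' drawn log-uniformly, untreated counts are negative binomial at the
#' baseline mean, treated counts at `mean * 2^delta * library_size_ratio`,
#' where `delta = 0` for unaltered genes and `delta = sign * |N(effect_mean,
#' effect_sd)|` for dysregulated ones. Genes inside the implanted pathways
#' are dysregulated at `within_implanted_dysreg_frac`, all others at
#' `background_dysreg_frac`. Deterministic under the config seed.
#'
#' @param config a [simulationConfig()] list.
#' @return A list with elements `counts` ([PairedCounts-class] with samples
#'   `"untreated"`/`"treated"`), `sets` ([GeneSets-class]) and `truth` (list
#'   with `true_class` — named factor up/down/unaltered partitioning the
#'   universe — and `implanted_pathway_ids`).
#' @examples
#' sim <- simulatePairedCounts(simulationConfig(n_genes = 300,
#'                                              n_pathways = 10,
#'                                              pathway_size_range = c(10, 20),
#'                                              n_implanted_pathways = 2,
#'                                              seed = 7))
#' table(sim$truth$true_class)
#' @export
simulatePairedCounts <- function(config = simulationConfig()) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulationConfig, config)
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))

  sizes <- sample(seq(config$pathway_size_range[1],
                      config$pathway_size_range[2]),
                  config$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("PW%04d", seq_len(config$n_pathways))
  implanted <- if (config$n_implanted_pathways > 0)
    sort(sample(names(sets), config$n_implanted_pathways)) else character()

  in_implanted <- genes %in% unique(unlist(sets[implanted], use.names = FALSE))
  p_dys <- ifelse(in_implanted, config$within_implanted_dysreg_frac,
                  config$background_dysreg_frac)
  dys <- stats::runif(config$n_genes) < p_dys
  up <- dys & (stats::runif(config$n_genes) < config$up_fraction)
  true_class <- factor(ifelse(!dys, "unaltered", ifelse(up, "up", "down")),
                       levels = c("up", "down", "unaltered"))
  names(true_class) <- genes

  delta <- numeric(config$n_genes)
  if (any(dys))
    delta[dys] <- ifelse(up[dys], 1, -1) *
      abs(stats::rnorm(sum(dys), config$effect_mean, config$effect_sd))

  mu <- exp(stats::runif(config$n_genes,
                         config$baseline_mean_log_range[1],
                         config$baseline_mean_log_range[2]))
  size <- 1 / config$nb_dispersion
  u <- stats::rnbinom(config$n_genes, mu = mu, size = size)
  t <- stats::rnbinom(config$n_genes,
                      mu = mu * 2^delta * config$library_size_ratio,
                      size = size)
  m <- cbind(untreated = u, treated = t)
  rownames(m) <- genes
  counts <- PairedCounts(m, condition = c(untreated = "untreated",
                                          treated = "treated"))
  list(counts = counts,
       sets = GeneSets(sets, universe = genes),
       truth = list(true_class = true_class,
                    implanted_pathway_ids = implanted))
}

#' Simulate a planted-partition interactome
#'
#' Generates a STRING-style interaction table over `n_nodes` proteins with
#' `n_communities` planted communities of `community_size` nodes each:
#' within-community pairs are linked with probability `p_in` (scores uniform
#' in `score_in_range`), all remaining pairs with probability `p_out`
#' (scores uniform in `score_out_range`). Deterministic under `seed`.
#'
#' @param n_nodes total number of nodes.
#' @param n_communities,community_size planted community layout
#'   (`n_communities * community_size <= n_nodes`).
#' @param p_in,p_out edge probabilities inside/outside communities.
#' @param score_in_range,score_out_range integer score ranges (0-999);
#'   ranges may overlap. The defaults put community edges above and
#'   background edges below the conventional 700 confidence cut.
#' @param seed integer random seed.
#' @param node_ids optional explicit node identifiers (length `n_nodes`);
#'   the first `n_communities * community_size` ids form the communities.
#' @return A list with `interactions` (an `interaction_table` data.frame)
#'   and `truth` (list with `planted_communities`, a list of node-id sets).
#' @examples
#' sim <- simulateInteractome(10, 2, 5, p_in = 1, p_out = 0, seed = 3)
#' nrow(sim$interactions)  # two 5-cliques: 2 * choose(5, 2) = 20 edges
#' @export
simulateInteractome <- function(n_nodes, n_communities, community_size,
                                p_in, p_out,
                                score_in_range = c(701L, 999L),
                                score_out_range = c(150L, 700L),
                                seed = 1L, node_ids = NULL) {
  if (n_communities * community_size > n_nodes)
    stop("communities do not fit: n_communities * community_size > n_nodes")
  if (any(c(p_in, p_out) < 0 | c(p_in, p_out) > 1))
    stop("edge probabilities must lie in [0, 1]")
  for (r in list(score_in_range, score_out_range))
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 999)
      stop("score ranges must be (min, max) within 0-999")
  if (is.null(node_ids)) node_ids <- sprintf("p%04d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes) stop("node_ids must have length n_nodes")
  set.seed(seed)

  comm <- split(node_ids[seq_len(n_communities * community_size)],
                rep(seq_len(n_communities), each = community_size))
  membership <- rep(NA_integer_, n_nodes)
  membership[seq_len(n_communities * community_size)] <-
    rep(seq_len(n_communities), each = community_size)

  pairs <- utils::combn(n_nodes, 2)
  same <- !is.na(membership[pairs[1, ]]) & !is.na(membership[pairs[2, ]]) &
    membership[pairs[1, ]] == membership[pairs[2, ]]
  same[is.na(same)] <- FALSE
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < p
  lo <- ifelse(same, score_in_range[1], score_out_range[1])[keep]
  hi <- ifelse(same, score_in_range[2], score_out_range[2])[keep]
  score <- lo + floor(stats::runif(sum(keep)) * (hi - lo + 1))
  out <- data.frame(protein_a = node_ids[pairs[1, keep]],
                    protein_b = node_ids[pairs[2, keep]],
                    combined_score = as.integer(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  list(interactions = out,
       truth = list(planted_communities = unname(comm)))
}
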