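#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

# ---------------------------------------------------------------------------
# PairedCounts: raw counts for one subject, one or more samples per condition
# ---------------------------------------------------------------------------

#' Paired single-subject count container
#'
#' `PairedCounts` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds the raw gene-level counts for one subject profiled under two
#' conditions (untreated and treated), typically one sample each, optionally
#' at a labelled time point. The single assay is named `"counts"` and must be
#' a matrix of non-negative integers with unique gene identifiers as row
#' names; `colData(x)$condition` records `"untreated"` or `"treated"` per
#' sample.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [PairedCounts()] for construction, [readCounts()] to parse a TSV.
#' @export
setClass("PairedCounts", contains = "SummarizedExperiment")

.validPairedCounts <- function(object) {
  msg <- character()
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
    if (is.null(rownames(m))) msg <- c(msg, "gene identifiers (rownames) required")
    else if (anyDuplicated(rownames(m)))
      msg <- c(msg, paste0("duplicated gene identifiers: ",
                           paste(unique(rownames(m)[duplicated(rownames(m))]),
                                 collapse = ", ")))
  }
  if (!("condition" %in% colnames(colData(object))))
    msg <- c(msg, "colData column 'condition' is required")
  else if (!all(object$condition %in% c("untreated", "treated")))
    msg <- c(msg, "condition must be 'untreated' or 'treated'")
  if (length(msg)) msg else TRUE
}
setValidity("PairedCounts", .validPairedCounts)

#' Construct a PairedCounts object
#'
#' @param counts integer matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param condition character vector, one of `"untreated"`/`"treated"` per
#'   sample; may be named by sample.
#' @param time_label optional free-text time-point label (e.g. `"5h"`).
#' @return A [PairedCounts-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("U", "T")))
#' pc <- PairedCounts(m, condition = c(U = "untreated", T = "treated"))
#' @export
PairedCounts <- function(counts, condition, time_label = NA_character_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (!is.null(names(condition)))
    condition <- condition[colnames(counts)]
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = unname(condition),
                        row.names = colnames(counts)))
  obj <- new("PairedCounts", se)
  metadata(obj)$time_label <- time_label
  validObject(obj)
  obj
}

#' @describeIn PairedCounts condition label per sample.
#' @param x a `PairedCounts` object.
#' @export
conditionOf <- function(x) {
  stopifnot(is(x, "PairedCounts"))
  stats::setNames(x$condition, colnames(x))
}

#' @describeIn PairedCounts the time-point label (may be `NA`).
#' @export
timeLabel <- function(x) {
  stopifnot(is(x, "PairedCounts"))
  metadata(x)$time_label
}

setMethod("show", "PairedCounts", function(object) {
  cat("PairedCounts:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  conditions:", paste(object$condition, collapse = ", "), "\n")
  tl <- metadata(object)$time_label
  if (!is.null(tl) && !is.na(tl)) cat("  time point:", tl, "\n")
})

# ---------------------------------------------------------------------------
# GeneSets: a GMT-style gene-set collection
# ---------------------------------------------------------------------------

#' Gene-set collection
#'
#' An S4 container for a GMT-style collection: named member lists, one
#' description per set, and an optional explicit gene universe. Member lists
#' are deduplicated and non-empty; set identifiers are unique.
#'
#' @slot sets named list of character vectors of member gene ids.
#' @slot descriptions character vector, parallel to `sets`.
#' @slot universe optional character vector; when empty the universe defaults
#'   to the union of all members (see [geneUniverse()]).
#' @seealso [GeneSets()], [readGmt()], [geneUniverse()]
#' @export
setClass("GeneSets",
         representation(sets = "list", descriptions = "character",
                        universe = "character"))

.validGeneSets <- function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "set ids must be unique and non-empty")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "members must be character vectors")
    else {
      if (any(vapply(s, length, integer(1)) == 0L))
        msg <- c(msg, "empty member lists are not allowed")
      if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        msg <- c(msg, "member lists must be deduplicated")
    }
    if (length(object@descriptions) != length(s))
      msg <- c(msg, "one description per set required")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneSets", .validGeneSets)

#' Construct a GeneSets collection
#'
#' @param sets named list of character vectors (member gene ids; duplicates
#'   are removed).
#' @param descriptions optional character vector parallel to `sets`
#'   (defaults to the set ids).
#' @param universe optional explicit gene universe.
#' @return A [GeneSets-class] object.
#' @examples
#' gs <- GeneSets(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")))
#' @export
GeneSets <- function(sets, descriptions = NULL, universe = character()) {
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) descriptions <- names(sets)
  if (is.null(descriptions)) descriptions <- character()
  new("GeneSets", sets = sets,
      descriptions = stats::setNames(as.character(descriptions), names(sets)),
      universe = unique(as.character(universe)))
}

#' @describeIn GeneSets number of sets.
#' @param x a `GeneSets` object.
#' @export
setMethod("length", "GeneSets", function(x) length(x@sets))

#' @describeIn GeneSets set identifiers.
#' @export
setMethod("names", "GeneSets", function(x) names(x@sets))

#' @describeIn GeneSets extract the member list of one set by id or index.
#' @param i set id or index.
#' @export
setMethod("[[", "GeneSets", function(x, i) x@sets[[i]])

#' Member lists of a GeneSets collection
#' @param x a [GeneSets-class] object.
#' @return Named list of character vectors.
#' @export
geneSetMembers <- function(x) {
  stopifnot(is(x, "GeneSets"))
  x@sets
}

#' Set descriptions of a GeneSets collection
#' @param x a [GeneSets-class] object.
#' @return Named character vector.
#' @export
geneSetDescriptions <- function(x) {
  stopifnot(is(x, "GeneSets"))
  x@descriptions
}

#' Gene universe of a collection
#'
#' The explicit universe when one is recorded, otherwise the union of all
#' member lists.
#' @param x a [GeneSets-class] object.
#' @return Character vector of gene ids.
#' @export
geneUniverse <- function(x) {
  stopifnot(is(x, "GeneSets"))
  if (length(x@universe)) x@universe
  else unique(unlist(x@sets, use.names = FALSE))
}

setMethod("show", "GeneSets", function(object) {
  cat("GeneSets:", length(object@sets), "sets,",
      length(geneUniverse(object)), "genes in universe\n")
  if (length(object@sets)) {
    sz <- vapply(object@sets, length, integer(1))
    cat("  set sizes:", min(sz), "-", max(sz), "\n")
  }
})

# ---------------------------------------------------------------------------
# MixtureFit: two-component Gaussian mixture over |log2FC|
# ---------------------------------------------------------------------------

#' Gaussian mixture fit over absolute log2 fold changes
#'
#' The result of [fitDysregulationMixture()]: component weights, means and
#' standard deviations (component order: increasing mean, so the last
#' component is the dysregulated one), the per-gene posterior probability of
#' the dysregulated component, the log-likelihood trace of the EM iterations,
#' and convergence/degeneracy flags. A degenerate fit (collapsed component)
#' carries zero posteriors so every gene is called unaltered downstream.
#'
#' @slot weights,means,sds numeric, one entry per component.
#' @slot posterior numeric, per-gene posterior of the dysregulated component,
#'   named by gene.
#' @slot loglik numeric log-likelihood trace (one entry per EM iteration).
#' @slot converged,degenerate logical flags.
#' @slot iterations integer, EM iterations performed.
#' @export
setClass("MixtureFit",
         representation(weights = "numeric", means = "numeric",
                        sds = "numeric", posterior = "numeric",
                        loglik = "numeric", converged = "logical",
                        degenerate = "logical", iterations = "integer"))

.validMixtureFit <- function(object) {
  msg <- character()
  if (!object@degenerate) {
    if (abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "component weights must sum to 1")
    if (length(object@weights) != length(object@means) ||
        length(object@means) != length(object@sds))
      msg <- c(msg, "weights, means, sds must have equal length")
  }
  if (length(object@posterior) &&
      (min(object@posterior) < -1e-12 || max(object@posterior) > 1 + 1e-12))
    msg <- c(msg, "posteriors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("MixtureFit", .validMixtureFit)

#' @describeIn MixtureFit per-gene posterior probability of dysregulation.
#' @param x a `MixtureFit` object.
#' @export
dysregulationPosterior <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  x@posterior
}

#' @describeIn MixtureFit data.frame of component weight/mean/sd.
#' @export
mixtureComponents <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  data.frame(component = seq_along(x@weights), weight = x@weights,
             mean = x@means, sd = x@sds)
}

#' @describeIn MixtureFit `TRUE` for a collapsed (fallback) fit.
#' @export
isDegenerate <- function(x) {
  stopifnot(is(x, "MixtureFit"))
  x@degenerate
}

setMethod("show", "MixtureFit", function(object) {
  if (object@degenerate) {
    cat("MixtureFit: degenerate (all genes called unaltered)\n")
  } else {
    cat(sprintf("MixtureFit: %d components over %d genes, %s after %d iterations\n",
                length(object@weights), length(object@posterior),
                if (object@converged) "converged" else "not converged",
                object@iterations))
    print(mixtureComponents(object), row.names = FALSE)
  }
})

# ---------------------------------------------------------------------------
# WeightedNetwork: DEG-seeded confidence-weighted PPI graph
# ---------------------------------------------------------------------------

#' Seed-anchored weighted interaction network
#'
#' Wraps an undirected [igraph::igraph] graph whose edge weights are STRING
#' combined scores retained above a strict threshold, together with the seed
#' node set and the construction policy. Built by [buildNetwork()].
#'
#' @slot graph an igraph object; vertex attribute `is_seed`, edge attribute
#'   `weight`.
#' @slot seeds character vector of seed node ids present in the network.
#' @slot scoreMin numeric score threshold used (edges satisfy
#'   `weight > scoreMin`).
#' @slot expansion `"first_shell"` or `"seeds_only"`.
#' @slot channels evidence channels required at construction (may be empty).
#' @export
setClass("WeightedNetwork",
         representation(graph = "ANY", seeds = "character",
                        scoreMin = "numeric", expansion = "character",
                        channels = "character"))

.validWeightedNetwork <- function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    if (is.null(w)) msg <- c(msg, "edges must carry a weight attribute")
    else if (any(w <= object@scoreMin))
      msg <- c(msg, "every edge weight must exceed the score threshold")
  }
  if (!all(object@seeds %in% igraph::V(g)$name))
    msg <- c(msg, "seeds must be nodes of the graph")
  if (length(msg)) msg else TRUE
}
setValidity("WeightedNetwork", .validWeightedNetwork)

#' @describeIn WeightedNetwork the underlying igraph object.
#' @param x a `WeightedNetwork` object.
#' @export
networkGraph <- function(x) {
  stopifnot(is(x, "WeightedNetwork"))
  x@graph
}

#' @describeIn WeightedNetwork node identifiers.
#' @export
nodeIds <- function(x) {
  stopifnot(is(x, "WeightedNetwork"))
  igraph::V(x@graph)$name
}

#' @describeIn WeightedNetwork seed node identifiers.
#' @export
seedNodes <- function(x) {
  stopifnot(is(x, "WeightedNetwork"))
  x@seeds
}

setMethod("show", "WeightedNetwork", function(object) {
  g <- object@graph
  cat(sprintf("WeightedNetwork: %d nodes (%d seeds), %d edges\n",
              igraph::vcount(g), length(object@seeds), igraph::ecount(g)))
  cat(sprintf("  score > %g, expansion: %s\n", object@scoreMin,
              object@expansion))
  if (length(object@channels))
    cat("  evidence channels:", paste(object@channels, collapse = ", "), "\n")
})
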