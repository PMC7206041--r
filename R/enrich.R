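# Gene-set enrichment: one shared one-sided (greater) exact hypergeometric
# core drives both the bidirectional pathway dysregulation test and the
# hub/cluster functional enrichment; Benjamini-Yekutieli adjustment controls
# the FDR under the arbitrary dependence created by overlapping sets.

# P(X >= a) with X ~ Hypergeometric(N, K, n): a of the n draws fall in the
# K-sized category. Vectorized over equal-length arguments.
.hyper_p_greater <- function(a, K, N, n) {
  stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

# Sample odds ratio ad/bc with the conventions: +Inf when bc = 0,
# ad/bc otherwise (0 when ad = 0 with bc > 0).
.sample_odds_ratio <- function(a, b, c, d) {
  ifelse(b * c == 0, Inf, (a * d) / (b * c))
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR adjustment valid under arbitrary dependence: with `m` tests
#' and `c(m) = sum(1/(1:m))`, `adj(i) = min(1, min over j >= i of
#' m * c(m) * p(j) / j)` on the ascending-sorted p values, returned in the
#' original order. Values outside \[0, 1\] are an error.
#'
#' @param p numeric vector of raw p values.
#' @return Adjusted p values, same length and order.
#' @examples
#' adjustBY(c(0.01, 0.02, 0.03, 0.04))  # all 1/12
#' @export
adjustBY <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

# Core 2x2 enrichment shared by pathwayFet and enrichGeneSet:
# hit = "interesting" genes (dysregulated, or the query), over a universe.
.set_enrichment <- function(hit, members_list, universe) {
  N <- length(universe)
  n_hit <- length(hit)
  res <- lapply(names(members_list), function(id) {
    mem <- intersect(members_list[[id]], universe)
    a <- length(intersect(mem, hit))
    b <- length(mem) - a
    cc <- n_hit - a
    d <- N - a - b - cc
    data.frame(set_id = id, a = a, b = b, c = cc, d = d,
               set_size = length(mem), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$odds_ratio <- .sample_odds_ratio(res$a, res$b, res$c, res$d)
  res$p_raw <- .hyper_p_greater(res$a, res$set_size, N, n_hit)
  res
}

#' Bidirectional pathway dysregulation enrichment
#'
#' For each gene set, tests whether dysregulated genes (up and down counted
#' together) are over-represented among the set's measured members with a
#' one-sided (greater) Fisher's exact test on the 2x2 table
#' dysregulated/unaltered x in-set/out-of-set, then adjusts all raw p values
#' in one Benjamini-Yekutieli batch. Set members are intersected with the
#' measured universe; sets with fewer than `min_set_size` measured members
#' are skipped. Optionally, separate up-only and down-only tests are added.
#'
#' @param classes a `gene_class_table` from [classifyGenes()].
#' @param sets a [GeneSets-class] collection.
#' @param universe the background gene universe; defaults to the measured
#'   genes (`classes$gene_id`).
#' @param min_set_size minimum measured members per tested set (default 5).
#' @param directional when `TRUE`, also report up-only/down-only p values.
#' @return A data.frame of class `enrichment_result`, one row per tested
#'   set: 2x2 counts `a` (dysregulated in set), `b` (unaltered in set), `c`,
#'   `d`, `odds_ratio`, up/down member counts, `p_raw` and BY-adjusted
#'   `p_adj`.
#' @export
pathwayFet <- function(classes, sets, universe = NULL, min_set_size = 5,
                       directional = FALSE) {
  stopifnot(is(sets, "GeneSets"),
            all(c("gene_id", "class") %in% colnames(classes)))
  if (is.null(universe)) universe <- classes$gene_id
  universe <- unique(universe)
  if (!length(universe)) warning("empty universe: all p values are 1")
  cls <- classes[classes$gene_id %in% universe, ]
  up <- cls$gene_id[cls$class == "up"]
  down <- cls$gene_id[cls$class == "down"]
  dys <- c(up, down)
  if (!length(dys) && length(universe))
    warning("no dysregulated genes: all p values are 1")
  members <- geneSetMembers(sets)
  measured <- lapply(members, intersect, y = universe)
  keep <- vapply(measured, length, integer(1)) >= min_set_size
  if (!any(keep)) {
    out <- data.frame(set_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), set_size = integer(),
                      odds_ratio = numeric(), n_up = integer(),
                      n_down = integer(), p_raw = numeric(), p_adj = numeric())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  res <- .set_enrichment(dys, measured[keep], universe)
  res$n_up <- vapply(measured[keep],
                     function(m) length(intersect(m, up)), integer(1))
  res$n_down <- vapply(measured[keep],
                       function(m) length(intersect(m, down)), integer(1))
  if (directional) {
    res$p_up <- .set_enrichment(up, measured[keep], universe)$p_raw
    res$p_down <- .set_enrichment(down, measured[keep], universe)$p_raw
  }
  res$p_adj <- adjustBY(res$p_raw)
  res <- res[, c("set_id", "a", "b", "c", "d", "set_size", "odds_ratio",
                 "n_up", "n_down",
                 if (directional) c("p_up", "p_down"), "p_raw", "p_adj")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Functional enrichment of a gene/protein set
#'
#' Tests a query set (e.g. network hubs or one cluster's members) against
#' every term of a GMT collection with the same one-sided hypergeometric
#' core as [pathwayFet()]. The universe defaults to all genes annotated in
#' the collection; query ids outside the universe are dropped with a
#' warning. By default p values are not corrected and terms with
#' `p_raw < alpha` are flagged significant; BH or BY correction is
#' selectable, in which case the flag uses the corrected value.
#'
#' @param query character vector of gene/protein ids (non-empty).
#' @param sets a [GeneSets-class] collection.
#' @param universe background universe (default: [geneUniverse()] of `sets`).
#' @param alpha significance level (default 0.05, strict `<`).
#' @param correction `"none"` (default), `"BH"` or `"BY"`.
#' @param min_set_size minimum measured members per tested term (default 1).
#' @return A data.frame of class `set_enrichment_report`: per term the
#'   overlap, term size, universe counts, `odds_ratio`, `p_raw`, `p_adj`
#'   (equal to `p_raw` when `correction = "none"`) and `significant`.
#' @export
enrichGeneSet <- function(query, sets, universe = NULL, alpha = 0.05,
                          correction = c("none", "BH", "BY"),
                          min_set_size = 1) {
  stopifnot(is(sets, "GeneSets"))
  correction <- match.arg(correction)
  if (!length(query)) stop("empty query set")
  query <- unique(query)
  if (is.null(universe)) universe <- geneUniverse(sets)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query id(s) outside the universe")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("no query ids left inside the universe")
  members <- geneSetMembers(sets)
  measured <- lapply(members, intersect, y = universe)
  keep <- vapply(measured, length, integer(1)) >= min_set_size
  res <- .set_enrichment(query, measured[keep], universe)
  res$p_adj <- switch(correction,
                      none = res$p_raw,
                      BH = stats::p.adjust(res$p_raw, "BH"),
                      BY = adjustBY(res$p_raw))
  res$significant <- res$p_adj < alpha
  res <- data.frame(term_id = res$set_id, overlap = res$a,
                    term_size = res$set_size, query_size = length(query),
                    universe_size = length(universe),
                    odds_ratio = res$odds_ratio, p_raw = res$p_raw,
                    p_adj = res$p_adj, significant = res$significant,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("set_enrichment_report", "data.frame")
  res
}
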