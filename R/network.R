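# DEG-seeded weighted PPI network analysis: strict score-thresholded
# construction with first-shell expansion, top-decile degree hubs, and
# overlapping clusters grown greedily under the cohesiveness score
# w_in / (w_in + w_bound + penalty * |V|), merged by overlap omega and
# scored by a one-sided Mann-Whitney test of internal vs boundary weights.

#' Build a seed-anchored weighted interaction network
#'
#' Keeps interactions with `combined_score > score_min` (strict, per the
#' STRING high-confidence convention) and, when `evidence_channels` is
#' given, with at least one listed channel score > 0. Under the default
#' `first_shell` policy the node set is the seeds found in the table plus
#' all their direct interactors, and all retained interactions among
#' included nodes become edges (weight = combined score); `seeds_only`
#' restricts nodes to the seeds. Seeds without retained edges are kept as
#' isolated nodes and reported.
#'
#' @param seeds character vector of seed ids, or a `deg_table` (its
#'   `gene_id` column is used).
#' @param interactions an `interaction_table` from [readInteractions()] or
#'   [simulateInteractome()].
#' @param score_min combined-score threshold, 0-999 (default 700, strict
#'   `>`).
#' @param expansion `"first_shell"` (default) or `"seeds_only"`.
#' @param evidence_channels optional channel column names (e.g.
#'   `"experiments"`, `"database"`); at least one must be positive.
#' @param alias_map optional named character vector translating seed ids to
#'   interactome protein ids (default: identity).
#' @return A [WeightedNetwork-class] object.
#' @export
buildNetwork <- function(seeds, interactions, score_min = 700,
                         expansion = c("first_shell", "seeds_only"),
                         evidence_channels = NULL, alias_map = NULL) {
  expansion <- match.arg(expansion)
  if (is.data.frame(seeds)) seeds <- seeds$gene_id
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("empty seed list")
  if (score_min < 0 || score_min > 999) stop("score_min must lie in 0-999")
  if (!is.null(alias_map)) {
    mapped <- ifelse(seeds %in% names(alias_map), alias_map[seeds], seeds)
    seeds <- unique(unname(mapped))
  }
  tab <- interactions
  if (nrow(tab)) {
    in_table <- seeds %in% c(tab$protein_a, tab$protein_b)
    if (!any(in_table))
      stop("none of the seeds occur in the interaction table: ",
           paste(utils::head(seeds, 10), collapse = ", "),
           if (length(seeds) > 10) ", ...")
    if (!all(in_table))
      .msg(sum(!in_table), " seed(s) absent from the interaction table ",
           "kept as isolated nodes: ",
           paste(utils::head(seeds[!in_table], 10), collapse = ", "))
  }
  keep <- tab$combined_score > score_min
  if (!is.null(evidence_channels)) {
    missing <- setdiff(evidence_channels, colnames(tab))
    if (length(missing))
      stop("evidence channel(s) not in table: ",
           paste(missing, collapse = ", "))
    ch <- as.matrix(tab[, evidence_channels, drop = FALSE])
    ch[is.na(ch)] <- 0
    keep <- keep & rowSums(ch > 0) > 0
  }
  tab <- tab[keep, , drop = FALSE]
  touches_seed <- tab$protein_a %in% seeds | tab$protein_b %in% seeds
  nodes <- if (expansion == "first_shell") {
    union(seeds, c(tab$protein_a[touches_seed], tab$protein_b[touches_seed]))
  } else seeds
  among <- tab$protein_a %in% nodes & tab$protein_b %in% nodes
  tab <- tab[among, , drop = FALSE]
  nodes <- sort(nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tab$protein_a, to = tab$protein_b,
               weight = as.numeric(tab$combined_score)),
    directed = FALSE,
    vertices = data.frame(name = nodes, is_seed = nodes %in% seeds))
  iso <- intersect(seeds, nodes[igraph::degree(g)[nodes] == 0])
  if (length(iso))
    .msg(length(iso), " isolated seed(s): ",
         paste(utils::head(iso, 10), collapse = ", "))
  new("WeightedNetwork", graph = g, seeds = sort(seeds),
      scoreMin = score_min, expansion = expansion,
      channels = as.character(evidence_channels %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identify hub nodes by degree
#'
#' Hubs are the top `fraction` of nodes by (unweighted) degree:
#' `k = ceiling(fraction * n)` nodes, ranked by degree descending with ties
#' broken by node id ascending.
#'
#' @param net a [WeightedNetwork-class] object (or an igraph graph).
#' @param fraction fraction of nodes retained (default 0.10).
#' @return A data.frame of class `hub_set` with columns `node_id`, `degree`,
#'   `is_seed`; attributes `cutoff_degree`, `fraction`, `k`.
#' @export
findHubs <- function(net, fraction = 0.10) {
  g <- if (is(net, "WeightedNetwork")) networkGraph(net) else net
  n <- igraph::vcount(g)
  if (n < 1) stop("empty network")
  deg <- igraph::degree(g)
  ids <- igraph::V(g)$name
  is_seed <- igraph::V(g)$is_seed %||% rep(NA, n)
  k <- ceiling(fraction * n)
  ord <- order(-deg, ids)
  top <- ord[seq_len(k)]
  out <- data.frame(node_id = ids[top], degree = as.integer(deg[top]),
                    is_seed = is_seed[top], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff_degree") <- min(out$degree)
  attr(out, "fraction") <- fraction
  attr(out, "k") <- k
  class(out) <- c("hub_set", "data.frame")
  out
}

# internal/boundary weight sums of a node set; idx is a logical membership
# vector over V(g).
.in_bound_weights <- function(g, member) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  a_in <- member[el[, 1]]; b_in <- member[el[, 2]]
  list(w_in = sum(w[a_in & b_in]), w_bound = sum(w[xor(a_in, b_in)]))
}

#' Cohesiveness of a node set
#'
#' `f(V) = w_in / (w_in + w_bound + penalty * |V|)` where `w_in` sums the
#' weights of edges with both ends in `V` and `w_bound` those with exactly
#' one end in `V`. Defined as 0 when the denominator is 0.
#'
#' @param net a [WeightedNetwork-class] object (or an igraph graph).
#' @param node_set character vector of node ids (non-empty, in the network).
#' @param penalty per-node penalty term (default 2) modelling unobserved
#'   interactions.
#' @return Numeric in \[0, 1\].
#' @export
cohesiveness <- function(net, node_set, penalty = 2) {
  g <- if (is(net, "WeightedNetwork")) networkGraph(net) else net
  ids <- igraph::V(g)$name
  if (!length(node_set)) stop("node_set must be non-empty")
  if (!all(node_set %in% ids)) stop("node_set contains unknown nodes")
  member <- ids %in% node_set
  wb <- .in_bound_weights(g, member)
  denom <- wb$w_in + wb$w_bound + penalty * length(unique(node_set))
  if (denom == 0) 0 else wb$w_in / denom
}

# Weighted adjacency lists (indices + parallel weights) built once per graph.
.adjacency_lists <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  ends <- c(el[, 1], el[, 2])
  other <- c(el[, 2], el[, 1])
  ww <- c(w, w)
  ord <- order(ends)
  nbr <- split(other[ord], factor(ends[ord], levels = seq_len(n)))
  wts <- split(ww[ord], factor(ends[ord], levels = seq_len(n)))
  list(nbr = nbr, wts = wts,
       w_tot = vapply(wts, sum, numeric(1)))
}

# Greedy local search from one seed node; returns the node index set at the
# cohesiveness local maximum, with incremental w_in/w_bound bookkeeping via
# per-node weight sums to the current set V.
.grow_one <- function(adjl, n, seed_idx, penalty) {
  nbr <- adjl$nbr; wts <- adjl$wts; w_tot <- adjl$w_tot
  member <- rep(FALSE, n)
  member[seed_idx] <- TRUE
  # s[v] = total weight from v to current members
  s <- rep(0, n)
  if (length(nbr[[seed_idx]]))
    s[nbr[[seed_idx]]] <- s[nbr[[seed_idx]]] + wts[[seed_idx]]
  w_in <- 0
  coh <- function(win, wbound, size) {
    den <- win + wbound + penalty * size
    if (den == 0) 0 else win / den
  }
  size <- 1L
  w_bound <- w_tot[seed_idx]
  cur <- coh(w_in, w_bound, size)
  repeat {
    boundary <- which(!member & s > 0)
    internal <- setdiff(which(member), seed_idx)
    best_gain <- 0; best_v <- NA_integer_; best_add <- NA
    for (v in boundary[order(boundary)]) {
      # adding v: w_in += s[v]; w_bound += w_tot[v] - 2 s[v]
      val <- coh(w_in + s[v], w_bound + w_tot[v] - 2 * s[v], size + 1L)
      if (val - cur > best_gain + 1e-12) {
        best_gain <- val - cur; best_v <- v; best_add <- TRUE
      }
    }
    for (v in internal[order(internal)]) {
      val <- coh(w_in - s[v], w_bound - w_tot[v] + 2 * s[v], size - 1L)
      if (val - cur > best_gain + 1e-12) {
        best_gain <- val - cur; best_v <- v; best_add <- FALSE
      }
    }
    if (is.na(best_v)) break
    v <- best_v
    if (best_add) {
      member[v] <- TRUE
      w_in <- w_in + s[v]
      w_bound <- w_bound + w_tot[v] - 2 * s[v]
      size <- size + 1L
      if (length(nbr[[v]])) s[nbr[[v]]] <- s[nbr[[v]]] + wts[[v]]
    } else {
      member[v] <- FALSE
      w_in <- w_in - s[v]
      w_bound <- w_bound - w_tot[v] + 2 * s[v]
      size <- size - 1L
      if (length(nbr[[v]])) s[nbr[[v]]] <- s[nbr[[v]]] - wts[[v]]
    }
    cur <- coh(w_in, w_bound, size)
  }
  which(member)
}

.cluster_row <- function(g, members_idx, penalty) {
  ids <- igraph::V(g)$name
  member <- seq_along(ids) %in% members_idx
  wb <- .in_bound_weights(g, member)
  size <- length(members_idx)
  sub <- igraph::induced_subgraph(g, members_idx)
  density <- if (size > 1)
    igraph::ecount(sub) / (size * (size - 1) / 2) else 0
  denom <- wb$w_in + wb$w_bound + penalty * size
  data.frame(members = I(list(sort(ids[members_idx]))), size = size,
             cohesiveness = if (denom == 0) 0 else wb$w_in / denom,
             w_in = wb$w_in, w_bound = wb$w_bound, density = density,
             stringsAsFactors = FALSE)
}

#' Grow overlapping cohesive clusters
#'
#' Greedy cohesiveness maximization: the highest-degree node not yet in any
#' cluster seeds a candidate set, which is grown by repeatedly applying the
#' single best move — adding a boundary vertex or removing an internal
#' non-seed vertex — until no move increases cohesiveness. Nodes already
#' used may be re-entered, so clusters can overlap. Growth continues until
#' every node is used; clusters smaller than `min_size` or with unweighted
#' edge density below `min_density` are discarded. Ties in the seed order
#' and in candidate moves are broken by node id, making the procedure
#' deterministic.
#'
#' @param net a [WeightedNetwork-class] object (or an igraph graph).
#' @param penalty cohesiveness penalty (default 2).
#' @param min_size minimum cluster size (default 3).
#' @param min_density minimum unweighted edge density (default 0.5).
#' @return A data.frame of class `cluster_set` with a list-column `members`
#'   and columns `size`, `cohesiveness`, `w_in`, `w_bound`, `density`.
#' @seealso [mergeOverlapping()], [clusterSignificance()]
#' @export
growClusters <- function(net, penalty = 2, min_size = 3, min_density = 0.5) {
  g <- if (is(net, "WeightedNetwork")) networkGraph(net) else net
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  seed_order <- order(-deg, ids)
  adjl <- .adjacency_lists(g)
  used <- rep(FALSE, n)
  rows <- list()
  for (seed_idx in seed_order) {
    if (used[seed_idx]) next
    members_idx <- .grow_one(adjl, n, seed_idx, penalty)
    used[members_idx] <- TRUE
    row <- .cluster_row(g, members_idx, penalty)
    if (row$size >= min_size && row$density >= min_density)
      rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(members = I(list()), size = integer(),
                  cohesiveness = numeric(), w_in = numeric(),
                  w_bound = numeric(), density = numeric())
  rownames(out) <- NULL
  out <- cbind(cluster_id = if (nrow(out))
    sprintf("C%03d", seq_len(nrow(out))) else character(), out)
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Merge highly overlapping clusters
#'
#' Computes the overlap score `omega(A, B) = |A & B|^2 / (|A| * |B|)` for
#' every cluster pair and transitively merges (unions) groups linked by
#' `omega > omega_threshold`, recomputing cohesiveness, weights and density
#' of the merged sets.
#'
#' @param clusters a `cluster_set` from [growClusters()].
#' @param net the network the clusters were grown on.
#' @param omega_threshold merge threshold (default 0.8, strict `>`).
#' @param penalty cohesiveness penalty used for recomputation (default 2).
#' @return A `cluster_set` data.frame of the merged clusters.
#' @export
mergeOverlapping <- function(clusters, net, omega_threshold = 0.8,
                             penalty = 2) {
  g <- if (is(net, "WeightedNetwork")) networkGraph(net) else net
  m <- nrow(clusters)
  if (m <= 1) return(clusters)
  mem <- clusters$members
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    ov <- length(intersect(mem[[i]], mem[[j]]))
    omega <- ov^2 / (length(mem[[i]]) * length(mem[[j]]))
    if (omega > omega_threshold) adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  ids <- igraph::V(g)$name
  rows <- lapply(split(seq_len(m), comp), function(grp) {
    nodes <- sort(unique(unlist(mem[grp])))
    .cluster_row(g, match(nodes, ids), penalty)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(cluster_id = sprintf("C%03d", seq_len(nrow(out))), out)
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Cluster significance by internal-vs-boundary weight comparison
#'
#' For each vertex of the cluster, its internal weight sum (edges to other
#' members) and boundary weight sum (edges to non-members) are computed; a
#' one-sided Mann-Whitney U test (alternative: internal > boundary) compares
#' the two samples. The exact U distribution is used for group sizes up to
#' 20 (ties resolved by midranks), the normal approximation with tie and
#' continuity correction otherwise; when every pooled value is tied there is
#' no evidence either way and p = 1. Clusters of size < 2 get p = 1 with a
#' warning.
#'
#' @param net a [WeightedNetwork-class] object (or an igraph graph).
#' @param members character vector of cluster member node ids.
#' @return The one-sided p value.
#' @export
clusterSignificance <- function(net, members) {
  g <- if (is(net, "WeightedNetwork")) networkGraph(net) else net
  ids <- igraph::V(g)$name
  members <- unique(members)
  if (!all(members %in% ids)) stop("cluster contains unknown nodes")
  if (length(members) < 2) {
    warning("cluster of size < 2: p = 1")
    return(1)
  }
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  internal <- boundary <- stats::setNames(rep(0, length(members)), members)
  for (e in seq_len(nrow(el))) {
    a <- el[e, 1]; b <- el[e, 2]
    a_in <- a %in% members; b_in <- b %in% members
    if (a_in && b_in) {
      internal[a] <- internal[a] + w[e]
      internal[b] <- internal[b] + w[e]
    } else if (a_in) {
      boundary[a] <- boundary[a] + w[e]
    } else if (b_in) {
      boundary[b] <- boundary[b] + w[e]
    }
  }
  .mann_whitney_greater(internal, boundary)
}

# One-sided Mann-Whitney p value P(U >= u_obs), alternative x > y. Exact U
# distribution for group sizes <= 20 (midranks under ties), otherwise normal
# approximation with tie and continuity correction.
.mann_whitney_greater <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n <= 20 && m <= 20)
    return(stats::pwilcox(ceiling(u - 1e-9) - 1, n, m, lower.tail = FALSE))
  N <- n + m
  t <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((u - n * m / 2 - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' Score a cluster set: significance flags
#'
#' Convenience wrapper adding `p_value` and `significant` (p < alpha)
#' columns to a `cluster_set` via [clusterSignificance()].
#'
#' @param clusters a `cluster_set` data.frame.
#' @param net the network the clusters belong to.
#' @param alpha significance level (default 0.05, strict `<`).
#' @return The cluster table with `p_value` and `significant` columns.
#' @export
scoreClusters <- function(clusters, net, alpha = 0.05) {
  if (!nrow(clusters)) {
    clusters$p_value <- numeric()
    clusters$significant <- logical()
    return(clusters)
  }
  clusters$p_value <- vapply(clusters$members,
                             function(m) clusterSignificance(net, m),
                             numeric(1))
  clusters$significant <- clusters$p_value < alpha
  clusters
}
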