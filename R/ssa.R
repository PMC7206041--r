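# Single-subject analysis: one untreated/treated pair is normalized, per-gene
# signed and absolute log2 fold changes are computed, a two-component
# Gaussian mixture over |log2FC| separates unaltered from dysregulated genes,
# and the dysregulated ones are split into up/down by the sign of the fold
# change. No replicates are required.

#' Normalize one untreated/treated sample pair
#'
#' Selects exactly one untreated and one treated column from a
#' [PairedCounts-class] object and applies between-sample normalization.
#' The default `upper_quartile` method divides each sample by the 75th
#' percentile of its nonzero counts and rescales by the mean of the two
#' factors so values stay on a count-like scale; `total_count` uses library
#' size as factor; `none` returns raw counts.
#'
#' @param x a [PairedCounts-class] object.
#' @param method `"upper_quartile"` (default), `"total_count"` or `"none"`.
#' @param untreated,treated optional sample (column) names; required when the
#'   object holds more than one sample per condition.
#' @return A data.frame of class `normalized_pair` with columns `gene_id`,
#'   `u_norm`, `t_norm`; attributes `method` and `scale_factors`.
#' @export
normalizePair <- function(x, method = c("upper_quartile", "total_count", "none"),
                          untreated = NULL, treated = NULL) {
  stopifnot(is(x, "PairedCounts"))
  method <- match.arg(method)
  cond <- conditionOf(x)
  pick <- function(label, given) {
    if (!is.null(given)) {
      if (!given %in% names(cond) || cond[[given]] != label)
        stop("sample '", given, "' is not a ", label, " sample")
      return(given)
    }
    hit <- names(cond)[cond == label]
    if (length(hit) != 1)
      stop("need exactly one ", label, " sample (found ", length(hit),
           "); select one explicitly")
    hit
  }
  us <- pick("untreated", untreated)
  ts <- pick("treated", treated)
  m <- SummarizedExperiment::assay(x, "counts")
  u <- as.numeric(m[, us]); t <- as.numeric(m[, ts])
  factor_of <- function(v) {
    switch(method,
           upper_quartile = {
             nz <- v[v > 0]
             if (!length(nz)) stop("all-zero sample: cannot normalize")
             stats::quantile(nz, 0.75, names = FALSE)
           },
           total_count = {
             s <- sum(v)
             if (s == 0) stop("all-zero sample: cannot normalize")
             s
           },
           none = 1)
  }
  f <- c(untreated = factor_of(u), treated = factor_of(t))
  scale_to <- if (method == "none") 1 else mean(f)
  out <- data.frame(gene_id = rownames(m),
                    u_norm = u / f[["untreated"]] * scale_to,
                    t_norm = t / f[["treated"]] * scale_to,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "scale_factors") <- f
  class(out) <- c("normalized_pair", "data.frame")
  out
}

#' Compute signed and absolute log2 fold changes
#'
#' `lfc_signed = log2((t_norm + pseudocount) / (u_norm + pseudocount))`, so a
#' positive value means higher expression under treatment; `lfc_abs` is its
#' absolute value (identical under either orientation of the ratio). The
#' pseudocount keeps genes with zeros finite.
#'
#' @param pair a `normalized_pair` data.frame from [normalizePair()].
#' @param pseudocount positive offset added to both conditions (default 0.5).
#' @return A data.frame of class `fold_change_profile` with columns
#'   `gene_id`, `lfc_signed`, `lfc_abs`; attribute `pseudocount`.
#' @export
computeFoldChanges <- function(pair, pseudocount = 0.5) {
  stopifnot(all(c("gene_id", "u_norm", "t_norm") %in% colnames(pair)))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  lfc <- log2((pair$t_norm + pseudocount) / (pair$u_norm + pseudocount))
  out <- data.frame(gene_id = pair$gene_id, lfc_signed = lfc,
                    lfc_abs = abs(lfc), stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("fold_change_profile", "data.frame")
  out
}

# One EM pass helper: log-sum-exp responsibilities for K Gaussians.
.mix_estep <- function(x, w, mu, sd) {
  logd <- vapply(seq_along(w),
                 function(k) log(w[k]) + stats::dnorm(x, mu[k], sd[k], log = TRUE),
                 numeric(length(x)))
  mx <- apply(logd, 1, max)
  lse <- mx + log(rowSums(exp(logd - mx)))
  list(resp = exp(logd - lse), loglik = sum(lse))
}

#' Fit the dysregulation mixture over |log2FC|
#'
#' Fits a two-component Gaussian mixture to the absolute log2 fold changes by
#' expectation-maximization: one component captures the unaltered bulk near
#' zero, the other the dysregulated tail. Means are initialized at the 50th
#' and 95th percentiles; EM stops when the log-likelihood gain drops below
#' `tol` or after `max_iter` iterations. The component with the larger mean
#' is the dysregulated one. A collapsed fit (component sd below 1e-6, weight
#' below 1e-4, or fewer than K distinct values) falls back, with a warning,
#' to a degenerate all-unaltered call (posteriors 0).
#'
#' @param profile a `fold_change_profile` data.frame (or a bare numeric
#'   vector of absolute log2 fold changes).
#' @param K number of components (default 2).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param seed kept for interface symmetry; the percentile initialization
#'   makes the fit deterministic regardless.
#' @return A [MixtureFit-class] object; posteriors are named by gene when the
#'   input carries gene ids.
#' @export
fitDysregulationMixture <- function(profile, K = 2L, tol = 1e-8,
                                    max_iter = 1000L, seed = NULL) {
  if (is.data.frame(profile)) {
    x <- profile$lfc_abs
    names(x) <- profile$gene_id
  } else {
    x <- as.numeric(profile)
    names(x) <- names(profile)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("lfc_abs must be finite")
  n <- length(x)
  degenerate_fit <- function() {
    warning("degenerate mixture fit: calling all genes unaltered")
    new("MixtureFit", weights = numeric(), means = numeric(), sds = numeric(),
        posterior = stats::setNames(rep(0, n), names(x)),
        loglik = numeric(), converged = FALSE, degenerate = TRUE,
        iterations = 0L)
  }
  if (length(unique(x)) < K) return(degenerate_fit())

  mu <- as.numeric(stats::quantile(x, c(0.5, 0.95), names = FALSE))
  if (K != 2L) mu <- as.numeric(stats::quantile(x, seq(0.5, 0.95, length.out = K)))
  if (any(diff(mu) <= 0)) mu <- mu + seq(0, 1e-6, length.out = K)
  # moment start: assign to nearest mean
  assign0 <- apply(abs(outer(x, mu, "-")), 1, which.min)
  w <- tabulate(assign0, K) / n
  w <- pmax(w, 1e-3); w <- w / sum(w)
  s0 <- stats::sd(x)
  sd <- vapply(seq_len(K), function(k) {
    v <- x[assign0 == k]
    if (length(v) > 1 && stats::sd(v) > 1e-6) stats::sd(v) else s0 / K
  }, numeric(1))
  sd <- pmax(sd, 1e-4)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- .mix_estep(x, w, mu, sd)
    loglik <- c(loglik, e$loglik)
    nk <- colSums(e$resp)
    if (any(nk / n < 1e-4)) return(degenerate_fit())
    w <- nk / n
    mu <- colSums(e$resp * x) / nk
    sd <- sqrt(colSums(e$resp * (outer(x, mu, "-")^2)) / nk)
    if (any(sd < 1e-6)) return(degenerate_fit())
    if (iter > 1 && loglik[iter] - loglik[iter - 1] < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  ord <- order(mu)
  w <- w[ord]; mu <- mu[ord]; sd <- sd[ord]
  e <- .mix_estep(x, w, mu, sd)
  post <- pmin(pmax(e$resp[, K], 0), 1)
  new("MixtureFit", weights = w, means = mu, sds = sd,
      posterior = stats::setNames(post, names(x)),
      loglik = loglik, converged = converged, degenerate = FALSE,
      iterations = iter)
}

#' Classify genes as up / down / unaltered
#'
#' A gene is called dysregulated when its posterior probability of the
#' dysregulated mixture component exceeds `threshold`; dysregulated genes
#' are split by the sign of the signed log2 fold change (positive = up,
#' i.e. higher under treatment). A gene with `lfc_signed == 0` stays
#' unaltered whatever its posterior. Degenerate fits yield all-unaltered.
#'
#' @param fit a [MixtureFit-class] from [fitDysregulationMixture()].
#' @param profile the matching `fold_change_profile` data.frame.
#' @param threshold posterior classification cutoff (default 0.5).
#' @return A data.frame of class `gene_class_table` with columns `gene_id`,
#'   `class` (factor up/down/unaltered), `posterior_dysregulated`,
#'   `lfc_signed`, `lfc_abs`.
#' @export
classifyGenes <- function(fit, profile, threshold = 0.5) {
  stopifnot(is(fit, "MixtureFit"),
            all(c("gene_id", "lfc_signed", "lfc_abs") %in% colnames(profile)))
  post <- dysregulationPosterior(fit)
  if (length(post) != nrow(profile))
    stop("fit and profile cover different gene universes")
  dys <- !isDegenerate(fit) & post > threshold & profile$lfc_signed != 0
  cls <- ifelse(!dys, "unaltered",
                ifelse(profile$lfc_signed > 0, "up", "down"))
  out <- data.frame(gene_id = profile$gene_id,
                    class = factor(cls, levels = c("up", "down", "unaltered")),
                    posterior_dysregulated = unname(post),
                    lfc_signed = profile$lfc_signed,
                    lfc_abs = profile$lfc_abs,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_class_table", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Two sources are supported. An external DEG table (columns `gene_id`,
#' `log2fc`, `p_adj`, e.g. a cohort analysis export) is filtered by
#' `|log2fc| > lfc_threshold` and `p_adj < p_adj_threshold` (defaults 1 and
#' 0.05). A single-subject `gene_class_table` keeps genes called up or down
#' whose `lfc_abs` exceeds `lfc_threshold`; these carry no adjusted p value
#' (`p_adj = NA`).
#'
#' @param x a `deg_table` or `gene_class_table` data.frame.
#' @param lfc_threshold absolute log2-fold-change cutoff (strict, default 1).
#' @param p_adj_threshold adjusted-p cutoff (strict, default 0.05; only used
#'   for DEG-table sources).
#' @return A `deg_table` data.frame of the selected genes.
#' @export
selectDegs <- function(x, lfc_threshold = 1, p_adj_threshold = 0.05) {
  if (all(c("gene_id", "log2fc", "p_adj") %in% colnames(x))) {
    keep <- abs(x$log2fc) > lfc_threshold & x$p_adj < p_adj_threshold
    keep[is.na(keep)] <- FALSE
    out <- data.frame(gene_id = x$gene_id[keep], log2fc = x$log2fc[keep],
                      p_adj = x$p_adj[keep], stringsAsFactors = FALSE)
  } else if (all(c("gene_id", "class", "lfc_abs") %in% colnames(x))) {
    keep <- x$class %in% c("up", "down") & x$lfc_abs > lfc_threshold
    out <- data.frame(gene_id = x$gene_id[keep], log2fc = x$lfc_signed[keep],
                      p_adj = NA_real_, stringsAsFactors = FALSE)
  } else {
    stop("x must be a deg_table or a gene_class_table")
  }
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}
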