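# Small in-code fixtures and independent oracles shared across test files.

# interaction table literal
itab <- function(a, b, score, ...) {
  df <- data.frame(protein_a = a, protein_b = b,
                   combined_score = as.integer(score),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("interaction_table", "data.frame")
  df
}

# WeightedNetwork over every node of an interaction table, optionally with
# all edge weights forced to 1 (for unit-weight toy graphs)
net_from_itab <- function(tab, unit_weights = FALSE, score_min = 0) {
  if (unit_weights) tab$combined_score <- 1L
  buildNetwork(unique(c(tab$protein_a, tab$protein_b)), tab,
               score_min = score_min)
}

# Brute-force right tail P(X >= a), X ~ Hypergeom(N, K, n), by binomial
# coefficients only (independent of phyper).
hyper_tail_oracle <- function(a, K, N, n) {
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  x <- seq(max(a, lo), hi)
  if (!length(x) || a > hi) return(if (a <= lo) 1 else 0)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Direct Benjamini-Yekutieli step-up, written from the definition.
by_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj_sorted <- rev(cummin(rev(m * cm * p[o] / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(1, adj_sorted)
  out
}

# classification F1 for the dysregulated class
f1_score <- function(pred_dys, true_dys) {
  tp <- sum(pred_dys & true_dys)
  fp <- sum(pred_dys & !true_dys)
  fn <- sum(!pred_dys & true_dys)
  2 * tp / (2 * tp + fp + fn)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
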