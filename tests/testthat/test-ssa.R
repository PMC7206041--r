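make_pc <- function(u, t, genes = sprintf("g%02d", seq_along(u))) {
  m <- cbind(U = as.integer(u), T = as.integer(t))
  rownames(m) <- genes
  PairedCounts(m, condition = c(U = "untreated", T = "treated"))
}

test_that("normalization is symmetric, scale-invariant and selectable", {
  u <- c(10, 0, 5, 100, 40)
  pc <- make_pc(u, u)
  p <- normalizePair(pc)
  expect_equal(p$u_norm, p$t_norm)

  # treated = 2 x untreated exactly: upper-quartile equalizes the columns
  pc2 <- make_pc(u, 2 * u)
  p2 <- normalizePair(pc2)
  expect_equal(p2$u_norm, p2$t_norm)

  p3 <- normalizePair(pc2, method = "none")
  expect_equal(p3$u_norm, u)
  expect_equal(p3$t_norm, 2 * u)

  p4 <- normalizePair(pc2, method = "total_count")
  expect_equal(p4$u_norm, p4$t_norm)

  expect_error(normalizePair(make_pc(c(0, 0), c(1, 2))), "all-zero")
})

test_that("fold changes follow the signed log2(T/U) convention", {
  pc <- make_pc(c(100, 100, 400), c(100, 400, 100))
  pair <- normalizePair(pc, method = "none")
  fc <- computeFoldChanges(pair, pseudocount = 1e-9)
  expect_equal(fc$lfc_signed[1], 0, tolerance = 1e-6)
  expect_equal(fc$lfc_signed[2], 2, tolerance = 1e-6)
  expect_equal(fc$lfc_abs[3], fc$lfc_abs[2], tolerance = 1e-6)  # sign symmetry
  expect_equal(fc$lfc_abs, abs(fc$lfc_signed))
  expect_error(computeFoldChanges(pair, pseudocount = 0), "> 0")
})

test_that("EM mixture recovers generating parameters and stays monotone", {
  set.seed(123)
  x <- c(abs(rnorm(4500, 0, 0.2)), abs(rnorm(500, 2.5, 0.4)))
  fit <- fitDysregulationMixture(x)
  comp <- mixtureComponents(fit)
  expect_false(isDegenerate(fit))
  expect_true(fit@converged)
  expect_lt(abs(comp$weight[2] - 0.1), 0.03)
  expect_lt(abs(comp$mean[2] - 2.5), 0.2)
  # log-likelihood trace is non-decreasing
  expect_true(all(diff(fit@loglik) >= -1e-8))
  # posteriors of the two components sum to 1 by construction (bounded in [0,1])
  post <- dysregulationPosterior(fit)
  expect_true(all(post >= 0 & post <= 1))
  # deterministic
  fit2 <- fitDysregulationMixture(x)
  expect_equal(comp, mixtureComponents(fit2))
})

test_that("EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(99)
  x <- c(abs(rnorm(2000, 0, 0.25)), abs(rnorm(300, 2, 0.5)))
  fit <- fitDysregulationMixture(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(mixtureComponents(fit)$mean),
               sort(unname(mc$parameters$mean)), tolerance = 0.05)
  expect_equal(sort(mixtureComponents(fit)$weight),
               sort(unname(mc$parameters$pro)), tolerance = 0.02)
})

test_that("degenerate inputs fall back to an all-unaltered call", {
  expect_warning(fit <- fitDysregulationMixture(rep(0.3, 200)), "degenerate")
  expect_true(isDegenerate(fit))
  expect_true(all(dysregulationPosterior(fit) == 0))
  prof <- data.frame(gene_id = paste0("g", 1:200),
                     lfc_signed = rep(0.3, 200), lfc_abs = rep(0.3, 200))
  cls <- classifyGenes(fit, prof)
  expect_true(all(cls$class == "unaltered"))
})

test_that("classification splits by sign, respects the zero tie rule and recovers truth", {
  set.seed(2024)
  n <- 2000
  true_dys <- rep(c(FALSE, TRUE), c(1800, 200))
  lfc_abs <- c(abs(rnorm(1800, 0, 0.2)), abs(rnorm(200, 2.5, 0.4)))
  sign <- sample(c(-1, 1), n, replace = TRUE)
  prof <- data.frame(gene_id = sprintf("g%04d", 1:n),
                     lfc_signed = sign * lfc_abs, lfc_abs = lfc_abs)
  fit <- fitDysregulationMixture(prof)
  cls <- classifyGenes(fit, prof)
  # classes partition the universe
  expect_equal(sum(table(cls$class)), n)
  # up/down match the sign of the fold change
  expect_true(all(cls$lfc_signed[cls$class == "up"] > 0))
  expect_true(all(cls$lfc_signed[cls$class == "down"] < 0))
  expect_gte(f1_score(cls$class != "unaltered", true_dys), 0.9)

  # lfc == 0 stays unaltered even at posterior 1
  prof0 <- data.frame(gene_id = c("a", "b"), lfc_signed = c(0, 3),
                      lfc_abs = c(0, 3))
  fit0 <- new("MixtureFit", weights = c(0.5, 0.5), means = c(0, 3),
              sds = c(1, 1), posterior = c(a = 0.99, b = 0.99),
              loglik = 0, converged = TRUE, degenerate = FALSE,
              iterations = 1L)
  cls0 <- classifyGenes(fit0, prof0)
  expect_equal(as.character(cls0$class), c("unaltered", "up"))
})

test_that("DEG selection applies both thresholds and matches a brute-force filter", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2fc = c(1.5, -1.5, 0.5),
                    p_adj = c(0.01, 0.2, 0.01))
  expect_equal(selectDegs(tab)$gene_id, "g1")
  # permissive thresholds keep everything
  expect_equal(nrow(selectDegs(tab, lfc_threshold = 0, p_adj_threshold = 1)), 3)

  set.seed(7)
  big <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                    log2fc = rnorm(1000, 0, 2),
                    p_adj = runif(1000))
  got <- selectDegs(big)$gene_id
  want <- big$gene_id[abs(big$log2fc) > 1 & big$p_adj < 0.05]
  expect_identical(got, want)

  # SSA source: up/down calls filtered by |lfc|
  cls <- data.frame(gene_id = c("a", "b", "c"),
                    class = factor(c("up", "down", "unaltered"),
                                   levels = c("up", "down", "unaltered")),
                    posterior_dysregulated = c(0.9, 0.9, 0.1),
                    lfc_signed = c(2, -0.5, 3), lfc_abs = c(2, 0.5, 3))
  expect_equal(selectDegs(cls)$gene_id, "a")
})
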