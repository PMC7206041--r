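make_classes <- function(universe, up = character(), down = character()) {
  cls <- ifelse(universe %in% up, "up",
                ifelse(universe %in% down, "down", "unaltered"))
  data.frame(gene_id = universe,
             class = factor(cls, levels = c("up", "down", "unaltered")),
             posterior_dysregulated = as.numeric(cls != "unaltered"),
             lfc_signed = ifelse(cls == "up", 2, ifelse(cls == "down", -2, 0)),
             lfc_abs = ifelse(cls == "unaltered", 0, 2))
}

test_that("pathway FET matches the hand-enumerated hypergeometric example", {
  universe <- sprintf("g%02d", 1:20)
  dys <- universe[1:5]
  set5 <- c(universe[1:4], universe[6])   # 4 dysregulated of 5 members
  cls <- make_classes(universe, up = dys[1:3], down = dys[4:5])
  gs <- GeneSets(list(S = set5))
  res <- pathwayFet(cls, gs)
  expect_equal(res$a, 4)
  expect_equal(res$b, 1)
  expect_equal(res$a + res$b, 5)                 # a+b = |set in universe|
  expect_equal(res$a + res$c, 5)                 # a+c = total dysregulated
  expect_equal(res$p_raw, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$n_up, 3)
  expect_equal(res$n_down, 1)

  # zero dysregulated members: right tail at 0 is 1
  gs2 <- GeneSets(list(S = universe[6:11]))
  res2 <- pathwayFet(cls, gs2)
  expect_equal(res2$p_raw, 1)

  # everything dysregulated: p = 1 for every set
  cls_all <- make_classes(universe, up = universe)
  res3 <- pathwayFet(cls_all, GeneSets(list(A = universe[1:6],
                                            B = universe[7:13])))
  expect_equal(res3$p_raw, c(1, 1))

  # no dysregulation at all: p = 1 with a warning
  cls_none <- make_classes(universe)
  expect_warning(res4 <- pathwayFet(cls_none, gs), "no dysregulated")
  expect_equal(res4$p_raw, 1)

  # sets below min_set_size are skipped
  res5 <- pathwayFet(cls, GeneSets(list(tiny = universe[1:3], S = set5)))
  expect_equal(res5$set_id, "S")
})

test_that("odds ratio follows the ad/bc sample-estimate conventions", {
  universe <- sprintf("g%02d", 1:20)
  cls <- make_classes(universe, up = universe[1:5])
  # b = 0 -> +Inf
  r <- pathwayFet(cls, GeneSets(list(S = universe[1:5])))
  expect_equal(r$odds_ratio, Inf)
  # a = 0 with bc > 0 -> 0
  r2 <- pathwayFet(cls, GeneSets(list(S = universe[6:10])))
  expect_equal(r2$odds_ratio, 0)
})

test_that("BY adjustment matches the worked step-up example and dominates BH", {
  expect_equal(adjustBY(0.02), 0.02)   # single test: c(1) = 1
  expect_equal(adjustBY(c(0.01, 0.02, 0.03, 0.04)), rep(1 / 12, 4),
               tolerance = 1e-12)
  expect_error(adjustBY(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  p <- runif(200)^2
  by <- adjustBY(p)
  bh <- p.adjust(p, "BH")
  expect_true(all(by >= bh - 1e-12))
  expect_true(all(bh >= p - 1e-12))
  # permutation equivariance
  perm <- sample(200)
  expect_equal(adjustBY(p[perm]), by[perm])
  # ranking of adjusted values respects ranking of raw values
  expect_true(all(diff(by[order(p)]) >= -1e-12))
})

test_that("functional enrichment shares the exact-test core and flags terms", {
  universe <- sprintf("g%03d", 1:100)
  gs <- GeneSets(list(T1 = universe[1:10], T2 = universe[11:40]),
                 universe = universe)
  # a full term as query attains the minimal p among same-size terms
  rep1 <- enrichGeneSet(universe[1:10], gs)
  expect_equal(rep1$overlap[rep1$term_id == "T1"], 10)
  expect_equal(rep1$p_raw[rep1$term_id == "T1"],
               hyper_tail_oracle(10, 10, 100, 10), tolerance = 1e-12)
  expect_true(rep1$significant[rep1$term_id == "T1"])

  # disjoint query: overlap 0 is the floor of the support, p = 1
  expect_equal(rep1$p_raw[rep1$term_id == "T2"],
               hyper_tail_oracle(0, 30, 100, 10))

  # query = universe: every term has overlap = term size and p = 1
  repU <- enrichGeneSet(universe, gs)
  expect_equal(repU$overlap, c(10, 30))
  expect_equal(repU$p_raw, c(1, 1))

  # ids outside the universe are dropped with a warning; empty query errors
  expect_warning(enrichGeneSet(c(universe[1:5], "nope"), gs), "outside")
  expect_error(enrichGeneSet(character(), gs), "empty")

  # invariant to query ordering
  q <- universe[c(3, 1, 7, 20, 15)]
  expect_equal(enrichGeneSet(q, gs)$p_raw,
               enrichGeneSet(rev(q), gs)$p_raw)

  # identical 2x2 tables give identical p in both public entry points
  cls <- make_classes(universe, up = universe[1:5], down = universe[6:10])
  fet <- pathwayFet(cls, gs, min_set_size = 1)
  hyp <- enrichGeneSet(universe[1:10], gs, universe = universe)
  expect_equal(fet$p_raw, hyp$p_raw, tolerance = 1e-12)

  # corrected flags use the corrected p
  repBY <- enrichGeneSet(universe[1:10], gs, correction = "BY")
  expect_equal(repBY$p_adj, adjustBY(repBY$p_raw))
})
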