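make_meta <- function(ids, system, cell_line = "CL", group = NA) {
  data.frame(sample_id = ids, cell_line = cell_line, model_system = system,
             group = group, stringsAsFactors = FALSE)
}

test_that("one-way F matches the hand-computed ANOVA", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: MSB = 3, MSW = 1, F = 3 (df 2, 6)
  x <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:9)))
  meta <- make_meta(colnames(x), rep(c("monolayer2D", "spheroid",
                                       "xenograft"), each = 3))
  res <- anova_filter(expression_matrix(x, "gene"), meta,
                      baseline = "monolayer2D", fdr = 1, lfc = 0.1)
  expect_equal(res$F, 3)
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))
  # log2FC columns are differences of group means vs baseline
  expect_equal(res$lfc_spheroid, 1)
  expect_equal(res$lfc_xenograft, 2)
  # cross-check against aov on the same data
  a <- summary(aov(as.vector(x) ~ meta$model_system))[[1]]
  expect_equal(res$F, a[["F value"]][1])
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("filter joins FDR and fold-change cuts and shrinks monotonically", {
  sim <- simulate_model_systems(replicates = 3, sigma = 0.3, seed = 8)
  f15 <- anova_filter(sim$matrix, sim$meta, baseline = "monolayer2D",
                      fdr = 0.01, lfc = 1.5)
  f20 <- anova_filter(sim$matrix, sim$meta, baseline = "monolayer2D",
                      fdr = 0.01, lfc = 2)
  expect_true(all(attr(f20, "passing") %in% attr(f15, "passing")))
  expect_lt(sum(f20$pass), sum(f15$pass))
  # q-values are monotone in p
  ord <- order(f15$p)
  expect_true(all(diff(f15$q[ord]) >= -1e-15))
  # "all" rule is at least as strict as "any"
  fall <- anova_filter(sim$matrix, sim$meta, baseline = "monolayer2D",
                       fdr = 0.01, lfc = 1.5, lfc_rule = "all")
  expect_true(all(attr(fall, "passing") %in% attr(f15, "passing")))
})

test_that("filter validates groups and excludes constant features", {
  x <- matrix(c(1, 1, 1, 1, 5, 5, 6, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("const", "var"), sprintf("s%d", 1:4)))
  meta <- make_meta(colnames(x), rep(c("monolayer2D", "spheroid"), each = 2))
  expect_warning(res <- anova_filter(expression_matrix(x, "gene"), meta,
                                     baseline = "monolayer2D",
                                     fdr = 1, lfc = 0),
                 "constant")
  expect_true(is.na(res$F[1]))
  expect_false(res$pass[1])
  meta_bad <- make_meta(colnames(x), c("monolayer2D", "spheroid",
                                       "spheroid", "spheroid"))
  expect_error(anova_filter(expression_matrix(x, "gene"), meta_bad,
                            baseline = "monolayer2D"), "fewer than 2")
})

test_that("pattern rules classify the canonical trajectories", {
  mu <- rbind(inc  = c(1.0, 2.0, 3.1),
              incp = c(1.0, 2.0, 2.1),
              dec  = c(3.0, 2.0, 0.9),
              decp = c(3.0, 2.0, 1.9),
              flat = c(2.0, 2.0, 2.0))
  colnames(mu) <- c("monolayer2D", "spheroid", "xenograft")
  m <- expression_matrix(mu, "gene")
  meta <- make_meta(colnames(mu), colnames(mu))
  pc <- pattern_classify(m, meta, delta = 0.25)
  expect_identical(pc$category,
                   c("increasing", "increase_then_plateau", "decreasing",
                     "decrease_then_plateau", "none"))
  expect_equal(attr(pc, "characteristic_fraction"), 4 / 5)
  expect_error(pattern_classify(m, make_meta(colnames(mu),
                                             rep("spheroid", 3))),
               "monolayer2D")
})

test_that("planted 152-gene fixture recovers the category composition", {
  sim <- simulate_model_systems(sigma = 0, seed = 15)
  pc <- pattern_classify(sim$matrix, sim$meta, delta = 0.25)
  tab <- table(pc$category)
  expect_equal(tab[["increasing"]], 64)
  expect_equal(tab[["decreasing"]], 25)
  expect_equal(tab[["increase_then_plateau"]], 3)
  expect_equal(tab[["decrease_then_plateau"]], 18)
  expect_equal(tab[["none"]], 42)
  expect_identical(unname(pc$category == "none"),
                   unname(sim$categories[pc$gene] == "none"))
  expect_equal(attr(pc, "characteristic_fraction"), 110 / 152)
  # delta = 0 on noise-free monotone data classifies every gene correctly
  pc0 <- pattern_classify(sim$matrix, sim$meta, delta = 0)
  planted <- sim$categories[pc0$gene]
  monotone <- planted %in% c("increasing", "decreasing")
  expect_identical(pc0$category[monotone], unname(planted[monotone]))
})

test_that("Pearson similarity reproduces hand correlations and verdicts", {
  ids <- c("m", "s", "x")
  prof <- cbind(m = c(1, 2, 3), s = c(1, 2, 3), x = c(2, 4, 6))
  rownames(prof) <- paste0("g", 1:3)
  meta <- make_meta(ids, c("monolayer2D", "spheroid", "xenograft"))
  colnames(prof) <- ids
  res <- model_similarity(expression_matrix(prof, "gene"), meta)
  expect_equal(res$r_spheroid_xeno, 1)
  expect_equal(res$r_2D_xeno, 1)

  prof2 <- cbind(m = c(1, 3, 2), s = c(1, 2, 3), x = c(1, 2, 3))
  colnames(prof2) <- ids
  rownames(prof2) <- paste0("g", 1:3)
  res2 <- model_similarity(expression_matrix(prof2, "gene"), meta)
  expect_equal(res2$r_spheroid_xeno, 1)
  expect_equal(res2$r_2D_xeno, 0.5)   # cor((1,3,2),(1,2,3)) = 0.5
  expect_identical(res2$closer, "spheroid")

  prof3 <- cbind(m = c(3, 2, 1), s = c(1, 2, 3), x = c(1, 2, 3))
  colnames(prof3) <- ids
  rownames(prof3) <- paste0("g", 1:3)
  res3 <- model_similarity(expression_matrix(prof3, "gene"), meta)
  expect_equal(res3$r_2D_xeno, -1)
})

test_that("planted structure makes spheroids closer to xenografts", {
  sim <- simulate_model_systems(replicates = 2, sigma = 0.3, seed = 44)
  res <- model_similarity(sim$matrix, sim$meta)
  expect_identical(unique(res$closer), "spheroid")
  expect_true(all(res$r_spheroid_xeno > res$r_2D_xeno))
})

test_that("average-linkage clustering merges the hand-worked example", {
  x <- matrix(c(0, 1, 10, 11), nrow = 1,
              dimnames = list("g", c("a", "b", "c", "d")))
  # need >= 2 genes for a sample profile; duplicate the coordinate
  x <- rbind(g1 = x[1, ], g2 = x[1, ] * 1.0)
  colnames(x) <- c("a", "b", "c", "d")
  cl <- hierarchical_cluster(expression_matrix(x, "gene"),
                             distance = "euclidean", cluster_genes = FALSE)
  hc <- cl$sample_hclust
  # first merges join (a,b) and (c,d); final height = mean inter-pair dist
  h <- hc$height
  expect_equal(h[1], sqrt(2) * 1)
  expect_equal(h[2], sqrt(2) * 1)
  expect_equal(h[3], sqrt(2) * 10)
  expect_identical(hc$labels[hc$order], c("a", "b", "c", "d"))
  expect_match(cl$newick, "^\\(")

  # identical pair merges first, before a distant third sample
  y <- cbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  rownames(y) <- c("g1", "g2")
  cl2 <- hierarchical_cluster(expression_matrix(y, "gene"),
                              distance = "euclidean", cluster_genes = FALSE)
  expect_equal(cl2$sample_hclust$height[1], 0)
  first <- sort(cl2$sample_hclust$labels[cl2$sample_hclust$order[1:2]])
  expect_identical(first, c("a", "b"))
})

test_that("marker ranking reports linear folds and is antisymmetric", {
  sim <- simulate_two_group(marker_lfc = 8.64, sigma = 0.4, seed = 12)
  rk <- rank_two_group_markers(sim$matrix, sim$meta,
                               "resistant", "sensitive")
  expect_identical(rk$gene[1], "CAV1")
  expect_equal(rk$fold[1], 2^rk$log2fc[1])
  expect_gt(rk$fold[1], 200)  # planted ~400-fold marker dominates
  # antisymmetry under group exchange
  rk_rev <- rank_two_group_markers(sim$matrix, sim$meta,
                                   "sensitive", "resistant")
  merged <- merge(rk, rk_rev, by = "gene")
  expect_equal(merged$log2fc.x, -merged$log2fc.y)
  # all-equal matrix: zero folds, id tie-break ordering
  sub <- sim$meta[c(1, 2, 6, 7), ]
  m0 <- expression_matrix(matrix(5, 3, 4,
                                 dimnames = list(c("b", "a", "c"),
                                                 sub$sample_id)),
                          "gene")
  rk0 <- rank_two_group_markers(m0, sub, "resistant", "sensitive")
  expect_equal(rk0$log2fc, c(0, 0, 0))
  expect_identical(rk0$gene, c("a", "b", "c"))
})
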