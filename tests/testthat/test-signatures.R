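test_that("module score is near zero for bin-matched null sets", {
  set.seed(8)
  ln <- matrix(rnorm(200 * 60, 2, 0.5), 200, 60,
               dimnames = list(sprintf("g%03d", 1:200),
                               sprintf("c%03d", 1:60)))
  ln[ln < 0] <- 0
  ds <- manual_dataset(ln)
  set_genes <- sample(ds$genes, 10)
  means <- vapply(1:50, function(s)
    mean(module_score(ds, set_genes, module_params(seed = s))), numeric(1))
  expect_lt(abs(mean(means)), 0.02)
})

test_that("module score recovers a constructed +1 uplift", {
  set.seed(9)
  # background genes span a range of means so that the uplifted set's
  # expression bins still contain plenty of control genes
  mu <- runif(1000, 1.5, 3.5)
  ln <- matrix(rnorm(1000 * 80, rep(mu, 80), 0.3), 1000, 80,
               dimnames = list(sprintf("g%04d", 1:1000),
                               sprintf("c%03d", 1:80)))
  ln[ln < 0] <- 0
  set_genes <- sprintf("g%04d", sample(which(mu < 2.4), 10))
  # a small positive population scores ~ +1 while the background stays ~ 0;
  # with binned controls the background absorbs the set's query-wide shift,
  # so the uplifted fraction must stay small for the absolute levels to hold
  on <- 1:8
  ln[set_genes, on] <- ln[set_genes, on] + 1
  ds <- manual_dataset(ln)
  sc <- module_score(ds, set_genes, module_params(seed = 1))
  expect_lt(abs(mean(sc[on]) - 1), 0.25)
  expect_lt(abs(mean(sc[-on])), 0.15)
  # with half the cells uplifted the score CONTRAST is still ~ +1
  ln2 <- ln
  ln2[set_genes, 9:40] <- ln2[set_genes, 9:40] + 1
  sc2 <- module_score(manual_dataset(ln2), set_genes,
                      module_params(seed = 1))
  expect_lt(abs(mean(sc2[1:40]) - mean(sc2[41:80]) - 1), 0.1)
})

test_that("module score is deterministic given a seed and shift-invariant", {
  ds <- log_normalize(random_count_dataset(150, 40, seed = 10))
  genes <- sample(ds$genes, 8)
  s1 <- module_score(ds, genes, module_params(seed = 99))
  s2 <- module_score(ds, genes, module_params(seed = 99))
  expect_identical(s1, s2)
  # adding a cell-constant offset to every gene leaves the score unchanged
  shifted <- ds
  off <- runif(n_cells(ds))
  ln <- as.matrix(ds$lognorm)
  ln <- sweep(ln, 2, off, `+`)
  shifted <- manual_dataset(ln)
  s3 <- module_score(shifted, genes, module_params(seed = 99))
  expect_lt(max(abs(s3 - s1)), 1e-12)
  expect_error(module_score(ds, c("nope1", "nope2")), "no gene")
})

test_that("find_markers recovers a constructed marker and applies thresholds", {
  ln <- matrix(0.2, 30, 20, dimnames = list(sprintf("g%02d", 1:30),
                                            sprintf("c%02d", 1:20)))
  set.seed(4)
  ln <- ln + matrix(runif(600, 0, 0.1), 30)
  ln["g05", 1:10] <- 5
  ln["g20", ] <- 1    # constant-ish gene, no contrast
  ds <- manual_dataset(ln, meta = data.frame(
    cell_id = colnames(ln), stringsAsFactors = FALSE))
  labels <- rep(c("A", "B"), each = 10)
  res <- find_markers(ds, labels)
  expect_identical(res$A$gene[1], "g05")
  expect_gt(res$A$log2fc[1], 1.5)
  expect_lt(res$A$fdr[1], 0.01)
  expect_false("g20" %in% res$A$gene)
  expect_warning(find_markers(ds, c(rep("A", 14), rep("B", 4),
                                    rep("C", 2))),
                 "skipped")
})

test_that("small-group Wilcoxon p-values equal exact enumeration", {
  # canonical case {1,2,3} vs {4,5,6}: p = 0.1
  ln <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
               dimnames = list("g1", paste0("c", 1:6)))
  ds <- manual_dataset(rbind(ln, g2 = c(2, 1, 3, 2, 1, 3)))
  res <- find_markers(ds, rep(c("A", "B"), each = 3),
                      fc_threshold = -Inf, fdr_threshold = Inf)
  expect_equal(res$A[res$A$gene == "g1", "p_value"], 0.1)
  expect_equal(wilcox_enum(1:3, 4:6), 0.1)
  # random instances, group sizes <= 6
  set.seed(21)
  for (rep in 1:5) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    vals <- matrix(sample(1:100, 3 * (n1 + n2)), 3)
    dimnames(vals) <- list(paste0("g", 1:3), paste0("c", seq_len(n1 + n2)))
    ds2 <- manual_dataset(vals / 10)
    labels <- c(rep("A", n1), rep("B", n2))
    res2 <- find_markers(ds2, labels, fc_threshold = -Inf,
                         fdr_threshold = Inf)
    for (g in paste0("g", 1:3)) {
      expect_equal(res2$A[res2$A$gene == g, "p_value"],
                   wilcox_enum(vals[g, labels == "A"] / 10,
                               vals[g, labels == "B"] / 10),
                   tolerance = 1e-12)
    }
  }
})

test_that("large-group Wilcoxon approximation matches stats::wilcox.test", {
  set.seed(33)
  ln <- matrix(rpois(5 * 60, 3) / 2, 5, 60,
               dimnames = list(paste0("g", 1:5), paste0("c", 1:60)))
  ds <- manual_dataset(ln)
  labels <- rep(c("A", "B"), each = 30)
  res <- find_markers(ds, labels, fc_threshold = -Inf, fdr_threshold = Inf)
  for (g in paste0("g", 1:5)) {
    ref <- suppressWarnings(
      wilcox.test(ln[g, 1:30], ln[g, 31:60], exact = FALSE))$p.value
    expect_equal(res$A[res$A$gene == g, "p_value"], ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment equals the brute-force step-up on short lists", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 0.9, 1)
  set.seed(14)
  for (len in 1:8) {
    for (rep in 1:10) {
      p <- sample(grid, len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  }
})

test_that("GSEA ES equals the naive running-sum oracle on small instances", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    scores <- setNames(rnorm(n), paste0("g", seq_len(n)))  # distinct scores
    set <- sample(names(scores), sample(2:(n - 2), 1))
    fit <- preranked_gsea(scores, set, n_perm = 50, seed = rep)
    expect_equal(fit$es, unname(gsea_oracle(scores, set)),
                 tolerance = 1e-12)
    # negation flips the ES sign, preserves magnitude
    neg <- preranked_gsea(-scores, set, n_perm = 50, seed = rep)
    expect_equal(abs(neg$es), abs(fit$es), tolerance = 1e-12)
  }
  # a set occupying the top ranks scores positive
  scores <- setNames(seq(3, 0.25, length.out = 12), paste0("g", 1:12))
  top <- preranked_gsea(scores, paste0("g", 1:4), n_perm = 100, seed = 2)
  expect_gt(top$es, 0)
})

test_that("GSEA is deterministic and validates its set", {
  scores <- setNames(rnorm(40), paste0("g", 1:40))
  a <- preranked_gsea(scores, paste0("g", 1:5), n_perm = 200, seed = 7)
  b <- preranked_gsea(scores, paste0("g", 1:5), n_perm = 200, seed = 7)
  expect_identical(a$nes, b$nes)
  expect_identical(a$p_value, b$p_value)
  expect_true(a$p_value > 0 && a$p_value <= 1)
  expect_lte(abs(a$es), 1)
  expect_error(preranked_gsea(scores, paste0("g", 1:40)), "all scored")
  expect_error(preranked_gsea(scores, c("x", "y")), "empty")
})
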